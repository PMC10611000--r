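#' Validate an annotation-pair table
#'
#' Each row pairs one image presentation's self-reported emotion set
#' (`user_labels`, non-empty) with the emotion set an algorithm detected
#' for the same presentation (`algo_labels`, possibly empty). Sets are
#' semicolon-joined emotion names; an optional `user` column identifies the
#' participant.
#'
#' @param pairs a data.frame with columns `image_id`, `user_labels`,
#'   `algo_labels` (and optionally `user`).
#' @return the table, invisibly.
#' @export
validate_pairs <- function(pairs) {
  missing <- setdiff(c("image_id", "user_labels", "algo_labels"), names(pairs))
  if (length(missing)) {
    stop("pair table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ul <- split_labels(pairs$user_labels)
  al <- split_labels(pairs$algo_labels)
  if (any(lengths(ul) == 0)) {
    stop("user_labels must be non-empty for every pair", call. = FALSE)
  }
  bad <- setdiff(unique(unlist(c(ul, al))), emotion_levels())
  if (length(bad)) {
    stop("unknown emotion: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(pairs)
}

#' Success rate of an algorithm against self-reports
#'
#' The fraction of presentations in which at least one of the user's
#' selected emotions and at least one of the algorithm's detections agree,
#' i.e. the two label sets intersect.
#'
#' @param pairs a validated pair table.
#' @return a number in \[0, 1\].
#' @examples
#' pairs <- data.frame(image_id = c("a", "b"),
#'                     user_labels = c("happy", "fear;surprise"),
#'                     algo_labels = c("happy;surprise", "sad"))
#' success_rate(pairs)  # 0.5
#' @export
success_rate <- function(pairs) {
  validate_pairs(pairs)
  if (nrow(pairs) == 0) stop("no pairs", call. = FALSE)
  ul <- split_labels(pairs$user_labels)
  al <- split_labels(pairs$algo_labels)
  hits <- mapply(function(u, a) length(intersect(u, a)) > 0, ul, al)
  mean(hits)
}

#' Per-emotion agreement metrics
#'
#' For each emotion, the pairs are reduced to a binary confusion matrix
#' with truth "the user selected the emotion" and prediction "the algorithm
#' detected it", scored with [metrics_from_confusion()]. Emotions no user
#' ever selected are reported with the zero-denominator convention and a
#' warning.
#'
#' @param pairs a validated pair table.
#' @return data.frame with one row per emotion: the four confusion counts
#'   and accuracy, precision, recall, specificity, f_score, g_mean.
#' @export
per_emotion_agreement <- function(pairs) {
  validate_pairs(pairs)
  if (nrow(pairs) == 0) stop("no pairs", call. = FALSE)
  ul <- split_labels(pairs$user_labels)
  al <- split_labels(pairs$algo_labels)
  rows <- lapply(emotion_levels(), function(em) {
    truth <- vapply(ul, function(s) em %in% s, logical(1))
    pred <- vapply(al, function(s) em %in% s, logical(1))
    if (!any(truth)) {
      warning("emotion '", em, "' absent from all user selections",
              call. = FALSE)
    }
    cm <- confusion_counts(as.integer(pred), as.integer(truth))
    cbind(data.frame(emotion = em, stringsAsFactors = FALSE),
          as.data.frame(t(cm)),
          as.data.frame(t(metrics_from_confusion(cm[["tp"]], cm[["fp"]],
                                                 cm[["tn"]], cm[["fn"]]))))
  })
  do.call(rbind, rows)
}

#' Full agreement report
#'
#' Combines the per-user success rates (when a `user` column is present;
#' otherwise the pooled rate) with the pooled per-emotion agreement
#' metrics.
#'
#' @param pairs a validated pair table.
#' @return an object of class `agreement_report`: list with `per_user`
#'   (named numeric vector of success rates), `mean_success_rate`,
#'   `per_emotion` (data.frame), `n_pairs`, `n_users`.
#' @export
agreement_report <- function(pairs) {
  validate_pairs(pairs)
  if (is.null(pairs$user)) pairs$user <- "all"
  per_user <- vapply(split(pairs, pairs$user), success_rate, numeric(1))
  structure(
    list(per_user = per_user,
         mean_success_rate = mean(per_user),
         per_emotion = per_emotion_agreement(pairs),
         n_pairs = nrow(pairs),
         n_users = length(per_user)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat(sprintf("Agreement over %d pairs from %d user(s)\n", x$n_pairs, x$n_users))
  cat(sprintf("Mean per-user success rate: %.1f%%\n",
              100 * x$mean_success_rate))
  tab <- x$per_emotion[c("emotion", "precision", "f_score", "g_mean")]
  tab[-1] <- lapply(tab[-1], round, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @rdname validate_pairs
#' @param path CSV file with columns `image_id,user_labels,algo_labels`
#'   (sets semicolon-joined, optional `user` column).
#' @export
read_pairs <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(image_id = "character"))
  tab$user_labels <- as.character(tab$user_labels)
  tab$algo_labels[is.na(tab$algo_labels)] <- ""
  tab$algo_labels <- as.character(tab$algo_labels)
  validate_pairs(tab)
  tab
}
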
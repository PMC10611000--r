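#' Encode and decode multi-label emotion selections
#'
#' Participant selections are stored as a 7-bit binary vector in the
#' canonical emotion order ([emotion_levels()]): a 1 for every selected
#' emotion, 0 elsewhere. At least one emotion must be selected, mirroring
#' the annotation interface, which only unlocks once a state is chosen.
#'
#' @param selected character vector (a non-empty subset of the seven
#'   emotions).
#' @param bits named or unnamed 0/1 vector of length 7 in canonical order.
#' @return `encode_labels()` returns a named integer 0/1 vector of length
#'   7; `decode_labels()` returns the character vector of set emotions.
#' @examples
#' encode_labels(c("fear", "surprise"))
#' decode_labels(encode_labels("happy"))
#' @export
encode_labels <- function(selected) {
  if (length(selected) == 0) {
    stop("at least one emotion required", call. = FALSE)
  }
  bad <- setdiff(selected, emotion_levels())
  if (length(bad)) {
    stop("unknown emotion: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bits <- as.integer(emotion_levels() %in% selected)
  names(bits) <- emotion_levels()
  bits
}

#' @rdname encode_labels
#' @export
decode_labels <- function(bits) {
  if (length(bits) != 7 || !all(bits %in% c(0, 1))) {
    stop("bits must be seven 0/1 values", call. = FALSE)
  }
  emotion_levels()[bits == 1]
}

feature_cols <- function() paste0("f", 0:43)

#' Validate a FeelPix-style sample table
#'
#' A sample table couples each observation's 44-value normalized landmark
#' feature vector (`f0..f43`) with its 7-bit self-reported emotion vector
#' (one 0/1 column per emotion in canonical order) plus optional metadata
#' columns (`subject`, `sex`, `age_band`, `glasses`).
#'
#' @param samples a data.frame.
#' @return the table, invisibly.
#' @export
validate_samples <- function(samples) {
  required <- c("sample_id", feature_cols(), emotion_levels())
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    stop("sample table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  labs <- as.matrix(samples[emotion_levels()])
  if (!all(labs %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (nrow(samples) && any(rowSums(labs) < 1)) {
    stop("every sample needs at least one selected emotion", call. = FALSE)
  }
  if (!all(is.finite(as.matrix(samples[feature_cols()])))) {
    stop("non-finite feature values", call. = FALSE)
  }
  invisible(samples)
}

#' Project a multi-label sample table to one emotion's binary task
#'
#' The seven-emotion recognition problem is decomposed into seven
#' independent binary problems: for a given emotion, class 1 means the
#' participant selected it and class 0 means they did not (whatever else
#' they selected). The feature matrix is shared across the seven tasks.
#'
#' @param samples a validated sample table.
#' @param emotion one of the seven emotions.
#' @return an object of class `binary_task`: list with `emotion`, `X`
#'   (numeric matrix) and `y` (integer 0/1 vector).
#' @export
binarize <- function(samples, emotion) {
  check_emotion(emotion)
  validate_samples(samples)
  if (nrow(samples) == 0) stop("empty sample table", call. = FALSE)
  structure(
    list(emotion = emotion,
         X = as.matrix(samples[feature_cols()]),
         y = as.integer(samples[[emotion]])),
    class = "binary_task"
  )
}

#' Rebalance a binary task by partial undersampling
#'
#' Selecting one emotion is much rarer than not selecting it, so the class-0
#' rows dominate. Rather than equalising the classes outright — the negative
#' rows span a wider variety of expressions than the positives — the
#' residual gap is set to half the minority count: every positive row is
#' kept and the negatives are reduced by seeded uniform sampling without
#' replacement to `n_pos + floor(n_pos / 2)` rows. If the negatives already
#' number at most that, the task is returned unchanged; likewise (with a
#' message) if class 1 is not the minority.
#'
#' @param task a `binary_task` with both classes present.
#' @param seed integer seed for the negative subsample.
#' @return the rebalanced `binary_task`.
#' @export
undersample <- function(task, seed = 1) {
  stopifnot(inherits(task, "binary_task"))
  n_pos <- sum(task$y == 1)
  n_neg <- sum(task$y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("cannot balance: task for '", task$emotion,
         "' has a class with zero rows", call. = FALSE)
  }
  if (n_pos > n_neg) {
    message("class 1 is not the minority for '", task$emotion,
            "'; task returned unchanged")
    return(task)
  }
  cap <- n_pos + n_pos %/% 2
  if (n_neg <= cap) return(task)
  keep_neg <- with_seed(seed, sample(which(task$y == 0), cap))
  keep <- sort(c(which(task$y == 1), keep_neg))
  task$X <- task$X[keep, , drop = FALSE]
  task$y <- task$y[keep]
  task
}

#' Read and write FeelPix-style sample tables
#'
#' Plain CSV with header `sample_id,f0..f43,anger,...,surprise` plus any
#' optional metadata columns. The reader validates each row and skips (with
#' a message) rows whose features are non-finite or whose label vector is
#' invalid; a header-only file yields an empty table.
#'
#' @param samples a validated sample table.
#' @param path file path.
#' @name feelpix_io
#' @export
write_feelpix <- function(samples, path) {
  validate_samples(samples)
  utils::write.csv(samples, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname feelpix_io
#' @export
read_feelpix <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character"))
  required <- c("sample_id", feature_cols(), emotion_levels())
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) return(tab)
  feats <- as.matrix(tab[feature_cols()])
  labs <- as.matrix(tab[emotion_levels()])
  ok <- apply(is.finite(feats), 1, all) &
    apply(labs == 0 | labs == 1, 1, all) &
    rowSums(labs) >= 1
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    message("skipping ", sum(!ok), " malformed row(s) in ", path)
  }
  tab[ok, , drop = FALSE]
}

#' Assemble a sample table from features and label selections
#'
#' Joins a feature table (`sample_id, f0..f43`, e.g. from
#' [frames_to_features()]) with a label table (`sample_id, labels` where
#' `labels` is a semicolon-joined non-empty emotion subset) into a
#' validated sample table. Extra columns in `labels_tab` are carried
#' through as metadata.
#'
#' @param features feature data.frame.
#' @param labels_tab label data.frame.
#' @return a validated sample table.
#' @export
build_samples <- function(features, labels_tab) {
  if (!all(features$sample_id %in% labels_tab$sample_id)) {
    stop("labels missing for some samples", call. = FALSE)
  }
  labels_tab <- labels_tab[match(features$sample_id, labels_tab$sample_id), ,
                           drop = FALSE]
  bits <- t(vapply(split_labels(labels_tab$labels), encode_labels,
                   integer(7)))
  out <- cbind(features, as.data.frame(bits),
               labels_tab[setdiff(names(labels_tab), c("sample_id", "labels"))])
  validate_samples(out)
  out
}
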
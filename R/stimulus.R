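#' Validate an affective image-ratings table
#'
#' A ratings table describes a set of candidate stimulus images with the
#' normative affective information used for stimulus selection: mean valence
#' and arousal on the 1-9 scale, the discrete basic-emotion labels assigned
#' by the norming study, and a 1-7 intensity value for each of the six basic
#' emotions.
#'
#' @param table a data.frame with columns `image_id`, `category`,
#'   `valence_mean`, `arousal_mean`, `labels` (semicolon-joined subset of the
#'   six basic emotion names) and `int_anger`, `int_disgust`, `int_fear`,
#'   `int_happy`, `int_sad`, `int_surprise`.
#' @return the table, invisibly, after validation.
#' @export
validate_ratings <- function(table) {
  required <- c("image_id", "valence_mean", "arousal_mean", "labels",
                paste0("int_", basic_emotions()))
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    stop("ratings table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table$image_id)) {
    stop("duplicate image_id in ratings table", call. = FALSE)
  }
  va <- c(table$valence_mean, table$arousal_mean)
  if (anyNA(va) || any(!is.finite(va))) {
    stop("non-finite valence/arousal ratings", call. = FALSE)
  }
  if (any(va < 1 | va > 9)) {
    stop("valence/arousal outside [1, 9]", call. = FALSE)
  }
  ints <- as.matrix(table[paste0("int_", basic_emotions())])
  if (anyNA(ints) || any(ints < 1 | ints > 7)) {
    stop("intensity values must lie in [1, 7]", call. = FALSE)
  }
  known <- unique(unlist(split_labels(table$labels)))
  bad <- setdiff(known, basic_emotions())
  if (length(bad)) {
    stop("unknown discrete labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(table)
}

#' Cluster images in the valence-arousal plane
#'
#' Runs seeded Lloyd's k-means on the (valence, arousal) coordinates of a
#' ratings table. Both axes share the 1-9 scale, so no feature scaling is
#' applied. Each restart draws its initial centroids uniformly from the
#' distinct observed rating points and runs until assignments stabilise (at
#' most 300 iterations); the best of `n_start` seeded restarts (lowest
#' total within-cluster sum of squares) is returned, guarding against the
#' split/merge local optima a single Lloyd start can fall into.
#'
#' @param table a validated ratings table.
#' @param k number of clusters (default 3: negative / neutral / positive).
#' @param seed integer seed for the centroid initialisation.
#' @param n_start number of seeded restarts (default 10).
#' @return an object of class `cluster_model`: a list with elements `k`,
#'   `assignment` (named integer vector, image_id -> cluster index),
#'   `centroids` (k x 2 matrix) and `labels` (filled by
#'   [label_clusters()]).
#' @seealso [label_clusters()], [build_stimulus_set()]
#' @export
cluster_images <- function(table, k = 3, seed = 1, n_start = 10) {
  validate_ratings(table)
  n <- nrow(table)
  if (n == 0) stop("insufficient data: empty ratings table", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (k > n) stop("insufficient data: fewer images than clusters", call. = FALSE)
  x <- cbind(valence = table$valence_mean, arousal = table$arousal_mean)
  pts <- unique(x)
  if (nrow(pts) < k) {
    stop("insufficient data: fewer distinct rating points than clusters",
         call. = FALSE)
  }
  fit <- with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_start)) {
      centers <- pts[sample.int(nrow(pts), k), , drop = FALSE]
      cand <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 300,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)  # e.g. a restart that empties a cluster
      if (!is.null(cand) &&
          (is.null(best) || cand$tot.withinss < best$tot.withinss)) best <- cand
    }
    if (is.null(best)) stop("empty cluster produced by k-means", call. = FALSE)
    best
  })
  assignment <- as.integer(fit$cluster)
  names(assignment) <- table$image_id
  if (length(unique(assignment)) < k) {
    stop("empty cluster produced by k-means", call. = FALSE)
  }
  structure(
    list(k = as.integer(k), assignment = assignment,
         centroids = unname(fit$centers), labels = NULL),
    class = "cluster_model"
  )
}

# Valence band of a scalar valence: negative [1,4), neutral [4,6),
# positive [6,9]. Half-open bands make the mapping single-valued.
valence_band <- function(v) {
  ifelse(v < 4, "negative", ifelse(v < 6, "neutral", "positive"))
}

#' Label clusters as negative, neutral or positive
#'
#' Each cluster receives the macro label of the valence band that contains
#' the majority of its member images, using the half-open bands
#' negative \eqn{[1,4)}, neutral \eqn{[4,6)}, positive \eqn{[6,9]}. Ties are
#' broken by the band containing the cluster's mean valence, then by the
#' fixed band order negative < neutral < positive.
#'
#' @param model a `cluster_model` from [cluster_images()].
#' @param table the ratings table the model was fit on.
#' @return the model with its `labels` element filled (character vector of
#'   length `k`).
#' @export
label_clusters <- function(model, table) {
  stopifnot(inherits(model, "cluster_model"))
  if (!all(table$image_id %in% names(model$assignment))) {
    stop("cluster assignment does not cover the table", call. = FALSE)
  }
  bands <- c("negative", "neutral", "positive")
  labels <- character(model$k)
  for (ci in seq_len(model$k)) {
    ids <- names(model$assignment)[model$assignment == ci]
    member <- table$image_id %in% ids
    if (!any(member)) stop("empty cluster ", ci, call. = FALSE)
    v <- table$valence_mean[member]
    counts <- table(factor(valence_band(v), levels = bands))
    best <- bands[counts == max(counts)]
    if (length(best) > 1) {
      mean_band <- valence_band(mean(v))
      best <- if (mean_band %in% best) mean_band else best[1]
    }
    labels[ci] <- best
  }
  model$labels <- labels
  model
}

#' Remove excessively disturbing images
#'
#' Images whose normed disgust intensity exceeds the threshold are dropped
#' before any per-emotion search, so that selected stimuli do not shock
#' participants. The cut is strict: intensity exactly at the threshold is
#' kept.
#'
#' @param table a validated ratings table.
#' @param threshold disgust-intensity cutoff (default 4).
#' @return the subtable with `int_disgust <= threshold`.
#' @export
prescreen <- function(table, threshold = 4) {
  validate_ratings(table)
  table[table$int_disgust <= threshold, , drop = FALSE]
}

#' Default emotion-to-cluster search map
#'
#' Where in the valence-arousal plane to search for images carrying each
#' discrete emotion: anger, disgust, fear and sad in the negative cluster,
#' happy in the positive cluster, neutral in the neutral cluster, and
#' surprise — which carries both positive and negative components — in all
#' three.
#'
#' @return a named list mapping each of the seven emotions to a character
#'   vector of macro cluster labels.
#' @export
emotion_cluster_map <- function() {
  list(
    anger    = "negative",
    disgust  = "negative",
    fear     = "negative",
    sad      = "negative",
    happy    = "positive",
    neutral  = "neutral",
    surprise = c("negative", "neutral", "positive")
  )
}

cluster_label_of <- function(model, ids) {
  model$labels[model$assignment[ids]]
}

#' Select the most intense images for one basic emotion
#'
#' Candidates are the images that (a) fall in a cluster whose macro label is
#' a search target for the emotion and (b) carry the emotion among their
#' discrete labels. Candidates are ranked by the emotion's intensity in
#' descending order (ties broken by `image_id` ascending) and the top `n`
#' are returned.
#'
#' @param table a pre-screened ratings table.
#' @param emotion one of the six basic emotions.
#' @param model a labelled `cluster_model`.
#' @param map emotion-to-cluster map (default [emotion_cluster_map()]).
#' @param n number of images to select (default 10).
#' @return character vector of `n` image ids, intensity-descending.
#' @export
select_for_emotion <- function(table, emotion, model, map = emotion_cluster_map(),
                               n = 10) {
  check_emotion(emotion, allow_neutral = FALSE)
  if (n == 0) return(character(0))
  if (is.null(model$labels)) stop("cluster model is unlabelled", call. = FALSE)
  targets <- map[[emotion]]
  in_cluster <- cluster_label_of(model, table$image_id) %in% targets
  has_lab <- vapply(split_labels(table$labels), function(l) emotion %in% l,
                    logical(1))
  cand <- table[in_cluster & has_lab, , drop = FALSE]
  if (nrow(cand) < n) {
    stop("insufficient candidates for emotion '", emotion, "' (",
         nrow(cand), " < ", n, ")", call. = FALSE)
  }
  intensity <- cand[[paste0("int_", emotion)]]
  ord <- order(-intensity, cand$image_id)
  cand$image_id[ord][seq_len(n)]
}

#' Select the calmest fully-labelled images as neutral stimuli
#'
#' Neutral stimuli have no intensity norms of their own, so the neutral pool
#' is built from images in neutral-labelled clusters to which the norming
#' study assigned all six basic-emotion labels; these are sorted by arousal
#' ascending (ties by `image_id`) and the `n` lowest-arousal images are
#' returned.
#'
#' @inheritParams select_for_emotion
#' @return character vector of `n` image ids, arousal-ascending.
#' @export
select_neutral <- function(table, model, n = 10) {
  if (n == 0) return(character(0))
  if (is.null(model$labels)) stop("cluster model is unlabelled", call. = FALSE)
  in_cluster <- cluster_label_of(model, table$image_id) == "neutral"
  all_six <- vapply(split_labels(table$labels),
                    function(l) all(basic_emotions() %in% l), logical(1))
  cand <- table[in_cluster & all_six, , drop = FALSE]
  if (nrow(cand) < n) {
    stop("insufficient candidates for emotion 'neutral' (",
         nrow(cand), " < ", n, ")", call. = FALSE)
  }
  ord <- order(cand$arousal_mean, cand$image_id)
  cand$image_id[ord][seq_len(n)]
}

#' Build the full seven-group stimulus set
#'
#' Runs the whole selection procedure: disgust pre-screen, k-means
#' clustering (k = 3) with macro labelling, then group selection in the
#' fixed processing order neutral, happy, anger, fear, sad, disgust,
#' surprise. Images picked by an earlier group are removed from later
#' candidate pools, so the seven groups are disjoint and, at the default
#' group size of 10, the set holds 70 unique images.
#'
#' @param table a validated ratings table.
#' @param seed integer seed (clustering initialisation).
#' @param n_per_group images per emotion group (default 10).
#' @return an object of class `stimulus_set`: list with `groups` (named list
#'   of image-id vectors in the canonical emotion order) and `group_size`.
#' @examples
#' tab <- generate_ratings(generator_config(seed = 1, n_images = 700))
#' set <- build_stimulus_set(tab, seed = 1)
#' lengths(set$groups)
#' @export
build_stimulus_set <- function(table, seed = 1, n_per_group = 10) {
  table <- prescreen(table)
  model <- label_clusters(cluster_images(table, k = 3, seed = seed), table)
  order_ <- c("neutral", "happy", "anger", "fear", "sad", "disgust", "surprise")
  groups <- vector("list", length(order_))
  names(groups) <- order_
  remaining <- table
  for (em in order_) {
    picked <- if (em == "neutral") {
      select_neutral(remaining, model, n = n_per_group)
    } else {
      select_for_emotion(remaining, em, model, n = n_per_group)
    }
    groups[[em]] <- picked
    remaining <- remaining[!remaining$image_id %in% picked, , drop = FALSE]
  }
  structure(
    list(groups = groups[emotion_levels()], group_size = as.integer(n_per_group)),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("Stimulus set:", length(x$groups), "emotion groups x",
      x$group_size, "images\n")
  for (em in names(x$groups)) {
    cat(sprintf("  %-8s %s\n", em, paste(x$groups[[em]], collapse = " ")))
  }
  invisible(x)
}

# Randomised backtracking arrangement of group tags with no two equal
# neighbours. Items is a character vector of group tags.
arrange_no_repeat <- function(tags) {
  n <- length(tags)
  counts <- table(tags)
  if (max(counts) > ceiling(n / 2)) {
    stop("infeasible arrangement: one group holds more than half the slots",
         call. = FALSE)
  }
  groups <- names(counts)
  counts <- as.integer(counts)
  out <- character(n)
  solve <- function(pos, counts, prev) {
    if (pos > n) return(TRUE)
    cand <- which(counts > 0 & groups != prev)
    for (gi in cand[sample.int(length(cand))]) {
      # prune: a group needing more than half the remaining slots must go now
      rem <- n - pos
      counts2 <- counts
      counts2[gi] <- counts2[gi] - 1L
      if (max(c(counts2, 0L)) <= ceiling(rem / 2)) {
        out[pos] <<- groups[gi]
        if (solve(pos + 1L, counts2, groups[gi])) return(TRUE)
      }
    }
    FALSE
  }
  if (!solve(1L, counts, "")) {
    stop("infeasible arrangement", call. = FALSE)
  }
  out
}

#' Sample one randomized presentation session from a stimulus set
#'
#' Draws `per_emotion` images uniformly (without replacement) from each of
#' the seven groups and arranges the 7 x `per_emotion` items in a random
#' order in which no two consecutive items come from the same emotion group,
#' using randomized placement with backtracking. At the default of five per
#' emotion the arrangement always exists.
#'
#' @param set a `stimulus_set`.
#' @param per_emotion images drawn per group (default 5).
#' @param seed integer seed.
#' @return an object of class `session`: a data.frame with columns
#'   `image_id` and `emotion` giving the presentation order.
#' @export
sample_session <- function(set, per_emotion = 5, seed = 1) {
  stopifnot(inherits(set, "stimulus_set"))
  short <- names(set$groups)[lengths(set$groups) < per_emotion]
  if (length(short)) {
    stop("groups smaller than per_emotion: ", paste(short, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    chosen <- lapply(set$groups, function(ids) sample(ids, per_emotion))
    tags <- rep(names(chosen), each = per_emotion)
    order_tags <- arrange_no_repeat(tags)
    # pop ids from each group's (already shuffled) draw in arranged order
    queues <- chosen
    ids <- character(length(order_tags))
    for (i in seq_along(order_tags)) {
      g <- order_tags[i]
      ids[i] <- queues[[g]][1]
      queues[[g]] <- queues[[g]][-1]
    }
    structure(
      data.frame(image_id = ids, emotion = order_tags,
                 stringsAsFactors = FALSE),
      class = c("session", "data.frame")
    )
  })
}

#' Read and write ratings tables and stimulus sets
#'
#' Ratings tables travel as plain CSV with the documented column layout;
#' stimulus sets and sessions as JSON documents keyed by emotion name.
#'
#' @param path file path.
#' @param table a ratings table.
#' @param set a `stimulus_set`.
#' @name stimulus_io
#' @export
read_ratings <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(image_id = "character"))
  validate_ratings(tab)
  tab
}

#' @rdname stimulus_io
#' @export
write_ratings <- function(table, path) {
  validate_ratings(table)
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname stimulus_io
#' @export
write_stimulus_set <- function(set, path) {
  stopifnot(inherits(set, "stimulus_set"))
  jsonlite::write_json(
    list(group_size = set$group_size, groups = set$groups),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname stimulus_io
#' @export
read_stimulus_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(doc$groups, as.character)
  structure(
    list(groups = groups[emotion_levels()],
         group_size = as.integer(doc$group_size)),
    class = "stimulus_set"
  )
}
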
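# Small fixtures built in code.

# A minimal valid ratings table: one row per (valence, arousal) pair with
# the given labels (semicolon strings) and flat intensities, overridable
# per column afterwards.
tiny_ratings <- function(valence, arousal = rep(5, length(valence)),
                         labels = rep("happy", length(valence)),
                         intensity = 2) {
  n <- length(valence)
  tab <- data.frame(
    image_id = sprintf("t%03d", seq_len(n)),
    category = "objects",
    valence_mean = valence, arousal_mean = arousal,
    labels = labels, stringsAsFactors = FALSE
  )
  for (em in basic_emotions()) tab[[paste0("int_", em)]] <- rep(intensity, n)
  tab
}

# A labelled cluster model that puts every image in one cluster with a
# chosen macro label (bypasses k-means for selection-rule tests).
manual_model <- function(table, label = "negative") {
  assignment <- rep(1L, nrow(table))
  names(assignment) <- table$image_id
  structure(
    list(k = 1L, assignment = assignment,
         centroids = matrix(c(5, 5), 1), labels = label),
    class = "cluster_model"
  )
}

# A random raw landmark frame guaranteed non-degenerate for the default
# anchors: template face plus bounded uniform perturbation.
random_frame <- function(max_jitter = 0.2) {
  pts <- face_template()$points +
    matrix(stats::runif(136, -max_jitter, max_jitter), 68, 2)
  landmark_frame(pts)
}

# A synthetic binary task with the requested class counts; features are
# standard-normal and carry a class shift so both classes are non-trivial.
random_task <- function(n_pos, n_neg, emotion = "happy", shift = 0) {
  n <- n_pos + n_neg
  X <- matrix(stats::rnorm(n * 44), n, 44)
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  X[y == 1, ] <- X[y == 1, ] + shift
  structure(list(emotion = emotion, X = X, y = y), class = "binary_task")
}

# Small sample table with the given per-row label sets.
tiny_samples <- function(label_sets) {
  n <- length(label_sets)
  feats <- matrix(stats::rnorm(n * 44), n, 44)
  tab <- data.frame(sample_id = sprintf("s%03d", seq_len(n)), feats,
                    stringsAsFactors = FALSE)
  names(tab) <- c("sample_id", paste0("f", 0:43))
  bits <- t(vapply(label_sets, encode_labels, integer(7)))
  cbind(tab, as.data.frame(bits))
}
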
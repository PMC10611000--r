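#' Synthetic-data generator configuration
#'
#' Bundles every knob of the synthetic study-data generator. The defaults
#' describe the emulated study conditions: three rating clusters at the
#' macro centroids of the valence-arousal plane (negative (2.7, 6.9),
#' neutral (5.0, 3.0), positive (8.0, 6.9)) with spread 0.3; 31 subjects
#' annotating 35 presentations each; per-coordinate landmark noise of 5%
#' of the unit anchor distances (the order of a real landmark detector's
#' jitter), putting the default expression signal-to-noise ratio at 20,
#' well inside the separable regime; camera jitter of up to
#' 50 px translation and 0.8-1.2x per-axis scale at a 100 px face scale;
#' and a 25% chance that a sample carries a second emotion label.
#'
#' @param seed integer seed.
#' @param n_images number of images in the generated ratings table.
#' @param cluster_centroids 3 x 2 matrix of (valence, arousal) centroids.
#' @param cluster_sd rating spread around each centroid.
#' @param n_subjects,images_per_subject landmark-sample layout.
#' @param expression_strength multiplier on the per-emotion displacement
#'   prototypes (face units; 0 removes all expression signal).
#' @param noise_sd per-coordinate Gaussian landmark noise (face units).
#' @param jitter_translation max absolute random frame translation (px).
#' @param jitter_scale range of the random per-axis scale factor.
#' @param pixel_scale face units to pixels conversion.
#' @param multi_label_rate probability of a second emotion per sample.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             n_images = 700,
                             cluster_centroids = rbind(
                               negative = c(2.7, 6.9),
                               neutral = c(5.0, 3.0),
                               positive = c(8.0, 6.9)),
                             cluster_sd = 0.3,
                             n_subjects = 31,
                             images_per_subject = 35,
                             expression_strength = 1,
                             noise_sd = 0.05,
                             jitter_translation = 50,
                             jitter_scale = c(0.8, 1.2),
                             pixel_scale = 100,
                             multi_label_rate = 0.25) {
  stopifnot(cluster_sd >= 0, noise_sd >= 0, expression_strength >= 0,
            multi_label_rate >= 0, multi_label_rate <= 1,
            jitter_scale[1] > 0, jitter_scale[1] <= jitter_scale[2])
  structure(
    list(seed = as.integer(seed), n_images = as.integer(n_images),
         cluster_centroids = cluster_centroids, cluster_sd = cluster_sd,
         n_subjects = as.integer(n_subjects),
         images_per_subject = as.integer(images_per_subject),
         expression_strength = expression_strength, noise_sd = noise_sd,
         jitter_translation = jitter_translation, jitter_scale = jitter_scale,
         pixel_scale = pixel_scale, multi_label_rate = multi_label_rate),
    class = "generator_config"
  )
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic affective ratings table
#'
#' Emulates the normed image table that stimulus selection consumes:
#' images are spread evenly over the three macro clusters, with valence and
#' arousal drawn around the configured centroids (clipped to \[1, 9\]) and
#' discrete labels plus \[1, 7\] intensities assigned consistently with the
#' generating cluster. Negative-cluster images cycle through
#' anger/fear/sad/disgust/surprise dominants; disgust dominants stay at or
#' below the pre-screen threshold while a dedicated filler role in the
#' neutral cluster carries disgust intensities above it, so the pre-screen
#' has work to do. A share of neutral-cluster images receives all six basic
#' labels at low intensity (the neutral-candidate pool) and each cluster
#' contains surprise dominants, so every emotion group can be filled when
#' `n_images` is a few hundred or more.
#'
#' @param config a [generator_config()].
#' @return a validated ratings table (data.frame).
#' @export
generate_ratings <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_images
  roles <- list(
    negative = c("anger", "fear", "sad", "disgust", "surprise"),
    neutral = c("neutral_all6", "surprise", "shock_filler"),
    positive = c("happy", "surprise", "filler")
  )
  categories <- c("people", "faces", "animals", "objects", "landscapes")
  with_seed(config$seed, {
    cluster <- rep_len(rownames(config$cluster_centroids), n)
    role <- character(n)
    for (cl in names(roles)) {
      idx <- which(cluster == cl)
      role[idx] <- rep_len(roles[[cl]], length(idx))
    }
    valence <- clip(stats::rnorm(n, config$cluster_centroids[cluster, 1],
                                 config$cluster_sd), 1, 9)
    arousal <- clip(stats::rnorm(n, config$cluster_centroids[cluster, 2],
                                 config$cluster_sd), 1, 9)
    ints <- matrix(stats::runif(n * 6, 1, 3), nrow = n,
                   dimnames = list(NULL, basic_emotions()))
    labels <- character(n)
    for (i in seq_len(n)) {
      r <- role[i]
      if (r == "neutral_all6") {
        labels[i] <- paste(basic_emotions(), collapse = ";")
        ints[i, ] <- stats::runif(6, 1, 2.5)
      } else if (r == "shock_filler") {
        labels[i] <- sample(basic_emotions(), 1)
        ints[i, "disgust"] <- stats::runif(1, 4.5, 6.5)
      } else if (r == "filler") {
        labels[i] <- sample(basic_emotions(), 1)
      } else if (r == "disgust") {
        labels[i] <- "disgust"
        ints[i, "disgust"] <- stats::runif(1, 3, 4)
      } else {
        labels[i] <- r
        ints[i, r] <- stats::runif(1, 5, 7)
      }
    }
    tab <- data.frame(
      image_id = sprintf("img%04d", seq_len(n)),
      category = sample(categories, n, replace = TRUE),
      valence_mean = valence, arousal_mean = arousal,
      labels = labels, stringsAsFactors = FALSE
    )
    for (em in basic_emotions()) tab[[paste0("int_", em)]] <- ints[, em]
    validate_ratings(tab)
    tab
  })
}

#' Canonical face template and expression displacement prototypes
#'
#' A schematic neutral 68-point face in "face units": the nasal center sits
#' at the origin, the left and right lateral anchors at (-1, 0) and (1, 0),
#' the subnasal center at (0, 1), and y grows downward as in image
#' coordinates, so all four anchor distances are exactly 1. Each emotion has
#' a 68 x 2 displacement prototype motivated by the action units typical of
#' that expression — brow raise and jaw drop for surprise, mouth-corner
#' raise for happy, brow lowering and lip press for anger, inner-brow raise
#' and lip-corner depression for sad, nose wrinkle and upper-lip raise for
#' disgust, brow raise with widened eyes and parted lips for fear, and the
#' zero field for neutral. The four anchors are displaced by no prototype:
#' anchor positions are taken to be unaffected by expression.
#'
#' @return list with `points` (68 x 2 matrix, the neutral face) and
#'   `displacements` (named list of seven 68 x 2 matrices).
#' @export
face_template <- function() {
  pts <- matrix(0, nrow = 68, ncol = 2, dimnames = list(NULL, c("x", "y")))
  theta <- seq(0, pi, length.out = 17)
  pts[1:17, ] <- cbind(-cos(theta), 2.2 * sin(theta))            # jaw
  bx <- seq(-0.85, -0.2, length.out = 5)
  by <- -0.55 - 0.1 * sin(seq(0, pi, length.out = 5))
  pts[18:22, ] <- cbind(bx, by)                                  # left brow
  pts[23:27, ] <- cbind(rev(-bx), by)                            # right brow
  pts[28:31, ] <- cbind(0, c(0, 0.33, 0.66, 0.85))               # nose bridge
  pts[32:36, ] <- cbind(c(-0.25, -0.12, 0, 0.12, 0.25),
                        c(1.05, 1.08, 1.0, 1.08, 1.05))          # nose base
  pts[37:42, ] <- cbind(c(-0.65, -0.55, -0.35, -0.25, -0.35, -0.55),
                        c(-0.15, -0.22, -0.22, -0.15, -0.08, -0.08))
  pts[43:48, ] <- cbind(c(0.25, 0.35, 0.55, 0.65, 0.55, 0.35),
                        c(-0.15, -0.22, -0.22, -0.15, -0.08, -0.08))
  pts[49, ] <- c(-0.5, 1.6)                                      # mouth
  pts[50:54, ] <- cbind(c(-0.33, -0.17, 0, 0.17, 0.33),
                        c(1.47, 1.42, 1.44, 1.42, 1.47))
  pts[55, ] <- c(0.5, 1.6)
  pts[56:60, ] <- cbind(c(0.33, 0.17, 0, -0.17, -0.33),
                        c(1.73, 1.78, 1.80, 1.78, 1.73))
  pts[61, ] <- c(-0.4, 1.6)
  pts[62:64, ] <- cbind(c(-0.15, 0, 0.15), c(1.52, 1.50, 1.52))
  pts[65, ] <- c(0.4, 1.6)
  pts[66:68, ] <- cbind(c(0.15, 0, -0.15), c(1.68, 1.70, 1.68))

  zero <- matrix(0, 68, 2)
  disp <- list()
  d <- zero
  d[c(49, 55, 61, 65), 2] <- -0.25                 # mouth corners up
  d[c(49, 61), 1] <- -0.12; d[c(55, 65), 1] <- 0.12  # and outward
  d[c(41, 42, 47, 48), 2] <- -0.08                 # cheek raise lifts lower lids
  disp$happy <- d
  d <- zero
  d[c(49, 55, 61, 65), 2] <- 0.25                  # lip-corner depressor
  d[c(21, 22, 23, 24), 2] <- -0.2                  # inner brow raise
  disp$sad <- d
  d <- zero
  d[18:27, 2] <- 0.15                              # brow lowerer
  d[c(21, 22, 23, 24), 2] <- 0.25
  d[18:22, 1] <- 0.08; d[23:27, 1] <- -0.08        # brows drawn together
  d[49, 1] <- 0.12; d[55, 1] <- -0.12              # lip press narrows mouth
  d[62:64, 2] <- 0.05; d[66:68, 2] <- -0.05
  disp$anger <- d
  d <- zero
  d[18:27, 2] <- -0.2                              # brow raise
  d[c(38, 39, 44, 45), 2] <- -0.08                 # eye widening
  d[c(41, 42, 47, 48), 2] <- 0.08
  d[56:60, 2] <- 0.2; d[66:68, 2] <- 0.15          # lips part
  d[c(49, 61), 1] <- -0.2; d[c(55, 65), 1] <- 0.2  # lip stretcher
  disp$fear <- d
  d <- zero
  d[18:27, 2] <- -0.3                              # strong brow raise
  d[c(38, 39, 44, 45), 2] <- -0.1
  d[c(41, 42, 47, 48), 2] <- 0.1
  d[56:60, 2] <- 0.4; d[66:68, 2] <- 0.35          # jaw drop opens mouth
  d[c(49, 61), 1] <- 0.15; d[c(55, 65), 1] <- -0.15  # rounded open mouth
  d[6:12, 2] <- 0.25
  disp$surprise <- d
  d <- zero
  d[c(32, 36), 2] <- -0.12                         # nose wrinkler
  d[c(33, 35), 2] <- -0.1
  d[29:31, 2] <- -0.05
  d[50:54, 2] <- -0.15; d[62:64, 2] <- -0.12       # upper lip raise
  d[18:27, 2] <- 0.1                               # slight brow lower
  disp$disgust <- d
  disp$neutral <- zero

  anchors <- c(1, 17, 28, 34)
  for (em in names(disp)) disp[[em]][anchors, ] <- 0
  list(points = pts, displacements = disp[emotion_levels()])
}

#' Generate synthetic landmark frames with known emotion labels
#'
#' Emulates the raw per-presentation landmark captures: for each of
#' `n_subjects * images_per_subject` samples an emotion is drawn uniformly
#' (a second one is added with probability `multi_label_rate`), the face
#' template is displaced by `expression_strength` times the summed
#' prototypes (neutrality, being the absence of a felt emotion, never
#' co-occurs with a second label), per-coordinate Gaussian noise of sd
#' `noise_sd` is added, and
#' the frame is mapped to pixel coordinates with a random per-axis scale
#' and translation (the camera jitter that anchor normalization must
#' remove). Noise is drawn before the jitter parameters, so two configs
#' differing only in jitter produce identical faces under the same seed.
#'
#' @param config a [generator_config()].
#' @return list with `frames` (data.frame `sample_id, x0, y0, ..., x67,
#'   y67`), `labels` (data.frame `sample_id, labels, subject, sex,
#'   age_band, glasses`) and `truth` (per-sample generating emotions plus
#'   the config).
#' @export
generate_landmarks <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  tmpl <- face_template()
  n <- config$n_subjects * config$images_per_subject
  with_seed(config$seed, {
    subj <- rep(sprintf("s%02d", seq_len(config$n_subjects)),
                each = config$images_per_subject)
    sex <- sample(c("F", "M"), config$n_subjects, replace = TRUE)
    age <- sample(c("20-29", "30-39", "40-49", "50-59", "60-69"),
                  config$n_subjects, replace = TRUE)
    glasses <- sample(c(0L, 1L), config$n_subjects, replace = TRUE)
    coords <- matrix(0, nrow = n, ncol = 136)
    emos <- vector("list", n)
    for (i in seq_len(n)) {
      e1 <- sample(emotion_levels(), 1)
      chosen <- e1
      # neutrality never co-occurs with a felt emotion: a second label is
      # only added to (and drawn from) the six basic emotions
      if (e1 != "neutral" && stats::runif(1) < config$multi_label_rate) {
        chosen <- c(e1, sample(setdiff(basic_emotions(), e1), 1))
      }
      field <- Reduce(`+`, tmpl$displacements[chosen])
      p <- tmpl$points + config$expression_strength * field +
        matrix(stats::rnorm(136, 0, config$noise_sd), 68, 2)
      # unit uniforms scaled by hand so the RNG stream is identical
      # whatever the jitter ranges (runif consumes nothing on degenerate
      # ranges)
      u <- stats::runif(4)
      js <- config$jitter_scale
      sx <- config$pixel_scale * (js[1] + u[1] * (js[2] - js[1]))
      sy <- config$pixel_scale * (js[1] + u[2] * (js[2] - js[1]))
      tx <- 320 + (2 * u[3] - 1) * config$jitter_translation
      ty <- 240 + (2 * u[4] - 1) * config$jitter_translation
      px <- cbind(sx * p[, 1] + tx, sy * p[, 2] + ty)
      coords[i, ] <- as.vector(t(px))
      emos[[i]] <- sort(chosen)
    }
    frames <- data.frame(sample_id = sprintf("smp%05d", seq_len(n)), coords,
                         stringsAsFactors = FALSE)
    names(frames) <- c("sample_id",
                       paste0(c("x", "y"), rep(0:67, each = 2)))
    subj_idx <- match(subj, sprintf("s%02d", seq_len(config$n_subjects)))
    labels <- data.frame(
      sample_id = frames$sample_id,
      labels = join_labels(emos),
      subject = subj, sex = sex[subj_idx], age_band = age[subj_idx],
      glasses = glasses[subj_idx], stringsAsFactors = FALSE
    )
    list(frames = frames, labels = labels,
         truth = list(emotions = stats::setNames(emos, frames$sample_id),
                      config = config))
  })
}
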
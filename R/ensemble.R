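#' Hyperparameter search spaces for the two classifier families
#'
#' Random-search distributions for the support-vector-machine and
#' random-forest families. SVM draws cost log-uniformly on
#' \[1e-2, 1e3\], a kernel uniformly from \{linear, radial\}, and the radial
#' kernel width log-uniformly on \[1e-4, 10\]. RF draws the number of trees
#' uniformly on \[50, 500\], a maximum depth from \{unlimited, 2..20\}
#' (0 encodes unlimited) and a minimum node size on \[2, 10\].
#'
#' @param family `"svm"` or `"rf"`.
#' @return a list describing the distributions (consumed by
#'   [random_search()]).
#' @export
hyperparameter_space <- function(family = c("svm", "rf")) {
  family <- match.arg(family)
  if (family == "svm") {
    list(family = "svm",
         log10_cost = c(-2, 3),
         kernel = c("linear", "radial"),
         log10_gamma = c(-4, 1))
  } else {
    list(family = "rf",
         num_trees = c(50L, 500L),
         max_depth = c(0L, 2:20),
         min_node = c(2L, 10L))
  }
}

draw_params <- function(space) {
  if (space$family == "svm") {
    list(
      kernel = sample(space$kernel, 1),
      cost = 10^stats::runif(1, space$log10_cost[1], space$log10_cost[2]),
      gamma = 10^stats::runif(1, space$log10_gamma[1], space$log10_gamma[2])
    )
  } else {
    list(
      num_trees = sample(space$num_trees[1]:space$num_trees[2], 1),
      max_depth = sample(space$max_depth, 1),
      min_node = sample(space$min_node[1]:space$min_node[2], 1)
    )
  }
}

fit_binary <- function(family, params, X, y, seed = 1) {
  y <- factor(y, levels = c(0, 1))
  if (family == "svm") {
    e1071::svm(x = X, y = y, kernel = params$kernel, cost = params$cost,
               gamma = params$gamma, scale = FALSE)
  } else {
    ranger::ranger(
      x = as.data.frame(X), y = y,
      num.trees = params$num_trees,
      max.depth = params$max_depth,
      min.node.size = params$min_node,
      num.threads = 1, seed = seed
    )
  }
}

predict_binary <- function(model, X) {
  if (inherits(model, "ranger")) {
    as.integer(as.character(
      stats::predict(model, data = as.data.frame(X), num.threads = 1)$predictions
    ))
  } else {
    as.integer(as.character(stats::predict(model, X)))
  }
}

# Seeded stratified k-fold assignment: integer fold id per row.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validate one classifier configuration on a binary task
#'
#' Seeded stratified k-fold cross-validation: each fold's held-out
#' confusion matrix is scored with [metrics_from_confusion()] and the
#' report carries the per-fold values together with their arithmetic mean.
#'
#' @param task a `binary_task` (see [binarize()], usually after
#'   [undersample()]).
#' @param family `"svm"` or `"rf"`.
#' @param params parameter list for the family (as drawn by
#'   [random_search()]).
#' @param k number of folds (default 5); both classes must have at least
#'   `k` members.
#' @param seed integer seed (fold assignment and RF tree growth).
#' @return an object of class `cv_report`: list with `emotion`, `family`,
#'   `params`, `per_fold` (data.frame of per-fold metrics), `mean` (named
#'   vector), `n_folds`, `seed`.
#' @export
cross_validate <- function(task, family = c("svm", "rf"), params, k = 5,
                           seed = 1) {
  stopifnot(inherits(task, "binary_task"))
  family <- match.arg(family)
  counts <- table(factor(task$y, levels = c(0, 1)))
  if (any(counts < k)) {
    stop("each class needs at least k = ", k, " rows (have ",
         paste(counts, collapse = "/"), ")", call. = FALSE)
  }
  fold <- stratified_folds(task$y, k, seed)
  per_fold <- t(vapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- fit_binary(family, params, task$X[tr, , drop = FALSE],
                        task$y[tr], seed = derive_seed(seed, f))
    pred <- predict_binary(model, task$X[!tr, , drop = FALSE])
    cm <- confusion_counts(pred, task$y[!tr])
    metrics_from_confusion(cm[["tp"]], cm[["fp"]], cm[["tn"]], cm[["fn"]])
  }, numeric(6)))
  structure(
    list(emotion = task$emotion, family = family, params = params,
         per_fold = as.data.frame(per_fold),
         mean = colMeans(per_fold),
         n_folds = as.integer(k), seed = as.integer(seed)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("%d-fold CV report — emotion '%s', family %s\n",
              x$n_folds, x$emotion, x$family))
  print(round(x$mean, digits))
  invisible(x)
}

#' Random hyperparameter search for one binary task
#'
#' Draws `n_iter` seeded configurations from the family's search space,
#' scores each by the mean F-measure under k-fold cross-validation, and
#' returns the best configuration (ties go to the earlier draw).
#'
#' @inheritParams cross_validate
#' @param n_iter number of random configurations (default 50).
#' @return list with `family`, `params` (best configuration), `score`
#'   (its mean F-measure), `report` (the winning configuration's
#'   `cv_report`, at the folds under which it was selected) and `n_iter`.
#' @export
random_search <- function(task, family = c("svm", "rf"), n_iter = 50, k = 5,
                          seed = 1) {
  stopifnot(inherits(task, "binary_task"))
  family <- match.arg(family)
  if (n_iter < 1) stop("n_iter must be at least 1", call. = FALSE)
  if (length(unique(task$y)) < 2) {
    stop("single-class task for '", task$emotion, "'", call. = FALSE)
  }
  space <- hyperparameter_space(family)
  draws <- with_seed(seed, lapply(seq_len(n_iter), function(i) draw_params(space)))
  reports <- lapply(seq_len(n_iter), function(i) {
    cross_validate(task, family, draws[[i]], k = k,
                   seed = derive_seed(seed, i))
  })
  scores <- vapply(reports, function(r) r$mean[["f_score"]], numeric(1))
  best <- which.max(scores)  # first maximum on ties
  list(family = family, params = draws[[best]], score = scores[best],
       report = reports[[best]], n_iter = as.integer(n_iter))
}

#' Fit the seven-emotion classifier ensemble
#'
#' The package's central fitting function. For each of the seven emotions
#' it: projects the multi-label sample table to a binary task
#' ([binarize()]), rebalances it ([undersample()]), tunes each requested
#' classifier family by random hyperparameter search scored with
#' stratified k-fold cross-validation ([random_search()]), compares the
#' tuned configurations on their selection-time cross-validation reports,
#' keeps the family with the higher mean F-measure (ties broken by G-mean,
#' then in favour of the SVM), and refits the winner on the full
#' rebalanced task. Reported metrics are the tuning-selection estimates
#' and carry the usual mild selection optimism.
#'
#' @param samples a validated sample table (see [validate_samples()]).
#' @param seed integer seed governing undersampling, search draws, fold
#'   assignment and tree growth.
#' @param n_iter random-search budget per family (default 50).
#' @param k cross-validation folds (default 5).
#' @param families classifier families to compare (default both).
#' @return an object of class `feelpix_ensemble`: list with `models`
#'   (per-emotion fitted model + configuration), `reports` (per-emotion
#'   list of `cv_report`s per family), `chosen` (per-emotion winning
#'   family), `subset_size`, `seed`, `call`.
#' @examples
#' \donttest{
#' cfg <- generator_config(seed = 7, n_images = 70, n_subjects = 6,
#'                         images_per_subject = 20)
#' lm <- generate_landmarks(cfg)
#' feats <- frames_to_features(lm$frames)
#' samples <- build_samples(feats, lm$labels)
#' fit <- fit_emotion_ensemble(samples, seed = 7, n_iter = 3)
#' summary(fit)
#' }
#' @export
fit_emotion_ensemble <- function(samples, seed = 1, n_iter = 50, k = 5,
                                 families = c("svm", "rf")) {
  validate_samples(samples)
  cl <- match.call()
  models <- list()
  reports <- list()
  chosen <- character(0)
  for (ei in seq_along(emotion_levels())) {
    em <- emotion_levels()[ei]
    task <- binarize(samples, em)
    if (all(task$y == 0) || all(task$y == 1)) {
      stop("emotion '", em, "' has a single class; cannot fit", call. = FALSE)
    }
    task <- undersample(task, seed = derive_seed(seed, ei))
    fam_reports <- list()
    for (fam in families) {
      search_seed <- derive_seed(seed, ei * 100 + match(fam, c("svm", "rf")))
      best <- random_search(task, fam, n_iter = n_iter, k = k,
                            seed = search_seed)
      # report the winner at the folds under which it was selected, so the
      # family comparison uses the same estimates the search optimised
      fam_reports[[fam]] <- best$report
    }
    means_f <- vapply(fam_reports, function(r) r$mean[["f_score"]], numeric(1))
    means_g <- vapply(fam_reports, function(r) r$mean[["g_mean"]], numeric(1))
    win <- names(fam_reports)[order(-means_f, -means_g,
                                    match(names(fam_reports), c("svm", "rf")))][1]
    final <- fit_binary(win, fam_reports[[win]]$params, task$X, task$y,
                        seed = derive_seed(seed, ei * 1000))
    models[[em]] <- list(family = win, params = fam_reports[[win]]$params,
                         model = final)
    reports[[em]] <- fam_reports
    chosen[em] <- win
  }
  structure(
    list(models = models, reports = reports, chosen = chosen,
         n_features = 44L, seed = as.integer(seed), n_iter = as.integer(n_iter),
         k = as.integer(k), call = cl),
    class = "feelpix_ensemble"
  )
}

#' @export
print.feelpix_ensemble <- function(x, ...) {
  cat("Seven-emotion landmark classifier ensemble\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Search budget %d per family, %d-fold CV, seed %d\n",
              x$n_iter, x$k, x$seed))
  cat("Chosen family per emotion:\n")
  print(x$chosen)
  invisible(x)
}

#' Summarise a fitted emotion ensemble
#'
#' @param object a `feelpix_ensemble`.
#' @param ... unused.
#' @return data.frame with one row per emotion: winning family and the
#'   cross-validated mean accuracy, precision, F-measure and G-mean.
#' @export
summary.feelpix_ensemble <- function(object, ...) {
  rows <- lapply(emotion_levels(), function(em) {
    rep <- object$reports[[em]][[object$chosen[[em]]]]
    data.frame(emotion = em, family = object$chosen[[em]],
               accuracy = rep$mean[["accuracy"]],
               precision = rep$mean[["precision"]],
               f_score = rep$mean[["f_score"]],
               g_mean = rep$mean[["g_mean"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.feelpix_ensemble", "data.frame")
  out
}

#' @export
print.summary.feelpix_ensemble <- function(x, digits = 3, ...) {
  cat("Cross-validated metrics of the winning classifier per emotion:\n")
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Predict emotion bit vectors with a fitted ensemble
#'
#' Each of the seven binary heads votes independently, so any subset of the
#' seven emotions — including none — can be predicted for a frame. (The
#' at-least-one constraint applies to human annotations, not predictions.)
#'
#' @param object a `feelpix_ensemble`.
#' @param newdata numeric matrix or data.frame of 44-value feature vectors
#'   (rows), or a single feature vector.
#' @param ... unused.
#' @return integer 0/1 matrix with one row per input and one column per
#'   emotion in canonical order.
#' @export
predict.feelpix_ensemble <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[intersect(names(newdata), feature_cols())])
  }
  if (ncol(newdata) != object$n_features) {
    stop("feature vectors must have length ", object$n_features,
         " (got ", ncol(newdata), ")", call. = FALSE)
  }
  colnames(newdata) <- feature_cols()
  out <- vapply(emotion_levels(), function(em) {
    predict_binary(object$models[[em]]$model, newdata)
  }, integer(nrow(newdata)))
  if (nrow(newdata) == 1) out <- matrix(out, nrow = 1,
                                        dimnames = list(NULL, emotion_levels()))
  out
}

#' Plot cross-validated metrics of a fitted ensemble
#'
#' Grouped barplot of the winning classifier's mean precision, F-measure
#' and G-mean per emotion.
#'
#' @param x a `feelpix_ensemble`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the matrix of plotted values.
#' @export
plot.feelpix_ensemble <- function(x, ...) {
  s <- summary(x)
  m <- t(as.matrix(s[c("precision", "f_score", "g_mean")]))
  colnames(m) <- s$emotion
  graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                    legend.text = c("precision", "F-measure", "G-mean"),
                    ylab = "metric", ...)
  invisible(m)
}
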
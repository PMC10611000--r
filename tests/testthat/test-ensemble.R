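test_that("confusion-matrix metrics match hand arithmetic and brute-force recounts", {
  perfect <- metrics_from_confusion(10, 0, 10, 0)
  expect_equal(unname(perfect[c("accuracy", "precision", "f_score", "g_mean")]),
               rep(1, 4))

  m <- metrics_from_confusion(tp = 8, fp = 2, tn = 5, fn = 5)
  expect_equal(m[["accuracy"]], 0.65)
  expect_equal(m[["precision"]], 0.80)
  expect_equal(m[["f_score"]], 2 * 0.8 * (8 / 13) / (0.8 + 8 / 13))
  expect_equal(m[["g_mean"]], sqrt((8 / 13) * (5 / 7)))

  degen <- metrics_from_confusion(0, 0, 10, 5)
  expect_equal(unname(degen[c("precision", "f_score", "g_mean")]), c(0, 0, 0))
  expect_equal(degen[["accuracy"]], 2 / 3)

  expect_error(metrics_from_confusion(0, 0, 0, 0), "all-zero")
  expect_error(metrics_from_confusion(-1, 0, 1, 0), "non-negative")

  # oracle: recount every metric from raw (prediction, truth) pairs
  set.seed(5)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    truth <- sample(0:1, n, replace = TRUE)
    pred <- sample(0:1, n, replace = TRUE)
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
    m <- metrics_from_confusion(tp, fp, tn, fn)
    expect_equal(m[["accuracy"]], mean(pred == truth))
    expect_equal(m[["precision"]], if (tp + fp == 0) 0 else tp / (tp + fp))
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spe <- if (tn + fp == 0) 0 else tn / (tn + fp)
    expect_equal(m[["g_mean"]], sqrt(rec * spe))
    expect_true(all(m >= 0 & m <= 1))
    expect_lte(m[["g_mean"]], sqrt(max(rec, spe)) + 1e-12)
  }
})

test_that("cross-validation is stratified, seeded and correct on extremes", {
  set.seed(2)
  # perfectly separable task: every metric 1 in every fold
  task <- random_task(40, 50, shift = 8)
  rep_ <- cross_validate(task, "svm",
                         list(kernel = "linear", cost = 1, gamma = 0.1),
                         k = 5, seed = 1)
  expect_equal(unname(rep_$mean), rep(1, 6))
  expect_equal(nrow(rep_$per_fold), 5)

  # chance level on shuffled labels: accuracy near 0.5
  accs <- vapply(1:6, function(s) {
    task <- random_task(350, 350, shift = 0)
    cross_validate(task, "svm", list(kernel = "radial", cost = 1, gamma = 0.05),
                   k = 5, seed = s)$mean[["accuracy"]]
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)

  # determinism under the seed
  r1 <- cross_validate(task, "rf", list(num_trees = 60, max_depth = 0,
                                        min_node = 5), k = 5, seed = 9)
  r2 <- cross_validate(task, "rf", list(num_trees = 60, max_depth = 0,
                                        min_node = 5), k = 5, seed = 9)
  expect_identical(r1$per_fold, r2$per_fold)

  expect_error(cross_validate(random_task(3, 50), "svm",
                              list(kernel = "linear", cost = 1, gamma = 1),
                              k = 5, seed = 1), "at least k")
})

test_that("random search returns the seeded argmax configuration", {
  set.seed(3)
  task <- random_task(30, 40, shift = 8)
  one <- random_search(task, "svm", n_iter = 1, seed = 5)
  expect_named(one$params, c("kernel", "cost", "gamma"))

  again <- random_search(task, "svm", n_iter = 1, seed = 5)
  expect_identical(one, again)

  best <- random_search(task, "svm", n_iter = 5, seed = 5)
  expect_equal(best$score, 1)  # separable: the chosen config must be perfect

  single <- random_task(20, 0)
  single$y <- rep(1L, 20)
  expect_error(random_search(single, "svm", n_iter = 2, seed = 1),
               "single-class")
})

test_that("the fitted ensemble recovers generated emotions in the separable regime", {
  lm <- generate_landmarks(generator_config(seed = 21, n_subjects = 10,
                                            images_per_subject = 35))
  samples <- build_samples(frames_to_features(lm$frames), lm$labels)
  fit <- fit_emotion_ensemble(samples, seed = 21, n_iter = 10)
  sm <- summary(fit)
  expect_equal(sm$emotion, emotion_levels())
  # at this reduced scale (~50 positives per head) the hardest head
  # (neutral) sits lower than at full scale
  expect_true(all(sm$f_score >= 0.8))
  expect_gte(median(sm$f_score), 0.9)

  # training positives predicted positive for a clear-cut emotion
  happy_rows <- samples[samples$happy == 1, ]
  pred <- predict(fit, happy_rows)
  expect_gte(mean(pred[, "happy"]), 0.9)

  expect_error(predict(fit, matrix(0, 2, 40)), "length 44")
  p1 <- predict(fit, as.numeric(samples[1, paste0("f", 0:43)]))
  expect_equal(dim(p1), c(1, 7))
  expect_identical(p1, predict(fit, as.numeric(samples[1, paste0("f", 0:43)])))
})

test_that("an emotion nobody selected aborts the fit with its name", {
  sets <- replicate(30, sample(c("happy", "sad", "anger"), 1))
  samples <- tiny_samples(as.list(sets))
  expect_error(fit_emotion_ensemble(samples, seed = 1, n_iter = 1),
               "disgust")
})

test_that("ensemble summaries and printing expose the chosen families", {
  lm <- generate_landmarks(generator_config(seed = 8, n_subjects = 4,
                                            images_per_subject = 30))
  samples <- build_samples(frames_to_features(lm$frames), lm$labels)
  fit <- fit_emotion_ensemble(samples, seed = 8, n_iter = 2, families = "svm")
  expect_true(all(fit$chosen == "svm"))
  expect_output(print(fit), "Chosen family")
  expect_output(print(summary(fit)), "emotion")
  expect_s3_class(summary(fit), "data.frame")
})
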
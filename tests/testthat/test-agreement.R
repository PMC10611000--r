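pairs_df <- function(user, algo, user_id = NULL) {
  out <- data.frame(image_id = sprintf("i%03d", seq_along(user)),
                    user_labels = user, algo_labels = algo,
                    stringsAsFactors = FALSE)
  if (!is.null(user_id)) out$user <- user_id
  out
}

test_that("success rate counts presentations with overlapping label sets", {
  p <- pairs_df(c("happy", "fear;surprise", "sad"),
                c("happy", "fear;surprise", "sad"))
  expect_equal(success_rate(p), 1)

  p <- pairs_df(c("happy", "fear"), c("sad", "anger;disgust"))
  expect_equal(success_rate(p), 0)

  # 19 of 35 overlapping, brute-force construction
  set.seed(31)
  user <- rep("happy", 35)
  algo <- c(rep("happy;surprise", 19), rep("sad", 16))[sample(35)]
  expect_equal(success_rate(pairs_df(user, algo)), 19 / 35)

  expect_error(success_rate(pairs_df(character(0), character(0))), "no pairs")
  expect_error(success_rate(pairs_df("", "happy")), "non-empty")
})

test_that("success rate is order-invariant and monotone in algo labels", {
  set.seed(13)
  user <- replicate(50, paste(sample(emotion_levels(), sample(1:3, 1)),
                              collapse = ";"))
  algo <- replicate(50, paste(sample(emotion_levels(), sample(0:2, 1)),
                              collapse = ";"))
  p <- pairs_df(user, algo)
  expect_equal(success_rate(p[sample(50), ]), success_rate(p))

  widened <- p
  widened$algo_labels <- vapply(strsplit(p$algo_labels, ";"), function(s) {
    paste(union(s[nzchar(s)], "happy"), collapse = ";")
  }, character(1))
  expect_gte(success_rate(widened), success_rate(p))
})

test_that("per-emotion agreement reduces to the right confusion matrices", {
  # echo algorithm: perfect metrics wherever the emotion occurs
  set.seed(3)
  user <- replicate(40, paste(sample(emotion_levels(), sample(1:2, 1)),
                              collapse = ";"))
  p <- pairs_df(user, user)
  res <- suppressWarnings(per_emotion_agreement(p))
  present <- vapply(emotion_levels(), function(em) {
    any(grepl(em, user, fixed = TRUE))
  }, logical(1))
  expect_true(all(res$precision[present] == 1))
  expect_true(all(res$f_score[present] == 1))
  expect_true(all(res$g_mean[present] == 1))

  # hand-built confusion for happy: tp=3 fp=1 tn=5 fn=1
  user <- c(rep("happy", 3), "happy", rep("sad", 5), "sad")
  algo <- c(rep("happy", 3), "sad", rep("sad", 5), "happy")
  user[4] <- "happy"; algo[4] <- "sad"        # fn
  user[10] <- "sad"; algo[10] <- "happy"      # fp
  res <- suppressWarnings(per_emotion_agreement(pairs_df(user, algo)))
  happy <- res[res$emotion == "happy", ]
  expect_equal(happy$tp, 3); expect_equal(happy$fp, 1)
  expect_equal(happy$tn, 5); expect_equal(happy$fn, 1)
  expect_equal(happy$precision, 0.75)
  expect_equal(happy$f_score, 0.75)
  expect_equal(happy$g_mean, sqrt(0.75 * 5 / 6))

  # algorithm that always claims all seven: specificity 0, hence g-mean 0
  all7 <- paste(emotion_levels(), collapse = ";")
  res <- suppressWarnings(per_emotion_agreement(pairs_df(user, rep(all7, 10))))
  expect_true(all(res$recall[res$tp + res$fn > 0] == 1))
  expect_true(all(res$g_mean == 0))

  # every emotion absent from all user selections warns
  w <- capture_warnings(per_emotion_agreement(pairs_df("happy", "happy")))
  expect_length(w, 6)
  expect_match(w, "absent", all = TRUE)
})

test_that("simulated detector error rates are recovered within binomial error", {
  set.seed(17)
  n <- 10000
  recall_true <- 0.7; fpr_true <- 0.2
  truth <- runif(n) < 0.4
  detected <- ifelse(truth, runif(n) < recall_true, runif(n) < fpr_true)
  user <- ifelse(truth, "happy", "sad")
  algo <- ifelse(detected, "happy", "")
  p <- pairs_df(user, algo)
  res <- suppressWarnings(per_emotion_agreement(p))
  happy <- res[res$emotion == "happy", ]
  se <- 3 * sqrt(0.25 / (n * 0.4))
  expect_lt(abs(happy$recall - recall_true), se)
  expect_lt(abs(1 - happy$specificity - fpr_true), se)
})

test_that("the agreement report aggregates per user and round-trips via CSV", {
  set.seed(23)
  user_id <- rep(c("u1", "u2"), each = 35)
  user <- replicate(70, paste(sample(emotion_levels(), sample(1:2, 1)),
                              collapse = ";"))
  algo <- replicate(70, paste(sample(emotion_levels(), sample(0:2, 1)),
                              collapse = ";"))
  p <- pairs_df(user, algo, user_id = user_id)
  rep_ <- suppressWarnings(agreement_report(p))
  expect_equal(rep_$n_users, 2)
  expect_equal(rep_$mean_success_rate,
               mean(c(success_rate(p[1:35, ]), success_rate(p[36:70, ]))))
  expect_output(print(rep_), "success rate")

  f <- tempfile(fileext = ".csv")
  utils::write.csv(p, f, row.names = FALSE)
  back <- read_pairs(f)
  expect_equal(success_rate(back), success_rate(p))
})
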
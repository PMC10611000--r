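#' Pipeline run configuration
#'
#' Settings for one end-to-end demonstration run: the generator
#' configuration, the stimulus group size, the classifier search budget and
#' fold count, and the evaluation flags.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param generator a [generator_config()] (defaults to one built from
#'   `seed`).
#' @param n_per_group stimulus images per emotion group.
#' @param per_emotion session presentations per emotion.
#' @param n_iter random-search budget per classifier family.
#' @param k cross-validation folds.
#' @param families classifier families to compare.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, generator = generator_config(seed = seed),
                            n_per_group = 10, per_emotion = 5,
                            n_iter = 15, k = 5, families = c("svm", "rf")) {
  structure(
    list(seed = as.integer(seed), generator = generator,
         n_per_group = n_per_group, per_emotion = per_emotion,
         n_iter = n_iter, k = k, families = families),
    class = "pipeline_config"
  )
}

#' Run the full pipeline on synthetic data
#'
#' Executes every stage in order: generate a ratings table, select the
#' stimulus set and one presentation session, generate labelled landmark
#' frames, normalize them and extract features, assemble the sample table,
#' fit the seven-emotion classifier ensemble, and score the ensemble's
#' predictions against the self-reported labels with the agreement
#' statistics. All intermediate artifacts and JSON reports are written into
#' `out_dir`; identical configurations yield identical reports.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory artifacts: `ratings`,
#'   `stimulus_set`, `session`, `samples`, `fit` (the `feelpix_ensemble`),
#'   `cv_summary`, `agreement`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("feelpix_run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) cat(..., "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  log_line("seed: ", config$seed)

  ratings <- generate_ratings(config$generator)
  write_ratings(ratings, file.path(out_dir, "ratings.csv"))
  log_line("ratings: ", nrow(ratings), " images")

  set <- build_stimulus_set(ratings, seed = derive_seed(config$seed, 1),
                            n_per_group = config$n_per_group)
  write_stimulus_set(set, file.path(out_dir, "stimulus_set.json"))
  session <- sample_session(set, per_emotion = config$per_emotion,
                            seed = derive_seed(config$seed, 2))
  jsonlite::write_json(session, file.path(out_dir, "session.json"),
                       auto_unbox = TRUE)
  log_line("stimulus set: ", sum(lengths(set$groups)), " images; session: ",
           nrow(session), " presentations")

  lm <- generate_landmarks(config$generator)
  write_frames(lm$frames, file.path(out_dir, "frames_raw.csv"))
  feats <- frames_to_features(lm$frames)
  samples <- build_samples(feats, lm$labels)
  write_feelpix(samples, file.path(out_dir, "feelpix.csv"))
  log_line("samples: ", nrow(samples), " x ", length(feature_cols()), " features")

  fit <- fit_emotion_ensemble(samples, seed = derive_seed(config$seed, 3),
                              n_iter = config$n_iter, k = config$k,
                              families = config$families)
  cv_summary <- summary(fit)
  jsonlite::write_json(cv_summary, file.path(out_dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  pred <- predict(fit, samples)
  algo <- apply(pred, 1, function(b) paste(emotion_levels()[b == 1],
                                           collapse = ";"))
  pairs <- data.frame(image_id = samples$sample_id,
                      user = samples$subject,
                      user_labels = join_labels(
                        lapply(seq_len(nrow(samples)),
                               function(i) decode_labels(
                                 as.integer(samples[i, emotion_levels()])))),
                      algo_labels = algo, stringsAsFactors = FALSE)
  agree <- agreement_report(pairs)
  jsonlite::write_json(
    list(mean_success_rate = agree$mean_success_rate,
         per_user = as.list(agree$per_user),
         per_emotion = agree$per_emotion,
         n_pairs = agree$n_pairs, n_users = agree$n_users),
    file.path(out_dir, "agreement.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_line("mean success rate: ", round(agree$mean_success_rate, 4))

  invisible(list(ratings = ratings, stimulus_set = set, session = session,
                 samples = samples, fit = fit, cv_summary = cv_summary,
                 agreement = agree, out_dir = out_dir))
}
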
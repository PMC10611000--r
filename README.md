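# feelpix

Landmark-based facial expression recognition from self-labelled data.

## The problem

Most facial-expression-recognition (FER) datasets are images labelled by
third-party annotators, which requires heavy convolutional models downstream
and captures the annotator's reading of an expression rather than what the
person actually felt. An alternative protocol shows participants highly
emotive images, records the 68 standard 2-D facial landmarks while they look,
and lets the participants themselves select the emotions they experienced
(one or more of Ekman's six basic emotions — anger, disgust, fear, happiness,
sadness, surprise — plus neutrality). The result is a lightweight, self-
labelled dataset of landmark coordinates on which classical classifiers work
well.

`feelpix` implements that entire pipeline in R, testable end to end with no
external downloads:

- **Stimulus selection** — pick 7 × 10 emotion-specific images from an
  affective norms table. Images are clustered with k-means (k = 3) on their
  mean valence/arousal ratings (both on \[1, 9\]); clusters are labelled
  *negative* / *neutral* / *positive* by the valence bands \[1,4), \[4,6),
  \[6,9\]; each basic emotion is searched in its macro cluster(s) (surprise in
  all three), candidates are ranked by that emotion's \[1, 7\] intensity, and
  images with disgust intensity > 4 are pre-screened away. Neutral stimuli
  are the lowest-arousal images of the neutral cluster that carry all six
  basic labels. Per-participant sessions present 5 images per emotion (35
  total) with no two consecutive images from the same emotion group.
- **Landmark normalization** — four expression-stable anchors (left/right
  lateral face points, nasal center, subnasal center) define three
  axis-aligned distances; x offsets from the nasal center are divided by the
  left or right anchor distance and y offsets by the vertical nose distance,
  making the coordinates invariant to translation and per-axis scale. A
  22-landmark, action-unit-motivated subset gives a 44-value feature vector.
- **Classifier ensemble** — one binary classifier per emotion (class 1 =
  emotion selected). Each task is rebalanced by keeping all positives and
  undersampling negatives to `n_pos + floor(n_pos / 2)`; SVM and random
  forest families are tuned by random hyperparameter search under seeded
  stratified five-fold cross-validation, scored by accuracy, precision,
  F-measure and G-mean (√(TPR·TNR)), and the better family
  per emotion is kept.
- **Agreement statistics** — the per-user success rate (fraction of
  presentations where the user's selections and an algorithm's detections
  share at least one emotion) and per-emotion precision/F/G-mean confusions.
- **Synthetic data** — a ratings-table generator around the macro centroids
  of the valence-arousal plane, and a landmark generator built from a
  schematic 68-point face plus per-emotion displacement prototypes with
  controllable signal-to-noise, so every claim above is testable.

## Worked example

```r
library(feelpix)

## stimulus selection on a synthetic norms table
ratings <- generate_ratings(generator_config(seed = 3))
set <- build_stimulus_set(ratings, seed = 3)
lengths(set$groups)
#>    anger  disgust     fear    happy  neutral      sad surprise
#>       10       10       10       10       10       10       10

session <- sample_session(set, per_emotion = 5, seed = 5)
nrow(session); sum(session$emotion[-1] == session$emotion[-35])
#> [1] 35
#> [1] 0

## landmark capture, normalization, dataset, ensemble
lm <- generate_landmarks(generator_config(seed = 11))
samples <- build_samples(frames_to_features(lm$frames), lm$labels)
fit <- fit_emotion_ensemble(samples, seed = 11, n_iter = 10)
summary(fit)
#> Cross-validated metrics of the winning classifier per emotion:
#>   emotion family accuracy precision f_score g_mean
#>     anger    svm    0.979     0.979   0.974  0.978
#>   disgust    svm    0.984     0.989   0.980  0.982
#>      fear    svm    0.985     0.979   0.981  0.984
#>     happy    svm    0.986     0.994   0.983  0.984
#>   neutral     rf    0.940     0.954   0.922  0.931
#>       sad    svm    0.996     1.000   0.995  0.995
#>  surprise    svm    1.000     1.000   1.000  1.000
```

Each row is the better of the tuned SVM and random-forest classifiers for
that emotion, with metrics averaged over the five cross-validation folds: at
the generator's default signal-to-noise the expressions are designed to be
recoverable, and every head recovers its emotion with F ≥ 0.9.
`predict(fit, features)`
returns a 7-bit emotion vector per frame, and `agreement_report()` compares
such detections with self-reports:

```r
pairs <- data.frame(image_id = c("a", "b"),
                    user_labels = c("happy", "fear;surprise"),
                    algo_labels = c("happy;surprise", "sad"))
success_rate(pairs)
#> [1] 0.5
```

An end-to-end seeded run (`run_pipeline(pipeline_config(seed = 1), "out")`)
writes the ratings table, stimulus set, session, raw frames, feature table,
cross-validation report and agreement report into one directory. A thin
command-line wrapper with the same stages lives at `inst/cli/feelpix`.

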
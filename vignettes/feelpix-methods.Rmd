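---
title: "Methods: landmark-based facial expression recognition with feelpix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark-based facial expression recognition with feelpix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`feelpix` models a facial-expression-recognition protocol in which
participants view emotionally evocative images, their 68 standard facial
landmarks are recorded, and they self-report the emotions they felt (any
non-empty subset of anger, disgust, fear, happiness, sadness, surprise and
neutrality). This vignette explains each stage's model, the parameters that
matter, the choices made where the design was genuinely open, and what the
synthetic-data tests do and do not establish.

## Stimulus selection

The input is a table of normed images with mean valence and arousal on
[1, 9], discrete basic-emotion labels, and per-emotion intensities on
[1, 7]. Selection proceeds as:

1. **Pre-screen.** Images with disgust intensity strictly greater than 4
   are removed globally, before any per-emotion search, so that no selected
   stimulus is needlessly disturbing. The cut is strict: intensity exactly 4
   is kept.
2. **Clustering.** Lloyd's k-means with k = 3 on the raw (valence, arousal)
   pairs. Both axes share the [1, 9] scale, so no standardization is
   applied. Initial centroids are drawn from the distinct observed points;
   because a single Lloyd start can fall into split/merge local optima even
   on well-separated data, `cluster_images()` takes the best of 10 seeded
   restarts by total within-cluster sum of squares. Convergence is
   assignment stability or 300 iterations.
3. **Macro labels.** Each cluster is labelled negative/neutral/positive by
   the majority valence band of its members. The bands are half-open —
   [1,4), [4,6), [6,9] — so every valence maps to exactly one band; the
   nominal band edges otherwise overlap at 4 and 6. Ties go to the band
   containing the cluster's mean valence, then to the fixed order
   negative < neutral < positive.
4. **Per-emotion pools.** Each basic emotion is searched in its macro
   cluster(s): anger, disgust, fear and sadness in the negative cluster,
   happiness in the positive, and surprise — which carries both positive
   and negative components — in all three. Candidates must carry the
   emotion's discrete label and are ranked by that emotion's intensity,
   descending; ties break by image id so runs are reproducible. Neutral
   stimuli have no intensity norms, so the neutral pool is the
   lowest-arousal images of the neutral cluster that carry *all six* basic
   labels (an image that everyone labels with everything is informative
   about nothing in particular).
5. **Disjointness.** The groups are built in the fixed order neutral,
   happy, anger, fear, sad, disgust, surprise, removing already-selected
   images from later pools. Seven groups of ten therefore always hold 70
   unique images. The processing order itself is a package choice: with
   surprise searched across all clusters, some order had to be fixed, and
   running surprise last lets the cluster-restricted emotions claim their
   most intense candidates first.

Sessions present `per_emotion` images from each group (default 5, hence 35
presentations) in a random order where no two consecutive presentations
come from the same group. The arrangement uses randomized backtracking with
a feasibility prune (no group may need more than half the remaining slots);
at 5-of-7 the arrangement always exists.

## Landmark normalization

A frame is 68 ordered (x, y) points in pixel coordinates, y growing
downward. Four expression-stable anchors drive normalization: the left and
right lateral face points, the nasal center (top of the nose bridge) and
the subnasal center (base of the nose). Their published identity is not
part of the 68-point standard, so the package defaults to scheme points 0,
16, 27 and 33 (R indices 1, 17, 28, 34) — the jaw extremes and the two
nose-bridge endpoints — and every function accepts a custom `anchor_set()`.

With the nasal center as origin, three *axis-aligned* distances are formed:
`d_left` and `d_right` horizontally to the lateral anchors and `d_vert`
vertically to the subnasal center. Then

- x offsets of points left of the nasal center divide by `d_left`,
- x offsets of the remaining points divide by `d_right` (points exactly at
  the nasal x fall on the right branch),
- y offsets of *all* points divide by `d_vert`.

This makes the representation exactly invariant under translation and
independent positive axis scalings (asserted to 1e-9 in the tests) — the
nuisance factors of head position, camera distance and aspect ratio — but
deliberately not under rotation: the distances are coordinate differences,
not Euclidean norms, and the tests assert that a 10° roll changes the
output. Separate left/right denominators balance facial asymmetry.

The feature vector keeps 22 of the 68 points — the landmarks over the
facial muscles that do the expressive work — giving 44 values per frame.
The exact 22 indices are not published either; the default subset covers
the brows (4 points), eye corners and upper lids (6), nose wings (2) and
mouth (10), and is overridable wherever it is consumed. One practical
consequence of anchor-based normalization worth knowing: noise on the
anchor coordinates enters every feature through the denominators as
correlated multiplicative noise, so landmark-detector jitter that is small
per point still degrades the whole vector once it becomes comparable to
the anchor distances.

## Dataset construction and rebalancing

Self-reports become 7-bit vectors in the fixed order anger, disgust, fear,
happy, neutral, sad, surprise; at least one bit must be set (the annotation
interface only unlocks after a choice). The seven-emotion problem is
decomposed into seven binary tasks sharing the feature matrix: class 1
means the emotion was selected.

Not selecting an emotion is far more common than selecting it, so each
task is rebalanced by undersampling — but only partially, because the
negative class spans a wider variety of expressions than the positive: all
positives are kept and negatives are sampled without replacement down to
`n_pos + floor(n_pos/2)` (the residual gap is half the minority count,
with the floor taken for odd counts). If the negatives already number at
most that, nothing changes. Rebalancing happens once, before
cross-validation; this mirrors the protocol being modelled, at the cost of
letting the balancing subsample inform all folds. Fold-internal
undersampling would be the leakage-free alternative and is easy to obtain
by composing `undersample()` per training fold; the package default keeps
the simpler, protocol-faithful order.

## Classifier ensemble

Two families are tuned per emotion and the better one kept:

| family | parameter | distribution |
|---|---|---|
| svm | cost | log-uniform on [1e-2, 1e3] |
| svm | kernel | uniform on {linear, radial} |
| svm | kernel width (gamma) | log-uniform on [1e-4, 10] |
| rf | trees | uniform integer on [50, 500] |
| rf | max depth | uniform on {unlimited, 2..20} |
| rf | min node size | uniform integer on [2, 10] |

Random search draws `n_iter` configurations (default 50) per family and
scores each by the mean F-measure under seeded *stratified* five-fold
cross-validation. Feature standardization is disabled inside the SVM: the
features are already on a common, anatomically meaningful scale after
anchor normalization, and per-column re-standardization measurably distorts
the radial kernel geometry on these data. The random-forest "min split"
notion maps to ranger's minimum node size, the closest control that
implementation exposes.

Per fold, the held-out confusion matrix yields accuracy, precision, recall,
specificity, F-measure and G-mean = sqrt(recall x specificity), the
standard imbalance-insensitive pair-summary; zero-denominator cases
(e.g. a fold with no positive prediction) score 0 by convention. Reported
per-emotion metrics are fold means of the *selected* configuration at the
folds under which it was selected — the same estimates the search
optimised, as tuning frameworks conventionally report. They therefore carry
mild selection optimism (on the synthetic data, of the order of 0.01–0.02
in F); an unbiased estimate would require an outer validation loop, which
is out of scope here. Family choice is by mean F-measure, ties by G-mean,
then SVM (the cheaper model at prediction time). The winner is refit on the
full rebalanced task; `predict()` runs the seven heads independently, so an
all-zero prediction is possible — the at-least-one rule binds human
annotators, not classifiers.

## Agreement statistics

For validating an external detector against self-reports, the *success
rate* is the fraction of presentations where the user's set and the
detector's set intersect; the report gives per-user rates and their mean
(both pooled-over-images and per-user views exist because either
aggregation is defensible; pooled is the default for the per-emotion
table). Per emotion, a binary confusion with truth "user selected it" and
prediction "detector reported it" yields the same precision/F/G-mean
metrics as the classifier evaluation, making the two directly comparable.
Accuracy is computed as well but the printed report leads with the three
imbalance-insensitive metrics.

## Synthetic data: what it emulates, and what passing tests show

`generate_ratings()` draws images evenly over three clusters at the macro
centroids (2.7, 6.9), (5.0, 3.0), (8.0, 6.9) of the valence-arousal plane
(spread `cluster_sd`, default 0.3, clipped to [1, 9]), and assigns labels
and intensities consistently with the generating cluster: dominant-emotion
intensities U(5, 7) (disgust dominants U(3, 4), so they survive the
pre-screen), non-dominant intensities low, a neutral-cluster share carrying
all six labels at low intensity, surprise dominants in every cluster, and a
filler role with disgust intensity above 4 so the pre-screen always has
work. With the default 700 images every emotion pool has candidates to
spare.

`generate_landmarks()` starts from a schematic neutral 68-point face whose
four anchor distances are exactly 1 ("face units"), adds
`expression_strength` times per-emotion displacement prototypes, then
Gaussian coordinate noise (`noise_sd`), then a random per-axis scale
(U(0.8, 1.2)) and translation (±50 px) at a 100 px/unit camera scale. The
prototypes are motivated by the action units typical of each expression —
mouth-corner raise for happiness, lip-corner depression and inner-brow
raise for sadness, brow lowering and lip press for anger, nose wrinkle and
upper-lip raise for disgust, brow raise with widened eyes and a lateral lip
stretch for fear, strong brow raise with jaw drop for surprise — with fear
and surprise given opposite horizontal mouth-corner signatures so the two
brow-raising expressions remain distinguishable. Anchors are displaced by
no prototype (anchor positions are taken to be expression-stable), and
samples may carry a second basic emotion with probability
`multi_label_rate` (default 0.25), in which case the displacement fields
add. Neutrality never co-occurs with a felt emotion: a neutral-plus-X
sample would be visually identical to a pure-X sample while labelled
neutral, making the neutral class unlearnable by construction.

Defaults are fixed study conditions, not tuning knobs: 31 subjects × 35
presentations, `expression_strength` 1 and `noise_sd` 0.05 — noise of 5%
of the unit anchor distances, the order of a real landmark detector's
jitter at this face scale, putting the default signal-to-noise ratio at 20.
Separability degrades well before the nominal signal reaches the noise
because of the anchor-denominator effect described above: with this
geometry the hardest head (neutral, which must distinguish "no field" from
six weak fields) needs a ratio of roughly 13 or more, and at the default 20
every head is comfortably recoverable.

A passing recovery test therefore shows that the pipeline's plumbing,
normalization, rebalancing, tuning and evaluation are sound — not that real
faces are this easy. The generator's faces lack identity variation,
expression intensity variation, rotation, occlusion and annotator
disagreement; real self-labelled data sits far closer to the decision
boundaries. Conversely, the chance-level test (label-permuted data scoring
accuracy 0.5 ± 0.05 on a 1:1-balanced task) shows the evaluation does not
manufacture signal; the permuted-label chance check is run at 1:1 balance
because after the 1.5:1 undersampling cap the no-information accuracy would
be 0.6 by construction.

## Numerical and scale choices

- Problem sizes: the shipped tests run recovery at 700 samples (20 × 35)
  with the default search budget of 50 draws per family, chance-level
  checks at 700 and 300 samples, property suites at 100–1000 replicates.
- All randomness flows from explicit integer seeds; child seeds derive via
  a fixed affine map mod 2^31 − 19. RNG state of the caller is saved and
  restored around every seeded operation. Degenerate-range jitter draws
  consume RNG state identically to non-degenerate ones, so configurations
  that differ only in jitter generate identical faces under one seed.
- Tie-breaks are total everywhere (intensity → id; F → G-mean → svm;
  majority band → mean band → band order), so equal seeds give
  byte-identical reports.
- Degenerate inputs error early with the offending emotion or anchor
  named: zero anchor distances, single-class tasks, groups smaller than a
  session's demand, fewer cluster centers than distinct points.

## Known limitations

- The published protocol's exact anchor landmarks and 22-point subset are
  not recorded anywhere authoritative; the defaults here are documented,
  overridable choices, so feature vectors are comparable only between runs
  using the same configuration.
- Pre-CV undersampling leaks the balancing subsample across folds (see
  above); reported metrics are tuning-selection estimates with mild
  optimism.
- Folds do not group by subject; with many frames per participant,
  subject-level generalization is not what the cross-validation measures.
- The normalization removes translation and axis scaling only; head roll
  must be corrected upstream.
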
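test_that("k-means clustering recovers structure and checks preconditions", {
  # k equal to n: singleton clusters whose centroids are the points
  tab <- tiny_ratings(valence = c(2, 5, 8), arousal = c(7, 3, 7))
  m <- cluster_images(tab, k = 3, seed = 1)
  expect_setequal(m$assignment, 1:3)
  cent <- m$centroids[m$assignment, ]
  expect_equal(unname(cent[, 1]), tab$valence_mean)
  expect_equal(unname(cent[, 2]), tab$arousal_mean)

  # well-separated blobs are recovered exactly, any seed; oracle is a
  # brute-force nearest-generating-centroid assignment
  centroids <- rbind(c(2.7, 6.9), c(5.0, 3.0), c(8.0, 6.9))
  set.seed(99)
  gen <- rep(1:3, each = 20)
  val <- pmin(pmax(rnorm(60, centroids[gen, 1], 0.2), 1), 9)
  aro <- pmin(pmax(rnorm(60, centroids[gen, 2], 0.2), 1), 9)
  tab <- tiny_ratings(valence = val, arousal = aro)
  oracle <- apply(cbind(val, aro), 1, function(p) {
    which.min(colSums((t(centroids) - p)^2))
  })
  for (seed in c(1, 7, 123)) {
    m <- cluster_images(tab, k = 3, seed = seed)
    # same partition as the oracle, up to cluster relabelling
    expect_equal(length(unique(paste(m$assignment, oracle))), 3)
  }

  expect_error(cluster_images(tab, k = 0), "k must be")
  expect_error(cluster_images(tab[0, ], k = 3), "empty|insufficient")
  expect_error(cluster_images(tiny_ratings(c(2, 5)), k = 3), "insufficient")
})

test_that("clusters are labelled by majority valence band with tie rules", {
  tab <- tiny_ratings(valence = c(2.0, 3.5, 4.5))
  m <- label_clusters(manual_model(tab), tab)
  expect_equal(m$labels, "negative")  # 2 of 3 members below 4

  tab <- tiny_ratings(valence = c(5.0, 5.0, 5.0))
  expect_equal(label_clusters(manual_model(tab), tab)$labels, "neutral")

  # tie between negative and neutral broken by the mean (4.0 -> neutral)
  tab <- tiny_ratings(valence = c(3.9, 4.1))
  expect_equal(label_clusters(manual_model(tab), tab)$labels, "neutral")

  # boundary values fall in the upper band (half-open bands)
  tab <- tiny_ratings(valence = c(4, 4, 6, 6, 6))
  expect_equal(label_clusters(manual_model(tab), tab)$labels, "positive")
})

test_that("disgust pre-screen removes strictly-greater intensities and is idempotent", {
  tab <- tiny_ratings(valence = c(2, 3, 4, 5))
  tab$int_disgust <- c(4.5, 4.0, 1.0, 6.9)
  out <- prescreen(tab)
  expect_setequal(out$image_id, tab$image_id[c(2, 3)])  # 4.0 kept: strict cut
  expect_identical(prescreen(out), out)
  expect_equal(nrow(prescreen(tab[0, ])), 0)
})

test_that("per-emotion selection sorts by intensity with id tie-break", {
  tab <- tiny_ratings(valence = rep(2, 4), labels = rep("fear", 4))
  tab$image_id <- c("a", "b", "c", "d")
  tab$int_fear <- c(5.1, 6.2, 3.3, 6.2)
  m <- manual_model(tab, "negative")
  expect_equal(select_for_emotion(tab, "fear", m, n = 2), c("b", "d"))
  expect_equal(select_for_emotion(tab, "fear", m, n = 0), character(0))
  expect_error(select_for_emotion(tab, "fear", m, n = 5),
               "insufficient candidates for emotion 'fear'")
  # images without the discrete label are not candidates
  tab$labels[2] <- "anger"
  expect_equal(select_for_emotion(tab, "fear", m, n = 2), c("d", "a"))
})

test_that("neutral selection requires all six labels and sorts by arousal", {
  all6 <- paste(basic_emotions(), collapse = ";")
  tab <- tiny_ratings(valence = rep(5, 3), arousal = c(2.1, 1.8, 3.0),
                      labels = rep(all6, 3))
  tab$image_id <- c("p", "q", "r")
  m <- manual_model(tab, "neutral")
  expect_equal(select_neutral(tab, m, n = 2), c("q", "p"))
  expect_equal(select_neutral(tab, m, n = 0), character(0))
  # a missing basic label excludes the image
  tab$labels[2] <- paste(setdiff(basic_emotions(), "sad"), collapse = ";")
  expect_equal(select_neutral(tab, m, n = 2), c("p", "r"))
})

test_that("the full stimulus set has 7 disjoint groups drawn from the table", {
  tab <- generate_ratings(generator_config(seed = 5, n_images = 700))
  set <- build_stimulus_set(tab, seed = 5)
  expect_named(set$groups, emotion_levels())
  expect_true(all(lengths(set$groups) == 10))
  ids <- unlist(set$groups)
  expect_equal(length(unique(ids)), 70)
  expect_true(all(ids %in% tab$image_id))

  # selected images carry the group's label; intensities are non-increasing
  for (em in basic_emotions()) {
    rows <- tab[match(set$groups[[em]], tab$image_id), ]
    labs <- strsplit(rows$labels, ";", fixed = TRUE)
    expect_true(all(vapply(labs, function(l) em %in% l, logical(1))))
    expect_true(all(diff(rows[[paste0("int_", em)]]) <= 1e-12))
  }

  small <- build_stimulus_set(tab, seed = 5, n_per_group = 1)
  expect_equal(length(unique(unlist(small$groups))), 7)
})

test_that("an all-shocking disgust pool fails with the emotion named", {
  tab <- generate_ratings(generator_config(seed = 5, n_images = 700))
  # shock every disgust-dominant image (but not the all-six-label neutral
  # pool, which only carries disgust at low intensity)
  tab$int_disgust[tab$labels == "disgust"] <- 5
  expect_error(build_stimulus_set(tab, seed = 5), "disgust")
})

test_that("sampled sessions respect the non-consecutive constraint", {
  tab <- generate_ratings(generator_config(seed = 5, n_images = 700))
  set <- build_stimulus_set(tab, seed = 5)

  ses <- sample_session(set, per_emotion = 1, seed = 1)
  expect_equal(nrow(ses), 7)
  expect_setequal(ses$emotion, emotion_levels())

  for (seed in 1:100) {
    ses <- sample_session(set, per_emotion = 5, seed = seed)
    expect_equal(nrow(ses), 35)
    expect_true(all(table(ses$emotion) == 5))
    expect_false(any(ses$emotion[-1] == ses$emotion[-35]))
    expect_true(all(!duplicated(ses$image_id)))
    expect_true(all(ses$image_id %in% unlist(set$groups)))
  }

  # single group: adjacency unavoidable
  lone <- structure(list(groups = list(happy = c("a", "b")), group_size = 2L),
                    class = "stimulus_set")
  expect_error(sample_session(lone, per_emotion = 2, seed = 1), "infeasible")
})

test_that("macro labels track the generating blobs on separated synthetic ratings", {
  for (seed in c(3, 17)) {
    cfg <- generator_config(seed = seed, n_images = 300, cluster_sd = 0.25)
    tab <- generate_ratings(cfg)
    m <- label_clusters(cluster_images(tab, k = 3, seed = seed), tab)
    # images generated at low/mid/high valence get negative/neutral/positive
    lab_of <- m$labels[m$assignment[tab$image_id]]
    gen <- rep_len(c("negative", "neutral", "positive"), nrow(tab))
    expect_equal(lab_of, gen)
  }
})

test_that("ratings and stimulus sets survive a file round trip", {
  tab <- generate_ratings(generator_config(seed = 2, n_images = 60))
  f <- tempfile(fileext = ".csv")
  write_ratings(tab, f)
  back <- read_ratings(f)
  expect_equal(back$valence_mean, tab$valence_mean, tolerance = 1e-12)
  expect_identical(back$labels, tab$labels)

  tab700 <- generate_ratings(generator_config(seed = 2, n_images = 700))
  set <- build_stimulus_set(tab700, seed = 2)
  g <- tempfile(fileext = ".json")
  write_stimulus_set(set, g)
  expect_identical(read_stimulus_set(g)$groups, set$groups)
})
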
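voc_proto <- make_protocol("two_photon_voc", seed = 3)

test_that("sound vectors line up windowed means in fixed stimulus order", {
  p <- voc_proto
  sp <- matrix(0, 2, p$n_frames)
  # neuron 2 responds only to sound 4, as an onset impulse
  k4 <- p$onsets[p$onsets$stimulus_index == 4, ]
  sp[2, k4$onset_frame] <- 3.2
  sv <- build_sound_vectors(toy_trace_set(sp, p), "vocal")
  wf <- floor(0.55 * 30)
  expect_equal(dim(sv$vectors), c(2, 10, 10))
  expect_true(all(sv$vectors[1, , ] == 0))
  expect_true(all(abs(sv$vectors[2, , 4] - 3.2 / wf) < 1e-12))
  expect_true(all(sv$vectors[2, , -4] == 0))
})

test_that("pt50 mode uses only the 50-dB recording", {
  p <- make_protocol("two_photon_pt", seed = 4)
  sp <- matrix(0, 1, p$n_frames)
  on50 <- p$onsets[p$onsets$spl_db == 50, ]
  sp[1, on50$onset_frame] <- 1
  sp[1, p$onsets$onset_frame[p$onsets$spl_db == 70]] <- 99  # must be ignored
  sv <- build_sound_vectors(toy_trace_set(sp, p), "pt50")
  expect_equal(dim(sv$vectors), c(1, 10, 17))
  expect_true(max(sv$vectors) <= 1 / 12 + 1e-12)
})

test_that("correlation structure handles exact, anti- and zero-variance cases", {
  v <- array(0, c(3, 4, 6))
  set.seed(14)
  x <- rnorm(6)
  for (r in 1:4) {            # noise-free: identical vectors in every repetition
    v[1, r, ] <- x
    v[2, r, ] <- x            # duplicate neuron
    v[3, r, ] <- -x           # anti-correlated neuron
  }
  sv <- structure(list(vectors = v, stimulus_ids = letters[1:6], mode = "vocal",
                       window_s = 0.55, n_repetitions = 4), class = "sound_vectors")
  cs <- correlation_structure(sv)
  expect_equal(cs$between[1, 2], 1)
  expect_equal(cs$between[1, 3], -1)
  expect_equal(cs$reliability[1], 1)
  expect_true(isSymmetric(cs$between))
  # zero-variance vectors exclude the neuron
  v[3, , ] <- 5
  sv$vectors <- v
  cs2 <- correlation_structure(sv)
  expect_true(cs2$excluded[3])
  expect_false(any(cs2$excluded[1:2]))
})

test_that("independent vectors have near-zero mean between-correlation", {
  m <- sapply(1:100, function(sd) {
    set.seed(sd)
    v <- array(rnorm(2 * 10 * 17), c(2, 10, 17))
    sv <- structure(list(vectors = v, stimulus_ids = 1:17, mode = "pt50",
                         window_s = 0.4, n_repetitions = 10), class = "sound_vectors")
    correlation_structure(sv)$between[1, 2]
  })
  expect_lte(abs(mean(m)), 0.05)
})

test_that("planted motif blocks cluster perfectly and survive the null filter", {
  sim <- simulate_vocal_responses(voc_proto,
                                  motif_config(within_corr = 0.9, noise_sd = 0),
                                  seed = 12)
  ens <- analyze_ensembles(sim$traces, "vocal", seed = 77)
  lab <- label_or_zero(ens$clusters$labels)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(lab, sim$ground_truth$motif_id), 1)
  expect_true(all(ens$clusters$clusters$status == "retained"))
  expect_equal(ens$stats$n_clusters, 3)
})

test_that("too few neurons yield zero clusters", {
  sim <- simulate_vocal_responses(voc_proto,
                                  motif_config(n_motifs = 1, neurons_per_motif = 2),
                                  seed = 2)
  sv <- build_sound_vectors(sim$traces, "vocal")
  cl <- cluster_cells(correlation_structure(sv))
  expect_equal(nrow(cl$clusters), 0)
})

test_that("shuffle null is deterministic and counts its passes", {
  sim <- simulate_vocal_responses(voc_proto, motif_config(), seed = 9)
  sv <- build_sound_vectors(sim$traces, "vocal")
  n1 <- shuffle_null(sv, n_shuffles = 5, seed = 31)
  n2 <- shuffle_null(sv, n_shuffles = 5, seed = 31)
  expect_identical(n1, n2)
  expect_equal(n1$n_shuffles, 5)
  # every pass either contributed clusters or was recorded as empty
  expect_equal(length(unique(n1$shuffle_of)) + n1$n_empty, 5)
})

test_that("the null filter applies the strict 2-SD rule", {
  cl <- structure(list(labels = c(1L, 1L, 1L, 2L, 2L, 2L),
                       clusters = data.frame(cluster = 1:2, size = 3,
                                             mean_corr = c(0.10, 0.09),
                                             status = "candidate"),
                       structure = list(between = diag(6),
                                        reliability = rep(0.5, 6))),
                  class = "cluster_set")
  null <- structure(list(values = 1, mean = 0.05, sd = 0.02, n_shuffles = 5,
                         n_empty = 0), class = "shuffle_null")
  out <- filter_clusters(cl, null)
  expect_equal(out$clusters$status, c("retained", "excluded_by_null"))
  expect_equal(out$labels, c(1L, 1L, 1L, 0L, 0L, 0L))
})

test_that("cluster statistics compute the six summary quantities", {
  # one retained cluster at the vertices of a 100-um equilateral triangle
  rois <- data.frame(x_um = c(0, 100, 50, 300), y_um = c(0, 0, 50 * sqrt(3), 300))
  between <- matrix(0.5, 4, 4); diag(between) <- 1
  cl <- structure(list(labels = c(1L, 1L, 1L, 0L),
                       clusters = data.frame(cluster = 1L, size = 3L,
                                             mean_corr = 0.5, status = "retained"),
                       structure = list(between = between,
                                        reliability = rep(0.4, 4))),
                  class = "cluster_set")
  st <- cluster_statistics(cl, rois)
  expect_equal(st$n_clusters, 1)
  expect_equal(st$cluster_sizes, 3L)
  expect_equal(st$fraction_clustered, 0.75)
  expect_equal(st$pair_distances_um, rep(100, 3), tolerance = 1e-9)
  expect_equal(st$cluster_corr, 0.5)
  expect_equal(st$cluster_reliability, 0.4)
  # zero retained clusters
  cl0 <- cl; cl0$clusters$status <- "excluded_by_null"; cl0$labels[] <- 0L
  st0 <- cluster_statistics(cl0, rois)
  expect_equal(st0$n_clusters, 0)
  expect_equal(st0$fraction_clustered, 0)
  expect_length(st0$pair_distances_um, 0)
})

test_that("planted spatial dispersion orders recovered pair distances", {
  dist_mean <- sapply(c(75, 250), function(disp) {
    mean(sapply(1:10, function(sd) {
      sim <- simulate_vocal_responses(voc_proto,
        motif_config(within_corr = 0.8, dispersion_um = disp), seed = sd)
      ens <- analyze_ensembles(sim$traces, "vocal", seed = sd + 50)
      mean(ens$stats$pair_distances_um)
    }), na.rm = TRUE)
  })
  expect_lt(dist_mean[1], dist_mean[2])
})
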
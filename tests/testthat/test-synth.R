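test_that("two-photon simulation is deterministic and respects invariants", {
  p <- gt_protocol()
  cfg <- pt_population_config(n_neurons = 30)
  a <- simulate_two_photon(p, cfg, seed = 4)
  b <- simulate_two_photon(p, cfg, seed = 4)
  expect_identical(a$traces$spike_prob, b$traces$spike_prob)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_true(all(a$traces$spike_prob >= 0))
  gt <- a$ground_truth
  expect_true(all(gt$x_um >= 0 & gt$x_um <= cfg$fov_um[1]))
  grid <- hz2oct(p$frequencies_hz)
  expect_true(all(gt$true_bf_oct[gt$tuning_class == "single"] %in% grid))
  expect_error(simulate_two_photon(p, pt_population_config(
    fractions = c(single = 0.5, double = 0.1, irregular = 0.1, unresponsive = 0)),
    seed = 1), "sum to 1")
})

test_that("empty population yields empty outputs", {
  p <- gt_protocol()
  out <- simulate_two_photon(p, pt_population_config(n_neurons = 0), seed = 1)
  expect_equal(nrow(out$traces$spike_prob), 0)
  expect_equal(nrow(out$ground_truth), 0)
})

test_that("noise-free responses reproduce the planted tuning curve exactly", {
  p <- make_protocol("two_photon_pt", seed = 2)
  cfg <- pt_population_config(n_neurons = 12, trial_cv = 0, noise_sd = 0,
                              fractions = c(single = 1, double = 0,
                                            irregular = 0, unresponsive = 0))
  sim <- simulate_two_photon(p, cfg, seed = 6)
  combo <- window_means(sim$traces)
  resp <- classify_responsive(combo)
  grid <- hz2oct(p$frequencies_hz)
  gains <- l5topo:::spl_gain(p$spls_db)
  for (i in 1:nrow(sim$ground_truth)) {
    gt <- sim$ground_truth[i, ]
    fra <- build_fra(combo, resp, i)
    planted <- outer(l5topo:::gauss_curve(grid, 1, gt$true_bf_oct,
                                          gt$true_bw_oct / (2 * sqrt(log(2)))),
                     gains) / combo$window_frames
    expect_equal(fra$response, planted, tolerance = 1e-6)
  }
})

test_that("single-peaked noise-free neuron recovers its planted BF every time", {
  p <- make_protocol("two_photon_pt", seed = 2)
  cfg <- pt_population_config(n_neurons = 5, trial_cv = 0, noise_sd = 0,
                              sigma_topo_oct = 0,
                              fractions = c(single = 1, double = 0,
                                            irregular = 0, unresponsive = 0))
  sim <- simulate_two_photon(p, cfg, seed = 3)
  tn <- tune_neurons(sim$traces)
  expect_equal(tn$bf_oct, sim$ground_truth$true_bf_oct)
  expect_true(all(tn$tuning_class == "single"))
})

test_that("vocal motif calibration hits the target within-motif correlation", {
  proto <- make_protocol("two_photon_voc", seed = 3)
  sim <- simulate_vocal_responses(proto, motif_config(), seed = 42)
  cs <- correlation_structure(build_sound_vectors(sim$traces, "vocal"))
  gt <- sim$ground_truth$motif_id
  same <- outer(gt, gt, `==`)
  same[is.na(same)] <- FALSE
  diag(same) <- FALSE
  expect_equal(mean(cs$between[same], na.rm = TRUE), 0.4, tolerance = 0.05)
  # perfect motifs: correlation 1 within motifs
  sim1 <- simulate_vocal_responses(proto, motif_config(within_corr = 1,
                                                       noise_sd = 0), seed = 5)
  cs1 <- correlation_structure(build_sound_vectors(sim1$traces, "vocal"))
  gt1 <- sim1$ground_truth$motif_id
  same1 <- outer(gt1, gt1, `==`); same1[is.na(same1)] <- FALSE; diag(same1) <- FALSE
  expect_true(all(abs(cs1$between[same1] - 1) < 1e-9))
  expect_error(motif_config(n_motifs = -1), "config error")
})

test_that("widefield simulation is deterministic with planted geometry", {
  sched <- make_protocol("widefield_pt", seed = 2)
  cfg <- widefield_map_config(size = 16)
  a <- simulate_widefield(cfg, sched, seed = 8)
  b <- simulate_widefield(cfg, sched, seed = 8)
  expect_identical(a$pixels, b$pixels)
  expect_true(all(a$pixels >= 0))
  gt <- a$ground_truth
  expect_true(all(is.na(gt$bf_oct[!gt$responsive_mask])))
  expect_true(all(gt$bf_oct[gt$responsive_mask] %in% hz2oct(sched$frequencies_hz)))
})

test_that("network reliability is monotone in planted reliability", {
  p <- make_protocol("two_photon_pt", seed = 2)
  levels <- c(0.2, 0.5, 0.8, 1.0)
  mean_rel <- sapply(levels, function(r) {
    vals <- sapply(1:10, function(sd) {
      sim <- simulate_two_photon(p, pt_population_config(
        n_neurons = 15, reliability = r,
        fractions = c(single = 1, double = 0, irregular = 0, unresponsive = 0)),
        seed = sd)
      cs <- correlation_structure(build_sound_vectors(sim$traces, "pt50"))
      mean(cs$reliability, na.rm = TRUE)
    })
    mean(vals)
  })
  expect_true(all(diff(mean_rel) > 0))
})
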
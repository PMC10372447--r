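test_that("dF/F is zero for constant and exactly-cubic signals", {
  m <- array(80, c(2, 2, 300))
  d <- compute_dff(m, frame_rate_hz = 10)
  expect_lt(max(abs(d$values)), 1e-9)
  tt <- seq_len(400)
  cub <- 100 + 0.05 * tt - 2e-4 * tt^2 + 3e-7 * tt^3
  d2 <- compute_dff(array(rep(cub, each = 4), c(2, 2, 400)), 10)
  expect_lt(max(abs(d2$values)), 1e-8)
})

test_that("dF/F is invariant under global rescaling and flags bad pixels", {
  set.seed(4)
  m <- array(runif(4 * 300, 50, 150), c(2, 2, 300))
  d1 <- compute_dff(m, 10)
  d2 <- compute_dff(m * 7.3, 10)
  expect_equal(d1$values, d2$values, tolerance = 1e-9)
  m[1, 1, ] <- 0  # baseline <= 0 -> invalid pixel
  d3 <- compute_dff(m, 10)
  expect_true(d3$invalid[1, 1])
  expect_true(all(is.na(d3$values[1, 1, ])))
})

test_that("a brief transient on a drifting baseline is recovered", {
  fps <- 100; T_ <- 6000
  tt <- seq_len(T_)
  base <- 100 * (1 + 0.02 * sin(2 * pi * tt / fps / 60))
  tr <- rep(0, T_); tr[3000:3020] <- 0.20 * exp(-(0:20) / (0.2 * fps))
  d <- compute_dff(array(base * (1 + tr), c(1, 1, T_)), fps)
  expect_equal(max(d$values[1, 1, ]), 20, tolerance = 0.01 * 20)
})

test_that("evoked detection applies the z > 2 rule on a constructed movie", {
  # 1 pixel, one stimulus, 3 repetitions; flat baseline noise of known SD
  sched <- make_protocol("widefield_pt", seed = 1, frequencies_hz = 8000,
                         n_repetitions = 3)
  set.seed(2)
  T_ <- sched$n_frames
  vals <- matrix(rnorm(T_, 0, 1), 1, T_)
  o <- sched$onsets$onset_frame
  vals[1, o[1] + 2] <- 30       # strong response: z >> 2
  vals[1, o[2] + 2] <- 0        # nothing
  dff <- structure(list(values = vals, f0 = vals * 0 + 100, invalid = FALSE,
                        frame_rate_hz = 10), class = "dff_movie")
  prt <- detect_pixel_responses(dff, sched)
  expect_true(prt$evoked[1, 1, 1])
  expect_false(prt$evoked[1, 1, 2])
  # zero baseline SD -> undefined z -> non-evoked
  vals2 <- matrix(0, 1, T_); vals2[1, o[1] + 2] <- 5
  dff2 <- structure(list(values = vals2, f0 = vals2 * 0 + 100, invalid = FALSE,
                         frame_rate_hz = 10), class = "dff_movie")
  prt2 <- detect_pixel_responses(dff2, sched)
  expect_false(prt2$evoked[1, 1, 1])
  expect_true(is.na(prt2$z[1, 1, 1]))
})

test_that("pixel BF follows the repetition-minimum and argmax rules", {
  # hand-built response table: 1 pixel x 2 stimuli x 16 reps
  mk <- function(ev1, ev2, a1 = 12, a2 = 9) {
    evoked <- array(FALSE, c(1, 2, 16))
    amplitude <- array(0, c(1, 2, 16))
    evoked[1, 1, seq_len(ev1)] <- TRUE; amplitude[1, 1, seq_len(ev1)] <- a1
    evoked[1, 2, seq_len(ev2)] <- TRUE; amplitude[1, 2, seq_len(ev2)] <- a2
    structure(list(amplitude = amplitude, z = amplitude, evoked = evoked,
                   stim_ids = 1:2, freq_hz = c(4000, 8000), dim_hw = NULL,
                   invalid = FALSE, z_threshold = 2), class = "pixel_responses")
  }
  bm <- pixel_bf(mk(6, 0), min_evoked_reps = 4)
  expect_equal(bm$bf_oct, 0)                    # only one qualifying frequency
  bm2 <- pixel_bf(mk(6, 6), min_evoked_reps = 4)
  expect_equal(bm2$bf_oct, 0)                   # 12% beats 9%
  bm3 <- pixel_bf(mk(6, 6, a1 = 9, a2 = 12), min_evoked_reps = 4)
  expect_equal(bm3$bf_oct, 1)
  bm4 <- pixel_bf(mk(3, 3), min_evoked_reps = 4) # one below the minimum everywhere
  expect_false(bm4$responsive_mask)
  expect_true(is.na(bm4$bf_oct))
})

test_that("raising the repetition minimum never adds responsive pixels", {
  sched <- make_protocol("widefield_pt", seed = 2)
  wf <- simulate_widefield(widefield_map_config(size = 16, noise_sd = 3,
                                                response_amp_pct = 6),
                           sched, seed = 3)
  prt <- detect_pixel_responses(compute_dff(wf$pixels, 10), sched)
  n_resp <- sapply(c(2, 4, 8), function(k) sum(pixel_bf(prt, k)$responsive_mask))
  expect_true(all(diff(n_resp) <= 0))
})

test_that("pixel BF matches an exhaustive oracle on a toy response table", {
  set.seed(9)
  npix <- 16; n_stim <- 5; n_rep <- 16
  evoked <- array(runif(npix * n_stim * n_rep) < 0.4, c(npix, n_stim, n_rep))
  amplitude <- array(runif(npix * n_stim * n_rep, 0, 20), c(npix, n_stim, n_rep))
  prt <- structure(list(amplitude = amplitude, z = amplitude, evoked = evoked,
                        stim_ids = 1:5, freq_hz = make_pt_grid(4000, 64000, 1),
                        dim_hw = NULL, invalid = rep(FALSE, npix),
                        z_threshold = 2), class = "pixel_responses")
  bm <- pixel_bf(prt, min_evoked_reps = 4)
  for (px in seq_len(npix)) {        # brute-force recomputation
    fa <- rep(NA_real_, n_stim)
    for (s in seq_len(n_stim)) {
      ev <- evoked[px, s, ]
      if (sum(ev) >= 4) fa[s] <- mean(amplitude[px, s, ev])
    }
    if (all(is.na(fa))) {
      expect_true(is.na(bm$bf_oct[px]))
    } else {
      expect_equal(bm$bf_oct[px], hz2oct(prt$freq_hz)[which.max(fa)])
      expect_equal(bm$amplitude[px], max(fa, na.rm = TRUE))
    }
  }
})

test_that("stitching normalizes per FOV and keeps the stronger map", {
  m1 <- toy_bf_map(matrix(0, 2, 2), matrix(c(8, 8, 8, 8), 2, 2))
  expect_equal(stitch_fovs(list(m1))$bf_oct, m1$bf_oct)  # identity
  bf1 <- matrix(1, 2, 2); amp1 <- matrix(c(10, 10, 10, 8), 2, 2)     # norm 0.8 at [2,2]
  bf2 <- matrix(3, 2, 2); amp2 <- matrix(c(4, 4, 4, 2), 2, 2)        # norm 0.5 at [2,2]
  st <- stitch_fovs(list(toy_bf_map(bf1, amp1), toy_bf_map(bf2, amp2)))
  expect_equal(st$bf_oct[2, 2], 1)
  expect_equal(st$amplitude[2, 2], 0.8)
  # two FOVs tiling one planted gradient reproduce it
  sched <- make_protocol("widefield_pt", seed = 2)
  wf <- simulate_widefield(widefield_map_config(size = 32), sched, seed = 5)
  prt <- detect_pixel_responses(compute_dff(wf$pixels, 10), sched)
  bm <- pixel_bf(prt, 4)
  left <- bm; left$bf_oct <- bm$bf_oct[, 1:20]; left$amplitude <- bm$amplitude[, 1:20]
  left$responsive_mask <- bm$responsive_mask[, 1:20]
  right <- bm; right$bf_oct <- bm$bf_oct[, 13:32]; right$amplitude <- bm$amplitude[, 13:32]
  right$responsive_mask <- bm$responsive_mask[, 13:32]
  st2 <- stitch_fovs(list(left, right), offsets_px = list(c(0, 0), c(0, 12)))
  gt <- wf$ground_truth
  both <- gt$responsive_mask & st2$responsive_mask
  expect_gte(mean(st2$bf_oct[both] == gt$bf_oct[both], na.rm = TRUE), 0.95)
})

test_that("reversal points need a maximum and boundary needs a full run", {
  # monotone profile along every ray: no reversal
  bf <- matrix(rep(seq(0, 4, length.out = 21), each = 21), 21, 21, byrow = FALSE)
  m <- toy_bf_map(bf, bf * 0 + 1)
  rv <- find_reversal_points(m, hub_centers = list(c(1, 11)), n_angles = 8)
  expect_equal(nrow(rv$points), 0)
  expect_error(find_reversal_points(toy_bf_map(matrix(NA_real_, 5, 5),
                                               matrix(1, 5, 5)),
                                    hub_centers = list(c(3, 3))),
               "responsive")
  # 9 unresponsive pixels in a row: no boundary; 10: boundary at the run start
  mask9 <- matrix(TRUE, 1, 30); mask9[1, 12:20] <- FALSE
  mk <- function(mask) toy_bf_map(ifelse(mask, 1, NA_real_),
                                  ifelse(mask, 1, NA_real_))
  b9 <- find_ac_boundary(mk(mask9), center = c(1, 1), n_angles = 4,
                         run_length = 10)
  expect_false(any(b9$radius_px == 11))
  mask10 <- matrix(TRUE, 1, 30); mask10[1, 12:21] <- FALSE
  b10 <- find_ac_boundary(mk(mask10), center = c(1, 1), n_angles = 4,
                          run_length = 10)
  expect_true(11 %in% b10$radius_px)
})

test_that("the radial scanner draws the full 0.25-degree fan", {
  sched <- make_protocol("widefield_pt", seed = 2)
  wf <- simulate_widefield(widefield_map_config(size = 48, noise_sd = 0,
                                                drift_pct = 0), sched, seed = 5)
  bm <- pixel_bf(detect_pixel_responses(compute_dff(wf$pixels, 10), sched), 4)
  rv <- find_reversal_points(bm, list(wf$ground_truth$hub_center))
  expect_equal(rv$n_angles, 1440)
  expect_false(any(duplicated(rv$points$angle_deg)))  # at most one point per ray
  expect_gte(nrow(rv$points), 0.9 * 1440)
  expect_true(all(rv$points$angle_deg %% 0.25 == 0))  # the 0.25-degree fan
})

test_that("block downsampling averages pixel blocks", {
  m <- array(seq_len(4 * 4 * 2), c(4, 4, 2))
  d <- downsample_movie(m, 2)
  expect_equal(dim(d), c(2, 2, 2))
  expect_equal(d[1, 1, 1], mean(m[1:2, 1:2, 1]))
})
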
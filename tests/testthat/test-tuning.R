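x17 <- hz2oct(make_pt_grid(4000, 64000, 4))

test_that("collapse averages the FRA across sound levels", {
  m <- matrix(0.3, 17, 5)
  expect_equal(collapse_fra(m), rep(0.3, 17))
  m2 <- matrix(0, 17, 5); m2[6, 3] <- 1.5
  cc <- collapse_fra(m2)
  expect_equal(cc[6], 1.5 / 5)
  expect_equal(sum(cc[-6]), 0)
})

test_that("exact gaussian curves are recovered to high precision", {
  y1 <- l5topo:::gauss_curve(x17, 1, 2, 0.5, 0)
  f1 <- fit_gauss1(y1, x17)
  expect_true(f1$converged)
  expect_equal(unname(f1$params[c("A1", "B1", "C1", "D")]), c(1, 2, 0.5, 0),
               tolerance = 1e-6)
  expect_gt(f1$r2_adj, 0.999999)

  y2 <- l5topo:::gauss_curve(x17, 1, 1, 0.4, 0.05, A2 = 0.8, B2 = 3, C2 = 0.5)
  f2 <- fit_gauss2(y2, x17)
  expect_true(f2$converged)
  expect_equal(unname(f2$params["B1"]), 1, tolerance = 1e-4)
  expect_equal(unname(f2$params["B2"]), 3, tolerance = 1e-4)
  expect_true(f2$params["B1"] < f2$params["B2"])  # canonical order
})

test_that("constant input routes to the irregular path", {
  y <- rep(0.2, 17)
  f1 <- fit_gauss1(y, x17)
  f2 <- fit_gauss2(y, x17)
  expect_identical(f1$r2_adj, -Inf)
  expect_equal(classify_tuning(f1, f2), "irregular")
  expect_true(is.na(center_frequency(f1)))
})

test_that("noisy single peaks: peak position recovered within half a grid step", {
  set.seed(21)
  err <- replicate(100, {
    b <- runif(1, 0.5, 3.5); c1 <- runif(1, 0.2, 0.6)
    y <- l5topo:::gauss_curve(x17, 1, b, c1, 0) + rnorm(17, 0, 0.1)
    f <- fit_gauss1(y, x17)
    abs(f$params["B1"] - b)
  })
  expect_lte(median(err), 0.125)
})

test_that("adjusted-R2 penalty keeps the bimodal model behind on single peaks", {
  set.seed(22)
  res <- replicate(100, {
    b <- runif(1, 0.5, 3.5); c1 <- runif(1, 0.3, 0.6)
    y <- l5topo:::gauss_curve(x17, 1, b, c1, 0) + rnorm(17, 0, 0.05)
    f1 <- fit_gauss1(y, x17); f2 <- fit_gauss2(y, x17)
    c(delta = f2$r2_adj - f1$r2_adj,
      double = classify_tuning(f1, f2) == "double")
  })
  expect_lte(median(res["delta", ]), 0.01)   # penalty dominates on average
  expect_lte(mean(res["double", ]), 0.10)    # spurious double calls stay rare
})

test_that("classification thresholds behave as specified", {
  mk <- function(r2, model = "gauss1", pars = NULL) {
    if (is.null(pars))
      pars <- if (model == "gauss1") c(A1 = 1, B1 = 2, C1 = 0.4, D = 0) else
        c(A1 = 1, B1 = 1, C1 = 0.4, A2 = 0.8, B2 = 3, C2 = 0.4, D = 0)
    structure(list(model = model, params = pars, r2_adj = r2, converged = TRUE),
              class = "gauss_fit")
  }
  expect_equal(classify_tuning(mk(0.29), mk(0.29, "gauss2")), "irregular")
  expect_equal(classify_tuning(mk(0.8), mk(0.5, "gauss2")), "single")
  expect_equal(classify_tuning(mk(0.5), mk(0.8, "gauss2")), "double")
  # an unresolvably narrow or faint second peak cannot win
  narrow <- mk(0.9, "gauss2", c(A1 = 1, B1 = 1, C1 = 0.4, A2 = 0.9, B2 = 3,
                                C2 = 0.05, D = 0))
  expect_equal(classify_tuning(mk(0.8), narrow), "single")
  faint <- mk(0.9, "gauss2", c(A1 = 1, B1 = 1, C1 = 0.4, A2 = 0.01, B2 = 3,
                               C2 = 0.4, D = 0))
  expect_equal(classify_tuning(mk(0.8), faint), "single")
})

test_that("bandwidth equals the closed-form FWHM and its invariances", {
  f <- fit_gauss1(l5topo:::gauss_curve(x17, 1, 2, 1, 0), x17)
  expect_equal(unname(bandwidth(f)), 2 * sqrt(log(2)), tolerance = 1e-6)
  f05 <- fit_gauss1(l5topo:::gauss_curve(x17, 1, 2, 0.5, 0), x17)
  expect_equal(unname(bandwidth(f05)), sqrt(log(2)), tolerance = 1e-6)
  # invariance under amplitude scaling and peak shifts
  fa <- fit_gauss1(l5topo:::gauss_curve(x17, 7, 2, 0.5, 0), x17)
  fb <- fit_gauss1(l5topo:::gauss_curve(x17, 1, 3, 0.5, 0), x17)
  expect_equal(bandwidth(fa), bandwidth(f05), tolerance = 1e-6)
  expect_equal(bandwidth(fb), bandwidth(f05), tolerance = 1e-6)
})

test_that("best frequency uses only significant combinations with low-frequency ties", {
  resp <- matrix(0, 17, 5)
  sig <- matrix(FALSE, 17, 5)
  resp[10, 3] <- 1.0            # strongest overall, not significant
  resp[4, 2] <- 0.5; sig[4, 2] <- TRUE
  fra <- structure(list(response = resp, significant = sig,
                        freq_hz = make_pt_grid(4000, 64000, 4),
                        freq_oct = x17, spls_db = seq(30, 70, 10)),
                   class = "fra")
  expect_equal(best_frequency(fra), x17[4])
  # tie across two frequencies breaks toward the lower one
  resp2 <- resp; sig2 <- sig
  resp2[8, 1] <- 0.5; sig2[8, 1] <- TRUE
  fra2 <- fra; fra2$response <- resp2; fra2$significant <- sig2
  expect_equal(best_frequency(fra2), x17[4])
  # no significant combination -> undefined
  fra3 <- fra; fra3$significant[] <- FALSE
  expect_true(is.na(best_frequency(fra3)))
})

test_that("center frequency is the unimodal fit peak", {
  y <- l5topo:::gauss_curve(x17, 0.8, 2.25, 0.5, 0.02)
  expect_equal(center_frequency(fit_gauss1(y, x17)), 2.25, tolerance = 1e-6)
})

test_that("classification is invariant to fit evaluation order", {
  set.seed(30)
  y <- l5topo:::gauss_curve(x17, 1, 1.5, 0.4, 0) + rnorm(17, 0, 0.08)
  f1 <- fit_gauss1(y, x17); f2 <- fit_gauss2(y, x17)
  f2b <- fit_gauss2(y, x17); f1b <- fit_gauss1(y, x17)  # other order
  expect_identical(classify_tuning(f1, f2), classify_tuning(f1b, f2b))
})
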
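#' Frequency response area of one neuron
#'
#' Mean post-onset window response per frequency-SPL combination (rows =
#' frequencies ascending, columns = SPLs ascending), plus the significance
#' mask from the responsiveness screen.
#'
#' @param combo a [window_means()] result (pure-tone protocol).
#' @param resp the matching [classify_responsive()] result.
#' @param neuron neuron index.
#' @return object of class `fra`: list with `response` (n_freq x n_spl),
#'   `significant` (same shape), `freq_oct`, `freq_hz`, `spls_db`.
#' @export
build_fra <- function(combo, resp, neuron) {
  stopifnot(inherits(combo, "combo_response"), !is.null(combo$combos$freq_index))
  cb <- combo$combos
  n_f <- max(cb$freq_index); n_l <- max(cb$spl_index)
  post_mean <- rowMeans(combo$post[neuron, , , drop = FALSE], dims = 2, na.rm = TRUE)
  m <- matrix(NA_real_, n_f, n_l); s <- matrix(FALSE, n_f, n_l)
  m[cbind(cb$freq_index, cb$spl_index)] <- post_mean
  s[cbind(cb$freq_index, cb$spl_index)] <- resp$significant[neuron, ]
  freq_hz <- numeric(n_f); freq_hz[cb$freq_index] <- cb$freq_hz
  spls <- numeric(n_l); spls[cb$spl_index] <- cb$spl_db
  structure(list(response = m, significant = s,
                 freq_hz = freq_hz, freq_oct = hz2oct(freq_hz), spls_db = spls),
            class = "fra")
}

#' Collapse an FRA across sound levels
#'
#' Per-frequency mean response over all SPLs: the 17-point tuning curve that
#' the gaussian models are fitted to.
#'
#' @param fra an [build_fra()] object (or a plain response matrix).
#' @return numeric vector, one mean per frequency.
#' @export
collapse_fra <- function(fra) {
  m <- if (inherits(fra, "fra")) fra$response else fra
  rowMeans(m, na.rm = TRUE)
}

r2_adjusted <- function(y, fitted, n_par) {
  n <- length(y)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(-Inf)
  r2 <- 1 - sum((y - fitted)^2) / ss_tot
  1 - (1 - r2) * (n - 1) / (n - n_par - 1)
}

gauss_fit_skeleton <- function(model, n_par) {
  list(model = model, params = NULL, r2_adj = -Inf, converged = FALSE,
       fitted = NULL, n_par = n_par)
}

#' Fit a unimodal gaussian tuning curve
#'
#' Nonlinear least squares of `A1 * exp(-((x - B1)/C1)^2) + D` to the
#' collapsed per-frequency means, on the octave axis. Multi-start
#' (peak position at the curve maximum and at the grid centre) bounded
#' Levenberg-Marquardt; `A1 >= 0`, `B1` in `[-1, 5]`, `C1` in `(0.05, 8]`,
#' `D` free. Goodness of fit is the adjusted coefficient of determination
#' with `p = 4` parameters over the `n = length(x)` points; non-convergence
#' yields `converged = FALSE` and `r2_adj = -Inf`.
#'
#' @param y per-frequency mean responses.
#' @param x octave positions of the tone grid (same length as `y`).
#' @return object of class `gauss_fit`: `model`, `params`
#'   (A1, B1, C1, D [, A2, B2, C2]), `r2_adj`, `converged`, `fitted`.
#' @export
fit_gauss1 <- function(y, x) {
  stopifnot(length(x) == length(y), all(is.finite(x)))
  out <- gauss_fit_skeleton("gauss1", 4L)
  if (!all(is.finite(y)) || stats::sd(y) == 0) return(structure(out, class = "gauss_fit"))
  lower <- c(A1 = 0, B1 = -1, C1 = 0.05, D = -Inf)
  upper <- c(A1 = Inf, B1 = 5, C1 = 8, D = Inf)
  b_starts <- unique(c(x[which.max(y)], mean(range(x))))
  best <- NULL
  for (b0 in b_starts) for (c0 in c(0.25, 0.5, 1)) {
    st <- c(A1 = max(y) - min(y), B1 = b0, C1 = c0, D = min(y))
    st["A1"] <- max(st["A1"], 1e-6)
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ A1 * exp(-((x - B1) / C1)^2) + D,
      start = as.list(st), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(structure(out, class = "gauss_fit"))
  pars <- stats::coef(best$fit)
  fitted_y <- gauss_curve(x, pars["A1"], pars["B1"], pars["C1"], pars["D"])
  out$params <- pars
  out$fitted <- fitted_y
  out$converged <- TRUE
  out$r2_adj <- r2_adjusted(y, fitted_y, 4L)
  structure(out, class = "gauss_fit")
}

# second-highest local maximum of a curve, for the bimodal start
second_peak_start <- function(y, x) {
  n <- length(y)
  is_max <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    y[i] >= l && y[i] >= r
  }, logical(1))
  cand <- setdiff(which(is_max), which.max(y))
  if (length(cand) == 0) return(x[which.max(y)] + diff(range(x)) / 3)
  x[cand[which.max(y[cand])]]
}

#' Fit a bimodal gaussian tuning curve
#'
#' As [fit_gauss1()] with a second gaussian component (`p = 7` parameters);
#' peaks are returned in canonical order `B1 < B2`. Starts place the peaks at
#' the global maximum and the second-highest local maximum.
#'
#' @inheritParams fit_gauss1
#' @return a `gauss_fit` with `model = "gauss2"`.
#' @export
fit_gauss2 <- function(y, x) {
  stopifnot(length(x) == length(y), all(is.finite(x)))
  out <- gauss_fit_skeleton("gauss2", 7L)
  if (!all(is.finite(y)) || stats::sd(y) == 0) return(structure(out, class = "gauss_fit"))
  lower <- c(A1 = 0, B1 = -1, C1 = 0.05, A2 = 0, B2 = -1, C2 = 0.05, D = -Inf)
  upper <- c(A1 = Inf, B1 = 5, C1 = 8, A2 = Inf, B2 = 5, C2 = 8, D = Inf)
  b1_0 <- x[which.max(y)]
  b2_0 <- second_peak_start(y, x)
  amp0 <- max(max(y) - min(y), 1e-6)
  best <- NULL
  for (c0 in c(0.25, 0.5)) for (swap in c(FALSE, TRUE)) {
    bb <- if (swap) c(b2_0, b1_0) else c(b1_0, b2_0)
    st <- c(A1 = amp0, B1 = bb[1], C1 = c0, A2 = amp0 / 2, B2 = bb[2], C2 = c0,
            D = min(y))
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ A1 * exp(-((x - B1) / C1)^2) + A2 * exp(-((x - B2) / C2)^2) + D,
      start = as.list(st), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(structure(out, class = "gauss_fit"))
  pars <- stats::coef(best$fit)
  if (pars["B1"] > pars["B2"]) {  # canonical ordering of the two peaks
    pars <- pars[c("A2", "B2", "C2", "A1", "B1", "C1", "D")]
    names(pars) <- c("A1", "B1", "C1", "A2", "B2", "C2", "D")
  }
  fitted_y <- gauss_curve(x, pars["A1"], pars["B1"], pars["C1"], pars["D"],
                          pars["A2"], pars["B2"], pars["C2"])
  out$params <- pars
  out$fitted <- fitted_y
  out$converged <- TRUE
  out$r2_adj <- r2_adjusted(y, fitted_y, 7L)
  structure(out, class = "gauss_fit")
}

#' Classify tuning type from the two gaussian fits
#'
#' Both fits below the adjusted-R2 threshold classify the neuron as
#' `irregular`; otherwise the better-fitting model decides `single` vs
#' `double`. A bimodal fit is only eligible when it describes two genuinely
#' resolvable peaks: both fitted amplitudes positive with the smaller at
#' least `min_amp_ratio` of the larger (under bounded least squares an
#' amplitude is never exactly zero, so a vanishing second component would
#' otherwise let the bimodal model win by absorbing one noise wiggle), and
#' the peaks separated by at least `min_separation_oct` (two gaussians
#' closer than one grid step are not identifiable as distinct peaks on the
#' tone grid); and both peak widths resolvable on the grid — full width at
#' half maximum of at least one grid step (a narrower component is pinned to
#' a single noisy sample) and at most the span of the frequency axis (a
#' wider component is a baseline tilt, not a peak). An ineligible bimodal
#' fit falls back to the unimodal comparison.
#'
#' @param fit1,fit2 the [fit_gauss1()] and [fit_gauss2()] results.
#' @param threshold adjusted-R2 cutoff (default 0.3).
#' @param min_amp_ratio minimum secondary/primary amplitude ratio (default 0.1).
#' @param min_separation_oct minimum peak separation in octaves (default
#'   0.25, one grid step of the standard tone grid).
#' @param min_peak_fwhm_oct,max_peak_fwhm_oct resolvable peak-width range
#'   (defaults: one grid step, full axis span of the standard grid).
#' @return `"single"`, `"double"` or `"irregular"`.
#' @export
classify_tuning <- function(fit1, fit2, threshold = 0.3,
                            min_amp_ratio = 0.1, min_separation_oct = 0.25,
                            min_peak_fwhm_oct = 0.25, max_peak_fwhm_oct = 4) {
  r1 <- if (fit1$converged) fit1$r2_adj else -Inf
  fwhm_ok <- function(C) {
    fw <- 2 * C * sqrt(log(2))
    fw >= min_peak_fwhm_oct && fw <= max_peak_fwhm_oct
  }
  eligible2 <- fit2$converged && !is.null(fit2$params) &&
    fit2$params["A1"] > 0 && fit2$params["A2"] > 0 &&
    min(fit2$params[c("A1", "A2")]) >=
      min_amp_ratio * max(fit2$params[c("A1", "A2")]) &&
    abs(fit2$params["B2"] - fit2$params["B1"]) >= min_separation_oct &&
    fwhm_ok(fit2$params["C1"]) && fwhm_ok(fit2$params["C2"])
  r2 <- if (eligible2) fit2$r2_adj else -Inf
  if (r1 < threshold && r2 < threshold) return("irregular")
  if (r2 > r1) "double" else "single"
}

#' Tuning bandwidth (FWHM) of a fitted gaussian peak
#'
#' The full width at half maximum of `exp(-((x - B)/C)^2)` is
#' `2 * C * sqrt(ln 2)` octaves; returned per peak for bimodal fits.
#'
#' @param fit a `gauss_fit`.
#' @return named numeric vector of bandwidths in octaves (one per peak);
#'   `NA` where the peak is undefined (C <= 0 or zero amplitude).
#' @export
bandwidth <- function(fit) {
  stopifnot(inherits(fit, "gauss_fit"))
  if (!fit$converged) return(NA_real_)
  p <- fit$params
  bw1 <- if (p["C1"] > 0 && p["A1"] > 0) 2 * p["C1"] * sqrt(log(2)) else NA_real_
  if (fit$model == "gauss1") return(c(bw = unname(bw1)))
  bw2 <- if (p["C2"] > 0 && p["A2"] > 0) 2 * p["C2"] * sqrt(log(2)) else NA_real_
  c(bw1 = unname(bw1), bw2 = unname(bw2))
}

#' Best frequency of a neuron
#'
#' The tone frequency eliciting the strongest significant response,
#' regardless of SPL. Undefined (NA) when no combination is significant;
#' ties are broken toward the lower frequency.
#'
#' @param fra a [build_fra()] object.
#' @return best frequency in octaves, or `NA`.
#' @export
best_frequency <- function(fra) {
  stopifnot(inherits(fra, "fra"))
  r <- fra$response
  r[!fra$significant] <- -Inf
  if (!any(fra$significant)) return(NA_real_)
  best <- which(r == max(r), arr.ind = TRUE)
  fra$freq_oct[min(best[, 1])]
}

#' Center frequency of a neuron
#'
#' The peak position (B1) of the unimodal gaussian fit, reported for all
#' responsive neurons regardless of tuning class; undefined when the fit
#' did not converge.
#'
#' @param fit1 the [fit_gauss1()] result.
#' @return center frequency in octaves, or `NA`.
#' @export
center_frequency <- function(fit1) {
  stopifnot(inherits(fit1, "gauss_fit"), fit1$model == "gauss1")
  if (!fit1$converged) return(NA_real_)
  unname(fit1$params["B1"])
}

#' Full tuning analysis of a two-photon recording
#'
#' Runs the responsiveness screen, builds per-neuron FRAs, fits the
#' unimodal and bimodal gaussians to the collapsed tuning curves of
#' responsive neurons, classifies tuning type and computes bandwidth,
#' best frequency and center frequency.
#'
#' @param traces a `trace_set` from a pure-tone recording.
#' @param window_s analysis window (default 0.4 s).
#' @param alpha per-combination significance level (default 0.01).
#' @param threshold adjusted-R2 classification cutoff (default 0.3).
#' @return data frame, one row per neuron: `id`, `responsive`,
#'   `tuning_class` (`NA` for non-responsive neurons), `r2adj_1`, `r2adj_2`,
#'   `bf_oct`, `bf_hz`, `cef_oct`, `bw_oct`, `bw2_oct`, fit parameters.
#' @export
tune_neurons <- function(traces, window_s = 0.4, alpha = 0.01, threshold = 0.3) {
  combo <- window_means(traces, window_s = window_s)
  resp <- classify_responsive(combo, alpha = alpha)
  n <- nrow(traces$spike_prob)
  x <- hz2oct(traces$protocol$frequencies_hz)
  res <- data.frame(id = traces$rois$id, responsive = resp$responsive,
                    tuning_class = NA_character_, r2adj_1 = NA_real_,
                    r2adj_2 = NA_real_, bf_oct = NA_real_, bf_hz = NA_real_,
                    cef_oct = NA_real_, bw_oct = NA_real_, bw2_oct = NA_real_,
                    A1 = NA_real_, B1 = NA_real_, C1 = NA_real_, D = NA_real_)
  for (i in seq_len(n)) {
    if (!resp$responsive[i]) next
    fra <- build_fra(combo, resp, i)
    y <- collapse_fra(fra)
    f1 <- fit_gauss1(y, x)
    f2 <- fit_gauss2(y, x)
    step <- stats::median(diff(x))
    cls <- classify_tuning(f1, f2, threshold,
                           min_separation_oct = step,
                           min_peak_fwhm_oct = step,
                           max_peak_fwhm_oct = diff(range(x)))
    res$tuning_class[i] <- cls
    res$r2adj_1[i] <- f1$r2_adj
    res$r2adj_2[i] <- f2$r2_adj
    res$bf_oct[i] <- best_frequency(fra)
    res$bf_hz[i] <- if (is.na(res$bf_oct[i])) NA_real_ else oct2hz(res$bf_oct[i])
    res$cef_oct[i] <- center_frequency(f1)
    if (cls == "single") {
      res$bw_oct[i] <- bandwidth(f1)
    } else if (cls == "double") {
      bw <- bandwidth(f2)
      res$bw_oct[i] <- bw[1]; res$bw2_oct[i] <- bw[2]
    }
    if (f1$converged) {
      res$A1[i] <- f1$params["A1"]; res$B1[i] <- f1$params["B1"]
      res$C1[i] <- f1$params["C1"]; res$D[i] <- f1$params["D"]
    }
  }
  attr(res, "respond") <- resp
  res
}
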
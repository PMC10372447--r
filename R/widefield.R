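#' Block-average downsampling of a widefield movie
#'
#' Reduces a raw `H x W x T` movie to the analysis resolution (typically
#' 256 x 256) by averaging non-overlapping pixel blocks.
#'
#' @param movie 3-D array `H x W x T`.
#' @param factor integer block size (H and W must be divisible by it).
#' @return downsampled `H/factor x W/factor x T` array.
#' @export
downsample_movie <- function(movie, factor) {
  d <- dim(movie)
  stopifnot(length(d) == 3, d[1] %% factor == 0, d[2] %% factor == 0)
  h2 <- d[1] %/% factor; w2 <- d[2] %/% factor
  m <- array(movie, c(factor, h2, factor, w2, d[3]))
  out <- apply(m, c(2, 4, 5), mean)
  out
}

# Savitzky-Golay style centred polynomial-fit weights: value at `at`
# (1-based index within the window) of a degree-`deg` LS fit on `len` points.
polyfit_weights <- function(len, at, deg = 3) {
  x <- (seq_len(len) - at) / max(len - at, at - 1, 1)  # conditioned abscissa
  v <- outer(x, 0:deg, `^`)
  as.vector((solve(crossprod(v)) %*% t(v))[1, ])
}

#' Temporal baseline and percent fluorescence change (dF/F0)
#'
#' Removes slow drifts by fitting, for every pixel and frame, a degree-3
#' polynomial over a 15-s window centred on the frame (the window truncates
#' at the recording edges rather than padding) and evaluating it at the frame:
#' that is the temporal baseline F0. The output is the percent change
#' `(F - F0) / F0 * 100`. Pixels whose baseline ever drops to zero or below
#' are flagged invalid and excluded from response detection.
#'
#' @param movie `H x W x T` array (or `npix x T` matrix).
#' @param frame_rate_hz acquisition rate.
#' @param window_s sliding-window length in seconds (default 15).
#' @param poly_degree polynomial degree (default 3).
#' @return object of class `dff_movie`: `values` and `f0` in the same shape
#'   as the input, `invalid` logical (pixels with non-positive baseline),
#'   `frame_rate_hz`.
#' @export
compute_dff <- function(movie, frame_rate_hz, window_s = 15, poly_degree = 3) {
  d <- dim(movie)
  is_array <- length(d) == 3
  m <- if (is_array) matrix(movie, d[1] * d[2], d[3]) else movie
  T_ <- ncol(m)
  wlen <- round(window_s * frame_rate_hz)
  if (wlen %% 2 == 0) wlen <- wlen + 1L  # symmetric window around the frame
  stopifnot(T_ > wlen)
  half <- (wlen - 1L) %/% 2L

  y <- t(m)  # T x npix, stats::filter works column-wise
  w_int <- polyfit_weights(wlen, half + 1L, poly_degree)
  f0 <- stats::filter(y, w_int, sides = 2)
  f0 <- matrix(as.numeric(f0), T_, ncol(y))
  for (t in c(seq_len(half), (T_ - half + 1L):T_)) {  # truncated edge windows
    a <- max(1L, t - half); b <- min(T_, t + half)
    w <- polyfit_weights(b - a + 1L, t - a + 1L, poly_degree)
    f0[t, ] <- as.vector(w %*% y[a:b, , drop = FALSE])
  }
  f0 <- t(f0)
  invalid <- apply(f0 <= 0, 1, any)
  vals <- (m - f0) / f0 * 100
  vals[invalid, ] <- NA_real_
  if (is_array) {
    vals <- array(vals, d); f0 <- array(f0, d)
    invalid <- matrix(invalid, d[1], d[2])
  }
  structure(list(values = vals, f0 = f0, invalid = invalid,
                 frame_rate_hz = frame_rate_hz),
            class = "dff_movie")
}

#' Detect tone-evoked pixel responses
#'
#' For every pixel, stimulus and repetition: the baseline is the mean and SD
#' of the dF/F amplitudes of all frames in the 2-s prestimulus period of that
#' presentation; the response is the maximum amplitude within the 750-ms
#' post-onset period averaged with its preceding and following frame. The
#' response is tone-evoked when it exceeds the prestimulus distribution by
#' more than two standard deviations (z-score > 2). A zero baseline SD makes
#' the z-score undefined; such presentations are marked non-evoked.
#'
#' @param dff a [compute_dff()] result.
#' @param schedule the widefield `stim_protocol`.
#' @param prestim_s prestimulus baseline period (default 2).
#' @param peak_window_s post-onset search window (default 0.75).
#' @param z_threshold evoked threshold (default 2).
#' @return object of class `pixel_responses`: arrays `amplitude`, `z`,
#'   `evoked` of shape `[npix, stimulus, repetition]`, plus `stim_ids`,
#'   `freq_hz`, `dim_hw`, `invalid`.
#' @export
detect_pixel_responses <- function(dff, schedule, prestim_s = 2,
                                   peak_window_s = 0.75, z_threshold = 2) {
  stopifnot(inherits(dff, "dff_movie"))
  d <- dim(dff$values)
  is_array <- length(d) == 3
  vals <- if (is_array) matrix(dff$values, d[1] * d[2], d[3]) else dff$values
  fps <- dff$frame_rate_hz
  ons <- schedule$onsets
  n_stim <- length(schedule$frequencies_hz)
  n_rep <- max(ons$repetition)
  npix <- nrow(vals); T_ <- ncol(vals)
  pre_f <- round(prestim_s * fps)
  post_f <- floor(peak_window_s * fps)
  stopifnot(all(ons$onset_frame - pre_f >= 1),
            all(ons$onset_frame + post_f + 1 <= T_))

  amplitude <- array(NA_real_, c(npix, n_stim, n_rep))
  z <- array(NA_real_, c(npix, n_stim, n_rep))
  for (k in seq_len(nrow(ons))) {
    o <- ons$onset_frame[k]
    base <- vals[, (o - pre_f):(o - 1), drop = FALSE]
    mu <- rowMeans(base)
    sdv <- sqrt(rowSums((base - mu)^2) / (pre_f - 1))
    win <- vals[, o:(o + post_f), drop = FALSE]
    pk <- max.col(replace(win, is.na(win), -Inf), ties.method = "first")
    pk_abs <- o + pk - 1L
    resp <- (vals[cbind(seq_len(npix), pk_abs - 1L)] +
             vals[cbind(seq_len(npix), pk_abs)] +
             vals[cbind(seq_len(npix), pk_abs + 1L)]) / 3
    s <- ons$freq_index[k]; r <- ons$repetition[k]
    amplitude[, s, r] <- resp
    zz <- (resp - mu) / sdv
    zz[sdv == 0] <- NA_real_
    z[, s, r] <- zz
  }
  evoked <- !is.na(z) & z > z_threshold
  inval <- if (is_array) as.vector(dff$invalid) else dff$invalid
  evoked[inval, , ] <- FALSE
  structure(list(amplitude = amplitude, z = z, evoked = evoked,
                 stim_ids = seq_len(n_stim), freq_hz = schedule$frequencies_hz,
                 dim_hw = if (is_array) d[1:2] else NULL,
                 invalid = inval, z_threshold = z_threshold),
            class = "pixel_responses")
}

#' Per-pixel best-frequency map
#'
#' A frequency-specific response amplitude is the mean of the tone-evoked
#' response amplitudes at that frequency, computed only when the tone evoked
#' a response in at least `min_evoked_reps` repetitions (2 of 16 for
#' recordings with sparse corticocollicular-limited expression, 4 of 16 for
#' general expression). The best frequency of a pixel is the frequency with
#' the highest frequency-specific amplitude; ties break toward the lower
#' frequency. Pixels with no qualifying frequency are unresponsive.
#'
#' @param prt a [detect_pixel_responses()] result.
#' @param min_evoked_reps minimum evoked repetitions (default 4).
#' @return object of class `bf_map`: `bf_oct`, `amplitude` (the BF's
#'   frequency-specific amplitude), `freq_amp` (`npix x n_stim`),
#'   `responsive_mask`, `freq_oct`, `dim_hw` (matrices when the source movie
#'   was an array).
#' @export
pixel_bf <- function(prt, min_evoked_reps = 4) {
  stopifnot(inherits(prt, "pixel_responses"))
  npix <- dim(prt$amplitude)[1]; n_stim <- dim(prt$amplitude)[2]
  n_evoked <- apply(prt$evoked, c(1, 2), sum)
  amp_sum <- apply(ifelse(prt$evoked, prt$amplitude, 0), c(1, 2), sum)
  freq_amp <- ifelse(n_evoked >= min_evoked_reps, amp_sum / n_evoked, NA_real_)
  has_any <- rowSums(!is.na(freq_amp)) > 0
  bf_idx <- max.col(replace(freq_amp, is.na(freq_amp), -Inf), ties.method = "first")
  freq_oct <- hz2oct(prt$freq_hz)
  bf_oct <- ifelse(has_any, freq_oct[bf_idx], NA_real_)
  amp <- ifelse(has_any, freq_amp[cbind(seq_len(npix), bf_idx)], NA_real_)
  out <- list(bf_oct = bf_oct, amplitude = amp, freq_amp = freq_amp,
              responsive_mask = has_any, freq_oct = freq_oct,
              freq_hz = prt$freq_hz, dim_hw = prt$dim_hw,
              min_evoked_reps = min_evoked_reps)
  if (!is.null(prt$dim_hw)) {
    out$bf_oct <- matrix(bf_oct, prt$dim_hw[1], prt$dim_hw[2])
    out$amplitude <- matrix(amp, prt$dim_hw[1], prt$dim_hw[2])
    out$responsive_mask <- matrix(has_any, prt$dim_hw[1], prt$dim_hw[2])
  }
  structure(out, class = "bf_map")
}

#' Stitch overlapping best-frequency maps
#'
#' Places per-FOV maps on a shared canvas. Frequency-specific amplitudes are
#' normalized within each FOV (divided by the FOV's maximum amplitude) to
#' make FOVs comparable; where FOVs overlap, the pixel takes the BF of the
#' FOV with the higher normalized amplitude.
#'
#' @param maps list of `bf_map`s (matrix form).
#' @param offsets_px list/matrix of `(row, col)` offsets (0-based) of each
#'   map's top-left corner on the canvas.
#' @param canvas_hw canvas size `c(H, W)`; default tight bounding box.
#' @return a stitched `bf_map` with normalized `amplitude`.
#' @export
stitch_fovs <- function(maps, offsets_px = NULL, canvas_hw = NULL) {
  stopifnot(length(maps) >= 1, all(vapply(maps, inherits, logical(1), "bf_map")))
  if (is.null(offsets_px)) offsets_px <- rep(list(c(0L, 0L)), length(maps))
  hw <- lapply(maps, function(m) dim(m$bf_oct))
  if (any(vapply(hw, is.null, logical(1))))
    stop("stitch_fovs needs maps in matrix form (movie input as H x W x T array)")
  if (is.null(canvas_hw))
    canvas_hw <- c(max(mapply(function(h, o) h[1] + o[1], hw, offsets_px)),
                   max(mapply(function(h, o) h[2] + o[2], hw, offsets_px)))
  bf <- matrix(NA_real_, canvas_hw[1], canvas_hw[2])
  amp <- matrix(-Inf, canvas_hw[1], canvas_hw[2])
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    norm_amp <- m$amplitude / max(m$amplitude, na.rm = TRUE)
    o <- offsets_px[[k]]
    ri <- o[1] + seq_len(nrow(m$bf_oct)); ci <- o[2] + seq_len(ncol(m$bf_oct))
    sub_bf <- bf[ri, ci]; sub_amp <- amp[ri, ci]
    better <- !is.na(norm_amp) & norm_amp > sub_amp
    sub_bf[better] <- m$bf_oct[better]
    sub_amp[better] <- norm_amp[better]
    bf[ri, ci] <- sub_bf; amp[ri, ci] <- sub_amp
  }
  amp[!is.finite(amp)] <- NA_real_
  structure(list(bf_oct = bf, amplitude = amp,
                 responsive_mask = !is.na(bf),
                 freq_oct = maps[[1]]$freq_oct, freq_hz = maps[[1]]$freq_hz,
                 dim_hw = canvas_hw, min_evoked_reps = maps[[1]]$min_evoked_reps),
            class = "bf_map")
}

moving_average <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  half_l <- (w - 1) %/% 2; half_r <- w %/% 2
  for (i in seq_len(n)) {
    a <- max(1, i - half_l); b <- min(n, i + half_r)
    out[i] <- mean(x[a:b], na.rm = TRUE)
  }
  out
}

gaussian_smooth <- function(x, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r) / sigma)^2 / 2)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1, i - r); b <- min(n, i + r)
    kk <- k[(a - i + r + 1):(b - i + r + 1)]
    xv <- x[a:b]
    ok <- !is.na(xv)
    out[i] <- if (any(ok)) sum(xv[ok] * kk[ok]) / sum(kk[ok]) else NA_real_
  }
  out
}

first_local_max <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_integer_)
  for (i in 2:(n - 1)) {
    if (is.na(x[i]) || is.na(x[i - 1]) || is.na(x[i + 1])) next
    if (x[i] >= x[i - 1] && x[i] > x[i + 1]) return(i)
  }
  NA_integer_
}

#' Automatic low-frequency hub centre
#'
#' Centroid of the largest 4-connected component of responsive pixels whose
#' BF falls in the lowest frequency class of the map.
#'
#' @param bfmap a `bf_map` (matrix form).
#' @return `c(row, col)` centre (1-based pixel coordinates).
#' @export
find_low_freq_hub <- function(bfmap) {
  bf <- bfmap$bf_oct
  lowest <- min(bf, na.rm = TRUE)
  mask <- !is.na(bf) & bf == lowest
  lab <- label_components(mask)
  if (max(lab) == 0) stop("no responsive low-frequency pixels")
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  colMeans(idx)
}

# 4-connected component labelling of a logical matrix (small masks)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(mask)) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

#' Reversal points along radial vectors
#'
#' From each low-frequency hub centre, 1,440 radial vectors (0 to 360
#' degrees in 0.25-degree steps) are drawn. The BF values of responsive
#' pixels within 1 degree of a vector are averaged per 1-pixel radial bin,
#' smoothed with a 10-sample moving average and then with a gaussian filter
#' (sigma = 3 samples); the first local maximum along the ray marks the
#' tonotopic reversal point.
#'
#' @param bfmap a `bf_map` (matrix form).
#' @param hub_centers list of `c(row, col)` centres; `NULL` for automatic
#'   low-frequency hub detection.
#' @param n_angles number of radial vectors (default 1440).
#' @param angular_tol_deg half-width of the angular window (default 1).
#' @param ma_window moving-average window in samples (default 10).
#' @param gauss_sigma gaussian smoothing sigma in samples (default 3).
#' @return object of class `reversal_set`: data frame `points`
#'   (hub, angle_deg, radius_px, row, col) with one row per ray that has a
#'   reversal, and `hub_centers`.
#' @export
find_reversal_points <- function(bfmap, hub_centers = NULL, n_angles = 1440,
                                 angular_tol_deg = 1, ma_window = 10,
                                 gauss_sigma = 3) {
  stopifnot(inherits(bfmap, "bf_map"), !is.null(dim(bfmap$bf_oct)))
  if (is.null(hub_centers)) hub_centers <- list(find_low_freq_hub(bfmap))
  bf <- bfmap$bf_oct
  H <- nrow(bf); W <- ncol(bf)
  resp <- which(!is.na(bf), arr.ind = TRUE)
  out <- list()
  for (hub_i in seq_along(hub_centers)) {
    ctr <- hub_centers[[hub_i]]
    if (ctr[1] < 1 || ctr[1] > H || ctr[2] < 1 || ctr[2] > W ||
        is.na(bf[round(ctr[1]), round(ctr[2])]))
      stop("hub center outside the responsive area")
    dr <- resp[, 1] - ctr[1]; dc <- resp[, 2] - ctr[2]
    radius <- sqrt(dr^2 + dc^2)
    theta <- (atan2(dc, -dr) * 180 / pi) %% 360  # 0 deg = up, clockwise
    vals <- bf[resp]
    r_bin <- round(radius)
    r_max <- max(r_bin)
    angles <- (seq_len(n_angles) - 1) * 360 / n_angles
    ord <- order(theta)
    theta_s <- theta[ord]; rbin_s <- r_bin[ord]; vals_s <- vals[ord]
    for (a_i in seq_len(n_angles)) {
      a <- angles[a_i]
      # angular-window bin means (pixels within +/- tol of the ray)
      dd <- abs(theta_s - a)
      sel <- dd <= angular_tol_deg | dd >= 360 - angular_tol_deg
      prof <- rep(NA_real_, r_max + 1)
      if (any(sel)) {
        agg <- tapply(vals_s[sel], rbin_s[sel], mean)
        prof[as.integer(names(agg)) + 1L] <- agg
      }
      # fall back to nearest-pixel sampling where the window is empty
      # (close to the centre the +/- 1 degree wedge is thinner than a pixel)
      rad <- a * pi / 180
      for (r in 0:r_max) {
        if (!is.na(prof[r + 1])) next
        rr2 <- round(ctr[1] - r * cos(rad)); cc2 <- round(ctr[2] + r * sin(rad))
        if (rr2 >= 1 && rr2 <= H && cc2 >= 1 && cc2 <= W)
          prof[r + 1] <- bf[rr2, cc2]
      }
      # restrict to the contiguous defined stretch from the centre outward
      last <- which(is.na(prof))[1]
      if (!is.na(last)) { if (last == 1) next else prof <- prof[seq_len(last - 1)] }
      if (length(prof) < 3) next
      sm <- gaussian_smooth(moving_average(prof, ma_window), gauss_sigma)
      i_max <- first_local_max(sm)
      if (is.na(i_max)) next
      r_rev <- i_max - 1
      out[[length(out) + 1L]] <- data.frame(
        hub = hub_i, angle_deg = a, radius_px = r_rev,
        row = ctr[1] - r_rev * cos(a * pi / 180),
        col = ctr[2] + r_rev * sin(a * pi / 180))
    }
  }
  points <- if (length(out)) do.call(rbind, out) else
    data.frame(hub = integer(), angle_deg = numeric(), radius_px = numeric(),
               row = numeric(), col = numeric())
  structure(list(points = points, hub_centers = hub_centers,
                 n_angles = n_angles), class = "reversal_set")
}

#' Cortex boundary from unresponsive runs
#'
#' Along each radial vector from the given centre, the end of the responsive
#' cortex is the first position where `run_length` consecutive pixels show no
#' sound-evoked response at all; the boundary is placed at the start of that
#' run. Rays without such a run yield no boundary point.
#'
#' @param bfmap a `bf_map` (matrix form).
#' @param center `c(row, col)`; default automatic low-frequency hub.
#' @param n_angles number of radial vectors (default 1440).
#' @param run_length unresponsive run defining the boundary (default 10).
#' @return data frame `(angle_deg, radius_px, row, col)`, one row per ray
#'   with a detected boundary, plus attribute `boundary_mask`.
#' @export
find_ac_boundary <- function(bfmap, center = NULL, n_angles = 1440,
                             run_length = 10) {
  stopifnot(inherits(bfmap, "bf_map"), !is.null(dim(bfmap$bf_oct)))
  if (is.null(center)) center <- find_low_freq_hub(bfmap)
  mask <- bfmap$responsive_mask
  H <- nrow(mask); W <- ncol(mask)
  angles <- (seq_len(n_angles) - 1) * 360 / n_angles
  bmask <- matrix(FALSE, H, W)
  rows <- list()
  r_max <- ceiling(sqrt(H^2 + W^2))
  for (a_i in seq_len(n_angles)) {
    a <- angles[a_i] * pi / 180
    run <- 0L
    for (r in 0:r_max) {
      rr <- round(center[1] - r * cos(a)); cc <- round(center[2] + r * sin(a))
      if (rr < 1 || rr > H || cc < 1 || cc > W) break
      if (!mask[rr, cc]) {
        run <- run + 1L
        if (run == run_length) {
          r0 <- r - run_length + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            angle_deg = angles[a_i], radius_px = r0,
            row = round(center[1] - r0 * cos(a)),
            col = round(center[2] + r0 * sin(a)))
          bmask[rows[[length(rows)]]$row, rows[[length(rows)]]$col] <- TRUE
          break
        }
      } else run <- 0L
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(angle_deg = numeric(), radius_px = numeric(),
               row = numeric(), col = numeric())
  attr(res, "boundary_mask") <- bmask
  res
}
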
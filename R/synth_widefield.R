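#' Configuration of the synthetic widefield map
#'
#' Plants a radially organized tonotopic map with a low-frequency hub at the
#' centre: the best frequency rises linearly with radial distance from the
#' hub up to the highest tone at `reversal_radius_px` (the planted tonotopic
#' reversal), falls symmetrically beyond it, and an unresponsive band outside
#' `ac_radius_px` marks the end of the auditory cortex. Planted BFs are
#' snapped to the widefield tone grid. Fluorescence is a drifting baseline
#' plus calcium-kernel responses (double-exponential, 1-s decay, peak
#' normalized to 1) to tones near each pixel's planted BF, with gaussian
#' noise clipped at zero. Default geometry follows the real acquisition
#' (256 x 256 at 10 Hz); analyses in this package's tests run a scaled-down
#' grid for speed.
#'
#' @param size grid side in pixels (H = W).
#' @param hub_center `c(row, col)`; default map centre.
#' @param reversal_radius_px radius of the planted reversal.
#' @param ac_radius_px radius beyond which pixels are unresponsive.
#' @param baseline mean fluorescence (arbitrary units).
#' @param response_amp_pct peak response at the pixel's BF, percent dF/F.
#' @param tuning_sigma_oct gaussian spectral tuning width of a pixel.
#' @param drift_pct slow baseline drift amplitude, percent (sinusoid,
#'   60-s period, plus a linear ramp).
#' @param noise_sd per-frame gaussian noise, raw units.
#' @param tau_decay_s,tau_rise_s calcium kernel time constants.
#' @return list of class `widefield_map_config`.
#' @export
widefield_map_config <- function(size = 256,
                                 hub_center = NULL,
                                 reversal_radius_px = round(0.3 * size),
                                 ac_radius_px = round(0.42 * size),
                                 baseline = 100,
                                 response_amp_pct = 15,
                                 tuning_sigma_oct = 1.0,
                                 drift_pct = 2,
                                 noise_sd = 1,
                                 tau_decay_s = 1, tau_rise_s = 0.15) {
  if (is.null(hub_center)) hub_center <- c(size / 2, size / 2)
  stopifnot(size >= 8, reversal_radius_px > 0, ac_radius_px > reversal_radius_px)
  structure(as.list(environment()), class = "widefield_map_config")
}

#' Simulate a widefield recording over a planted tonotopic map
#'
#' @param config a [widefield_map_config()].
#' @param schedule a `widefield_pt` [make_protocol()] object.
#' @param seed integer seed.
#' @return list of class `widefield_movie`: `pixels` (`H x W x T` array),
#'   `frame_rate_hz`, `schedule`, `ground_truth` (list: `bf_oct` matrix on
#'   the tone grid, `responsive_mask`, `hub_center`, `reversal_radius_px`,
#'   `ac_radius_px`).
#' @export
simulate_widefield <- function(config = widefield_map_config(), schedule = NULL,
                               seed = 1L) {
  if (is.null(schedule)) schedule <- make_protocol("widefield_pt", seed = seed)
  stopifnot(inherits(schedule, "stim_protocol"), schedule$modality == "widefield_pt")
  H <- config$size; W <- config$size
  fps <- schedule$frame_rate_hz
  T_ <- schedule$n_frames
  grid_oct <- hz2oct(schedule$frequencies_hz)

  rr <- matrix(seq_len(H), H, W) - config$hub_center[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - config$hub_center[2]
  radius <- sqrt(rr^2 + cc^2)
  span <- max(grid_oct) - min(grid_oct)
  bf_cont <- ifelse(radius <= config$reversal_radius_px,
                    radius / config$reversal_radius_px * span,
                    pmax(0, span - (radius - config$reversal_radius_px) /
                           config$reversal_radius_px * span)) + min(grid_oct)
  bf_true <- matrix(snap_to_grid(as.vector(bf_cont), grid_oct), H, W)
  responsive <- radius <= config$ac_radius_px
  bf_true[!responsive] <- NA_real_

  # spectral tuning of each pixel against the 5 tones
  npix <- H * W
  tune <- matrix(0, npix, length(grid_oct))
  bf_vec <- as.vector(bf_true)
  ok <- !is.na(bf_vec)
  for (s in seq_along(grid_oct))
    tune[ok, s] <- exp(-((bf_vec[ok] - grid_oct[s]) / config$tuning_sigma_oct)^2)
  tune <- tune * config$response_amp_pct  # percent dF/F at each tone

  # per-tone stimulus time courses convolved with the calcium kernel
  kt <- seq(0, 4, by = 1 / fps)
  kern <- exp(-kt / config$tau_decay_s) - exp(-kt / config$tau_rise_s)
  kern <- kern / max(kern)
  stim_tc <- matrix(0, length(grid_oct), T_)
  ons <- schedule$onsets
  for (k in seq_len(nrow(ons))) {
    o <- ons$onset_frame[k]
    idx <- o:min(T_, o + length(kern) - 1L)
    stim_tc[ons$freq_index[k], idx] <- stim_tc[ons$freq_index[k], idx] +
      kern[seq_along(idx)]
  }

  tt <- seq_len(T_) / fps
  drift <- 1 + config$drift_pct / 100 *
    (sin(2 * pi * tt / 60) / 2 + (tt - mean(tt)) / max(tt) / 2)

  withr::with_seed(as.integer(seed), {
    resp <- tune %*% stim_tc                # npix x T, in dF/F fraction*100
    pix <- config$baseline * (1 + resp / 100)
    pix <- sweep(pix, 2, drift, `*`)
    if (config$noise_sd > 0)
      pix <- pix + stats::rnorm(length(pix), 0, config$noise_sd)
    pix <- pmax(pix, 0)
    movie <- array(pix, c(H, W, T_))
    structure(list(pixels = movie, frame_rate_hz = fps, schedule = schedule,
                   ground_truth = list(bf_oct = bf_true,
                                       responsive_mask = responsive,
                                       hub_center = config$hub_center,
                                       reversal_radius_px = config$reversal_radius_px,
                                       ac_radius_px = config$ac_radius_px)),
              class = "widefield_movie")
  })
}
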
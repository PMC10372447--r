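#' Configuration for the synthetic two-photon population
#'
#' Defines the planted ground truth of a simulated layer-5 population:
#' tuning-class mixture, tonotopic gradient with local scatter, bandwidth
#' distribution, response amplitude, trial-to-trial reliability and noise.
#' The defaults emulate an awake corticocollicular-labelled recording:
#' class fractions near the observed awake values (about 60% single-peaked,
#' 6% double-peaked, the rest without clear tuning), a full 4-octave gradient
#' across a 500 um field of view with 0.5-octave local scatter, mean tuning
#' bandwidth 0.4 octaves, and a trial coefficient of variation of 0.3.
#'
#' @param n_neurons number of neurons.
#' @param fractions named fractions for classes `single`, `double`,
#'   `irregular`, `unresponsive`; must sum to 1.
#' @param fov_um field-of-view extent `c(width, height)` in micrometres.
#' @param cc_fraction probability that a neuron is corticocollicular (CC).
#' @param subfield subfield label assigned to all neurons.
#' @param gradient_oct_per_um slope of the planted tonotopic gradient along x.
#' @param gradient_origin_oct octave value at x = 0.
#' @param sigma_topo_oct gaussian scatter of the planted best frequency
#'   around the gradient, in octaves.
#' @param bw_mean_oct,bw_sd_oct,bw_min_oct bandwidth (FWHM) distribution of
#'   planted peaks, octaves.
#' @param amp_base response magnitude (deconvolved spike-probability units
#'   delivered as a single-frame transient).
#' @param trial_cv multiplicative trial-to-trial amplitude jitter
#'   (lognormal, coefficient of variation).
#' @param reliability trial success probability in `[0, 1]`.
#' @param noise_sd per-frame additive noise (gaussian clipped at zero).
#' @return list of class `pt_population_config`.
#' @export
pt_population_config <- function(n_neurons = 500,
                                 fractions = c(single = 0.60, double = 0.06,
                                               irregular = 0.34, unresponsive = 0),
                                 fov_um = c(500, 500),
                                 cc_fraction = 0.5,
                                 subfield = "A1",
                                 gradient_oct_per_um = 4 / 500,
                                 gradient_origin_oct = 0,
                                 sigma_topo_oct = 0.5,
                                 bw_mean_oct = 0.4, bw_sd_oct = 0.08, bw_min_oct = 0.2,
                                 amp_base = 1,
                                 trial_cv = 0.3,
                                 reliability = 1,
                                 noise_sd = 0.01) {
  fr <- fractions[c("single", "double", "irregular", "unresponsive")]
  fr[is.na(fr)] <- 0
  if (abs(sum(fr) - 1) > 1e-8) stop("config error: class fractions must sum to 1")
  structure(as.list(environment()), class = "pt_population_config")
}

# monotone saturating SPL gain, in (0, 1)
spl_gain <- function(spl_db) 1 - exp(-(spl_db - 20) / 25)

# planted tuning curve on the octave axis
gauss_curve <- function(x, A1, B1, C1, D = 0, A2 = 0, B2 = 0, C2 = 1) {
  A1 * exp(-((x - B1) / C1)^2) + A2 * exp(-((x - B2) / C2)^2) + D
}

snap_to_grid <- function(x, grid) grid[pmax(1L, pmin(length(grid),
                                                     findInterval(x, (grid[-1] + grid[-length(grid)]) / 2) + 1L))]

#' Simulate a two-photon pure-tone recording with planted ground truth
#'
#' Generates deconvolved spike-probability traces for a population of neurons
#' under a pure-tone protocol. A trial response is the planted tuning curve
#' evaluated at the tone's octave position, scaled by a saturating SPL gain,
#' a Bernoulli reliability draw and lognormal amplitude jitter, and delivered
#' as a single-frame transient at the onset frame (deconvolved traces are
#' impulse-like, so the 400-ms window mean equals magnitude / window frames).
#' Irregular neurons draw an independent mean response per frequency-SPL
#' combination. Additive gaussian noise clipped at zero preserves the
#' non-negativity of spike probabilities.
#'
#' @param protocol a `two_photon_pt` [make_protocol()] object.
#' @param config a [pt_population_config()].
#' @param seed integer seed.
#' @return list with elements `traces` (class `trace_set`: `spike_prob`
#'   neurons x frames matrix, `frame_rate_hz`, `protocol`, `rois`) and
#'   `ground_truth` (one row per neuron: position, type, subfield, class,
#'   `true_bf_oct`, `true_cef_oct`, `true_bw_oct`, reliability).
#' @export
simulate_two_photon <- function(protocol, config = pt_population_config(), seed = 1L) {
  stopifnot(inherits(protocol, "stim_protocol"), protocol$modality == "two_photon_pt")
  n <- config$n_neurons
  grid_oct <- protocol$freq_oct
  ons <- protocol$onsets

  withr::with_seed(as.integer(seed), {
    if (n == 0) {
      gt <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                       neuron_type = character(), subfield = character(),
                       tuning_class = character(), true_bf_oct = numeric(),
                       true_cef_oct = numeric(), true_bw_oct = numeric(),
                       reliability_level = numeric())
      traces <- structure(list(spike_prob = matrix(0, 0, protocol$n_frames),
                               frame_rate_hz = protocol$frame_rate_hz,
                               protocol = protocol, rois = gt[, 0:5]),
                          class = "trace_set")
      return(list(traces = traces, ground_truth = gt))
    }
    x_um <- stats::runif(n, 0, config$fov_um[1])
    y_um <- stats::runif(n, 0, config$fov_um[2])
    neuron_type <- ifelse(stats::runif(n) < config$cc_fraction, "CC", "non-CC")
    counts <- diff(c(0, round(cumsum(config$fr) * n)))  # sums to n exactly
    classes <- sample(rep(names(config$fr), counts))

    bf_cont <- config$gradient_origin_oct + config$gradient_oct_per_um * x_um +
      stats::rnorm(n, 0, config$sigma_topo_oct)
    bf_oct <- snap_to_grid(pmin(pmax(bf_cont, min(grid_oct)), max(grid_oct)), grid_oct)
    bw <- pmax(stats::rnorm(n, config$bw_mean_oct, config$bw_sd_oct), config$bw_min_oct)
    C1 <- bw / (2 * sqrt(log(2)))
    amp <- rep(config$amp_base, n)
    # second peak for double-peaked neurons
    delta <- stats::runif(n, 1, 2) * sample(c(-1, 1), n, replace = TRUE)
    b2_raw <- bf_oct + delta
    flip <- b2_raw < min(grid_oct) | b2_raw > max(grid_oct)
    b2_raw[flip] <- bf_oct[flip] - delta[flip]
    b2 <- snap_to_grid(pmin(pmax(b2_raw, min(grid_oct)), max(grid_oct)), grid_oct)
    amp2 <- amp * stats::runif(n, 0.6, 1)
    bw2 <- pmax(stats::rnorm(n, config$bw_mean_oct, config$bw_sd_oct), config$bw_min_oct)
    C2 <- bw2 / (2 * sqrt(log(2)))

    # expected response of each neuron to each frequency-SPL combination
    n_f <- length(grid_oct); n_l <- length(protocol$spls_db)
    gain <- spl_gain(protocol$spls_db)
    combo_mean <- matrix(0, n, n_f * n_l)  # columns ordered (freq within spl)
    for (i in seq_len(n)) {
      cl <- classes[i]
      tune <- switch(cl,
        single = gauss_curve(grid_oct, amp[i], bf_oct[i], C1[i]),
        double = gauss_curve(grid_oct, amp[i], bf_oct[i], C1[i],
                             A2 = amp2[i], B2 = b2[i], C2 = C2[i]),
        irregular = amp[i] * stats::runif(n_f * n_l),
        unresponsive = 0)
      combo_mean[i, ] <- if (cl == "irregular") tune else
        if (cl == "unresponsive") 0 else as.vector(outer(tune, gain))
    }

    rel <- rep(config$reliability, length.out = n)
    sdlog <- sqrt(log(1 + config$trial_cv^2))
    col_of <- (ons$spl_index - 1L) * n_f + ons$freq_index
    n_tr <- nrow(ons)
    success <- matrix(stats::rbinom(n * n_tr, 1, rep(rel, n_tr)), n, n_tr)
    jitter <- matrix(stats::rlnorm(n * n_tr, -sdlog^2 / 2, sdlog), n, n_tr)
    mag <- combo_mean[, col_of, drop = FALSE] * success * jitter

    traces_mat <- matrix(0, n, protocol$n_frames)
    traces_mat[, ons$onset_frame] <- traces_mat[, ons$onset_frame] + mag
    if (config$noise_sd > 0)
      traces_mat <- traces_mat +
        pmax(matrix(stats::rnorm(n * protocol$n_frames, 0, config$noise_sd),
                    n, protocol$n_frames), 0)

    gt <- data.frame(id = seq_len(n), x_um = x_um, y_um = y_um,
                     neuron_type = neuron_type, subfield = config$subfield,
                     tuning_class = classes,
                     true_bf_oct = ifelse(classes %in% c("single", "double"), bf_oct, NA),
                     true_cef_oct = ifelse(classes == "single", bf_oct, NA),
                     true_bw_oct = ifelse(classes %in% c("single", "double"), bw, NA),
                     true_bf2_oct = ifelse(classes == "double", b2, NA),
                     true_bw2_oct = ifelse(classes == "double", bw2, NA),
                     reliability_level = rel)
    rois <- gt[, c("id", "x_um", "y_um", "neuron_type", "subfield")]
    traces <- structure(list(spike_prob = traces_mat,
                             frame_rate_hz = protocol$frame_rate_hz,
                             protocol = protocol, rois = rois),
                        class = "trace_set")
    list(traces = traces, ground_truth = gt)
  })
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set>", nrow(x$spike_prob), "neurons x", ncol(x$spike_prob),
      "frames @", x$frame_rate_hz, "fps\n")
  invisible(x)
}

#' Configuration for the synthetic vocalization-response population
#'
#' Neurons belonging to one response motif share a per-sound response
#' template; independent additive noise is calibrated so that the expected
#' pairwise Pearson correlation between same-motif sound vectors equals
#' `within_corr` (noise sd = template sd x sqrt((1 - r) / r)). Neurons
#' outside any motif respond with stimulus-independent noise (fresh draws per
#' repetition and sound), carrying no reliability and no between-neuron
#' correlation. Templates are
#' drawn from `template_range` high enough above zero that clipping of
#' negative responses (traces are non-negative) is negligible.
#'
#' @param n_motifs number of planted motifs.
#' @param neurons_per_motif motif size.
#' @param within_corr target within-motif correlation, in (0, 1].
#' @param frac_unclustered fraction of the population outside any motif
#'   (1 = a pure-noise population of `n_motifs * neurons_per_motif` neurons).
#' @param dispersion_um sd of member positions around the motif centre.
#' @param fov_um field-of-view extent in micrometres.
#' @param template_range uniform range of per-sound template responses.
#' @param noise_sd per-frame additive trace noise.
#' @return list of class `motif_config`.
#' @export
motif_config <- function(n_motifs = 3, neurons_per_motif = 15,
                         within_corr = 0.4, frac_unclustered = 0,
                         dispersion_um = 150, fov_um = c(500, 500),
                         template_range = c(4, 9), noise_sd = 0.005) {
  if (n_motifs < 0) stop("config error: n_motifs must be >= 0")
  stopifnot(frac_unclustered >= 0, frac_unclustered <= 1)
  if (n_motifs > 0 && frac_unclustered < 1)
    stopifnot(within_corr > 0, within_corr <= 1)
  structure(as.list(environment()), class = "motif_config")
}

#' Simulate vocalization responses with planted motif structure
#'
#' @param protocol a `two_photon_voc` [make_protocol()] object.
#' @param config a [motif_config()].
#' @param seed integer seed.
#' @return list with `traces` (a `trace_set`) and `ground_truth` (per neuron:
#'   position, `motif_id` — `NA` for unclustered neurons).
#' @export
simulate_vocal_responses <- function(protocol, config = motif_config(), seed = 1L) {
  stopifnot(inherits(protocol, "stim_protocol"), protocol$modality == "two_photon_voc")
  n_sounds <- length(protocol$vocal_set$sound_ids)
  n_base <- config$n_motifs * config$neurons_per_motif

  withr::with_seed(as.integer(seed), {
    if (config$frac_unclustered >= 1) {
      n_motif_neurons <- 0; n_unc <- n_base
    } else {
      n_motif_neurons <- n_base
      n_unc <- round(config$frac_unclustered / (1 - config$frac_unclustered) * n_base)
    }
    n <- n_motif_neurons + n_unc
    motif_id <- c(if (n_motif_neurons) rep(seq_len(config$n_motifs),
                                           each = config$neurons_per_motif),
                  rep(NA_integer_, n_unc))

    centers <- cbind(stats::runif(max(config$n_motifs, 1), 0.2, 0.8) * config$fov_um[1],
                     stats::runif(max(config$n_motifs, 1), 0.2, 0.8) * config$fov_um[2])
    x_um <- numeric(n); y_um <- numeric(n)
    in_motif <- !is.na(motif_id)
    x_um[in_motif] <- centers[motif_id[in_motif], 1] +
      stats::rnorm(sum(in_motif), 0, config$dispersion_um)
    y_um[in_motif] <- centers[motif_id[in_motif], 2] +
      stats::rnorm(sum(in_motif), 0, config$dispersion_um)
    x_um[!in_motif] <- stats::runif(n_unc, 0, config$fov_um[1])
    y_um[!in_motif] <- stats::runif(n_unc, 0, config$fov_um[2])

    # one template per motif; neurons outside any motif are stimulus-
    # independent noise (fresh independent draws per repetition and sound,
    # so they carry neither reliability nor between-neuron correlation)
    templates <- if (config$n_motifs > 0)
      matrix(stats::runif(config$n_motifs * n_sounds,
                          config$template_range[1], config$template_range[2]),
             nrow = config$n_motifs) else NULL
    rho <- config$within_corr
    noise_scale <- function(tpl) stats::sd(tpl) * sqrt((1 - rho) / rho)

    ons <- protocol$onsets
    traces_mat <- matrix(0, n, protocol$n_frames)
    resp <- array(0, c(n, protocol$n_repetitions, n_sounds))
    for (i in seq_len(n)) {
      if (in_motif[i]) {
        tpl <- templates[motif_id[i], ]
        sn <- if (rho < 1) noise_scale(tpl) else 0
        r <- matrix(tpl, protocol$n_repetitions, n_sounds, byrow = TRUE)
        if (sn > 0) r <- r + stats::rnorm(length(r), 0, sn)
      } else {
        r <- matrix(stats::runif(protocol$n_repetitions * n_sounds,
                                 config$template_range[1], config$template_range[2]),
                    protocol$n_repetitions, n_sounds)
      }
      resp[i, , ] <- pmax(r, 0)
    }
    mag <- t(apply(resp, 1, function(m) m[cbind(ons$repetition, ons$stimulus_index)]))
    if (n == 1) mag <- matrix(mag, nrow = 1)
    traces_mat[, ons$onset_frame] <- traces_mat[, ons$onset_frame] + mag
    if (config$noise_sd > 0)
      traces_mat <- traces_mat +
        pmax(matrix(stats::rnorm(length(traces_mat), 0, config$noise_sd),
                    nrow(traces_mat)), 0)

    gt <- data.frame(id = seq_len(n), x_um = x_um, y_um = y_um,
                     neuron_type = "CC", subfield = "A1", motif_id = motif_id)
    rois <- gt[, c("id", "x_um", "y_um", "neuron_type", "subfield")]
    traces <- structure(list(spike_prob = traces_mat,
                             frame_rate_hz = protocol$frame_rate_hz,
                             protocol = protocol, rois = rois),
                        class = "trace_set")
    list(traces = traces, ground_truth = gt)
  })
}
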
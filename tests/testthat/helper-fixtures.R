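# shared fixtures and independent oracles, built in code at test time

# brute-force O(n^2) oracle for local heterogeneity
brute_local_iqr <- function(df, radius_um = 100, min_n = 5) {
  df <- df[!is.na(df$value), , drop = FALSE]
  out <- rep(NA_real_, nrow(df))
  for (i in seq_len(nrow(df))) {
    v <- c()
    for (j in seq_len(nrow(df))) {
      if (sqrt((df$x_um[i] - df$x_um[j])^2 + (df$y_um[i] - df$y_um[j])^2) <= radius_um)
        v <- c(v, df$value[j])
    }
    if (length(v) >= min_n)
      out[i] <- unname(diff(stats::quantile(v, c(0.25, 0.75), type = 7)))
  }
  out
}

# minimal bf_map constructor for stitching / geometry tests
toy_bf_map <- function(bf, amp, freq_hz = make_pt_grid(4000, 64000, 1)) {
  structure(list(bf_oct = bf, amplitude = amp, freq_amp = NULL,
                 responsive_mask = !is.na(bf), freq_oct = hz2oct(freq_hz),
                 freq_hz = freq_hz, dim_hw = dim(bf), min_evoked_reps = 4),
            class = "bf_map")
}

# trace_set with hand-placed impulses for windowing tests
toy_trace_set <- function(sp, proto) {
  structure(list(spike_prob = sp, frame_rate_hz = proto$frame_rate_hz,
                 protocol = proto,
                 rois = data.frame(id = seq_len(nrow(sp)),
                                   x_um = 0, y_um = 0,
                                   neuron_type = "CC", subfield = "A1")),
            class = "trace_set")
}

# cheap pure-tone protocol for ground-truth-only simulations
gt_protocol <- function(seed = 1L) make_protocol("two_photon_pt", seed = seed,
                                                 n_repetitions = 1L)

# shuffle sound vectors per neuron and repetition (to construct "fully
# shuffled" input data, mirroring the null's granularity)
shuffle_vectors <- function(sv, seed) {
  v <- sv$vectors
  withr::with_seed(seed, {
    for (i in seq_len(dim(v)[1])) for (r in seq_len(dim(v)[2]))
      v[i, r, ] <- v[i, r, sample(dim(v)[3])]
  })
  structure(list(vectors = v, stimulus_ids = sv$stimulus_ids, mode = sv$mode,
                 window_s = sv$window_s, n_repetitions = sv$n_repetitions),
            class = "sound_vectors")
}

label_or_zero <- function(x) ifelse(is.na(x), 0L, x)
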
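#' Octave/Hz conversions
#'
#' Frequencies are handled internally on the octave axis relative to a
#' reference frequency (default 4 kHz), i.e. `x = log2(f / f_ref)`. All
#' bandwidth and heterogeneity measures are expressed in octaves; Hz is an
#' input/output representation only.
#'
#' @param f_hz frequency in Hz.
#' @param x_oct position on the octave axis.
#' @param f_ref_hz reference frequency in Hz (default 4000).
#' @return `hz2oct` returns octaves re `f_ref_hz`; `oct2hz` returns Hz.
#' @export
hz2oct <- function(f_hz, f_ref_hz = 4000) log2(f_hz / f_ref_hz)

#' @rdname hz2oct
#' @export
oct2hz <- function(x_oct, f_ref_hz = 4000) f_ref_hz * 2^x_oct

#' Geometric pure-tone grid
#'
#' Builds the geometrically spaced tone grid used for frequency-response-area
#' mapping: frequencies from `f_low_hz` to `f_high_hz` inclusive, spaced
#' `1/steps_per_octave` octaves apart. The standard two-photon grid
#' (4-64 kHz, 4 steps per octave) has 17 tones; the widefield grid
#' (4-64 kHz, 1 octave steps) has 5.
#'
#' @param f_low_hz,f_high_hz grid endpoints in Hz; `f_high_hz >= f_low_hz > 0`.
#' @param steps_per_octave number of tones per octave (>= 1).
#' @return numeric vector of frequencies in Hz, strictly increasing.
#' @examples
#' length(make_pt_grid(4000, 64000, 4))  # 17
#' make_pt_grid(4000, 64000, 1) / 1000   # 4 8 16 32 64
#' @export
make_pt_grid <- function(f_low_hz, f_high_hz, steps_per_octave) {
  stopifnot(f_low_hz > 0, f_high_hz >= f_low_hz, steps_per_octave >= 1)
  n_oct <- log2(f_high_hz / f_low_hz)
  n_steps <- n_oct * steps_per_octave
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("grid endpoints incompatible with step size")
  n_steps <- round(n_steps)
  f_low_hz * 2^(seq(0L, n_steps) / steps_per_octave)
}

#' Vocalization stimulus set
#'
#' Describes a set of complex sounds (animal vocalizations) of varying
#' duration, analyzed over a common fixed window from sound onset. Because
#' the sounds differ in length, the analysis window is limited to the first
#' 550 ms of each sound by default.
#'
#' @param sound_ids character labels, one per sound (default: 10 generic ids).
#' @param durations_s per-sound duration in seconds.
#' @param analysis_window_s analysis window from onset, seconds.
#' @return object of class `vocal_set`.
#' @export
make_vocal_set <- function(sound_ids = sprintf("voc%02d", 1:10),
                           durations_s = seq(0.6, 2.4, length.out = length(sound_ids)),
                           analysis_window_s = 0.55) {
  stopifnot(length(sound_ids) == length(durations_s), analysis_window_s > 0)
  if (analysis_window_s > min(durations_s))
    warning("analysis window exceeds the shortest sound; window truncates the sound set")
  structure(list(sound_ids = as.character(sound_ids),
                 durations_s = as.numeric(durations_s),
                 analysis_window_s = analysis_window_s),
            class = "vocal_set")
}

#' Stimulus protocol
#'
#' Generates the complete stimulus schedule for one recording session:
#' the tone/sound grid, sound-level grid, repetition structure, frame timing,
#' and a randomized onset table. Three modalities are supported:
#'
#' * `two_photon_pt`: 17 pure tones (4-64 kHz, 4 steps/octave) at 5 SPLs
#'   (30-70 dB, 10 dB steps), 10 repetitions, 250 ms tone + 1 s pause at
#'   ~30 fps. Each SPL is acquired as a separate recording; recordings are
#'   laid out back-to-back on one global frame axis. Within each recording,
#'   every repetition block is an independent permutation of the 17 tones.
#' * `two_photon_voc`: 10 vocalizations, 10 repetitions, 1 s inter-stimulus
#'   pause at ~30 fps, analysis window 550 ms.
#' * `widefield_pt`: 5 tones (4-64 kHz, 1 octave steps) at 70 dB, 16
#'   repetitions, 500 ms tone + 5 s pause at 10 Hz.
#'
#' @param modality one of `"two_photon_pt"`, `"two_photon_voc"`,
#'   `"widefield_pt"`.
#' @param seed integer seed for the randomized presentation order.
#' @param frequencies_hz tone grid (ignored for vocalizations).
#' @param spls_db sound levels in dB SPL.
#' @param n_repetitions repetitions per stimulus (or per combination).
#' @param tone_duration_s,pause_s stimulus duration and following pause.
#' @param frame_rate_hz acquisition frame rate.
#' @param lead_s quiet lead-in before the first onset (must exceed the
#'   prestimulus windows used downstream).
#' @param tail_s quiet tail after the last onset.
#' @param vocal_set a [make_vocal_set()] object (vocalization modality only).
#' @return object of class `stim_protocol`: list with the grids, timing
#'   constants, `n_frames`, and an `onsets` data frame with columns
#'   `trial`, `stimulus_id`, `repetition`, `onset_frame` (plus `freq_hz`,
#'   `spl_db`, `recording` where applicable). For `two_photon_pt` a stimulus
#'   is a frequency-SPL combination (`stimulus_id = "f<i>_l<j>"`).
#' @export
make_protocol <- function(modality = c("two_photon_pt", "two_photon_voc", "widefield_pt"),
                          seed = 1L,
                          frequencies_hz = NULL, spls_db = NULL,
                          n_repetitions = NULL,
                          tone_duration_s = NULL, pause_s = NULL,
                          frame_rate_hz = NULL,
                          lead_s = 3, tail_s = 2,
                          vocal_set = NULL) {
  modality <- match.arg(modality)
  defaults <- switch(modality,
    two_photon_pt = list(frequencies_hz = make_pt_grid(4000, 64000, 4),
                         spls_db = seq(30, 70, by = 10), n_repetitions = 10L,
                         tone_duration_s = 0.25, pause_s = 1, frame_rate_hz = 30),
    two_photon_voc = list(frequencies_hz = NULL, spls_db = 50, n_repetitions = 10L,
                          tone_duration_s = NA_real_, pause_s = 1, frame_rate_hz = 30),
    widefield_pt = list(frequencies_hz = make_pt_grid(4000, 64000, 1),
                        spls_db = 70, n_repetitions = 16L,
                        tone_duration_s = 0.5, pause_s = 5, frame_rate_hz = 10))
  if (is.null(frequencies_hz)) frequencies_hz <- defaults$frequencies_hz
  if (is.null(spls_db)) spls_db <- defaults$spls_db
  if (is.null(n_repetitions)) n_repetitions <- defaults$n_repetitions
  if (is.null(tone_duration_s)) tone_duration_s <- defaults$tone_duration_s
  if (is.null(pause_s)) pause_s <- defaults$pause_s
  if (is.null(frame_rate_hz)) frame_rate_hz <- defaults$frame_rate_hz
  for (fld in c("n_repetitions", "pause_s", "frame_rate_hz"))
    if (is.null(get(fld)) || is.na(get(fld))) stop("configuration error: missing timing field ", fld)

  if (modality == "two_photon_voc") {
    if (is.null(vocal_set)) vocal_set <- make_vocal_set()
    onsets <- withr::with_seed(as.integer(seed), {
      rows <- list()
      t_cur <- lead_s
      trial <- 0L
      for (rep_i in seq_len(n_repetitions)) {
        order_i <- sample(seq_along(vocal_set$sound_ids))
        for (s in order_i) {
          trial <- trial + 1L
          rows[[trial]] <- data.frame(trial = trial,
                                      stimulus_id = vocal_set$sound_ids[s],
                                      stimulus_index = s,
                                      repetition = rep_i,
                                      onset_frame = floor(t_cur * frame_rate_hz) + 1L)
          t_cur <- t_cur + vocal_set$durations_s[s] + pause_s
        }
      }
      do.call(rbind, rows)
    })
    n_frames <- max(onsets$onset_frame) + ceiling((max(vocal_set$durations_s) + tail_s) * frame_rate_hz)
    proto <- list(modality = modality, frequencies_hz = NULL,
                  spls_db = spls_db, n_repetitions = as.integer(n_repetitions),
                  tone_duration_s = tone_duration_s, pause_s = pause_s,
                  frame_rate_hz = frame_rate_hz, vocal_set = vocal_set,
                  onsets = onsets, n_frames = n_frames, seed = as.integer(seed))
    return(structure(proto, class = "stim_protocol"))
  }

  stopifnot(all(diff(frequencies_hz) > 0), all(frequencies_hz > 0))
  if (is.na(tone_duration_s)) stop("configuration error: missing timing field tone_duration_s")
  trial_s <- tone_duration_s + pause_s
  n_freq <- length(frequencies_hz)
  n_spl <- length(spls_db)
  frames_per_rec <- ceiling((lead_s + n_freq * n_repetitions * trial_s + tail_s) * frame_rate_hz)

  onsets <- withr::with_seed(as.integer(seed), {
    rows <- vector("list", n_spl)
    for (l in seq_len(n_spl)) {  # each SPL is its own recording
      ord <- unlist(lapply(seq_len(n_repetitions), function(r) sample(n_freq)))
      k <- seq_along(ord)
      t_on <- lead_s + (k - 1) * trial_s
      rows[[l]] <- data.frame(
        recording = l,
        trial = k,
        stimulus_id = sprintf("f%02d_l%d", ord, l),
        freq_index = ord,
        spl_index = l,
        freq_hz = frequencies_hz[ord],
        spl_db = spls_db[l],
        repetition = rep(seq_len(n_repetitions), each = n_freq),
        onset_frame = (l - 1) * frames_per_rec + floor(t_on * frame_rate_hz) + 1L)
    }
    do.call(rbind, rows)
  })
  # repetition index within (freq, spl): the r-th occurrence in time
  onsets <- onsets[order(onsets$onset_frame), ]
  onsets$repetition <- stats::ave(seq_len(nrow(onsets)),
                                  onsets$stimulus_id, FUN = seq_along)
  onsets$trial <- seq_len(nrow(onsets))
  rownames(onsets) <- NULL

  structure(list(modality = modality,
                 frequencies_hz = frequencies_hz,
                 freq_oct = hz2oct(frequencies_hz),
                 spls_db = spls_db,
                 n_repetitions = as.integer(n_repetitions),
                 tone_duration_s = tone_duration_s, pause_s = pause_s,
                 frame_rate_hz = frame_rate_hz,
                 onsets = onsets,
                 n_frames = n_spl * frames_per_rec,
                 frames_per_recording = frames_per_rec,
                 seed = as.integer(seed)),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>", x$modality, "\n")
  if (!is.null(x$frequencies_hz))
    cat("  tones:", length(x$frequencies_hz), sprintf("(%.1f-%.1f kHz)",
        min(x$frequencies_hz) / 1000, max(x$frequencies_hz) / 1000), "\n")
  if (!is.null(x$vocal_set)) cat("  sounds:", length(x$vocal_set$sound_ids), "\n")
  cat("  SPLs:", paste(x$spls_db, collapse = ", "), "dB;",
      x$n_repetitions, "repetitions;", nrow(x$onsets), "onsets;",
      x$frame_rate_hz, "fps;", x$n_frames, "frames\n")
  invisible(x)
}

#' Serialize / read a stimulus protocol
#'
#' The grids and timing constants go to JSON; the onset table goes to CSV
#' next to it (same path with extension `.onsets.csv`).
#'
#' @param proto a `stim_protocol`.
#' @param path path of the JSON file to write/read.
#' @return `read_protocol` returns the reconstructed `stim_protocol`.
#' @export
write_protocol <- function(proto, path) {
  meta <- proto[setdiff(names(proto), "onsets")]
  if (!is.null(meta$vocal_set)) meta$vocal_set <- unclass(meta$vocal_set)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(proto$onsets, sub("\\.json$", "", path) |> paste0(".onsets.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  onsets <- utils::read.csv(paste0(sub("\\.json$", "", path), ".onsets.csv"),
                            stringsAsFactors = FALSE)
  if (!is.null(meta$vocal_set)) class(meta$vocal_set) <- "vocal_set"
  meta$onsets <- onsets
  structure(meta, class = "stim_protocol")
}
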
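#' Pre/post window means per stimulus combination
#'
#' For every neuron, stimulus combination and repetition, computes the mean
#' deconvolved spike probability over a window of `floor(window_s * fps)`
#' frames ending at the onset frame (pre) and starting at the onset frame
#' (post). At 30 fps the default 400-ms window spans 12 frames. Onsets too
#' close to a recording edge for a full window are dropped (with a log
#' attribute).
#'
#' @param traces a `trace_set`.
#' @param protocol the matching `stim_protocol` (defaults to the one carried
#'   by `traces`).
#' @param window_s window length in seconds (default 0.4).
#' @return object of class `combo_response`: list with `pre` and `post`
#'   arrays `[neuron, combo, repetition]`, a `combos` data frame
#'   (`stimulus_id`, `freq_index`, `spl_index`, `freq_hz`, `spl_db` where
#'   applicable), `window_frames`, and `dropped` (dropped onset rows).
#' @export
window_means <- function(traces, protocol = traces$protocol, window_s = 0.4) {
  stopifnot(inherits(traces, "trace_set"), inherits(protocol, "stim_protocol"))
  sp <- traces$spike_prob
  n <- nrow(sp); n_frames <- ncol(sp)
  wf <- floor(window_s * traces$frame_rate_hz)
  stopifnot(wf >= 1)
  ons <- protocol$onsets
  ok <- ons$onset_frame - wf >= 1 & ons$onset_frame + wf - 1 <= n_frames
  dropped <- ons[!ok, , drop = FALSE]
  ons <- ons[ok, , drop = FALSE]

  combos <- unique(ons[, intersect(c("stimulus_id", "stimulus_index", "freq_index",
                                     "spl_index", "freq_hz", "spl_db"), names(ons)),
                       drop = FALSE])
  if (!is.null(combos$freq_index))
    combos <- combos[order(combos$spl_index, combos$freq_index), , drop = FALSE]
  else combos <- combos[order(combos$stimulus_index), , drop = FALSE]
  rownames(combos) <- NULL
  combo_of <- match(ons$stimulus_id, combos$stimulus_id)
  n_combo <- nrow(combos)
  n_rep <- max(ons$repetition)

  pre <- array(NA_real_, c(n, n_combo, n_rep))
  post <- array(NA_real_, c(n, n_combo, n_rep))
  pre_cols <- outer(-(wf:1), ons$onset_frame, `+`)    # wf x trials
  post_cols <- outer(0:(wf - 1), ons$onset_frame, `+`)
  for (k in seq_len(nrow(ons))) {
    pre[, combo_of[k], ons$repetition[k]] <- rowMeans(sp[, pre_cols[, k], drop = FALSE])
    post[, combo_of[k], ons$repetition[k]] <- rowMeans(sp[, post_cols[, k], drop = FALSE])
  }
  structure(list(pre = pre, post = post, combos = combos,
                 window_frames = wf, window_s = window_s,
                 frame_rate_hz = traces$frame_rate_hz,
                 dropped = dropped),
            class = "combo_response")
}

# one-way ANOVA F and p for two groups (pre vs post repetition means);
# algebraically F = t^2 of the pooled-variance t-test (checked in tests
# against stats::aov). Zero variance in both groups with equal means gives
# p = 1 by convention; unequal means with zero variance give p = 0.
two_group_anova_p <- function(pre, post) {
  n1 <- rowSums(!is.na(pre)); n2 <- rowSums(!is.na(post))
  m1 <- rowMeans(pre, na.rm = TRUE); m2 <- rowMeans(post, na.rm = TRUE)
  ss1 <- rowSums((pre - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((post - m2)^2, na.rm = TRUE)
  nt <- n1 + n2
  gm <- (n1 * m1 + n2 * m2) / nt
  ss_between <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ss_within <- ss1 + ss2
  f <- (ss_between / 1) / (ss_within / (nt - 2))
  p <- stats::pf(f, 1, nt - 2, lower.tail = FALSE)
  degenerate <- ss_within == 0
  p[degenerate & ss_between == 0] <- 1
  p[degenerate & ss_between > 0] <- 0
  p[nt < 3] <- NA_real_
  p
}

#' Screen neurons for pure-tone responsiveness
#'
#' For every frequency-SPL combination a one-way ANOVA compares the
#' per-repetition pre-onset window means against the post-onset window means
#' (two groups of `n_repetitions` values). A neuron is responsive if at least
#' one combination reaches `p <= alpha`; if p > alpha in every combination it
#' is non-responsive. For downstream best-frequency analysis a combination is
#' additionally flagged `significant` only when its mean post response exceeds
#' the mean pre response (`signed_bf = TRUE`, the default), since the ANOVA is
#' two-sided but best frequency is defined on excitatory responses.
#'
#' @param combo a [window_means()] result.
#' @param alpha per-combination significance level (default 0.01;
#'   `p <= alpha` counts as significant).
#' @param signed_bf require post > pre for the `significant` matrix.
#' @return list of class `respond_result`: `p` matrix `[neuron, combo]`,
#'   `significant` logical matrix, `responsive` logical vector, `alpha`,
#'   and the `combos` table.
#' @export
classify_responsive <- function(combo, alpha = 0.01, signed_bf = TRUE) {
  stopifnot(inherits(combo, "combo_response"))
  n <- dim(combo$pre)[1]; n_combo <- dim(combo$pre)[2]
  p <- matrix(NA_real_, n, n_combo)
  excite <- matrix(FALSE, n, n_combo)
  for (j in seq_len(n_combo)) {
    pre_j <- combo$pre[, j, , drop = TRUE]
    post_j <- combo$post[, j, , drop = TRUE]
    if (is.null(dim(pre_j))) { pre_j <- matrix(pre_j, nrow = n); post_j <- matrix(post_j, nrow = n) }
    p[, j] <- two_group_anova_p(pre_j, post_j)
    excite[, j] <- rowMeans(post_j, na.rm = TRUE) > rowMeans(pre_j, na.rm = TRUE)
  }
  sig <- !is.na(p) & p <= alpha
  if (signed_bf) sig <- sig & excite
  structure(list(p = p, significant = sig,
                 responsive = apply(!is.na(p) & p <= alpha, 1, any),
                 alpha = alpha, combos = combo$combos),
            class = "respond_result")
}
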
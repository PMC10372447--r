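#' Local tuning heterogeneity (IQR within a radius)
#'
#' For each neuron, collects the tuning values (best or center frequency, in
#' octaves) of all neurons of the same population within `radius_um`
#' (Euclidean distance in the imaging plane, centre neuron included) and
#' reports the interquartile range of that local distribution as a measure of
#' local tonotopic heterogeneity. No IQR is computed when fewer than `min_n`
#' neurons (including the centre) fall inside the radius. Quartiles use
#' linear interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param neurons data frame with columns `x_um`, `y_um`, `value` (octaves);
#'   optional `id`, `population`, `subfield`. Rows with `NA` values are
#'   ignored both as centres and as neighbours.
#' @param radius_um neighbourhood radius (default 100).
#' @param min_n minimum neighbourhood size, centre included (default 5).
#' @return data frame, one row per (non-NA) centre neuron: `id`,
#'   `n_neighbors`, `iqr_oct` (`NA` when `n_neighbors < min_n`).
#' @export
local_iqr <- function(neurons, radius_um = 100, min_n = 5) {
  stopifnot(all(c("x_um", "y_um", "value") %in% names(neurons)))
  keep <- !is.na(neurons$value)
  nb <- neurons[keep, , drop = FALSE]
  n <- nrow(nb)
  id <- if (!is.null(nb$id)) nb$id else which(keep)
  out <- data.frame(id = id, n_neighbors = integer(n), iqr_oct = NA_real_)
  if (n == 0) return(out)
  d2 <- outer(nb$x_um, nb$x_um, `-`)^2 + outer(nb$y_um, nb$y_um, `-`)^2
  within <- d2 <= radius_um^2
  for (i in seq_len(n)) {
    vals <- nb$value[within[i, ]]
    out$n_neighbors[i] <- length(vals)
    if (length(vals) >= min_n) {
      q <- stats::quantile(vals, c(0.25, 0.75), type = 7, names = FALSE)
      out$iqr_oct[i] <- q[2] - q[1]
    }
  }
  if (!is.null(nb$population)) out$population <- nb$population
  if (!is.null(nb$subfield)) out$subfield <- nb$subfield
  out
}

#' Random subsampling of a population before heterogeneity analysis
#'
#' Randomly excludes a fraction of neurons within each subfield, the control
#' used to rule out sample-size effects when comparing local heterogeneity
#' between populations of different size.
#'
#' @param neurons data frame with a `subfield` column (a single implicit
#'   subfield is assumed when absent).
#' @param exclude_frac fraction of neurons to exclude per subfield, in `[0, 1)`.
#' @param seed integer seed.
#' @return the retained subset of `neurons` (row order preserved).
#' @export
subsample_population <- function(neurons, exclude_frac, seed = 1L) {
  stopifnot(exclude_frac >= 0, exclude_frac < 1)
  if (exclude_frac == 0) return(neurons)
  sf <- if (!is.null(neurons$subfield)) neurons$subfield else rep("all", nrow(neurons))
  keep <- withr::with_seed(as.integer(seed), {
    k <- logical(nrow(neurons))
    for (s in unique(sf)) {
      idx <- which(sf == s)
      n_keep <- round(length(idx) * (1 - exclude_frac))
      k[sample(idx, n_keep)] <- TRUE
    }
    k
  })
  neurons[keep, , drop = FALSE]
}
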
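#' Build per-repetition sound vectors
#'
#' For every neuron and repetition, the windowed mean spike probabilities to
#' all stimuli are lined up in a fixed stimulus order to form one "sound
#' vector". Pure-tone mode uses the 17 tones of the 50-dB recording with the
#' 400-ms tuning window; vocalization mode uses the 10 sounds with a 550-ms
#' window from sound onset.
#'
#' @param traces a `trace_set`.
#' @param mode `"pt50"` (pure tones at 50 dB) or `"vocal"`.
#' @param window_s analysis window; defaults to 0.4 s (`pt50`) / 0.55 s
#'   (`vocal`).
#' @param spl_db level selected in `pt50` mode (default 50).
#' @return object of class `sound_vectors`: `vectors` array
#'   `[neuron, repetition, stimulus]`, `stimulus_ids`, `mode`.
#' @export
build_sound_vectors <- function(traces, mode = c("pt50", "vocal"),
                                window_s = NULL, spl_db = 50) {
  mode <- match.arg(mode)
  proto <- traces$protocol
  if (is.null(window_s)) window_s <- if (mode == "pt50") 0.4 else 0.55
  wf <- floor(window_s * traces$frame_rate_hz)
  ons <- proto$onsets
  if (mode == "pt50") {
    stopifnot(proto$modality == "two_photon_pt")
    ons <- ons[ons$spl_db == spl_db, , drop = FALSE]
    if (nrow(ons) == 0) stop("no onsets at ", spl_db, " dB")
    stim_index <- ons$freq_index
    stim_ids <- sprintf("f%02d", sort(unique(ons$freq_index)))
    n_stim <- length(stim_ids)
  } else {
    stopifnot(proto$modality == "two_photon_voc")
    stim_index <- ons$stimulus_index
    stim_ids <- proto$vocal_set$sound_ids
    n_stim <- length(stim_ids)
  }
  n_rep <- max(ons$repetition)
  missing <- which(table(factor(stim_index, levels = seq_len(n_stim)),
                         factor(ons$repetition, levels = seq_len(n_rep))) == 0,
                   arr.ind = TRUE)
  if (length(missing) > 0)
    stop("missing (stimulus, repetition) presentations: ",
         paste(apply(missing, 1, paste, collapse = "/"), collapse = ", "))
  sp <- traces$spike_prob
  n <- nrow(sp)
  vec <- array(NA_real_, c(n, n_rep, n_stim))
  for (k in seq_len(nrow(ons))) {
    cols <- ons$onset_frame[k] + 0:(wf - 1)
    cols <- cols[cols <= ncol(sp)]
    vec[, ons$repetition[k], stim_index[k]] <- rowMeans(sp[, cols, drop = FALSE])
  }
  structure(list(vectors = vec, stimulus_ids = stim_ids, mode = mode,
                 window_s = window_s, n_repetitions = n_rep),
            class = "sound_vectors")
}

#' Cross-repetition correlation structure
#'
#' Pearson-correlates sound vectors across repetitions: within one neuron to
#' measure response reliability (mean over distinct repetition pairs), and
#' between neurons to measure response similarity. The between-neuron value
#' for a pair (i, j) is the mean correlation over all repetition pairs
#' (a, b); by default pairs with a = b are excluded (`pair_mode =
#' "offdiag"`), which keeps shared single-trial noise out of the similarity
#' estimate; `pair_mode = "all"` includes them.
#'
#' Neurons with a zero-variance sound vector in any repetition have undefined
#' correlations; those repetition pairs are dropped from the means, and a
#' neuron with no defined pair at all is marked excluded.
#'
#' @param sv a [build_sound_vectors()] result.
#' @param pair_mode `"offdiag"` (default) or `"all"`.
#' @return object of class `corr_structure`: `between` (n x n symmetric,
#'   reliability on the diagonal), `reliability` (length n), `excluded`
#'   (logical).
#' @export
correlation_structure <- function(sv, pair_mode = c("offdiag", "all")) {
  pair_mode <- match.arg(pair_mode)
  v <- sv$vectors
  n <- dim(v)[1]; R <- dim(v)[2]; S <- dim(v)[3]
  # stack (neuron, rep) rows and standardize; zero-variance rows become NA
  m <- matrix(aperm(v, c(2, 1, 3)), n * R, S)  # row = (rep within neuron)
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (S - 1))
  z <- (m - mu) / sdv
  z[sdv == 0, ] <- NA_real_
  cc <- tcrossprod(z) / (S - 1)  # correlation of every (neuron, rep) pair
  between <- matrix(NA_real_, n, n)
  reliability <- rep(NA_real_, n)
  off <- row(diag(R)) != col(diag(R))
  lower <- lower.tri(matrix(0, R, R))
  for (i in seq_len(n)) {
    ri <- (i - 1) * R + seq_len(R)
    bi <- cc[ri, ri]
    reliability[i] <- mean(bi[lower], na.rm = TRUE)
    for (j in seq_len(i)) {
      rj <- (j - 1) * R + seq_len(R)
      bij <- cc[ri, rj]
      val <- if (i == j) reliability[i] else
        mean(if (pair_mode == "offdiag") bij[off] else bij, na.rm = TRUE)
      between[i, j] <- between[j, i] <- val
    }
  }
  reliability[is.nan(reliability)] <- NA_real_
  between[is.nan(between)] <- NA_real_
  excluded <- is.na(reliability) | apply(between, 1, function(r) all(is.na(r)))
  structure(list(between = between, reliability = reliability,
                 excluded = excluded, pair_mode = pair_mode),
            class = "corr_structure")
}

#' Cluster neurons from their correlation structure
#'
#' Builds an average-linkage hierarchical tree on the dissimilarity
#' `1 - between-neuron correlation` and cuts it with the dynamic hybrid tree
#' cut ([cutree_hybrid()], `deep_split = 0.5`). Neurons excluded for
#' zero-variance vectors, or not assigned by the cut, are unclustered.
#'
#' @param struct a [correlation_structure()] result.
#' @param min_cluster_size smallest admissible cluster (default 3).
#' @param deep_split passed to [cutree_hybrid()].
#' @return object of class `cluster_set`: `labels` (0 = unclustered, `NA` =
#'   excluded neuron), `clusters` data frame (cluster, size, mean_corr,
#'   status), `structure`.
#' @export
cluster_cells <- function(struct, min_cluster_size = 3, deep_split = 0.5) {
  stopifnot(inherits(struct, "corr_structure"))
  n <- length(struct$reliability)
  keep <- which(!struct$excluded)
  labels <- rep(NA_integer_, n)
  if (length(keep) >= max(2, min_cluster_size)) {
    b <- struct$between[keep, keep]
    d <- 1 - b
    diag(d) <- 0
    tree <- stats::hclust(stats::as.dist(d), method = "average")
    lab <- cutree_hybrid(tree, d, min_cluster_size = min_cluster_size,
                         deep_split = deep_split)
    labels[keep] <- lab
  } else labels[keep] <- 0L
  cl_ids <- sort(unique(labels[!is.na(labels) & labels > 0]))
  clusters <- data.frame(cluster = cl_ids,
                         size = vapply(cl_ids, function(k) sum(labels == k, na.rm = TRUE), integer(1)),
                         mean_corr = vapply(cl_ids, function(k) {
                           m <- which(labels == k)
                           bb <- struct$between[m, m]
                           mean(bb[lower.tri(bb)], na.rm = TRUE)
                         }, numeric(1)),
                         status = if (length(cl_ids)) "candidate" else character(0))
  structure(list(labels = labels, clusters = clusters, structure = struct,
                 min_cluster_size = min_cluster_size, deep_split = deep_split),
            class = "cluster_set")
}

#' Shuffle null for cluster correlations
#'
#' Destroys stimulus structure by randomly re-assigning each neuron's
#' windowed responses to stimulus identities, independently per neuron and
#' per repetition, then recomputes the correlation structure and re-clusters.
#' The mean correlations of all clusters found in the shuffled data, pooled
#' over `n_shuffles` passes (default 5), form the null distribution used to
#' exclude clusters that could arise from random correlations at noise level.
#'
#' @param sv a [build_sound_vectors()] result.
#' @param n_shuffles number of shuffle passes (default 5).
#' @param seed integer seed.
#' @param min_cluster_size,deep_split,pair_mode as in the real-data analysis.
#' @return list of class `shuffle_null`: `values` (pooled shuffled-cluster
#'   mean correlations), `mean`, `sd`, `n_shuffles`, `n_empty` (shuffles that
#'   produced no cluster).
#' @export
shuffle_null <- function(sv, n_shuffles = 5, seed = 1L,
                         min_cluster_size = 3, deep_split = 0.5,
                         pair_mode = "offdiag") {
  v <- sv$vectors
  n <- dim(v)[1]; R <- dim(v)[2]; S <- dim(v)[3]
  vals <- withr::with_seed(as.integer(seed), {
    out <- numeric(0); of <- integer(0); empty <- 0L
    for (s in seq_len(n_shuffles)) {
      vs <- v
      for (i in seq_len(n)) for (r in seq_len(R))
        vs[i, r, ] <- v[i, r, sample(S)]
      svs <- structure(list(vectors = vs, stimulus_ids = sv$stimulus_ids,
                            mode = sv$mode, window_s = sv$window_s,
                            n_repetitions = R), class = "sound_vectors")
      cs <- cluster_cells(correlation_structure(svs, pair_mode),
                          min_cluster_size, deep_split)
      if (nrow(cs$clusters) == 0) empty <- empty + 1L
      out <- c(out, cs$clusters$mean_corr)
      of <- c(of, rep(s, nrow(cs$clusters)))
    }
    list(values = out, shuffle_of = of, n_empty = empty)
  })
  structure(list(values = vals$values, shuffle_of = vals$shuffle_of,
                 mean = if (length(vals$values)) mean(vals$values) else NA_real_,
                 sd = if (length(vals$values) > 1) stats::sd(vals$values) else NA_real_,
                 n_shuffles = n_shuffles, n_empty = vals$n_empty),
            class = "shuffle_null")
}

#' Filter clusters against the shuffle null
#'
#' A cluster is retained only if its mean within-cluster correlation strictly
#' exceeds the mean of the shuffled-cluster correlations by at least two
#' standard deviations; others are marked `excluded_by_null` and their
#' members set to unclustered. When the null is undefined (all shuffles
#' empty), all clusters are retained with a warning.
#'
#' @param clusters a [cluster_cells()] result.
#' @param null a [shuffle_null()] result.
#' @return the `cluster_set` with `status` set to `retained` /
#'   `excluded_by_null`, `labels` zeroed for excluded clusters, and the null
#'   summary attached.
#' @export
filter_clusters <- function(clusters, null) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(null, "shuffle_null"))
  cl <- clusters$clusters
  if (nrow(cl) > 0) {
    if (is.na(null$mean) || is.na(null$sd)) {
      warning("shuffle null undefined (no shuffled clusters); retaining all clusters")
      cl$status <- "retained"
    } else {
      thr <- null$mean + 2 * null$sd
      cl$status <- ifelse(cl$mean_corr > thr, "retained", "excluded_by_null")
    }
    for (k in cl$cluster[cl$status != "retained"])
      clusters$labels[!is.na(clusters$labels) & clusters$labels == k] <- 0L
  }
  clusters$clusters <- cl
  clusters$null <- null
  clusters
}

#' Cluster statistics
#'
#' The six per-FOV ensemble statistics: number of retained clusters, neurons
#' per cluster, fraction of clustered cells (retained-cluster members over
#' all neurons in the FOV, excluded neurons counted in the denominator),
#' pairwise physical distance (micrometres) between all within-cluster neuron
#' pairs, per-cluster mean correlation and per-cluster mean reliability.
#'
#' @param clusters a filtered `cluster_set`.
#' @param rois data frame with `x_um`, `y_um` aligned with the clustered
#'   neurons.
#' @return list of class `cluster_stats`: `n_clusters`, `cluster_sizes`,
#'   `fraction_clustered`, `pair_distances_um`, `cluster_corr`,
#'   `cluster_reliability`, `per_cluster` data frame.
#' @export
cluster_statistics <- function(clusters, rois) {
  stopifnot(inherits(clusters, "cluster_set"))
  labels <- clusters$labels
  n <- length(labels)
  stopifnot(nrow(rois) == n)
  cl <- clusters$clusters
  retained <- cl[cl$status == "retained", , drop = FALSE]
  sizes <- integer(0); corr <- numeric(0); reli <- numeric(0)
  dists <- numeric(0)
  for (k in retained$cluster) {
    m <- which(!is.na(labels) & labels == k)
    sizes <- c(sizes, length(m))
    bb <- clusters$structure$between[m, m]
    corr <- c(corr, mean(bb[lower.tri(bb)], na.rm = TRUE))
    reli <- c(reli, mean(clusters$structure$reliability[m], na.rm = TRUE))
    if (length(m) >= 2) {
      dd <- as.vector(stats::dist(cbind(rois$x_um[m], rois$y_um[m])))
      dists <- c(dists, dd)
    }
  }
  structure(list(n_clusters = nrow(retained),
                 cluster_sizes = sizes,
                 fraction_clustered = sum(sizes) / n,
                 pair_distances_um = dists,
                 cluster_corr = corr,
                 cluster_reliability = reli,
                 per_cluster = data.frame(cluster = retained$cluster,
                                          size = sizes, mean_corr = corr,
                                          mean_reliability = reli)),
            class = "cluster_stats")
}

#' One-call ensemble analysis of a FOV
#'
#' Sound vectors, correlation structure, dynamic-hybrid clustering, shuffle
#' null, null filtering and cluster statistics in one step.
#'
#' @inheritParams build_sound_vectors
#' @inheritParams shuffle_null
#' @return list with `vectors`, `structure`, `clusters` (filtered), `null`,
#'   `stats`.
#' @export
analyze_ensembles <- function(traces, mode = c("pt50", "vocal"), seed = 1L,
                              min_cluster_size = 3, deep_split = 0.5,
                              n_shuffles = 5, pair_mode = "offdiag") {
  mode <- match.arg(mode)
  sv <- build_sound_vectors(traces, mode)
  cs <- correlation_structure(sv, pair_mode)
  cl <- cluster_cells(cs, min_cluster_size, deep_split)
  nul <- shuffle_null(sv, n_shuffles, seed, min_cluster_size, deep_split, pair_mode)
  cl <- filter_clusters(cl, nul)
  st <- cluster_statistics(cl, traces$rois)
  list(vectors = sv, structure = cs, clusters = cl, null = nul, stats = st)
}
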
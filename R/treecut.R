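#' Dynamic hybrid tree cut
#'
#' Adaptive dendrogram cutting in the dynamic hybrid style: clusters are
#' branches of the hierarchical tree that (1) contain at least
#' `min_cluster_size` objects, (2) are tightly connected internally (the mean
#' pairwise dissimilarity of their core objects stays below a scatter
#' threshold), and (3) are separated from their surroundings (the height at
#' which the branch joins the rest of the tree exceeds its own last internal
#' merge by a minimum gap). Objects left over after branch identification are
#' assigned in a second, partitioning-around-medoids-like stage to the cluster
#' with the smallest average dissimilarity, provided that dissimilarity does
#' not exceed the cut height. Branches merging above `cut_height` are never
#' joined.
#'
#' The `deep_split` parameter in `[0, 4]` trades cluster sensitivity against
#' robustness by interpolating the scatter/gap thresholds over the standard
#' default tables (`max_core_scatter` {0.64, 0.73, 0.82, 0.91, 0.95} and
#' `min_gap = (1 - max_core_scatter) * 3/4`, both as fractions of the height
#' range between the 5th-percentile merge and `cut_height`); fractional
#' values such as the 0.5 used for ensemble clustering are interpolated
#' linearly.
#'
#' @param tree an [stats::hclust()] object.
#' @param dist_m symmetric dissimilarity matrix the tree was built from.
#' @param min_cluster_size smallest admissible cluster (default 3; ensemble
#'   analyses routinely observe clusters far below the size-20 default used
#'   in gene-network applications).
#' @param deep_split split sensitivity in `[0, 4]` (default 0.5).
#' @param cut_height maximum joining height; default is 99% of the range
#'   between the 5th-percentile merge height and the tree top.
#' @param pam_stage run the second-stage assignment of leftover objects.
#' @return integer vector of cluster labels along the tree's leaf order
#'   (1-based; 0 = unassigned), with attribute `cut_height`.
#' @export
cutree_hybrid <- function(tree, dist_m,
                          min_cluster_size = 3,
                          deep_split = 0.5,
                          cut_height = NULL,
                          pam_stage = TRUE) {
  stopifnot(inherits(tree, "hclust"))
  dist_m <- as.matrix(dist_m)
  n <- nrow(dist_m)
  stopifnot(n == length(tree$order))
  if (deep_split < 0 || deep_split > 4) stop("deep_split must be in [0, 4]")
  h <- tree$height
  merge <- tree$merge
  n_merge <- length(h)
  labels <- integer(n)
  if (n_merge < 1 || n < min_cluster_size) return(structure(labels, cut_height = NA_real_))

  ref_height <- h[max(1L, round(0.05 * n_merge))]
  if (is.null(cut_height)) cut_height <- 0.99 * (max(h) - ref_height) + ref_height
  mcs_def <- c(0.64, 0.73, 0.82, 0.91, 0.95)
  max_core_scatter <- stats::approx(0:4, mcs_def, xout = deep_split, rule = 2)$y
  min_gap <- (1 - max_core_scatter) * 3 / 4
  rng <- cut_height - ref_height
  max_abs_scatter <- ref_height + max_core_scatter * rng
  min_abs_gap <- min_gap * rng

  core_size <- function(sz) {
    base <- min_cluster_size / 2 + 1
    if (sz <= base) sz else floor(base + sqrt(sz - base))
  }
  # basic-cluster criteria for a branch attached to the rest at `attach_h`;
  # the branch height for the gap criterion is the mean of its internal
  # merge heights (the last merge alone reflects only the straggliest
  # member and under-states the separation of an otherwise tight branch)
  qualifies <- function(br, attach_h) {
    sz <- length(br$members)
    if (sz < min_cluster_size) return(FALSE)
    if (!(attach_h - br$h_sum / br$h_n > min_abs_gap)) return(FALSE)
    cs <- core_size(sz)
    core <- br$members[seq_len(cs)]
    sub <- dist_m[core, core]
    scatter <- sum(sub) / (cs * (cs - 1))
    scatter < max_abs_scatter
  }

  branches <- vector("list", n_merge)
  active <- rep(FALSE, n_merge)
  clusters <- list()
  get_child <- function(idx) {
    if (idx < 0) list(members = -idx, h_sum = 0, h_n = 0L, composite = FALSE,
                      singleton = TRUE)
    else branches[[idx]]
  }
  for (i in seq_len(n_merge)) {
    if (h[i] > cut_height) break
    a <- get_child(merge[i, 1]); b <- get_child(merge[i, 2])
    if (merge[i, 1] > 0) active[merge[i, 1]] <- FALSE
    if (merge[i, 2] > 0) active[merge[i, 2]] <- FALSE
    if (!a$composite && !b$composite) {
      qa <- qualifies(a, h[i]); qb <- qualifies(b, h[i])
      hs <- a$h_sum + b$h_sum + h[i]; hn <- a$h_n + b$h_n + 1L
      if (qa && qb) {
        clusters[[length(clusters) + 1L]] <- a$members
        clusters[[length(clusters) + 1L]] <- b$members
        br <- list(members = c(a$members, b$members), h_sum = hs, h_n = hn,
                   composite = TRUE)
      } else {
        br <- list(members = c(a$members, b$members), h_sum = hs, h_n = hn,
                   composite = FALSE)
      }
    } else if (xor(a$composite, b$composite)) {
      plain <- if (a$composite) b else a
      comp <- if (a$composite) a else b
      if (!isTRUE(plain$singleton) && qualifies(plain, h[i]))
        clusters[[length(clusters) + 1L]] <- plain$members
      br <- list(members = c(comp$members, plain$members),
                 h_sum = a$h_sum + b$h_sum + h[i], h_n = a$h_n + b$h_n + 1L,
                 composite = TRUE)
    } else {
      br <- list(members = c(a$members, b$members),
                 h_sum = a$h_sum + b$h_sum + h[i], h_n = a$h_n + b$h_n + 1L,
                 composite = TRUE)
    }
    branches[[i]] <- br
    active[i] <- TRUE
  }
  # top-level plain branches (attached above cut_height or never attached)
  for (i in which(active)) {
    br <- branches[[i]]
    if (!br$composite && qualifies(br, cut_height))
      clusters[[length(clusters) + 1L]] <- br$members
  }

  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k

  if (pam_stage && length(clusters) > 0) {
    unassigned <- which(labels == 0L)
    for (u in unassigned) {
      avg <- vapply(clusters, function(m) mean(dist_m[u, m]), numeric(1))
      k <- which.min(avg)
      if (avg[k] <= cut_height) labels[u] <- k
    }
  }
  # relabel clusters by decreasing size (ties: smallest member index)
  if (any(labels > 0)) {
    sizes <- table(labels[labels > 0])
    firsts <- vapply(names(sizes), function(k) min(which(labels == as.integer(k))),
                     numeric(1))
    ord <- order(-as.integer(sizes), firsts)
    remap <- integer(length(sizes))
    remap[as.integer(names(sizes))[ord]] <- seq_along(ord)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  structure(labels, cut_height = cut_height)
}
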
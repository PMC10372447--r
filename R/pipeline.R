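#' Demo pipeline configuration
#'
#' A self-contained configuration for [run_pipeline()]: synthetic two-photon
#' pure-tone and vocalization recordings are generated, screened, tuned,
#' mapped for local heterogeneity and clustered. All stage seeds derive from
#' one base seed; every stochastic stage has an explicit seed in the config.
#'
#' @param seed base seed.
#' @param out_dir output directory.
#' @param n_neurons two-photon population size.
#' @param n_motifs,neurons_per_motif vocalization motif structure.
#' @return nested config list of class `pipeline_config`.
#' @export
demo_pipeline_config <- function(seed = 1L, out_dir = tempfile("l5topo_run_"),
                                 n_neurons = 120, n_motifs = 3,
                                 neurons_per_motif = 12) {
  seed <- as.integer(seed)
  structure(list(
    out_dir = out_dir,
    seeds = list(protocol_pt = seed, protocol_voc = seed + 1L,
                 synth_pt = seed + 2L, synth_voc = seed + 3L,
                 ensembles_pt = seed + 4L, ensembles_voc = seed + 5L,
                 subsample = seed + 6L),
    synth_pt = list(n_neurons = n_neurons),
    synth_voc = list(n_motifs = n_motifs, neurons_per_motif = neurons_per_motif,
                     within_corr = 0.4, frac_unclustered = 0.2),
    respond = list(alpha = 0.01, window_s = 0.4),
    tuning = list(threshold = 0.3),
    topography = list(radius_um = 100, min_n = 5, value = "bf"),
    network = list(min_cluster_size = 3, deep_split = 0.5, n_shuffles = 5)),
    class = "pipeline_config")
}

signif_df <- function(df, digits = 6) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in order: protocol generation, synthetic-data generation,
#' responsiveness screening, gaussian tuning classification, local
#' heterogeneity, ensemble clustering with the shuffle null (pure tones at
#' 50 dB and vocalizations), and the CC vs non-CC group comparison of local
#' heterogeneity. Writes stage outputs as CSV (numbers at 6 significant
#' digits for diff-stability) and a JSON manifest with parameters, seeds and
#' per-stage record counts. Reruns with the same config are byte-identical.
#'
#' @param config a [demo_pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config = demo_pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  required_seeds <- c("protocol_pt", "protocol_voc", "synth_pt", "synth_voc",
                      "ensembles_pt", "ensembles_voc", "subsample")
  for (s in required_seeds)
    if (is.null(config$seeds[[s]])) stop("config validation error: missing seed ", s)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "l5topo",
                   version = as.character(utils::packageVersion("l5topo")),
                   seeds = config$seeds, stages = list())

  # protocols
  proto_pt <- make_protocol("two_photon_pt", seed = config$seeds$protocol_pt)
  proto_voc <- make_protocol("two_photon_voc", seed = config$seeds$protocol_voc)
  write_protocol(proto_pt, file.path(config$out_dir, "protocol_pt.json"))
  write_protocol(proto_voc, file.path(config$out_dir, "protocol_voc.json"))
  manifest$stages$protocol <- list(pt_onsets = nrow(proto_pt$onsets),
                                   voc_onsets = nrow(proto_voc$onsets))

  # synthetic data
  pt_cfg <- do.call(pt_population_config, config$synth_pt)
  sim_pt <- simulate_two_photon(proto_pt, pt_cfg, seed = config$seeds$synth_pt)
  voc_cfg <- do.call(motif_config, config$synth_voc)
  sim_voc <- simulate_vocal_responses(proto_voc, voc_cfg, seed = config$seeds$synth_voc)
  utils::write.csv(signif_df(sim_pt$ground_truth),
                   file.path(config$out_dir, "ground_truth_pt.csv"), row.names = FALSE)
  utils::write.csv(signif_df(sim_voc$ground_truth),
                   file.path(config$out_dir, "ground_truth_voc.csv"), row.names = FALSE)
  manifest$stages$synth <- list(pt_neurons = nrow(sim_pt$traces$spike_prob),
                                voc_neurons = nrow(sim_voc$traces$spike_prob))

  # responsiveness + tuning
  tuning <- tune_neurons(sim_pt$traces, window_s = config$respond$window_s,
                         alpha = config$respond$alpha,
                         threshold = config$tuning$threshold)
  tuning$neuron_type <- sim_pt$traces$rois$neuron_type
  tuning$subfield <- sim_pt$traces$rois$subfield
  utils::write.csv(signif_df(tuning), file.path(config$out_dir, "tuning.csv"),
                   row.names = FALSE)
  manifest$stages$respond <- list(neurons = nrow(tuning),
                                  responsive = sum(tuning$responsive),
                                  non_responsive = sum(!tuning$responsive))
  manifest$stages$tuning <- as.list(table(tuning$tuning_class))

  # local heterogeneity (BF of single-peaked neurons), per neuron type
  value_col <- if (config$topography$value == "bf") "bf_oct" else "cef_oct"
  topo_rows <- list()
  for (ty in unique(tuning$neuron_type)) {
    sel <- tuning$neuron_type == ty & !is.na(tuning[[value_col]]) &
      tuning$tuning_class %in% "single"
    nb <- data.frame(id = tuning$id[sel],
                     x_um = sim_pt$traces$rois$x_um[sel],
                     y_um = sim_pt$traces$rois$y_um[sel],
                     value = tuning[[value_col]][sel])
    iq <- local_iqr(nb, radius_um = config$topography$radius_um,
                    min_n = config$topography$min_n)
    if (nrow(iq)) iq$neuron_type <- ty
    topo_rows[[ty]] <- iq
  }
  topo <- do.call(rbind, topo_rows)
  rownames(topo) <- NULL
  utils::write.csv(signif_df(topo), file.path(config$out_dir, "heterogeneity.csv"),
                   row.names = FALSE)
  manifest$stages$topography <- list(centers = nrow(topo),
                                     with_iqr = sum(!is.na(topo$iqr_oct)))

  # group comparison of IQR between neuron types (when both have data)
  cmp <- NULL
  iq_cc <- topo$iqr_oct[topo$neuron_type == "CC" & !is.na(topo$iqr_oct)]
  iq_ncc <- topo$iqr_oct[topo$neuron_type == "non-CC" & !is.na(topo$iqr_oct)]
  if (length(iq_cc) >= 3 && length(iq_ncc) >= 3) {
    cmp <- compare_groups(iq_cc, iq_ncc)
    jsonlite::write_json(unclass(cmp), file.path(config$out_dir, "iqr_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # ensemble clustering: PT at 50 dB and vocalizations
  ens_pt <- analyze_ensembles(sim_pt$traces, "pt50",
                              seed = config$seeds$ensembles_pt,
                              min_cluster_size = config$network$min_cluster_size,
                              deep_split = config$network$deep_split,
                              n_shuffles = config$network$n_shuffles)
  ens_voc <- analyze_ensembles(sim_voc$traces, "vocal",
                               seed = config$seeds$ensembles_voc,
                               min_cluster_size = config$network$min_cluster_size,
                               deep_split = config$network$deep_split,
                               n_shuffles = config$network$n_shuffles)
  for (nm in c("pt", "voc")) {
    ens <- if (nm == "pt") ens_pt else ens_voc
    lab <- data.frame(neuron = seq_along(ens$clusters$labels),
                      cluster = ens$clusters$labels)
    utils::write.csv(lab, file.path(config$out_dir, paste0("clusters_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(signif_df(ens$clusters$clusters),
                     file.path(config$out_dir, paste0("cluster_summary_", nm, ".csv")),
                     row.names = FALSE)
    manifest$stages[[paste0("ensembles_", nm)]] <-
      list(neurons = length(ens$clusters$labels),
           clusters_retained = ens$stats$n_clusters,
           fraction_clustered = signif(ens$stats$fraction_clustered, 6),
           null_mean = signif(ens$null$mean, 6), null_sd = signif(ens$null$sd, 6))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(protocols = list(pt = proto_pt, voc = proto_voc),
                 sim_pt = sim_pt, sim_voc = sim_voc, tuning = tuning,
                 topography = topo, iqr_comparison = cmp,
                 ensembles_pt = ens_pt, ensembles_voc = ens_voc,
                 manifest = manifest))
}
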
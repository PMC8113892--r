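#' Build a diffusion dataset from event logs
#'
#' Runs the full ingest chain per trial: filter exclusions, reconstruct
#' occupancy, compute target-zone discovery times, detect following
#' interactions, build individual following and homogeneous networks, and the
#' exploration-rate ILV table.
#'
#' @param events Validated transition events (all trials; see
#'   [read_transition_events()]).
#' @param meta Collective metadata (see [read_collective_meta()]).
#' @param graph A [zone_graph()].
#' @param trial_duration Trial length in seconds.
#' @return A [diffusion_data()] object; the per-trial interactions, discovery
#'   tables and following summaries are attached as attribute `details`.
#' @export
build_diffusion_data <- function(events, meta, graph = default_zone_graph(),
                                 trial_duration = 2400) {
  trials <- unique(meta$trial_id)
  cols <- vector("list", length(trials))
  all_int <- list(); all_disc <- list()
  filt_all <- filter_events(events)
  for (k in seq_along(trials)) {
    tr <- trials[k]
    mtr <- meta[meta$trial_id == tr, , drop = FALSE]
    ev <- filt_all[filt_all$trial_id == tr, , drop = FALSE]
    occ <- build_occupancy(ev, mtr$individual_id, graph, trial_duration)
    disc <- discovery_times(occ, graph)
    ints <- detect_followings(ev, occ)
    nets <- build_individual_networks(ints, disc, mtr$individual_id,
                                      trial_duration)
    ilv <- ilv_table(ev, ints, disc, mtr$individual_id, trial_duration)
    tf <- nets$t_focal
    cols[[k]] <- make_collective(
      tr, unique(mtr$collective_type), mtr$individual_id,
      t = pmax(tf, 1e-9), censored = nets$censored,
      networks = list(following = nets$weights,
                      homogeneous = homogeneous_networks(mtr$individual_id)),
      ilv = ilv["exploration_rate"])
    all_int[[k]] <- ints
    all_disc[[k]] <- disc
  }
  data <- diffusion_data(cols, trial_duration)
  interactions <- do.call(rbind, all_int)
  discovery <- do.call(rbind, all_disc)
  attr(data, "details") <- list(
    interactions = interactions,
    discovery = discovery,
    following_summary = summarize_following(filt_all, interactions),
    filter_counts = attr(filt_all, "filter_counts"))
  data
}

#' Study-level discovery and feeding summary
#'
#' Proportions of individuals that reached the target zone and that fed,
#' expressed as percentages of all individuals across trials.
#'
#' @param discovery Combined [discovery_times()] table (one row per
#'   individual across all trials).
#' @param feeding Feeding events (or `NULL`).
#' @return List: `n`, `n_discovered`, `pct_discovered`, `n_fed`, `pct_fed`.
#' @export
summarize_study <- function(discovery, feeding = NULL) {
  n <- nrow(discovery)
  nd <- sum(!discovery$censored)
  nf <- if (is.null(feeding) || !nrow(feeding)) 0L
        else nrow(unique(feeding[c("trial_id", "individual_id")]))
  list(n = n, n_discovered = nd, pct_discovered = 100 * nd / n,
       n_fed = nf, pct_fed = 100 * nf / n)
}

#' Ingest validation report
#'
#' Counts of events, exclusions, followings, discoveries and feeders, per the
#' ingest chain.
#'
#' @inheritParams build_diffusion_data
#' @param feeding Optional feeding events.
#' @return List of counts and the per-trial following summary.
#' @export
ingest_report <- function(events, meta, feeding = NULL,
                          graph = default_zone_graph(),
                          trial_duration = 2400) {
  data <- build_diffusion_data(events, meta, graph, trial_duration)
  det <- attr(data, "details")
  summ <- summarize_study(det$discovery, feeding)
  list(n_collectives = length(data$collectives),
       n_individuals = summ$n,
       n_events_raw = nrow(events),
       n_excluded_pretrial = unname(det$filter_counts["pretrial_escape"]),
       n_startle = unname(det$filter_counts["startle"]),
       n_followings = nrow(det$interactions),
       n_discovered = summ$n_discovered,
       pct_discovered = summ$pct_discovered,
       n_fed = summ$n_fed,
       pct_fed = summ$pct_fed,
       following_summary = det$following_summary)
}

#' Run the full diffusion analysis
#'
#' Event logs in, ranked model table out: builds the diffusion dataset, fits
#' every model of the grid, ranks by AICc, forms the best-model set (5 AICc),
#' model-averages the social transmission and ILV parameters, and computes
#' the per-discoverer social-transmission probabilities using the averaged s
#' of the requested collective type.
#'
#' @inheritParams build_diffusion_data
#' @param grid List of [model_spec()]s.
#' @param options Fit options (see [fit_nbda()]).
#' @param ci_params Parameters for which conditional profile CIs are
#'   computed (set to `character(0)` to skip).
#' @param p_social_type Collective type over which `p_social` is averaged.
#' @return List: `data`, `table` (full ranked table), `best` (best-model
#'   set), `averages` (model-averaged estimates with conditional CIs),
#'   `p_social`, `summary`.
#' @export
run_diffusion_analysis <- function(events, meta,
                                   graph = default_zone_graph(),
                                   trial_duration = 2400,
                                   grid = default_model_grid(),
                                   options = list(),
                                   ci_params = character(0),
                                   p_social_type = "C") {
  data <- build_diffusion_data(events, meta, graph, trial_duration)
  fits <- fit_model_grid(data, grid, options)
  table <- rank_models(fits)
  best <- best_model_set(table)
  params <- unique(unlist(lapply(attr(best, "fits"),
                                 function(f) names(f$estimates))))
  params <- setdiff(params, "lambda0")
  averages <- lapply(params, function(p) {
    ma <- model_average(best, p)
    if (p %in% ci_params && !is.na(ma$top_index))
      ma$ci <- conditional_ci(data, best, p, options = options)
    ma
  })
  names(averages) <- params
  s_avg <- if ("s_C" %in% params) averages[["s_C"]]$estimate
           else if ("s" %in% params) averages[["s"]]$estimate
           else 0
  ps <- p_social(data, max(s_avg, 0), network = "following",
                 collective_types = p_social_type)
  det <- attr(data, "details")
  list(data = data, table = table, best = best, averages = averages,
       p_social = ps,
       summary = summarize_study(det$discovery))
}

#' Export helpers
#'
#' `write_model_table` writes a ranked model table as CSV;
#' `write_networks_csv` writes following networks as an edge-list CSV
#' (focal, partner, weight).
#'
#' @param table A [rank_models()] table.
#' @param path Output path.
#' @export
write_model_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_table
#' @param networks A [build_individual_networks()] result.
#' @export
write_networks_csv <- function(networks, path) {
  W <- networks$weights
  idx <- which(W != 0, arr.ind = TRUE)
  out <- data.frame(focal = rownames(W)[idx[, 1]],
                    partner = colnames(W)[idx[, 2]],
                    weight = W[idx], stringsAsFactors = FALSE)
  out <- out[order(out$focal, out$partner), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
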
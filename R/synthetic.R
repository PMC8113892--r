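#' Configuration for the agent-based arena simulator
#'
#' Emulates the study design: collectives of 8 on a 9-zone arena for 2400 s,
#' all starting in the start zone, moving between adjacent zones at a
#' treatment-dependent exponential rate, with a bias toward gates that a
#' conspecific recently transited (and whose destination that conspecific
#' still occupies). Defaults: control movement rate 0.66 transitions/min
#' (about 26 transitions per individual per trial, matching the order of
#' magnitude of the observed transition counts), tutors at 0.55 of that
#' (tutors are less active), bias 3 within a 10 s window. Feeding onset after
#' target discovery is delayed by an exponential neophobia delay, long for
#' naive individuals and short for tutors.
#'
#' @param graph A [zone_graph()].
#' @param n_individuals Members per collective.
#' @param trial_duration Seconds.
#' @param move_rate Named vector, transitions per minute per treatment.
#' @param following_bias Multiplier (>= 1 attracts, 1 = none) on a recently
#'   used gate.
#' @param window Seconds a prior transit remains attractive.
#' @param feeding_delay_mean Named vector of mean neophobia delays (s).
#' @param feeding_duration Range (min, max) of feeding bout lengths (s).
#' @param startle_prob Probability a transition is flagged `startle`.
#' @return List of class `arena_sim_config`.
#' @export
arena_sim_config <- function(graph = default_zone_graph(),
                             n_individuals = 8,
                             trial_duration = 2400,
                             move_rate = c(control = 0.66, spirulina = 0.363),
                             following_bias = 3,
                             window = 10,
                             feeding_delay_mean = c(control = 12000,
                                                    spirulina = 1500),
                             feeding_duration = c(10, 60),
                             startle_prob = 0) {
  stopifnot(all(move_rate > 0), following_bias > 0, window > 0,
            trial_duration > 0, n_individuals >= 1,
            all(feeding_delay_mean > 0), startle_prob >= 0, startle_prob < 1)
  structure(list(graph = graph, n_individuals = n_individuals,
                 trial_duration = trial_duration, move_rate = move_rate,
                 following_bias = following_bias, window = window,
                 feeding_delay_mean = feeding_delay_mean,
                 feeding_duration = feeding_duration,
                 startle_prob = startle_prob),
            class = "arena_sim_config")
}

#' Simulate one arena trial
#'
#' Continuous-time simulation: each individual waits an exponential time at
#' its treatment's movement rate, then picks an adjacent gate with
#' probability proportional to 1, or to the following bias if another
#' individual transited that gate (same direction) within the window and
#' still occupies the destination. Emits an event log that satisfies every
#' ingest and occupancy invariant, plus feeding state events.
#'
#' @param config An [arena_sim_config()].
#' @param seed Integer seed (deterministic output for a given seed).
#' @param trial_id Trial identifier.
#' @param collective_type `"C"` or `"S"`.
#' @param treatments Treatment per member (`"control"`/`"spirulina"`);
#'   default all control.
#' @return List with `events`, `feeding`, `meta` data frames.
#' @export
simulate_arena_trial <- function(config = arena_sim_config(), seed = NULL,
                                 trial_id = "T1", collective_type = "C",
                                 treatments = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals
  if (is.null(treatments)) treatments <- rep("control", n)
  stopifnot(length(treatments) == n,
            all(treatments %in% names(config$move_rate)))
  ids <- sprintf("%s_i%d", trial_id, seq_len(n))
  g <- config$graph
  dur <- config$trial_duration
  rate_s <- config$move_rate[treatments] / 60
  zone <- rep(g$start_zone, n)
  next_t <- stats::rexp(n, rate_s)
  ev_time <- numeric(0); ev_ind <- integer(0)
  ev_from <- integer(0); ev_to <- integer(0); ev_flag <- character(0)
  while (TRUE) {
    i <- which.min(next_t)
    t <- next_t[i]
    if (t > dur) break
    nbs <- zone_neighbors(g, zone[i])
    wts <- rep(1, length(nbs))
    if (config$following_bias != 1 && length(ev_time)) {
      recent <- which(ev_time > t - config$window & ev_ind != i &
                        ev_from == zone[i])
      for (r in recent) {
        k <- match(ev_to[r], nbs)
        if (!is.na(k) && zone[ev_ind[r]] == ev_to[r])
          wts[k] <- config$following_bias
      }
    }
    dest <- if (length(nbs) == 1) nbs else sample(nbs, 1, prob = wts)
    flag <- if (config$startle_prob > 0 &&
                stats::runif(1) < config$startle_prob) "startle" else "normal"
    ev_time <- c(ev_time, t); ev_ind <- c(ev_ind, i)
    ev_from <- c(ev_from, zone[i]); ev_to <- c(ev_to, dest)
    ev_flag <- c(ev_flag, flag)
    zone[i] <- dest
    next_t[i] <- t + stats::rexp(1, rate_s[i])
  }
  events <- data.frame(trial_id = rep(trial_id, length(ev_time)),
                       individual_id = ids[ev_ind],
                       time = ev_time, from_zone = ev_from, to_zone = ev_to,
                       flag = ev_flag, stringsAsFactors = FALSE)
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  # feeding: neophobia delay after first target-zone entry
  feed <- list()
  for (m in seq_len(n)) {
    hits <- ev_time[ev_ind == m & ev_to == g$target_zone]
    if (!length(hits)) next
    delay <- stats::rexp(1, 1 / config$feeding_delay_mean[[treatments[m]]])
    start <- min(hits) + delay
    if (start >= dur) next
    end <- min(start + stats::runif(1, config$feeding_duration[1],
                                    config$feeding_duration[2]), dur)
    feed[[length(feed) + 1]] <- data.frame(
      trial_id = trial_id, individual_id = ids[m], start = start, end = end,
      stringsAsFactors = FALSE)
  }
  feeding <- if (length(feed)) do.call(rbind, feed)
             else data.frame(trial_id = character(0),
                             individual_id = character(0),
                             start = numeric(0), end = numeric(0),
                             stringsAsFactors = FALSE)
  rownames(feeding) <- NULL
  meta <- data.frame(trial_id = trial_id, collective_type = collective_type,
                     individual_id = ids, treatment = treatments,
                     stringsAsFactors = FALSE)
  list(events = events, feeding = feeding, meta = meta)
}

#' Simulate a full study
#'
#' 8 control (all-naive) and 8 tutored collectives of 8 by default, the
#' tutored ones containing 5 control and 3 spirulina members (tutors listed
#' last). One global seed fans out into per-trial seeds by a single
#' `sample.int` draw, so the whole study is reproducible from the one seed.
#'
#' @param config An [arena_sim_config()].
#' @param seed Global seed.
#' @param n_collectives Named vector `c(C = ..., S = ...)`.
#' @param tutors_per_S Number of spirulina members in S collectives.
#' @return List with combined `events`, `feeding`, `meta` data frames.
#' @export
simulate_study <- function(config = arena_sim_config(), seed = 1L,
                           n_collectives = c(C = 8, S = 8),
                           tutors_per_S = 3) {
  set.seed(seed)
  n_tot <- sum(n_collectives)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  out <- list()
  idx <- 0
  for (type in names(n_collectives)) {
    for (r in seq_len(n_collectives[[type]])) {
      idx <- idx + 1
      trt <- if (type == "S")
        c(rep("control", config$n_individuals - tutors_per_S),
          rep("spirulina", tutors_per_S))
      else rep("control", config$n_individuals)
      out[[idx]] <- simulate_arena_trial(
        config, seed = trial_seeds[idx],
        trial_id = sprintf("%s%02d", type, r),
        collective_type = type, treatments = trt)
    }
  }
  list(events = do.call(rbind, lapply(out, `[[`, "events")),
       feeding = do.call(rbind, lapply(out, `[[`, "feeding")),
       meta = do.call(rbind, lapply(out, `[[`, "meta")))
}

#' Simulate acquisition times from the diffusion hazard
#'
#' Event-driven sampling directly from the model's hazard: between
#' acquisitions each naive individual's relative rate is constant, so the
#' next event time is drawn exactly by inverting the total cumulative hazard
#' (closed form for the constant baseline; via the gamma quantile function
#' for the gamma baseline). Used for clean parameter-recovery checks where
#' the fitted model is exactly true.
#'
#' @param collectives Collectives as in [diffusion_data()] (their `t` and
#'   `censored` entries are ignored and replaced by simulated values).
#' @param params Named parameter vector (as in [neg_log_likelihood()]).
#' @param spec A [model_spec()] (generative model).
#' @param trial_duration Censoring time (s).
#' @param seed Optional seed.
#' @return A [diffusion_data()] with simulated acquisition times.
#' @export
simulate_diffusion <- function(collectives, params, spec,
                               trial_duration = 2400, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  est <- unlist(params)
  H <- function(t) {
    if (spec$baseline == "constant") est[["lambda0"]] * t
    else gamma_cumulative_hazard(t, est[["gamma_shape"]], est[["lambda0"]])
  }
  Hinv <- function(h) {
    if (spec$baseline == "constant") h / est[["lambda0"]]
    else stats::qgamma(exp(-h), shape = est[["gamma_shape"]],
                       rate = est[["lambda0"]], lower.tail = FALSE)
  }
  sim_cols <- lapply(collectives, function(col) {
    n <- length(col$ids)
    t_acq <- rep(trial_duration, n)
    cens <- rep(TRUE, n)
    informed <- integer(0)
    t_cur <- 0
    repeat {
      naive <- setdiff(seq_len(n), informed)
      if (!length(naive)) break
      R <- vapply(naive, function(i)
        relative_rate(i, informed, est, spec, col$networks[[spec$network]],
                      col$ilv, col$type), numeric(1))
      Rtot <- sum(R)
      if (Rtot <= 1e-300) break
      h_next <- H(t_cur) + stats::rexp(1) / Rtot
      t_next <- Hinv(h_next)
      if (!is.finite(t_next) || t_next > trial_duration) break
      who <- naive[sample.int(length(naive), 1, prob = R)]
      t_acq[who] <- t_next
      cens[who] <- FALSE
      informed <- c(informed, who)
      t_cur <- t_next
    }
    make_collective(col$id, col$type, col$ids, t_acq, cens, col$networks,
                    col$ilv)
  })
  diffusion_data(sim_cols, trial_duration)
}

#' Random following-like weight matrices
#'
#' Sparse lognormal weights shaped like observed following-network ties, for
#' simulation studies.
#'
#' @param ids Member ids.
#' @param density Probability an ordered pair has a tie.
#' @param meanlog,sdlog Lognormal parameters of nonzero weights.
#' @return Weight matrix (zero diagonal).
#' @export
random_following_weights <- function(ids, density = 0.4, meanlog = -2,
                                     sdlog = 1) {
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  mask <- matrix(stats::runif(n * n) < density, n, n)
  W[mask] <- stats::rlnorm(sum(mask), meanlog, sdlog)
  diag(W) <- 0
  W
}

#' A tiny hand-checkable trial
#'
#' Three individuals on the default arena: B follows A twice (latencies 2 s
#' and 5 s) and then discovers the target zone at 600 s, so B's tie toward A
#' is `(1/2 + 1/5)/600 * 600 = 0.7` and B's exploration rate is 1 transition
#' per 10 min; C never moves and is censored.
#'
#' @return List with `events` and `meta` data frames.
#' @export
hand_trial <- function() {
  events <- data.frame(
    trial_id = "hand",
    individual_id = c("A", "B", "A", "B", "B", "B"),
    time = c(10, 12, 100, 105, 300, 600),
    from_zone = c(1, 1, 2, 2, 3, 6),
    to_zone = c(2, 2, 3, 3, 6, 9),
    flag = "normal", stringsAsFactors = FALSE)
  meta <- data.frame(trial_id = "hand", collective_type = "C",
                     individual_id = c("A", "B", "C"), treatment = "control",
                     stringsAsFactors = FALSE)
  list(events = events, meta = meta)
}

#' Write a deterministic fixture suite to disk
#'
#' A 16-collective study-shaped dataset (events, feeding, metadata), the
#' hand-checkable trial, and the arena graph, in the same CSV/YAML formats
#' the ingest functions consume. Byte-identical for a given seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Global seed.
#' @param config An [arena_sim_config()].
#' @return Invisibly, the vector of files written.
#' @export
make_fixture_suite <- function(dir, seed = 1L, config = arena_sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config, seed = seed)
  files <- c(events = file.path(dir, "events.csv"),
             feeding = file.path(dir, "feeding.csv"),
             meta = file.path(dir, "meta.csv"),
             hand_events = file.path(dir, "hand_events.csv"),
             hand_meta = file.path(dir, "hand_meta.csv"),
             arena = file.path(dir, "arena.yaml"))
  write_events(study$events, files[["events"]])
  write_feeding_events(study$feeding, files[["feeding"]])
  utils::write.table(study$meta, files[["meta"]], sep = ",",
                     row.names = FALSE, quote = FALSE)
  ht <- hand_trial()
  write_events(ht$events, files[["hand_events"]])
  utils::write.table(ht$meta, files[["hand_meta"]], sep = ",",
                     row.names = FALSE, quote = FALSE)
  write_zone_graph(config$graph, files[["arena"]])
  invisible(files)
}
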
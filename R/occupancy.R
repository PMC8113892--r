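#' Reconstruct zone occupancy from a trial's transition events
#'
#' Replays one trial's transitions for each individual, starting everyone in
#' the graph's start zone, and returns contiguous half-open occupancy
#' intervals `[enter, exit)` covering the whole trial. At the instant of a
#' transition the individual is in the destination zone, which makes the
#' "leader still present when the follower arrived" predicate decidable at
#' equal times.
#'
#' @param events Transition events of a single trial (post [filter_events()],
#'   so pre-trial escapes are gone; startle transits still move the animal).
#' @param members Character vector of all member ids (so individuals with no
#'   transitions get a single full-trial interval).
#' @param graph A [zone_graph()].
#' @param trial_duration Trial length in seconds.
#' @param strict_adjacency If `TRUE` a transition across a non-gate pair is an
#'   error; if `FALSE`, a warning.
#' @return Data frame with columns `individual_id`, `zone`, `enter`, `exit`;
#'   attributes `trial_id` and `trial_duration`. Class `occupancy`.
#' @export
build_occupancy <- function(events, members, graph = default_zone_graph(),
                            trial_duration = 2400, strict_adjacency = TRUE) {
  trial <- unique(events$trial_id)
  if (length(trial) > 1)
    stop("build_occupancy expects events of a single trial, got: ",
         paste(trial, collapse = ", "))
  if (length(trial) == 0) trial <- NA_character_
  members <- as.character(members)
  extra <- setdiff(unique(events$individual_id), members)
  if (length(extra))
    stop("events refer to non-member individual(s): ", paste(extra, collapse = ", "))
  rows <- vector("list", length(members))
  for (m in seq_along(members)) {
    id <- members[m]
    ev <- events[events$individual_id == id, , drop = FALSE]
    cur <- graph$start_zone
    t_prev <- 0
    zs <- integer(0); en <- numeric(0); ex <- numeric(0)
    for (i in seq_len(nrow(ev))) {
      if (ev$from_zone[i] != cur)
        stop(sprintf(
          "continuity error: individual %s at t=%g transitions from zone %d but occupies zone %d",
          id, ev$time[i], ev$from_zone[i], cur))
      if (!is_gate(graph, ev$from_zone[i], ev$to_zone[i])) {
        msg <- sprintf("adjacency error: individual %s at t=%g crosses non-gate pair %d-%d",
                       id, ev$time[i], ev$from_zone[i], ev$to_zone[i])
        if (strict_adjacency) stop(msg) else warning(msg)
      }
      zs <- c(zs, cur); en <- c(en, t_prev); ex <- c(ex, ev$time[i])
      cur <- ev$to_zone[i]
      t_prev <- ev$time[i]
    }
    zs <- c(zs, cur); en <- c(en, t_prev); ex <- c(ex, trial_duration)
    rows[[m]] <- data.frame(individual_id = id, zone = zs, enter = en,
                            exit = ex, stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, rows)
  rownames(occ) <- NULL
  attr(occ, "trial_id") <- trial
  attr(occ, "trial_duration") <- trial_duration
  class(occ) <- c("occupancy", "data.frame")
  occ
}

#' Zone occupied by an individual at a time point
#'
#' Intervals are half-open `[enter, exit)`; the trial's final instant belongs
#' to the last interval.
#'
#' @param occupancy An [build_occupancy()] result.
#' @param id Individual id.
#' @param t Time in seconds.
#' @return A zone index.
#' @export
zone_at <- function(occupancy, id, t) {
  dur <- attr(occupancy, "trial_duration")
  if (t < 0 || t > dur) stop("t outside [0, trial_duration]")
  iv <- occupancy[occupancy$individual_id == id, , drop = FALSE]
  hit <- iv$enter <= t & (t < iv$exit | (t == iv$exit & iv$exit == dur))
  iv$zone[which(hit)[1]]
}

#' Number of conspecifics in a zone at a time point
#'
#' @inheritParams zone_at
#' @param zone Zone index.
#' @param exclude Optional focal individual id to leave out of the count.
#' @return Integer count.
#' @export
conspecific_count <- function(occupancy, zone, t, exclude = NULL) {
  dur <- attr(occupancy, "trial_duration")
  if (t < 0 || t > dur) stop("t outside [0, trial_duration]")
  iv <- occupancy[occupancy$zone == zone, , drop = FALSE]
  if (!is.null(exclude)) iv <- iv[!iv$individual_id %in% exclude, , drop = FALSE]
  hit <- iv$enter <= t & (t < iv$exit | (t == iv$exit & iv$exit == dur))
  length(unique(iv$individual_id[hit]))
}

#' First entry times into the target zone
#'
#' The diffusion trait is discovery of the target zone; individuals that never
#' enter are censored at trial end. A (synthetic, degenerate) individual whose
#' first interval is already the target zone discovers at time 0.
#'
#' @param occupancy An [build_occupancy()] result.
#' @param graph The [zone_graph()] that defines the target zone.
#' @return Data frame `individual_id`, `t_discovery`, `censored`.
#' @export
discovery_times <- function(occupancy, graph = default_zone_graph()) {
  dur <- attr(occupancy, "trial_duration")
  ids <- unique(occupancy$individual_id)
  t_d <- numeric(length(ids)); cens <- logical(length(ids))
  for (i in seq_along(ids)) {
    iv <- occupancy[occupancy$individual_id == ids[i] &
                      occupancy$zone == graph$target_zone, , drop = FALSE]
    if (nrow(iv) == 0) {
      t_d[i] <- dur; cens[i] <- TRUE
    } else {
      t_d[i] <- min(iv$enter); cens[i] <- FALSE
    }
  }
  data.frame(individual_id = ids, t_discovery = t_d, censored = cens,
             stringsAsFactors = FALSE)
}

#' Re-emit transition events from an occupancy timeline
#'
#' Inverse of [build_occupancy()] up to flags (which occupancy does not
#' retain; re-emitted events are flagged `normal`).
#'
#' @param occupancy An [build_occupancy()] result.
#' @return Transition event data frame sorted by time.
#' @export
occupancy_to_events <- function(occupancy) {
  trial <- attr(occupancy, "trial_id")
  out <- lapply(unique(occupancy$individual_id), function(id) {
    iv <- occupancy[occupancy$individual_id == id, , drop = FALSE]
    n <- nrow(iv)
    if (n < 2) return(NULL)
    data.frame(trial_id = trial, individual_id = id,
               time = iv$enter[-1], from_zone = iv$zone[-n],
               to_zone = iv$zone[-1], flag = "normal",
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, out)
  if (is.null(ev))
    return(data.frame(trial_id = character(0), individual_id = character(0),
                      time = numeric(0), from_zone = integer(0),
                      to_zone = integer(0), flag = character(0),
                      stringsAsFactors = FALSE))
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Validate an occupancy timeline against its invariants
#'
#' Checks per individual: intervals contiguous and non-overlapping, covering
#' `[0, trial_duration]`; consecutive intervals differ in zone across a gate;
#' first zone is the start zone.
#'
#' @param occupancy An [build_occupancy()] result.
#' @param graph A [zone_graph()].
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_occupancy <- function(occupancy, graph = default_zone_graph()) {
  dur <- attr(occupancy, "trial_duration")
  for (id in unique(occupancy$individual_id)) {
    iv <- occupancy[occupancy$individual_id == id, , drop = FALSE]
    n <- nrow(iv)
    if (iv$enter[1] != 0 || iv$exit[n] != dur)
      stop("intervals of ", id, " do not cover the trial")
    if (iv$zone[1] != graph$start_zone)
      stop(id, " does not start in the start zone")
    if (n > 1) {
      if (any(abs(iv$exit[-n] - iv$enter[-1]) > 0))
        stop("intervals of ", id, " are not contiguous")
      if (any(iv$zone[-n] == iv$zone[-1]))
        stop("consecutive intervals of ", id, " share a zone")
      if (!all(is_gate(graph, iv$zone[-n], iv$zone[-1])))
        stop("non-gate move in intervals of ", id)
    }
    if (abs(sum(iv$exit - iv$enter) - dur) > 1e-9)
      stop("interval lengths of ", id, " do not sum to trial_duration")
  }
  invisible(TRUE)
}
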
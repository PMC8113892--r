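#' Detect leader-follower interactions in a trial
#'
#' A transition makes its individual a leader through that gate; the first
#' subsequent transition by a different individual through the same gate
#' (same origin, same destination) while the leader is still in the
#' destination zone is a following. Two caps apply: each leader transition
#' credits at most one following (its first follower), and each follower
#' transition is attributed to at most one leader — the most recent eligible
#' leader transition through that gate that has not yet credited a follower
#' (attribution falls back to the next most recent uncredited leader when the
#' most recent one is taken). Startle-flagged transits are ineligible on both
#' sides but still move the animal.
#'
#' @param events One trial's filtered events (with `follow_eligible` from
#'   [filter_events()]; absent column means all eligible).
#' @param occupancy Matching [build_occupancy()] result (used to check the
#'   leader is still in the destination zone).
#' @return Data frame of interactions: `trial_id`, `leader_id`, `follower_id`,
#'   `from_zone`, `to_zone`, `leader_time`, `follower_time`, `delta_t`.
#' @export
detect_followings <- function(events, occupancy) {
  n <- nrow(events)
  elig <- if ("follow_eligible" %in% names(events)) events$follow_eligible
          else rep(TRUE, n)
  ord <- order(events$time)        # stable
  ev <- events[ord, , drop = FALSE]
  elig <- elig[ord]
  credited <- logical(n)
  dur <- attr(occupancy, "trial_duration")
  res <- list()
  for (k in seq_len(n)) {
    if (!elig[k]) next
    cand <- which(elig[seq_len(k - 1)] &
                    !credited[seq_len(k - 1)] &
                    ev$from_zone[seq_len(k - 1)] == ev$from_zone[k] &
                    ev$to_zone[seq_len(k - 1)] == ev$to_zone[k] &
                    ev$individual_id[seq_len(k - 1)] != ev$individual_id[k] &
                    ev$time[seq_len(k - 1)] < ev$time[k])
    if (!length(cand)) next
    # leader must have stayed in the destination zone since its transition
    still <- vapply(cand, function(j) {
      iv <- occupancy[occupancy$individual_id == ev$individual_id[j] &
                        occupancy$zone == ev$to_zone[j] &
                        occupancy$enter == ev$time[j], , drop = FALSE]
      nrow(iv) > 0 && any(iv$exit > ev$time[k] |
                            (iv$exit == dur & ev$time[k] == dur))
    }, logical(1))
    cand <- cand[still]
    if (!length(cand)) next
    # most recent eligible leader; equal times resolved by latest file order
    j <- cand[ev$time[cand] == max(ev$time[cand])]
    j <- j[length(j)]
    credited[j] <- TRUE
    res[[length(res) + 1]] <- data.frame(
      trial_id = ev$trial_id[k],
      leader_id = ev$individual_id[j], follower_id = ev$individual_id[k],
      from_zone = ev$from_zone[k], to_zone = ev$to_zone[k],
      leader_time = ev$time[j], follower_time = ev$time[k],
      delta_t = ev$time[k] - ev$time[j],
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(trial_id = character(0), leader_id = character(0),
                      follower_id = character(0), from_zone = integer(0),
                      to_zone = integer(0), leader_time = numeric(0),
                      follower_time = numeric(0), delta_t = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tie strength of a follower toward one partner
#'
#' Multiple followings of the same partner are summed as reciprocals of their
#' latencies, standardized by the focal's target-zone discovery time and
#' expressed as a 10-minute rate:
#' `w = sum(1 / delta_t) / t_focal * 600`.
#'
#' @param delta_t Latencies (s) of the focal's followings of this partner.
#' @param t_focal Focal's discovery time (s); trial duration if censored.
#' @return Nonnegative weight; 0 for no interactions.
#' @export
#' @examples
#' tie_strength(c(2, 5), 600)  # (1/2 + 1/5) / 600 * 600 = 0.7
tie_strength <- function(delta_t, t_focal) {
  if (t_focal <= 0) stop("t_focal must be positive")
  if (!length(delta_t)) return(0)
  if (any(delta_t <= 0)) stop("delta_t must be positive")
  sum(1 / delta_t) / t_focal * 600
}

#' Build the individual following networks of a trial
#'
#' One directed weighted network per focal individual; entry `(i, j)` of the
#' weight matrix is focal `i`'s following rate toward `j`, computed only from
#' interactions in which `i` followed `j` before `i`'s own discovery of the
#' target zone. Censored focals are standardized by the trial duration (their
#' full exposure).
#'
#' @param interactions [detect_followings()] output for the trial.
#' @param discovery [discovery_times()] output for the trial.
#' @param members Character vector of member ids.
#' @param trial_duration Trial length in seconds.
#' @return List with `weights` (members x members matrix, focal in rows),
#'   `t_focal` (named vector), `censored` (named logical). Class
#'   `individual_networks`.
#' @export
build_individual_networks <- function(interactions, discovery, members,
                                      trial_duration = 2400) {
  members <- as.character(members)
  W <- matrix(0, length(members), length(members),
              dimnames = list(members, members))
  tf <- stats::setNames(ifelse(discovery$censored, trial_duration,
                               discovery$t_discovery),
                        discovery$individual_id)[members]
  cens <- stats::setNames(discovery$censored, discovery$individual_id)[members]
  for (i in members) {
    ints <- interactions[interactions$follower_id == i &
                           interactions$follower_time < tf[[i]], , drop = FALSE]
    if (!nrow(ints)) next
    for (j in unique(ints$leader_id))
      W[i, j] <- tie_strength(ints$delta_t[ints$leader_id == j], tf[[i]])
  }
  structure(list(weights = W, t_focal = tf, censored = cens),
            class = "individual_networks")
}

#' Homogeneous networks
#'
#' All possible connections set to 1; used to test whether information
#' diffusion operates independently of the following networks.
#'
#' @param members Character vector of at least two member ids.
#' @return Square 0/1 matrix with zero diagonal.
#' @export
homogeneous_networks <- function(members) {
  members <- as.character(members)
  if (length(members) < 2) stop("need at least 2 members")
  W <- matrix(1, length(members), length(members),
              dimnames = list(members, members))
  diag(W) <- 0
  W
}

#' Exploration rate of a focal individual
#'
#' Number of the focal's zone transitions before its target-zone discovery
#' that were not the follower side of a following interaction, divided by the
#' discovery time and expressed as a 10-minute rate. This is the asocial
#' (personal-information) covariate of the diffusion models.
#'
#' @param events One trial's filtered events.
#' @param interactions [detect_followings()] output.
#' @param discovery [discovery_times()] output.
#' @param focal Focal individual id.
#' @param trial_duration Trial length in seconds.
#' @return Nonnegative rate (transitions per 10 min).
#' @export
exploration_rate <- function(events, interactions, discovery, focal,
                             trial_duration = 2400) {
  d <- discovery[discovery$individual_id == focal, , drop = FALSE]
  if (!nrow(d)) stop("focal not in discovery table")
  tf <- if (d$censored) trial_duration else d$t_discovery
  if (tf <= 0) stop("focal discovery time must be positive")
  times <- events$time[events$individual_id == focal & events$time < tf]
  ftimes <- interactions$follower_time[interactions$follower_id == focal &
                                         interactions$follower_time < tf]
  n <- length(times) - length(ftimes)
  n / tf * 600
}

#' Individual-level variable table for a trial
#'
#' @inheritParams exploration_rate
#' @param members Character vector of member ids.
#' @return Data frame `individual_id`, `exploration_rate`.
#' @export
ilv_table <- function(events, interactions, discovery, members,
                      trial_duration = 2400) {
  data.frame(
    individual_id = as.character(members),
    exploration_rate = vapply(
      as.character(members),
      function(m) exploration_rate(events, interactions, discovery, m,
                                   trial_duration),
      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-collective following summary
#'
#' Counts transitions and followings and the proportion of transitions that
#' elicited a following, per trial.
#'
#' @param events Filtered events (one or more trials).
#' @param interactions Detected interactions for the same trials.
#' @return Data frame `trial_id`, `n_transitions`, `n_followings`,
#'   `prop_following` (`NA` for trials with no transitions).
#' @export
summarize_following <- function(events, interactions) {
  trials <- sort(unique(events$trial_id))
  out <- data.frame(
    trial_id = trials,
    n_transitions = vapply(trials, function(tr) sum(events$trial_id == tr),
                           integer(1)),
    n_followings = vapply(trials, function(tr)
      sum(interactions$trial_id == tr), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$prop_following <- ifelse(out$n_transitions > 0,
                               out$n_followings / out$n_transitions, NA_real_)
  out
}
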
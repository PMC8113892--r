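# Independent oracles and fixture builders used across the suite.

# Brute-force re-derivation of following interactions from the raw event list
# alone (no occupancy object): a leader occupies its destination zone until
# its own next transition. All ordered pairs are examined; the same two caps
# apply (one following per leader event, one leader per follower event, most
# recent eligible uncredited leader wins, ties by file order).
bf_followings <- function(events) {
  ev <- events[order(events$time), , drop = FALSE]
  n <- nrow(ev)
  elig <- if ("follow_eligible" %in% names(ev)) ev$follow_eligible
          else rep(TRUE, n)
  departure <- rep(Inf, n)
  for (k in seq_len(n)) {
    later <- which(ev$individual_id == ev$individual_id[k] & seq_len(n) > k)
    if (length(later)) departure[k] <- ev$time[later[1]]
  }
  credited <- logical(n)
  rows <- list()
  for (k in seq_len(n)) {
    if (!elig[k]) next
    best <- 0L
    if (k > 1) for (j in seq_len(k - 1)) {
      if (!elig[j] || credited[j]) next
      if (ev$individual_id[j] == ev$individual_id[k]) next
      if (ev$from_zone[j] != ev$from_zone[k] ||
          ev$to_zone[j] != ev$to_zone[k]) next
      if (!(ev$time[j] < ev$time[k])) next
      if (!(departure[j] > ev$time[k])) next
      best <- j   # ascending scan: last hit = most recent time, latest order
    }
    if (best == 0L) next
    credited[best] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(
      trial_id = ev$trial_id[k],
      leader_id = ev$individual_id[best], follower_id = ev$individual_id[k],
      from_zone = ev$from_zone[k], to_zone = ev$to_zone[k],
      leader_time = ev$time[best], follower_time = ev$time[k],
      delta_t = ev$time[k] - ev$time[best], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(trial_id = character(0), leader_id = character(0),
                      follower_id = character(0), from_zone = integer(0),
                      to_zone = integer(0), leader_time = numeric(0),
                      follower_time = numeric(0), delta_t = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Numerical-integration oracle for the diffusion likelihood on a 0.01 s grid.
# Relative rates are piecewise constant with breakpoints at acquisition
# times; instances are drawn with times on the 0.01 s lattice, so cell
# midpoints never hit a breakpoint and the midpoint rule is exact for the
# constant baseline. For the gamma baseline the baseline hazard varies within
# cells and composite Simpson on the same grid is used (gamma shape >= 1 so
# the hazard is finite at 0).
quad_nll <- function(data, params, spec, h = 0.01) {
  est <- unlist(params)
  TT <- data$trial_duration
  a <- seq(0, TT - h, by = h)
  mid <- a + h / 2
  b <- a + h
  if (spec$baseline == "constant") {
    base_cell <- rep(est[["lambda0"]] * h, length(a))
    log_h0 <- function(t) rep(log(est[["lambda0"]]), length(t))
  } else {
    h0 <- function(t) exp(
      stats::dgamma(t, est[["gamma_shape"]], rate = est[["lambda0"]],
                    log = TRUE) -
        stats::pgamma(t, est[["gamma_shape"]], rate = est[["lambda0"]],
                      lower.tail = FALSE, log.p = TRUE))
    base_cell <- (h0(a) + 4 * h0(mid) + h0(b)) / 6 * h
    # near t = 0 the gamma hazard has a t^(shape-1) branch whose derivatives
    # are singular for non-integer shape; integrate the first cells adaptively
    for (k in seq_len(50))
      base_cell[k] <- stats::integrate(h0, a[k], b[k], rel.tol = 1e-12,
                                       abs.tol = 1e-14)$value
    log_h0 <- function(t)
      stats::dgamma(t, est[["gamma_shape"]], rate = est[["lambda0"]],
                    log = TRUE) -
        stats::pgamma(t, est[["gamma_shape"]], rate = est[["lambda0"]],
                      lower.tail = FALSE, log.p = TRUE)
  }
  ll <- 0
  for (col in data$collectives) {
    n <- length(col$ids)
    A <- col$networks[[spec$network]]
    asoc <- rep(1, n)
    if (length(spec$ilv)) {
      X <- as.matrix(col$ilv[, spec$ilv, drop = FALSE])
      asoc <- exp(drop(X %*% est[paste0("beta_", colnames(X))]))
    }
    s <- switch(spec$s_structure,
                none = 0,
                C_only = if (col$type == "C") est[["s_C"]] else 0,
                S_only = if (col$type == "S") est[["s_S"]] else 0,
                shared = est[["s"]],
                by_type = if (col$type == "C") est[["s_C"]] else est[["s_S"]])
    w0 <- if (spec$asocial_weight == "complement") 1 - s else 1
    informed_t <- ifelse(col$censored, Inf, col$t)
    Z <- outer(mid, informed_t, ">=")            # cells x individuals
    for (i in seq_len(n)) {
      soc <- drop(Z %*% A[i, ])
      r <- if (spec$interaction == "additive") s * soc + w0 * asoc[i]
           else (s * soc + w0) * asoc[i]
      r <- pmax(r, 1e-12)
      end_i <- if (col$censored[i]) TT else col$t[i]
      use <- mid < end_i
      ll <- ll - sum(r[use] * base_cell[use])
      if (!col$censored[i]) {
        before <- which(!col$censored & col$t < col$t[i])
        soc_i <- sum(A[i, before])
        r_i <- if (spec$interaction == "additive") s * soc_i + w0 * asoc[i]
               else (s * soc_i + w0) * asoc[i]
        r_i <- max(r_i, 1e-12)
        ll <- ll + log_h0(col$t[i]) + log(r_i)
      }
    }
  }
  -ll
}

# Random small diffusion instance on the 0.01 s lattice (distinct times).
rand_instance <- function(seed, TT = 200) {
  set.seed(seed)
  n_col <- sample(1:2, 1)
  cols <- lapply(seq_len(n_col), function(k) {
    n <- sample(3:8, 1)
    ids <- sprintf("c%d_i%d", k, seq_len(n))
    cens <- stats::runif(n) < 0.3
    t <- ifelse(cens, TT, sample(seq(0.01, TT - 0.01, by = 0.01), n))
    make_collective(sprintf("c%d", k), sample(c("C", "S"), 1), ids, t, cens,
                    networks = list(
                      following = random_following_weights(ids, 0.5,
                                                           meanlog = -1),
                      homogeneous = homogeneous_networks(ids)),
                    ilv = data.frame(exploration_rate = stats::runif(n, 0, 3)))
  })
  diffusion_data(cols, TT)
}

rand_params <- function(seed, spec) {
  set.seed(seed + 10000)
  est <- c(lambda0 = stats::runif(1, 0.002, 0.02))
  if (spec$baseline == "gamma")
    est <- c(est, gamma_shape = stats::runif(1, 1, 3))
  est <- c(est, switch(spec$s_structure,
                       none = NULL,
                       C_only = c(s_C = stats::runif(1, 0, 3)),
                       S_only = c(s_S = stats::runif(1, 0, 3)),
                       shared = c(s = stats::runif(1, 0, 3)),
                       by_type = c(s_C = stats::runif(1, 0, 3),
                                   s_S = stats::runif(1, 0, 3))))
  if (length(spec$ilv))
    est <- c(est, stats::setNames(stats::runif(length(spec$ilv), -0.5, 0.5),
                                  paste0("beta_", spec$ilv)))
  est
}

# Events data frame renamed to the default CSV dialect (for read round-trips).
as_dialect_df <- function(events) {
  out <- events[c("trial_id", "individual_id", "time", "from_zone", "to_zone",
                  "flag")]
  names(out) <- c("trial_id", "subject", "time_s", "from_zone", "to_zone",
                  "flag")
  out
}

# Template collectives (censored placeholders) for diffusion simulation.
template_collectives <- function(n_col = 16, n = 8, seed = 1,
                                 trial_duration = 2400, density = 0.5,
                                 meanlog = -1.5, with_ilv = FALSE) {
  set.seed(seed)
  lapply(seq_len(n_col), function(k) {
    ids <- sprintf("T%d_i%d", k, seq_len(n))
    make_collective(sprintf("T%d", k), if (k <= ceiling(n_col / 2)) "C" else "S",
                    ids, rep(trial_duration, n), rep(TRUE, n),
                    networks = list(
                      following = random_following_weights(ids, density,
                                                           meanlog = meanlog),
                      homogeneous = homogeneous_networks(ids)),
                    ilv = if (with_ilv)
                      data.frame(exploration_rate = stats::runif(n, 0, 3))
                    else NULL)
  })
}
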
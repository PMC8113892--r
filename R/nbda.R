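#' Specify one cell of the diffusion-model grid
#'
#' A model is defined by its baseline hazard (constant, or the hazard of a
#' gamma distribution), how social and asocial effects combine when
#' individual-level variables (ILVs) are present, how the social transmission
#' parameter is structured across collective types, which network carries the
#' social pathway, and which ILVs enter. When no social parameter or no ILV is
#' present the interaction form is irrelevant and is normalized to
#' `"additive"`; asocial models do not use a network and are normalized to
#' `"following"` so equivalent specifications compare equal.
#'
#' `asocial_weight` selects the asocial term of the relative rate:
#' `"complement"` uses `(1 - s)` (the conventional additive parameterization,
#' which makes the asocial weight negative when s > 1 — evaluations are then
#' floored, see [neg_log_likelihood()]); `"unit"` uses a constant 1, i.e.
#' `s * network + asocial`, which is well behaved for any s >= 0.
#'
#' @param baseline `"constant"` or `"gamma"`.
#' @param interaction `"additive"` or `"multiplicative"`.
#' @param s_structure One of `"none"`, `"C_only"`, `"S_only"`, `"shared"`,
#'   `"by_type"`.
#' @param network `"following"` or `"homogeneous"`.
#' @param ilv Character vector of ILV names (columns of the data's ILV table).
#' @param asocial_weight `"complement"` or `"unit"`.
#' @return An object of class `nbda_spec`.
#' @export
model_spec <- function(baseline = c("constant", "gamma"),
                       interaction = c("additive", "multiplicative"),
                       s_structure = c("none", "C_only", "S_only", "shared",
                                       "by_type"),
                       network = c("following", "homogeneous"),
                       ilv = character(0),
                       asocial_weight = c("complement", "unit")) {
  baseline <- match.arg(baseline)
  interaction <- match.arg(interaction)
  s_structure <- match.arg(s_structure)
  network <- match.arg(network)
  asocial_weight <- match.arg(asocial_weight)
  if (s_structure == "none" || !length(ilv)) interaction <- "additive"
  if (s_structure == "none") network <- "following"
  structure(list(baseline = baseline, interaction = interaction,
                 s_structure = s_structure, network = network,
                 ilv = as.character(ilv), asocial_weight = asocial_weight),
            class = "nbda_spec")
}

#' @export
print.nbda_spec <- function(x, ...) {
  cat(spec_label(x), "\n")
  invisible(x)
}

#' Short label for a model specification
#' @param spec An `nbda_spec`.
#' @return Character scalar.
#' @export
spec_label <- function(spec) {
  paste0(spec$baseline, "/",
         if (spec$s_structure == "none") "asocial"
         else paste0("s_", spec$s_structure, "/", spec$network, "/",
                     spec$interaction),
         if (length(spec$ilv)) paste0("/ilv:", paste(spec$ilv, collapse = "+"))
         else "")
}

#' Default diffusion-model grid
#'
#' Enumerates the grid actually compared in this kind of analysis: social
#' models (4 s-structures x 2 networks x 2 baselines x 2 interaction forms
#' with the ILV, plus the same without the ILV where the interaction form
#' collapses) and asocial models (2 baselines, with and without the ILV) — 52
#' specifications for one ILV. Pass an explicit list to [fit_model_grid()] to
#' use any other grid.
#'
#' @param ilv Character vector of ILV names (default the exploration rate).
#' @param asocial_weight Passed to every [model_spec()].
#' @return List of `nbda_spec` objects.
#' @export
default_model_grid <- function(ilv = "exploration_rate",
                               asocial_weight = "complement") {
  specs <- list()
  add <- function(s) specs[[length(specs) + 1]] <<- s
  for (base in c("constant", "gamma")) {
    add(model_spec(base, s_structure = "none", asocial_weight = asocial_weight))
    add(model_spec(base, s_structure = "none", ilv = ilv,
                   asocial_weight = asocial_weight))
    for (ss in c("C_only", "S_only", "shared", "by_type"))
      for (net in c("following", "homogeneous")) {
        add(model_spec(base, "additive", ss, net,
                       asocial_weight = asocial_weight))
        for (int in c("additive", "multiplicative"))
          add(model_spec(base, int, ss, net, ilv = ilv,
                         asocial_weight = asocial_weight))
      }
  }
  specs
}

#' Assemble a diffusion dataset
#'
#' Bundles, per collective: member ids, type, acquisition (target-discovery)
#' times with censoring, both candidate networks and the ILV table.
#'
#' @param collectives List of collectives as built by [make_collective()].
#' @param trial_duration Trial length in seconds.
#' @return Object of class `diffusion_data`.
#' @export
diffusion_data <- function(collectives, trial_duration = 2400) {
  if (!length(collectives)) stop("need at least one collective")
  for (col in collectives) {
    n <- length(col$ids)
    stopifnot(col$type %in% c("C", "S"),
              length(col$t) == n, length(col$censored) == n,
              all(col$t > 0 & col$t <= trial_duration),
              all(dim(col$networks$following) == c(n, n)),
              all(dim(col$networks$homogeneous) == c(n, n)))
    if (!is.null(col$ilv) && nrow(col$ilv) != n)
      stop("ILV table of collective ", col$id, " does not cover every member")
  }
  structure(list(collectives = collectives, trial_duration = trial_duration),
            class = "diffusion_data")
}

#' Build one collective of a diffusion dataset
#'
#' @param id Collective (trial) id.
#' @param type `"C"` or `"S"`.
#' @param ids Member ids.
#' @param t Acquisition times (named or in `ids` order); trial duration for
#'   censored members.
#' @param censored Logical vector.
#' @param networks List with `following` and `homogeneous` weight matrices
#'   (focal in rows).
#' @param ilv Optional data frame of ILVs with one row per member (in `ids`
#'   order).
#' @return A collective list suitable for [diffusion_data()].
#' @export
make_collective <- function(id, type, ids, t, censored, networks, ilv = NULL) {
  list(id = id, type = type, ids = as.character(ids),
       t = as.numeric(t), censored = as.logical(censored),
       networks = networks, ilv = ilv)
}

#' @export
print.diffusion_data <- function(x, ...) {
  n_ev <- sum(vapply(x$collectives, function(cl) sum(!cl$censored), numeric(1)))
  cat(sprintf("diffusion_data: %d collectives, %d acquisition events, T = %g s\n",
              length(x$collectives), n_ev, x$trial_duration))
  invisible(x)
}

# ---- internal: prepared likelihood structures -------------------------------

# Acquisition events within a collective are processed in stable time order;
# ties are separated only by their order, so the informed set before the k-th
# event is exactly the first k-1 events.
.prep_collective <- function(col, spec, trial_duration) {
  n <- length(col$ids)
  A <- col$networks[[spec$network]]
  unc <- which(!col$censored)
  ord <- unc[order(col$t[unc])]          # stable
  m <- length(ord)
  tau <- c(0, col$t[ord], trial_duration)
  # rank of each individual's event (Inf for censored)
  rank_of <- rep(Inf, n)
  rank_of[ord] <- seq_len(m)
  nseg <- m + 1
  z <- matrix(0, nseg, n)
  for (k in seq_len(nseg)) if (k > 1) z[k, ord[seq_len(k - 1)]] <- 1
  naive <- matrix(0, nseg, n)
  for (k in seq_len(nseg)) naive[k, ] <- as.numeric(rank_of >= k)
  socsum <- z %*% t(A)                    # socsum[k, i] = sum_j A[i,j] z_j
  X <- NULL
  if (length(spec$ilv)) {
    if (is.null(col$ilv)) stop("spec requires ILVs absent from collective ", col$id)
    X <- as.matrix(col$ilv[, spec$ilv, drop = FALSE])
  }
  list(n = n, m = m, type = col$type, tau = tau, dt = diff(tau),
       socsum = socsum, naive = naive, ev_seg = seq_len(m), ev_idx = ord,
       X = X, id = col$id)
}

.prepare_nbda <- function(data, spec) {
  lapply(data$collectives, .prep_collective, spec = spec,
         trial_duration = data$trial_duration)
}

.s_for_type <- function(spec, est, type) {
  switch(spec$s_structure,
         none = 0,
         C_only = if (type == "C") est[["s_C"]] else 0,
         S_only = if (type == "S") est[["s_S"]] else 0,
         shared = est[["s"]],
         by_type = if (type == "C") est[["s_C"]] else est[["s_S"]])
}

# Relative-rate matrix (segments x individuals) for one prepared collective.
.rel_matrix <- function(prep, spec, est, floor = 1e-12) {
  asoc <- rep(1, prep$n)
  if (!is.null(prep$X)) {
    beta <- est[paste0("beta_", colnames(prep$X))]
    asoc <- exp(drop(prep$X %*% beta))
  }
  s <- .s_for_type(spec, est, prep$type)
  if (s < 0) stop("social transmission parameter must be nonnegative")
  asoc_row <- matrix(asoc, nrow(prep$socsum), prep$n, byrow = TRUE)
  R <- switch(paste(spec$interaction, spec$asocial_weight),
              "additive complement" = s * prep$socsum + (1 - s) * asoc_row,
              "additive unit" = s * prep$socsum + asoc_row,
              "multiplicative complement" = (s * prep$socsum + (1 - s)) * asoc_row,
              "multiplicative unit" = (s * prep$socsum + 1) * asoc_row)
  clamped <- R < floor
  if (any(clamped)) {
    R[clamped] <- floor
    attr(R, "clamped") <- sum(clamped)
  }
  R
}

#' Cumulative hazard of the gamma baseline
#'
#' `H(t) = -log(1 - F_gamma(t; shape, rate))`, computed on the log scale so
#' large `t` stay finite; where the survival function underflows to zero the
#' value is capped at a large finite constant with a warning. With piecewise
#' constant relative rates the likelihood integrates as
#' `relative_rate * diff(H)`. Shape 1 reduces to `rate * t` exactly.
#'
#' @param t Nonnegative times.
#' @param shape,rate Gamma parameters (> 0).
#' @return Cumulative hazard values.
#' @export
gamma_cumulative_hazard <- function(t, shape, rate) {
  if (any(t < 0)) stop("t must be nonnegative")
  if (shape <= 0 || rate <= 0) stop("shape and rate must be positive")
  H <- -stats::pgamma(t, shape = shape, rate = rate, lower.tail = FALSE,
                      log.p = TRUE)
  if (any(!is.finite(H))) {
    warning("gamma survival underflow; cumulative hazard capped")
    H[!is.finite(H)] <- 1e10
  }
  H
}

.log_base_hazard <- function(t, spec, est) {
  if (spec$baseline == "constant") {
    rep(log(est[["lambda0"]]), length(t))
  } else {
    stats::dgamma(t, shape = est[["gamma_shape"]], rate = est[["lambda0"]],
                  log = TRUE) -
      stats::pgamma(t, shape = est[["gamma_shape"]], rate = est[["lambda0"]],
                    lower.tail = FALSE, log.p = TRUE)
  }
}

.delta_H <- function(tau, spec, est) {
  if (spec$baseline == "constant") {
    est[["lambda0"]] * diff(tau)
  } else {
    diff(gamma_cumulative_hazard(tau, est[["gamma_shape"]], est[["lambda0"]]))
  }
}

#' Relative acquisition rate of a naive individual
#'
#' The multiplier on the baseline hazard for naive individual `i`: additive
#' form `s * sum_j(a_ij z_j) + w_asoc * exp(sum_k beta_k x_ki)`,
#' multiplicative form `(s * sum_j(a_ij z_j) + w_asoc) * exp(...)`, where
#' `w_asoc` is `(1 - s)` or 1 per the spec's `asocial_weight`.
#'
#' @param i Index of the (naive) focal within `networks`' rows.
#' @param informed Indices of currently informed individuals.
#' @param params Named parameter vector/list (needs the s parameters named per
#'   the structure and `beta_<ilv>` entries).
#' @param spec A [model_spec()].
#' @param networks Weight matrix (focal in rows).
#' @param ilv Optional data frame/matrix of ILVs (rows match the matrix).
#' @param type Collective type, `"C"` or `"S"`.
#' @return Nonnegative scalar (floored at 1e-12).
#' @export
relative_rate <- function(i, informed, params, spec, networks, ilv = NULL,
                          type = "C") {
  est <- unlist(params)
  s <- .s_for_type(spec, est, type)
  if (s < 0) stop("social transmission parameter must be nonnegative")
  soc <- if (length(informed)) sum(networks[i, informed]) else 0
  asoc <- 1
  if (length(spec$ilv)) {
    beta <- est[paste0("beta_", spec$ilv)]
    asoc <- exp(sum(beta * as.numeric(as.matrix(ilv)[i, spec$ilv])))
  }
  w0 <- if (spec$asocial_weight == "complement") 1 - s else 1
  r <- if (spec$interaction == "additive") s * soc + w0 * asoc
       else (s * soc + w0) * asoc
  max(r, 1e-12)
}

# Full negative log-likelihood over prepared collectives.
.nll_prepared <- function(prep_list, spec, est, floor = 1e-12) {
  ll <- 0
  for (prep in prep_list) {
    R <- .rel_matrix(prep, spec, est, floor)
    dH <- .delta_H(prep$tau, spec, est)
    integral <- sum((R * prep$naive) * dH)
    ev_ll <- 0
    if (prep$m > 0) {
      t_ev <- prep$tau[2:(prep$m + 1)]
      lbh <- .log_base_hazard(t_ev, spec, est)
      ev_ll <- sum(lbh + log(R[cbind(prep$ev_seg, prep$ev_idx)]))
    }
    ll <- ll + ev_ll - integral
  }
  if (!is.finite(ll)) return(NA_real_)
  -ll
}

#' Negative log-likelihood of a diffusion dataset
#'
#' Continuous time-of-acquisition likelihood: each naive individual's hazard
#' is `lambda_0(t)` times its relative rate given the currently informed set;
#' informed sets are piecewise constant between acquisition events within a
#' collective; collectives are independent; censored individuals contribute
#' only their survival (integral) term. Evaluations where the relative rate
#' would be nonpositive (possible under the printed additive form with s > 1)
#' are floored at `floor`.
#'
#' @param data A [diffusion_data()] object.
#' @param params Named list/vector: `lambda0` (> 0), `gamma_shape` (gamma
#'   baseline only), the s parameters required by the structure (`s`, `s_C`,
#'   `s_S`) and `beta_<ilv>` coefficients.
#' @param spec A [model_spec()].
#' @param floor Lower clamp for relative rates.
#' @return The negative log-likelihood (scalar; `NA` if non-finite).
#' @export
neg_log_likelihood <- function(data, params, spec, floor = 1e-12) {
  est <- unlist(params)
  prep <- .prepare_nbda(data, spec)
  .nll_prepared(prep, spec, est, floor)
}

# ---- internal: parameter bookkeeping and optimization -----------------------

.param_names <- function(spec) {
  c("lambda0",
    if (spec$baseline == "gamma") "gamma_shape",
    switch(spec$s_structure, none = NULL, C_only = "s_C", S_only = "s_S",
           shared = "s", by_type = c("s_C", "s_S")),
    if (length(spec$ilv)) paste0("beta_", spec$ilv))
}

.is_positive_param <- function(nm) nm %in% c("lambda0", "gamma_shape")
.is_s_param <- function(nm) nm %in% c("s", "s_C", "s_S")

.softplus <- function(u) ifelse(u > 30, u, log1p(exp(u)))
.inv_softplus <- function(v) {
  v <- pmax(v, 1e-10)
  ifelse(v > 30, v, log(expm1(v)))
}

.to_trans <- function(est, nms) {
  vapply(nms, function(nm) {
    if (.is_positive_param(nm)) log(est[[nm]])
    else if (.is_s_param(nm)) .inv_softplus(est[[nm]])
    else est[[nm]]
  }, numeric(1))
}

.from_trans <- function(theta, nms) {
  stats::setNames(vapply(seq_along(nms), function(i) {
    if (.is_positive_param(nms[i])) exp(theta[i])
    else if (.is_s_param(nms[i])) .softplus(theta[i])
    else theta[i]
  }, numeric(1)), nms)
}

.n_events_total <- function(data)
  sum(vapply(data$collectives, function(cl) sum(!cl$censored), numeric(1)))

.total_exposure <- function(data)
  sum(vapply(data$collectives, function(cl) sum(cl$t), numeric(1)))

.with_preserved_seed <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  force(code)
}

# Maximize the log-likelihood with optional fixed parameters. For the constant
# baseline, lambda0 is profiled analytically: logL(lambda0) =
# n log(lambda0) + sum log R_ev - lambda0 * I with I = sum(R * naive * dt), so
# lambda0_hat = n / I given the other parameters.
.maximize <- function(data, spec, prep, fixed = NULL,
                      options = list()) {
  opt <- utils::modifyList(list(n_starts = 5, seed = 1L, floor = 1e-12),
                           options)
  nms <- .param_names(spec)
  fixed_nms <- names(fixed)
  free <- setdiff(nms, fixed_nms)
  n_ev <- .n_events_total(data)
  profile_l0 <- spec$baseline == "constant" && "lambda0" %in% free
  inner <- setdiff(free, if (profile_l0) "lambda0")

  assemble <- function(inner_est, lambda0 = NULL) {
    est <- c(inner_est, unlist(fixed))
    if (!is.null(lambda0)) est[["lambda0"]] <- lambda0
    est[nms]
  }

  # returns logL (and the implied lambda0 when profiled)
  eval_ll <- function(inner_est) {
    if (profile_l0) {
      est <- assemble(inner_est, lambda0 = 1)
      slogR <- 0; I <- 0
      for (p in prep) {
        R <- .rel_matrix(p, spec, est, opt$floor)
        I <- I + sum((R * p$naive) * p$dt)
        if (p$m > 0)
          slogR <- slogR + sum(log(R[cbind(p$ev_seg, p$ev_idx)]))
      }
      if (n_ev == 0 || I <= 0) {
        # no events: logL = -lambda0 * I maximized as lambda0 -> 0 boundary
        return(list(ll = if (n_ev == 0) 0 else -Inf, lambda0 = 1e-12))
      }
      l0 <- n_ev / I
      list(ll = n_ev * log(l0) + slogR - n_ev, lambda0 = l0)
    } else {
      est <- assemble(inner_est)
      nll <- .nll_prepared(prep, spec, est, opt$floor)
      list(ll = if (is.na(nll)) -Inf else -nll,
           lambda0 = est[["lambda0"]])
    }
  }

  obj <- function(theta) {
    r <- eval_ll(.from_trans(theta, inner))
    if (!is.finite(r$ll)) 1e10 else -r$ll
  }

  # start values
  l0_start <- max(n_ev, 1) / max(.total_exposure(data), 1e-9)
  base_est <- stats::setNames(rep(0, length(nms)), nms)
  base_est["lambda0"] <- l0_start
  if ("gamma_shape" %in% nms) base_est["gamma_shape"] <- 1
  base_est[nms[.is_s_param(nms)]] <- 1
  theta0 <- .to_trans(as.list(base_est[inner]), inner)

  conv <- FALSE
  if (length(inner) == 0) {
    r <- eval_ll(stats::setNames(numeric(0), character(0)))
    best_est <- assemble(stats::setNames(numeric(0), character(0)),
                         lambda0 = if (profile_l0) r$lambda0)
    best_ll <- r$ll
    conv <- is.finite(best_ll)
  } else if (length(inner) == 1) {
    o <- stats::optimize(obj, interval = c(theta0 - 15, theta0 + 15),
                         tol = 1e-10)
    # refine near the optimum for tight tolerance
    o2 <- stats::optimize(obj, interval = o$minimum + c(-0.05, 0.05),
                          tol = 1e-12)
    th <- if (o2$objective <= o$objective) o2$minimum else o$minimum
    r <- eval_ll(.from_trans(th, inner))
    best_est <- assemble(.from_trans(th, inner),
                         lambda0 = if (profile_l0) r$lambda0)
    best_ll <- r$ll
    conv <- is.finite(best_ll)
  } else {
    starts <- list(theta0)
    if (opt$n_starts > 1) {
      .with_preserved_seed({
        set.seed(opt$seed)
        for (k in seq_len(opt$n_starts - 1))
          starts[[k + 1]] <- theta0 + stats::rnorm(length(theta0), 0, 1)
      })
    }
    best_val <- Inf; best_th <- theta0
    for (st in starts) {
      fit1 <- tryCatch(
        stats::optim(st, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit1)) next
      fit2 <- tryCatch(
        stats::optim(fit1$par, obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14)),
        error = function(e) fit1)
      cand <- if (fit2$value <= fit1$value) fit2 else fit1
      if (is.finite(cand$value) && cand$value < best_val) {
        best_val <- cand$value
        best_th <- cand$par
        conv <- TRUE
      }
    }
    r <- eval_ll(.from_trans(best_th, inner))
    best_est <- assemble(.from_trans(best_th, inner),
                         lambda0 = if (profile_l0) r$lambda0)
    best_ll <- r$ll
    conv <- conv && is.finite(best_ll)
  }
  list(estimates = best_est, logLik = best_ll, converged = conv)
}

#' Fit one diffusion model by maximum likelihood
#'
#' Maximizes the continuous time-of-acquisition likelihood over the spec's
#' free parameters on smooth unconstrained transforms (log for `lambda0` and
#' `gamma_shape`, softplus for the nonnegative s parameters, identity for
#' betas), with multi-start Nelder-Mead plus BFGS polishing for
#' multi-parameter models. Under the constant baseline `lambda0` is profiled
#' out analytically, so asocial constant-baseline fits equal the closed-form
#' censored-exponential MLE.
#'
#' @param data A [diffusion_data()] object.
#' @param spec A [model_spec()].
#' @param options List: `n_starts` (default 5), `seed` (start jitter, default
#'   1), `floor` (relative-rate clamp), `aicc_n` (sample size for the AICc
#'   correction; default the number of uncensored acquisition events).
#' @return Object of class `nbda_fit` with elements `spec`, `estimates`
#'   (named vector), `logLik`, `k` (free-parameter count), `n_events`, `aicc`,
#'   `converged`.
#' @export
fit_nbda <- function(data, spec, options = list()) {
  if (spec$s_structure %in% c("C_only", "by_type") &&
      !any(vapply(data$collectives, function(cl) cl$type == "C", logical(1))))
    stop("spec requires C collectives absent from the data")
  if (spec$s_structure %in% c("S_only", "by_type") &&
      !any(vapply(data$collectives, function(cl) cl$type == "S", logical(1))))
    stop("spec requires S collectives absent from the data")
  prep <- .prepare_nbda(data, spec)
  res <- .maximize(data, spec, prep, fixed = NULL, options = options)
  k <- length(.param_names(spec))
  n_ev <- .n_events_total(data)
  n_aicc <- if (!is.null(options$aicc_n)) options$aicc_n else n_ev
  structure(list(spec = spec, estimates = res$estimates, logLik = res$logLik,
                 k = k, n_events = n_ev,
                 aicc = aicc(res$logLik, k, n_aicc),
                 converged = res$converged, options = options),
            class = "nbda_fit")
}

#' @export
print.nbda_fit <- function(x, ...) {
  cat(sprintf("nbda_fit %s\n  logLik %.4f  k %d  AICc %.4f  converged %s\n",
              spec_label(x$spec), x$logLik, x$k, x$aicc, x$converged))
  est <- x$estimates
  cat("  ", paste(sprintf("%s=%.5g", names(est), est), collapse = "  "), "\n")
  invisible(x)
}

#' Fit a list of model specifications
#'
#' @param data A [diffusion_data()] object.
#' @param grid List of [model_spec()]s (e.g. [default_model_grid()]).
#' @param options Passed to [fit_nbda()].
#' @return List of `nbda_fit` objects.
#' @export
fit_model_grid <- function(data, grid = default_model_grid(),
                           options = list()) {
  lapply(grid, function(sp) fit_nbda(data, sp, options))
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Finds the parameter values at which twice the drop from the maximized
#' log-likelihood equals the chi-squared(1) quantile, re-optimizing all other
#' parameters at each candidate value (bracketed root search). The lower bound
#' of nonnegative parameters is clipped at 0 when the profile never drops
#' enough there; a bound the profile never crosses inside the search range is
#' reported as open (`0` or `Inf`) with attribute `open`.
#'
#' @param data A [diffusion_data()] object.
#' @param spec The fitted [model_spec()].
#' @param fit The [fit_nbda()] result.
#' @param param Parameter name (e.g. `"s_C"`, `"lambda0"`,
#'   `"beta_exploration_rate"`).
#' @param level Confidence level.
#' @param options Optimizer options (as in [fit_nbda()]).
#' @return Numeric vector `c(lower, upper)` with attribute `open` (logical
#'   pair).
#' @export
profile_ci <- function(data, spec, fit, param, level = 0.95,
                       options = list()) {
  if (!isTRUE(fit$converged)) stop("profile_ci requires a converged fit")
  nms <- .param_names(spec)
  if (!param %in% nms) stop("parameter ", param, " is not in this model")
  prep <- .prepare_nbda(data, spec)
  llmax <- fit$logLik
  drop_target <- stats::qchisq(level, df = 1) / 2
  pll <- function(v) {
    .maximize(data, spec, prep, fixed = stats::setNames(list(v), param),
              options = options)$logLik
  }
  f <- function(v) (llmax - pll(v)) - drop_target
  est <- fit$estimates[[param]]
  nonneg <- .is_positive_param(param) || .is_s_param(param)
  scale <- max(abs(est), 0.5)
  open <- c(FALSE, FALSE)

  # lower bound
  if (.is_s_param(param)) {
    if (est <= 1e-8 || f(0) <= 0) {
      lower <- 0
    } else {
      lower <- stats::uniroot(f, c(0, est), tol = 1e-7 * scale)$root
    }
  } else if (nonneg) {
    lo <- est
    found <- FALSE
    for (j in 1:50) {
      lo <- lo / 2
      if (f(lo) > 0) { found <- TRUE; break }
    }
    if (found) lower <- stats::uniroot(f, c(lo, est), tol = 1e-7 * scale)$root
    else { lower <- 0; open[1] <- TRUE }
  } else {
    lo <- est; step <- scale
    found <- FALSE
    for (j in 1:40) {
      lo <- lo - step; step <- step * 2
      if (f(lo) > 0) { found <- TRUE; break }
    }
    if (found) lower <- stats::uniroot(f, c(lo, est), tol = 1e-7 * scale)$root
    else { lower <- -Inf; open[1] <- TRUE }
  }

  # upper bound
  hi <- if (est > 1e-8) est else 0
  step <- max(scale, 0.5)
  found <- FALSE
  for (j in 1:40) {
    hi <- hi + step; step <- step * 2
    if (f(hi) > 0) { found <- TRUE; break }
  }
  if (found) upper <- stats::uniroot(f, c(max(est, 1e-12), hi),
                                     tol = 1e-7 * scale)$root
  else { upper <- Inf; open[2] <- TRUE }

  out <- c(lower = lower, upper = upper)
  attr(out, "open") <- open
  attr(out, "level") <- level
  out
}
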
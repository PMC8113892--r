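#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`. Undefined (returned as `NA` with
#' a warning) when `n <= k + 1`; such models are excluded from ranking.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size for the correction (here, the number of uncensored
#'   acquisition events).
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    warning("AICc undefined for n <= k + 1 (n = ", n, ", k = ", k, ")")
    return(NA_real_)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_m` proportional to `exp(-delta_m / 2)` with `delta_m` the AICc
#' difference to the best model; non-finite entries get weight 0.
#'
#' @param aicc_values Numeric vector of AICc values (NA/Inf allowed).
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  fin <- is.finite(aicc_values)
  if (!any(fin)) stop("no finite AICc values")
  d <- aicc_values - min(aicc_values[fin])
  w <- ifelse(fin, exp(-d / 2), 0)
  w / sum(w)
}

#' Rank fitted models by AICc
#'
#' @param fits List of [fit_nbda()] results.
#' @return Data frame (class `nbda_model_table`) ordered by AICc with columns
#'   describing each spec plus `k`, `logLik`, `aicc`, `delta_aicc`, `weight`;
#'   the (reordered) fits are kept in attribute `fits`.
#' @export
rank_models <- function(fits) {
  tab <- data.frame(
    model = vapply(fits, function(f) spec_label(f$spec), character(1)),
    baseline = vapply(fits, function(f) f$spec$baseline, character(1)),
    interaction = vapply(fits, function(f) f$spec$interaction, character(1)),
    s_structure = vapply(fits, function(f) f$spec$s_structure, character(1)),
    network = vapply(fits, function(f) f$spec$network, character(1)),
    ilv = vapply(fits, function(f) paste(f$spec$ilv, collapse = "+"),
                 character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE)
  tab$weight <- akaike_weights(tab$aicc)
  ord <- order(tab$aicc)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  attr(tab, "fits") <- fits[ord]
  class(tab) <- c("nbda_model_table", "data.frame")
  tab
}

#' Best-model set
#'
#' Models within `delta` AICc of the best-fitting model; the top model is
#' always included. The subset's summed Akaike weight (computed over the full
#' table) is attached as attribute `summed_weight`.
#'
#' @param table A [rank_models()] table.
#' @param delta AICc window (default 5).
#' @return Subset of the table (same class), fits subset in attribute `fits`.
#' @export
best_model_set <- function(table, delta = 5) {
  keep <- which(table$delta_aicc <= delta & is.finite(table$delta_aicc))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- attr(table, "fits")[keep]
  attr(out, "summed_weight") <- sum(table$weight[keep])
  class(out) <- class(table)
  out
}

#' Model-averaged parameter estimate
#'
#' Weighted mean of a parameter over the models of a set that contain it. By
#' default the weights are renormalized within that subset (natural
#' averaging); with `renormalize = FALSE` absent models contribute zero
#' (shrinkage averaging). The summed (unrenormalized) weight of contributing
#' models is reported alongside.
#'
#' @param table A [rank_models()] or [best_model_set()] table.
#' @param param Parameter name.
#' @param renormalize Renormalize weights over containing models.
#' @return List with `parameter`, `estimate` (`NA` if the parameter appears in
#'   no model), `summed_weight`, `top_index` (row of the highest-ranked
#'   containing model, `NA` if none).
#' @export
model_average <- function(table, param, renormalize = TRUE) {
  fits <- attr(table, "fits")
  has <- vapply(fits, function(f) param %in% names(f$estimates), logical(1))
  if (!any(has))
    return(list(parameter = param, estimate = NA_real_, summed_weight = 0,
                top_index = NA_integer_))
  est <- vapply(fits[has], function(f) f$estimates[[param]], numeric(1))
  w <- table$weight[has]
  avg <- if (renormalize) sum(w * est) / sum(w) else sum(w * est)
  list(parameter = param, estimate = avg,
       summed_weight = sum(table$weight[has]),
       top_index = which(has)[1])
}

#' Conditional profile-likelihood CI for a model-averaged parameter
#'
#' The interval is taken from the highest-ranked model of the set that
#' contains the parameter (conditional CI; unconditional standard errors are
#' deliberately not computed, as the s profiles are strongly asymmetric).
#'
#' @param data The [diffusion_data()] the models were fitted to.
#' @param table A [best_model_set()] table.
#' @param param Parameter name.
#' @param level Confidence level.
#' @param options Optimizer options.
#' @return [profile_ci()] result, or `NULL` if no model contains the
#'   parameter.
#' @export
conditional_ci <- function(data, table, param, level = 0.95,
                           options = list()) {
  ma <- model_average(table, param)
  if (is.na(ma$top_index)) return(NULL)
  fit <- attr(table, "fits")[[ma$top_index]]
  profile_ci(data, fit$spec, fit, param, level = level, options = options)
}

#' Probability that each discovery was social
#'
#' For each uncensored discoverer `i` with social input
#' `S_i = sum_j a_ij z_j(t_i)` evaluated just before its discovery,
#' `p_social_i = s S_i / (1 + s S_i)`; the first discoverer of a collective
#' has no informed partners and contributes 0. Simultaneous discoveries are
#' ordered stably, the earlier-listed event informing the later.
#'
#' @param data A [diffusion_data()] object.
#' @param s_value Social transmission parameter (>= 0), typically the
#'   model-averaged estimate for the relevant collective type.
#' @param network `"following"` or `"homogeneous"`.
#' @param collective_types Which collective types to include (default `"C"`,
#'   where the social effect is estimated).
#' @return List with `table` (collective, individual, t, social_sum,
#'   p_social) and `mean` over the included discoverers.
#' @export
p_social <- function(data, s_value, network = "following",
                     collective_types = "C") {
  if (s_value < 0) stop("s_value must be nonnegative")
  rows <- list()
  for (col in data$collectives) {
    if (!col$type %in% collective_types) next
    A <- col$networks[[network]]
    unc <- which(!col$censored)
    ord <- unc[order(col$t[unc])]
    informed <- integer(0)
    for (i in ord) {
      S <- if (length(informed)) sum(A[i, informed]) else 0
      rows[[length(rows) + 1]] <- data.frame(
        collective = col$id, individual_id = col$ids[i], t = col$t[i],
        social_sum = S, p_social = s_value * S / (1 + s_value * S),
        stringsAsFactors = FALSE)
      informed <- c(informed, i)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(collective = character(0),
                         individual_id = character(0), t = numeric(0),
                         social_sum = numeric(0), p_social = numeric(0),
                         stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab,
       mean = if (nrow(tab)) mean(tab$p_social) else NA_real_)
}
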
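one_ind_data <- function(t, censored, TT = 2400) {
  diffusion_data(list(make_collective(
    "c1", "C", "i1", t, censored,
    networks = list(following = matrix(0, 1, 1, dimnames = list("i1", "i1")),
                    homogeneous = matrix(0, 1, 1,
                                         dimnames = list("i1", "i1"))))),
    trial_duration = TT)
}

test_that("relative rate reduces correctly in its special cases", {
  ids <- c("a", "b", "c")
  A <- matrix(c(0, 0.3, 0.4, 0.2, 0, 0.1, 0.5, 0.2, 0), 3, 3, byrow = TRUE,
              dimnames = list(ids, ids))
  ilv <- data.frame(exploration_rate = c(1, 2, 3))
  sp_asoc <- model_spec("constant", s_structure = "none")
  expect_equal(relative_rate(1, c(2, 3), c(lambda0 = 1), sp_asoc, A), 1)
  sp_add <- model_spec("constant", "additive", "shared")
  expect_equal(relative_rate(1, c(2, 3), c(lambda0 = 1, s = 1), sp_add, A),
               0.7)
  # beta = 0: additive and multiplicative agree for any s
  sp_a <- model_spec("constant", "additive", "shared",
                     ilv = "exploration_rate")
  sp_m <- model_spec("constant", "multiplicative", "shared",
                     ilv = "exploration_rate")
  for (s in c(0, 0.4, 0.9))
    expect_equal(
      relative_rate(2, 1, c(lambda0 = 1, s = s, beta_exploration_rate = 0),
                    sp_a, A, ilv),
      relative_rate(2, 1, c(lambda0 = 1, s = s, beta_exploration_rate = 0),
                    sp_m, A, ilv))
  expect_error(relative_rate(1, 2, c(lambda0 = 1, s = -1), sp_add, A),
               "nonnegative")
})

test_that("single-individual likelihood matches its closed form", {
  sp <- model_spec("constant", s_structure = "none")
  l0 <- 0.002
  d_ev <- one_ind_data(700, FALSE)
  expect_equal(neg_log_likelihood(d_ev, c(lambda0 = l0), sp),
               -log(l0) + l0 * 700, tolerance = 1e-12)
  d_cens <- one_ind_data(2400, TRUE)
  expect_equal(neg_log_likelihood(d_cens, c(lambda0 = l0), sp),
               l0 * 2400, tolerance = 1e-12)
})

test_that("simultaneous acquisitions are handled in stable order", {
  ids <- c("a", "b")
  d <- diffusion_data(list(make_collective(
    "c1", "C", ids, c(500, 500), c(FALSE, FALSE),
    networks = list(following = matrix(0, 2, 2, dimnames = list(ids, ids)),
                    homogeneous = homogeneous_networks(ids)))),
    trial_duration = 2400)
  sp <- model_spec("constant", s_structure = "none")
  l0 <- 0.001
  expect_equal(neg_log_likelihood(d, c(lambda0 = l0), sp),
               -(2 * log(l0) - 2 * l0 * 500), tolerance = 1e-12)
})

test_that("gamma cumulative hazard behaves as a cumulative hazard", {
  t <- seq(0, 500, by = 10)
  expect_equal(gamma_cumulative_hazard(t, 1, 0.01), 0.01 * t)
  H <- gamma_cumulative_hazard(t, 2.5, 0.01)
  expect_equal(H[1], 0)
  expect_true(all(diff(H) >= 0))
  expect_error(gamma_cumulative_hazard(-1, 1, 1), "nonnegative")
  # log-scale computation keeps extreme survival tails finite
  expect_equal(gamma_cumulative_hazard(1e8, 1, 10), 1e9)
})

test_that("likelihood matches the quadrature oracle on a mixed instance", {
  d <- rand_instance(3)
  for (spec in list(
    model_spec("constant", "additive", "shared", "following",
               ilv = "exploration_rate"),
    model_spec("gamma", "multiplicative", "by_type", "homogeneous",
               ilv = "exploration_rate"))) {
    p <- rand_params(3, spec)
    expect_equal(neg_log_likelihood(d, p, spec), quad_nll(d, p, spec),
                 tolerance = 1e-7)
  }
})

test_that("likelihood is invariant to permuting labels under homogeneous networks", {
  set.seed(42)
  ids <- paste0("i", 1:6)
  t <- sort(runif(6, 100, 2300))
  cens <- c(rep(FALSE, 4), TRUE, TRUE)
  t[cens] <- 2400
  mk <- function(perm) {
    make_collective("c", "C", ids, t[perm], cens[perm],
                    networks = list(following = homogeneous_networks(ids),
                                    homogeneous = homogeneous_networks(ids)),
                    ilv = data.frame(exploration_rate = rep(1.3, 6)))
  }
  sp <- model_spec("constant", "additive", "shared", "homogeneous",
                   ilv = "exploration_rate")
  p <- c(lambda0 = 0.001, s = 0.6, beta_exploration_rate = 0.2)
  base <- neg_log_likelihood(diffusion_data(list(mk(1:6))), p, sp)
  for (k in 1:3) {
    perm <- sample(6)
    expect_equal(neg_log_likelihood(diffusion_data(list(mk(perm))), p, sp),
                 base, tolerance = 1e-10)
  }
})

test_that("zero network weights collapse a social model onto the asocial one", {
  ids <- paste0("i", 1:5)
  Z <- matrix(0, 5, 5, dimnames = list(ids, ids))
  t <- c(300, 800, 1500, 2400, 2400)
  cens <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  d <- diffusion_data(list(make_collective(
    "c", "C", ids, t, cens,
    networks = list(following = Z, homogeneous = Z))))
  sp_soc <- model_spec("constant", "additive", "shared", "following")
  sp_asoc <- model_spec("constant", s_structure = "none")
  l0 <- 0.002; s <- 0.4
  # additive complement form with zero weights: rate = lambda0 * (1 - s)
  expect_equal(neg_log_likelihood(d, c(lambda0 = l0, s = s), sp_soc),
               neg_log_likelihood(d, c(lambda0 = l0 * (1 - s)), sp_asoc),
               tolerance = 1e-10)
})

test_that("the naive acquisition rate increases with s given informed partners", {
  ids <- c("a", "b")
  A <- matrix(c(0, 2, 0, 0), 2, 2, byrow = TRUE, dimnames = list(ids, ids))
  sp <- model_spec("constant", "additive", "shared")
  r <- vapply(c(0, 0.5, 1, 2, 5), function(s)
    relative_rate(1, 2, c(lambda0 = 1, s = s), sp, A), numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("asocial constant-baseline fit equals the censored-exponential MLE", {
  set.seed(9)
  cols <- template_collectives(4, 6, seed = 9)
  sp0 <- model_spec("constant", s_structure = "none")
  d <- simulate_diffusion(cols, c(lambda0 = 1 / 1500), sp0, seed = 99)
  f <- fit_nbda(d, sp0)
  n_ev <- sum(sapply(d$collectives, function(cl) sum(!cl$censored)))
  expo <- sum(sapply(d$collectives, function(cl) sum(cl$t)))
  expect_true(f$converged)
  expect_equal(f$estimates[["lambda0"]], n_ev / expo, tolerance = 1e-12)
  expect_equal(f$k, 1)
  expect_equal(f$aicc, aicc(f$logLik, 1, n_ev))
  # independent cross-check: censored exponential fit via survreg
  skip_if_not_installed("survival")
  tt <- unlist(lapply(d$collectives, function(cl) cl$t))
  ss <- unlist(lapply(d$collectives, function(cl) !cl$censored))
  sr <- survival::survreg(survival::Surv(tt, ss) ~ 1, dist = "exponential")
  expect_equal(f$estimates[["lambda0"]], exp(-unname(coef(sr))),
               tolerance = 1e-6)
})

test_that("fitting a social spec on asocial data drives s toward zero", {
  cols <- template_collectives(8, 8, seed = 21)
  sp0 <- model_spec("constant", s_structure = "none")
  d <- simulate_diffusion(cols, c(lambda0 = 1 / 2000), sp0, seed = 22)
  sp_s <- model_spec("constant", "additive", "shared", "following",
                     asocial_weight = "unit")
  f <- fit_nbda(d, sp_s)
  expect_true(f$converged)
  expect_lt(f$estimates[["s"]], 0.75)
  ci <- profile_ci(d, sp_s, f, "s")
  expect_equal(unname(ci["lower"]), 0)
  expect_true(ci["lower"] <= f$estimates[["s"]] &&
                f$estimates[["s"]] <= ci["upper"])
})

test_that("profile interval approaches the Wald interval on near-quadratic profiles", {
  # large asocial dataset: lambda0 profile is close to quadratic
  cols <- template_collectives(30, 8, seed = 5)
  sp0 <- model_spec("constant", s_structure = "none")
  d <- simulate_diffusion(cols, c(lambda0 = 1 / 1200), sp0,
                          trial_duration = 2400, seed = 6)
  f <- fit_nbda(d, sp0)
  ci <- profile_ci(d, sp0, f, "lambda0")
  n_ev <- sum(sapply(d$collectives, function(cl) sum(!cl$censored)))
  l0 <- f$estimates[["lambda0"]]
  wald <- l0 + c(-1, 1) * 1.959964 * l0 / sqrt(n_ev)
  expect_lt(abs(ci[["lower"]] - wald[1]) / (wald[2] - wald[1]), 0.1)
  expect_lt(abs(ci[["upper"]] - wald[2]) / (wald[2] - wald[1]), 0.1)
})

test_that("specs demanding a collective type absent from the data are rejected", {
  cols <- template_collectives(2, 4, seed = 1)
  cols <- cols[1]  # C only
  d <- simulate_diffusion(cols, c(lambda0 = 1 / 1000),
                          model_spec("constant", s_structure = "none"),
                          seed = 2)
  expect_error(fit_nbda(d, model_spec("constant", "additive", "S_only")),
               "requires S collectives")
})

test_that("the default grid enumerates the full model space once", {
  grid <- default_model_grid()
  expect_length(grid, 52)
  expect_equal(anyDuplicated(vapply(grid, spec_label, character(1))), 0)
  # combinatorial recount: social specs with/without ILV plus asocial specs
  expect_equal(4 * 2 * 2 * 2 + 4 * 2 * 2 + 2 + 2, 52)
})
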
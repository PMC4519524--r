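test_that("negative log-likelihood has its closed-form values", {
  # beta = 0, rho = 0: both stages uniform, nll = n_obs * ln 2 exactly
  ds <- trials_to_dataset(random_trials(50, seed = 1))
  r <- nll_subject(ds, model_spec("hybrid"), agent_params(0.5, 0, 0, 0.5))
  expect_identical(r$n_obs, 100L)
  expect_equal(r$nll, 100 * log(2))
  # a single trial from zero-initialised values is uniform at both stages
  one <- trials_to_dataset(random_trials(1, seed = 2))
  r1 <- nll_subject(one, model_spec("hybrid"), agent_params(0.3, 1, 0, 0.5))
  expect_equal(r1$nll, 2 * log(2))
  # omitted trials contribute nothing
  ds$trials$omitted[1:10] <- TRUE
  r2 <- nll_subject(ds, model_spec("hybrid"), agent_params(0.5, 0, 0, 0.5))
  expect_identical(r2$n_obs, 80L)
})

test_that("likelihood equals the brute-force enumeration oracle", {
  model <- model_spec("hybrid")
  # 2-trial datasets across parameter corners
  for (seed in 1:6) {
    tr <- random_trials(2, seed = seed,
                        valence = if (seed %% 2) "reward" else "punishment")
    ds <- trials_to_dataset(tr)
    for (par in list(c(0.5, 3, 0.7, 0.4), c(0.2, 8, -0.5, 0.9),
                     c(0.9, 1, 0, 0), c(0.4, 5, 1.2, 1))) {
      got <- nll_subject(ds, model, agent_params(par[1], par[2], par[3], par[4]))
      want <- oracle_nll(tr, par[1], par[2], par[3], par[4])
      expect_equal(got$nll, want$nll, tolerance = 1e-10)
      expect_identical(got$n_obs, want$n_obs)
    }
  }
  # and on a long sequence, including omissions
  tr <- random_trials(120, seed = 11)
  tr$omitted[c(5, 6, 60)] <- TRUE
  got <- nll_subject(trials_to_dataset(tr), model, agent_params(0.6, 4, 0.8, 0.35))
  want <- oracle_nll(tr, 0.6, 4, 0.8, 0.35)
  expect_equal(got$nll, want$nll, tolerance = 1e-10)
})

test_that("Q-SARSA is the hybrid model with omega and rho frozen at zero", {
  qs <- model_spec("qsarsa"); hy <- model_spec("hybrid")
  expect_identical(qs$free_params, c("alpha", "beta"))
  expect_identical(hy$free_params, c("alpha", "beta", "rho", "omega"))
  ds <- trials_to_dataset(random_trials(60, seed = 3))
  p <- agent_params(0.45, 6, rho = 0, omega = 0)
  expect_equal(nll_subject(ds, qs, p)$nll, nll_subject(ds, hy, p)$nll)
})

test_that("fitting is deterministic, bounded, and a fixed point of itself", {
  cfg <- task_config("reward", n_trials = 120L, n_sessions = 1L)
  ds <- simulate_subject(agent_params(0.5, 5, 0.5, 0.6), cfg, seed = 31)
  model <- model_spec("hybrid")
  f1 <- fit_subject(ds, model, n_restarts = 8, seed = 2)
  f2 <- fit_subject(ds, model, n_restarts = 8, seed = 2)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$nll, f2$nll)
  est <- f1$estimates
  expect_true(est$alpha >= 0 && est$alpha <= 1)
  expect_true(est$beta >= 0 && est$beta <= 20)
  expect_true(est$omega >= 0 && est$omega <= 1)
  # the reported nll is the likelihood at the reported estimates
  expect_equal(nll_subject(ds, model, est)$nll, f1$nll, tolerance = 1e-8)
  # restarting the optimiser at the solution cannot improve beyond tolerance
  f3 <- fit_subject(ds, model, n_restarts = 8, seed = 977)
  expect_lt(abs(f3$nll - f1$nll), 1e-4)
})

test_that("nested-model dominance: hybrid fits at least as well as Q-SARSA", {
  cfg <- task_config("reward", n_trials = 100L, n_sessions = 1L)
  for (seed in c(13, 17)) {
    ds <- simulate_subject(agent_params(0.4, 4, 0.4, 0.5), cfg, seed = seed)
    f_h <- fit_subject(ds, model_spec("hybrid"), n_restarts = 10, seed = 1)
    f_q <- fit_subject(ds, model_spec("qsarsa"), n_restarts = 10, seed = 1)
    expect_lte(f_h$nll, f_q$nll + 1e-6)
  }
})

test_that("a strongly model-based subject is recovered as such", {
  par <- agent_params(0.5, 8, 0.2, 0.9)
  cfg <- task_config("reward")
  dss <- list(simulate_subject(par, cfg, seed = 41),
              simulate_subject(par, cfg, seed = 42))
  f <- fit_subject(dss, model_spec("hybrid"), n_restarts = 20, seed = 6)
  expect_identical(f$n_obs, 804L)
  expect_gt(f$estimates$omega, 0.5)
})

test_that("BIC log evidence follows the stated formula", {
  expect_equal(bic_log_evidence(100, 4, 402), -100 - 2 * log(402))
  expect_equal(bic_log_evidence(57.3, 0, 100), -57.3)
  # with equal fit, fewer parameters means higher evidence
  expect_gt(bic_log_evidence(100, 2, 402), bic_log_evidence(100, 4, 402))
  expect_error(bic_log_evidence(10, 2, 0), "positive")
})

test_that("random-effects BMS behaves at its symmetric and dominant limits", {
  le_eq <- matrix(-100, 15, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  b <- bms_random_effects(le_eq, seed = 1, n_mc_samples = 2e5)
  expect_equal(unname(b$expected_frequency), rep(1 / 3, 3))
  expect_equal(unname(b$exceedance_probability), rep(1 / 3, 3), tolerance = 0.02)
  expect_equal(sum(b$dirichlet_alpha), 3 * 1 + 15)
  # one model better by 10 ln-units for all 20 subjects dominates
  le_dom <- cbind(hybrid = rep(-90, 20), qsarsa = rep(-100, 20))
  bd <- bms_random_effects(le_dom, seed = 2, n_mc_samples = 2e5)
  expect_gt(bd$exceedance_probability[["hybrid"]], 0.99)
  expect_equal(sum(bd$exceedance_probability), 1, tolerance = 1e-9)
  expect_equal(sum(bd$dirichlet_alpha), 2 + 20)
  expect_error(bms_random_effects(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(bms_random_effects(matrix(1, 3, 1)), "2 models")
})

test_that("Shapiro-Wilk screen is calibrated and has power", {
  expect_error(normality_screen(c(1, 2)), "3 <= n")
  cst <- normality_screen(rep(0.4, 10))
  expect_false(cst$normal)
  expect_true(is.na(cst$p))
  set.seed(8)
  p_norm <- replicate(20, normality_screen(rnorm(5000))$p)
  expect_gte(mean(p_norm > 0.05), 0.7) # calibration under the null
  p_sq <- replicate(10, normality_screen(rnorm(5000)^2)$p)
  expect_true(all(p_sq < 0.05)) # power against a squared normal
})

test_that("group comparison matches the one-way closed form and handles ties", {
  fake_fit <- function(id, a) {
    structure(list(subject_id = id, model = "hybrid",
                   estimates = agent_params(a, 1, 0, 0.5)), class = "fit_result")
  }
  g1 <- lapply(1:3, function(i) fake_fit(paste0("a", i), c(0.2, 0.3, 0.4)[i]))
  g2 <- lapply(1:3, function(i) fake_fit(paste0("b", i), c(0.5, 0.7, 0.6)[i]))
  res <- compare_params_between_groups(list(G1 = g1, G2 = g2),
                                       params = "alpha", transform = "none")
  x1 <- c(0.2, 0.3, 0.4); x2 <- c(0.5, 0.7, 0.6)
  msb <- 3 * sum((c(mean(x1), mean(x2)) - mean(c(x1, x2)))^2) / 1
  msw <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / 4
  expect_equal(res$univariate$F, msb / msw, tolerance = 1e-10)
  expect_equal(res$univariate$df1, 1)
  expect_equal(res$univariate$df2, 4)
  # identical distributions across groups: zero between-group variance, F = 0
  res0 <- compare_params_between_groups(list(G1 = g1, G2 = g1),
                                        params = "alpha", transform = "none")
  expect_equal(res0$univariate$F, 0, tolerance = 1e-12)
})

test_that("MANOVA compares full parameter vectors and flags transforms", {
  set.seed(21)
  mk <- function(id, shift) {
    structure(list(subject_id = id, model = "hybrid",
                   estimates = agent_params(runif(1, 0.3, 0.7),
                                            runif(1, 2, 8),
                                            rnorm(1, 0.5, 0.3),
                                            min(max(rnorm(1, 0.4 + shift, 0.1), 0), 1))),
              class = "fit_result")
  }
  g1 <- lapply(1:12, function(i) mk(paste0("a", i), 0))
  g2 <- lapply(1:12, function(i) mk(paste0("b", i), 0.35))
  res <- compare_params_between_groups(list(G1 = g1, G2 = g2), transform = "all")
  expect_true(all(res$transform_flags))
  expect_false(res$manova_dropped)
  expect_true(res$manova$wilks > 0 && res$manova$wilks < 1)
  expect_equal(res$manova$df1, 4)
  # the engineered omega difference shows up in the univariate tests
  expect_lt(res$univariate$p[res$univariate$param == "omega"], 0.05)
  # signed square root was used for rho (negative values survive)
  expect_true(is.finite(res$univariate$F[res$univariate$param == "rho"]))
})
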
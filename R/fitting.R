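# Per-subject maximum-likelihood fitting of the Q-SARSA and hybrid models,
# BIC log-evidence, group-level random-effects Bayesian model selection, and
# between-group comparison of fitted parameters.

#' Specification of a candidate model
#'
#' `"qsarsa"` is the pure model-free baseline with two free parameters
#' (`alpha`, `beta`); `"hybrid"` adds the perseveration index and the
#' model-based weight (`alpha`, `beta`, `rho`, `omega`). Q-SARSA is exactly
#' the hybrid model with `rho = 0` and `omega = 0` frozen. The eligibility
#' constant `lam` is fixed (default 1) in both.
#'
#' @param name `"qsarsa"` or `"hybrid"`.
#' @param lam fixed eligibility constant.
#' @param beta_max upper bound of the softmax temperature search space
#'   (prevents likelihood plateaus); default 20.
#' @return an object of class `model_spec` with `free_params`, `fixed_params`
#'   and per-parameter `bounds`.
#' @export
model_spec <- function(name = c("hybrid", "qsarsa"), lam = 1, beta_max = 20) {
  name <- match.arg(name)
  free <- switch(name, qsarsa = c("alpha", "beta"),
                 hybrid = c("alpha", "beta", "rho", "omega"))
  fixed <- switch(name,
                  qsarsa = list(rho = 0, omega = 0, lam = lam),
                  hybrid = list(lam = lam))
  bounds <- list(alpha = c(0, 1), beta = c(0, beta_max),
                 rho = c(-10, 10), omega = c(0, 1))
  structure(list(name = name, free_params = free, fixed_params = fixed,
                 bounds = bounds), class = "model_spec")
}

# Integer-code the canonical trial columns of one dataset for the C++ core.
encode_trials <- function(dataset) {
  tr <- dataset$trials
  list(choice1 = as.integer(tr$choice1 == "B"),
       state2 = as.integer(tr$state2 == "S2"),
       choice2 = as.integer(tr$choice2 == "b"),
       outcome = as.numeric(tr$outcome),
       omitted = as.logical(tr$omitted))
}

#' Negative log-likelihood of a choice sequence
#'
#' Accumulates `-ln P(choice)` over both stage choices of every non-omitted
#' trial, advancing the agent state exactly as the simulator does. Omitted
#' trials contribute no terms, trigger no update, and reset the perseveration
#' reference. When `dataset` is a list of datasets (e.g. a subject's reward
#' and punishment sessions), state is reset per dataset and the terms are
#' summed, giving the joint likelihood under shared parameters.
#'
#' @param dataset a `subject_dataset` or list of them.
#' @param model a [model_spec()].
#' @param params an [agent_params()] (frozen entries from `model` are
#'   ignored/overridden by the model's fixed values only for `lam`;
#'   pass the full parameter set).
#' @param p_common common-transition probability of the task.
#' @return list with `nll` (finite, nonnegative for non-degenerate data) and
#'   `n_obs` (2 x non-omitted trials).
#' @export
nll_subject <- function(dataset, model, params, p_common = 0.7) {
  if (inherits(dataset, "subject_dataset")) dataset <- list(dataset)
  total <- 0; n_obs <- 0L
  for (ds in dataset) {
    enc <- encode_trials(ds)
    res <- nll_choices_cpp(enc$choice1, enc$state2, enc$choice2, enc$outcome,
                           enc$omitted, params$alpha, params$beta, params$rho,
                           params$omega, model$fixed_params$lam %||% params$lam,
                           p_common)
    total <- total + res$nll
    n_obs <- n_obs + res$n_obs
  }
  list(nll = total, n_obs = n_obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Maps between the free-parameter vector (natural scale) and the
# unconstrained search space: logistic for alpha/omega, log for beta
# (box-bounded above at log(beta_max)), identity for rho.
to_natural <- function(x, free, beta_max) {
  out <- numeric(length(free)); names(out) <- free
  for (i in seq_along(free)) {
    out[i] <- switch(free[i],
                     alpha = stats::plogis(x[i]),
                     omega = stats::plogis(x[i]),
                     beta = exp(x[i]),
                     rho = x[i])
  }
  out
}

transformed_box <- function(free, beta_max) {
  lower <- vapply(free, function(p) switch(p, alpha = -12, omega = -12,
                                           beta = -7, rho = -10), 0)
  upper <- vapply(free, function(p) switch(p, alpha = 12, omega = 12,
                                           beta = log(beta_max), rho = 10), 0)
  list(lower = lower, upper = upper)
}

start_box <- function(free, beta_max) {
  lower <- vapply(free, function(p) switch(p, alpha = -3, omega = -3,
                                           beta = -2, rho = -2), 0)
  upper <- vapply(free, function(p) switch(p, alpha = 3, omega = 3,
                                           beta = log(beta_max) - 0.3, rho = 2), 0)
  list(lower = lower, upper = upper)
}

# Assemble a full agent_params from free values + model's frozen values.
full_params <- function(est, model) {
  fx <- model$fixed_params
  agent_params(alpha = est[["alpha"]], beta = est[["beta"]],
               rho = if ("rho" %in% names(est)) est[["rho"]] else fx$rho,
               omega = if ("omega" %in% names(est)) est[["omega"]] else fx$omega,
               lam = fx$lam)
}

#' Fit one subject by maximum likelihood
#'
#' Minimises the negative log-likelihood over the transformed unconstrained
#' parameters from `n_restarts` seeded random starts (L-BFGS-B, with a
#' Nelder-Mead retry for any start where the quasi-Newton run fails), and
#' returns the best solution with its BIC log-evidence. Deterministic given
#' `seed`.
#'
#' @param dataset a `subject_dataset` or list of them (joint fit).
#' @param model a [model_spec()].
#' @param n_restarts random restarts; default 20.
#' @param seed integer seed for the start draws.
#' @param p_common common-transition probability.
#' @return a `fit_result`: list with `subject_id`, `model`, `estimates`
#'   ([agent_params()]), `nll`, `n_obs`, `log_evidence`, `n_restarts`,
#'   `converged`, `seed`.
#' @export
fit_subject <- function(dataset, model = model_spec("hybrid"),
                        n_restarts = 20L, seed = 1L, p_common = 0.7) {
  single <- if (inherits(dataset, "subject_dataset")) dataset else dataset[[1]]
  free <- model$free_params
  k <- length(free)
  box <- transformed_box(free, model$bounds$beta[2])
  sbox <- start_box(free, model$bounds$beta[2])
  obj <- function(x) {
    est <- to_natural(x, free, model$bounds$beta[2])
    nll_subject(dataset, model, full_params(est, model), p_common)$nll
  }
  starts <- with_local_seed(seed, {
    lapply(seq_len(n_restarts), function(i)
      stats::runif(k, sbox$lower, sbox$upper))
  })
  best <- NULL
  n_ok <- 0L
  for (x0 in starts) {
    fit <- tryCatch(
      stats::optim(x0, obj, method = "L-BFGS-B",
                   lower = box$lower, upper = box$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        stats::optim(x0, function(x) obj(pmin(pmax(x, box$lower), box$upper)),
                     method = "Nelder-Mead", control = list(maxit = 2000)),
        error = function(e) NULL)
      if (!is.null(fit)) fit$par <- pmin(pmax(fit$par, box$lower), box$upper)
    }
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimisation restarts failed for subject ",
                          single$subject_id)
  est <- to_natural(best$par, free, model$bounds$beta[2])
  res <- nll_subject(dataset, model, full_params(est, model), p_common)
  structure(list(subject_id = single$subject_id,
                 model = model$name,
                 estimates = full_params(est, model),
                 nll = res$nll, n_obs = res$n_obs,
                 log_evidence = bic_log_evidence(res$nll, k, res$n_obs),
                 n_restarts = n_ok, converged = best$convergence == 0,
                 seed = seed),
            class = "fit_result")
}

#' BIC approximation to the log model evidence
#'
#' `log_evidence = -nll - (k / 2) * ln(n_obs)`, the Laplace/BIC surrogate
#' commonly used for per-subject model evidence in this literature.
#'
#' @param nll minimised negative log-likelihood.
#' @param n_free number of free parameters `k`.
#' @param n_obs number of modelled decisions.
#' @return the approximate log evidence.
#' @export
bic_log_evidence <- function(nll, n_free, n_obs) {
  if (n_obs <= 0) stop("n_obs must be positive")
  -nll - (n_free / 2) * log(n_obs)
}

#' Group-level random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects: a Dirichlet
#' prior over model frequencies is updated by a variational scheme in which
#' subject-wise model responsibilities are proportional to
#' `exp(log_evidence + digamma(alpha_m) - digamma(sum(alpha)))` and the
#' Dirichlet counts are `prior_alpha + summed responsibilities`, iterated to
#' convergence. Exceedance probabilities (the posterior probability that each
#' model is the most frequent in the population) are estimated by Monte-Carlo
#' sampling from the converged Dirichlet.
#'
#' @param log_evidence_matrix numeric matrix, subjects x models, with model
#'   names as column names.
#' @param prior_alpha Dirichlet prior count per model; default 1 (uniform).
#' @param n_mc_samples Monte-Carlo draws for the exceedance probabilities.
#' @param seed integer seed for the Monte-Carlo step.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   Dirichlet counts.
#' @return a `bms_result`: list with `dirichlet_alpha`, `expected_frequency`,
#'   `exceedance_probability` (all named per model) and `n_subjects`.
#' @export
bms_random_effects <- function(log_evidence_matrix, prior_alpha = 1,
                               n_mc_samples = 1e6, seed = 1L,
                               max_iter = 500L, tol = 1e-8) {
  le <- as.matrix(log_evidence_matrix)
  if (any(!is.finite(le))) stop("log-evidence entries must be finite")
  n <- nrow(le); K <- ncol(le)
  if (n < 1 || K < 2) stop("need >= 1 subject and >= 2 models")
  models <- colnames(le) %||% paste0("m", seq_len(K))
  alpha <- rep(prior_alpha, K)
  for (it in seq_len(max_iter)) {
    u <- sweep(le, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- u - apply(u, 1, max)
    g <- exp(u); g <- g / rowSums(g)
    alpha_new <- prior_alpha + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
    if (it == max_iter) stop("BMS did not converge within ", max_iter,
                             " iterations; last alpha = ",
                             paste(signif(alpha, 6), collapse = ", "))
  }
  xp <- with_local_seed(seed, {
    draws <- matrix(stats::rgamma(n_mc_samples * K, shape = rep(alpha, each = n_mc_samples)),
                    nrow = n_mc_samples, ncol = K)
    tabulate(max.col(draws), nbins = K) / n_mc_samples
  })
  names(alpha) <- names(xp) <- models
  structure(list(dirichlet_alpha = alpha,
                 expected_frequency = alpha / sum(alpha),
                 exceedance_probability = xp,
                 n_subjects = n),
            class = "bms_result")
}

#' Shapiro-Wilk normality screen
#'
#' Used to gate the square-root transform before group comparison. A constant
#' sample has no defined W and is reported as non-normal (`p = NA`,
#' `normal = FALSE`).
#'
#' @param values numeric sample, `3 <= n <= 5000`.
#' @param alpha_level significance level of the screen.
#' @return list with `statistic`, `p`, `normal`.
#' @export
normality_screen <- function(values, alpha_level = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("normality_screen requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, normal = FALSE))
  }
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value,
       normal = sw$p.value >= alpha_level)
}

# Square-root transform; signed version for the unbounded rho.
sqrt_transform <- function(x, signed = FALSE) {
  if (signed) sign(x) * sqrt(abs(x)) else sqrt(x)
}

#' Compare fitted parameters between two groups
#'
#' Applies the square-root transform to parameters flagged non-normal by the
#' Shapiro-Wilk screen in either group (`sign(x) * sqrt(|x|)` for the
#' unbounded `rho`, plain square root otherwise), then computes a one-way
#' MANOVA (Wilks' lambda with its F approximation) on the parameter vectors
#' plus a univariate one-way F per parameter. If the within-group covariance
#' is singular the MANOVA is dropped and flagged, and the univariate tests
#' are still returned.
#'
#' @param fits_by_group named list of two lists of `fit_result`s (names are
#'   the group labels).
#' @param params parameters to compare; defaults to the four free parameters
#'   of the hybrid model.
#' @param transform `"auto"` (screen-gated), `"none"`, or `"all"`.
#' @param alpha_level screen significance level.
#' @return list with `univariate` (data frame: param, F, df1, df2, p,
#'   transformed), `manova` (list with statistic `wilks`, `F`, `df1`, `df2`,
#'   `p`, or `NULL` if singular), `transform_flags`.
#' @export
compare_params_between_groups <- function(fits_by_group,
                                          params = c("alpha", "beta", "rho", "omega"),
                                          transform = c("auto", "none", "all"),
                                          alpha_level = 0.05) {
  transform <- match.arg(transform)
  stopifnot(length(fits_by_group) == 2)
  groups <- names(fits_by_group)
  mats <- lapply(fits_by_group, function(fits) {
    do.call(rbind, lapply(fits, function(f)
      vapply(params, function(p) f$estimates[[p]], 0)))
  })
  if (any(vapply(mats, nrow, 0L) < 2)) stop("need >= 2 subjects per group")
  flags <- vapply(params, function(p) {
    if (transform == "none") return(FALSE)
    if (transform == "all") return(TRUE)
    any(vapply(mats, function(m) {
      scr <- normality_screen(m[, p])
      !isTRUE(scr$normal)
    }, TRUE))
  }, TRUE)
  for (p in params[flags]) {
    for (g in groups) mats[[g]][, p] <- sqrt_transform(mats[[g]][, p],
                                                       signed = (p == "rho"))
  }
  y <- rbind(mats[[1]], mats[[2]])
  grp <- factor(rep(groups, times = vapply(mats, nrow, 0L)))
  uni <- do.call(rbind, lapply(params, function(p) {
    fit <- stats::aov(y[, p] ~ grp)
    tab <- summary(fit)[[1]]
    data.frame(param = p, F = tab$`F value`[1], df1 = tab$Df[1],
               df2 = tab$Df[2], p = tab$`Pr(>F)`[1],
               transformed = flags[[p]], stringsAsFactors = FALSE)
  }))
  man <- tryCatch({
    mfit <- stats::manova(y ~ grp)
    tab <- summary(mfit, test = "Wilks")$stats
    list(wilks = tab[1, "Wilks"], F = tab[1, "approx F"],
         df1 = tab[1, "num Df"], df2 = tab[1, "den Df"],
         p = tab[1, "Pr(>F)"])
  }, error = function(e) NULL)
  list(univariate = uni, manova = man, transform_flags = flags,
       manova_dropped = is.null(man))
}
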
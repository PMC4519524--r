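# End-to-end study pipeline: simulate (or load) the two-group, two-valence
# study, run the factorial stay/shift ANOVAs and signature classification,
# fit both candidate models per subject, select models by group-level
# random-effects BMS, compare fitted parameters between groups, and report
# recovery metrics where the generating truth is known.

#' Configuration of a full study run
#'
#' A single global seed deterministically derives every stage seed, so a
#' rerun with the same config reproduces all numbers.
#'
#' @param configs named list of [task_config()]s (`reward`, `punishment`).
#' @param specs named list of [group_spec()]s (`TD`, `BAL`); defaults to
#'   [default_group_specs()].
#' @param n_restarts optimisation restarts per subject-model fit.
#' @param alpha_level significance level for ANOVAs and the signature
#'   classification.
#' @param transform transform policy for the group comparison
#'   (`"auto"`, `"none"`, `"all"`).
#' @param run_fitting run the model-fitting/BMS/parameter-comparison stages
#'   (the factorial stage does not depend on them).
#' @param out_dir optional directory; when given, intermediate CSVs and the
#'   JSON report are written there.
#' @param seed global integer seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(configs = NULL, specs = default_group_specs(),
                         n_restarts = 20L, alpha_level = 0.05,
                         transform = "auto", run_fitting = TRUE,
                         out_dir = NULL, seed = 1L) {
  if (is.null(configs)) {
    configs <- list(reward = task_config("reward"),
                    punishment = task_config("punishment"))
  }
  structure(list(configs = configs, specs = specs, n_restarts = n_restarts,
                 alpha_level = alpha_level, transform = transform,
                 run_fitting = run_fitting, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "study_config")
}

# Factorial stage shared by run_study and the replicate experiments.
factorial_stage <- function(datasets, alpha_level = 0.05) {
  stay <- lapply(datasets, compute_stay_table)
  long <- stay_long_table(stay)
  res <- list(excluded = attr(long, "excluded"))
  # subjects with complete data in both valences enter the 4-way ANOVA
  have <- table(long$subject_id) == 8L
  full <- long[have[long$subject_id], , drop = FALSE]
  res$fourway <- tryCatch(
    mixed_anova(full, "stay_p_arcsine", "subject_id",
                within = c("valence", "outcome_cat", "transition"),
                between = "group"),
    error = function(e) NULL)
  res$per_valence <- list(); res$per_group_valence <- list()
  res$classification <- list()
  for (v in c("reward", "punishment")) {
    dv <- long[long$valence == v, , drop = FALSE]
    res$per_valence[[v]] <- tryCatch(
      mixed_anova(dv, "stay_p_arcsine", "subject_id",
                  within = c("outcome_cat", "transition"), between = "group"),
      error = function(e) NULL)
    for (g in unique(dv$group)) {
      dgv <- dv[dv$group == g, , drop = FALSE]
      an <- mixed_anova(dgv, "stay_p_arcsine", "subject_id",
                        within = c("outcome_cat", "transition"))
      key <- paste(g, v, sep = "_")
      res$per_group_valence[[key]] <- an
      res$classification[[key]] <- classify_signature(an, alpha_level)
    }
  }
  res$long <- long
  res
}

# Fit every subject (joint over valences) under both models.
fitting_stage <- function(datasets, subjects, n_restarts, seed, p_common) {
  models <- list(qsarsa = model_spec("qsarsa"), hybrid = model_spec("hybrid"))
  fits <- list()
  for (v in c("reward", "punishment")) {
    rows <- list()
    for (i in seq_len(nrow(subjects))) {
      sid <- subjects$subject_id[i]
      ds <- datasets[[paste(sid, v, sep = "_")]]
      if (is.null(ds)) next
      for (m in names(models)) {
        f <- fit_subject(ds, models[[m]], n_restarts = n_restarts,
                         seed = derive_seed(seed, i * 7L + (m == "hybrid") +
                                              100L * (v == "punishment")),
                         p_common = p_common)
        rows[[length(rows) + 1L]] <- f
      }
    }
    fits[[v]] <- rows
  }
  fits
}

fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(subject_id = f$subject_id, model = f$model,
               alpha = f$estimates$alpha, beta = f$estimates$beta,
               rho = f$estimates$rho, omega = f$estimates$omega,
               nll = f$nll, n_obs = f$n_obs, log_evidence = f$log_evidence,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
}

# Subjects x models log-evidence matrix from a flat list of fit_results.
log_evidence_matrix <- function(fits) {
  tab <- fit_table(fits)
  subjects <- unique(tab$subject_id); models <- unique(tab$model)
  le <- matrix(NA_real_, length(subjects), length(models),
               dimnames = list(subjects, models))
  for (i in seq_len(nrow(tab))) le[tab$subject_id[i], tab$model[i]] <- tab$log_evidence[i]
  le
}

#' Run the full synthetic study
#'
#' Simulates (or accepts) the two-group, two-valence study, then runs:
#' the factorial stay/shift analysis (per-valence three-way mixed ANOVAs,
#' the four-way valence ANOVA, per-group post hocs with signature
#' classification); per-subject ML fitting of Q-SARSA and the hybrid model;
#' group-level random-effects BMS per group and valence; the between-group
#' parameter comparison (MANOVA + univariate F) on the winning model per
#' valence; and recovery metrics against the generating truth when known.
#'
#' @param config a [study_config()].
#' @param datasets optional externally supplied list of `subject_dataset`s
#'   (e.g. from [read_subjects_csv()]); when `NULL` the study is simulated
#'   from `config$specs`.
#' @return a `study_report` list; see the elements `factorial`, `fits`,
#'   `bms`, `param_comparison`, `cumulative`, `recovery`, `classification`.
#' @export
run_study <- function(config = study_config(), datasets = NULL) {
  seed <- config$seed
  if (is.null(datasets)) {
    datasets <- simulate_group_study(config$specs$TD, config$specs$BAL,
                                     config$configs, seed = derive_seed(seed, 1L))
  }
  subjects <- attr(datasets, "subjects")
  if (is.null(subjects)) {
    ids <- unique(vapply(datasets, function(d) paste(d$subject_id, d$group), ""))
    parts <- strsplit(ids, " ")
    subjects <- data.frame(subject_id = vapply(parts, `[`, "", 1),
                           group = vapply(parts, `[`, "", 2),
                           stringsAsFactors = FALSE)
  }
  report <- list(seed = seed, n_subjects = nrow(subjects))

  report$factorial <- factorial_stage(datasets, config$alpha_level)
  report$classification <- report$factorial$classification

  cum <- do.call(rbind, lapply(datasets, function(d)
    data.frame(subject_id = d$subject_id, group = d$group, valence = d$valence,
               cumulative = cumulative_outcome(d), stringsAsFactors = FALSE)))
  rownames(cum) <- NULL
  report$cumulative <- cum

  if (config$run_fitting) {
    p_common <- config$configs$reward$p_common
    fits <- fitting_stage(datasets, subjects, config$n_restarts,
                          derive_seed(seed, 2L), p_common)
    report$fits <- lapply(fits, fit_table)
    report$bms <- list()
    for (v in names(fits)) {
      for (g in unique(subjects$group)) {
        gs <- subjects$subject_id[subjects$group == g]
        sub <- Filter(function(f) f$subject_id %in% gs, fits[[v]])
        le <- log_evidence_matrix(sub)
        report$bms[[paste(g, v, sep = "_")]] <-
          bms_random_effects(le, seed = derive_seed(seed, 3L))
      }
      hyb <- Filter(function(f) f$model == "hybrid", fits[[v]])
      by_group <- split(hyb, vapply(hyb, function(f)
        subjects$group[match(f$subject_id, subjects$subject_id)], ""))
      report$param_comparison[[v]] <-
        compare_params_between_groups(by_group, transform = config$transform,
                                      alpha_level = config$alpha_level)
    }
    report$recovery <- recovery_metrics(datasets, fits)
  }

  if (!is.null(config$out_dir)) write_study_outputs(report, datasets, config)
  class(report) <- "study_report"
  report
}

# Correlation/bias/RMSE of hybrid-model estimates against generating truth.
recovery_metrics <- function(datasets, fits) {
  rows <- list()
  for (v in names(fits)) {
    hyb <- Filter(function(f) f$model == "hybrid", fits[[v]])
    truth <- lapply(hyb, function(f) {
      ds <- datasets[[paste(f$subject_id, v, sep = "_")]]
      ds$true_params
    })
    if (any(vapply(truth, is.null, TRUE))) next
    for (p in c("alpha", "beta", "rho", "omega")) {
      tv <- vapply(truth, function(x) x[[p]], 0)
      ev <- vapply(hyb, function(f) f$estimates[[p]], 0)
      rows[[length(rows) + 1L]] <- data.frame(
        valence = v, param = p,
        correlation = if (stats::sd(tv) > 0 && stats::sd(ev) > 0)
          stats::cor(tv, ev) else NA_real_,
        bias = mean(ev - tv), rmse = sqrt(mean((ev - tv)^2)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

write_study_outputs <- function(report, datasets, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_subjects_csv(datasets, file.path(config$out_dir, "trials.csv"))
  utils::write.csv(report$factorial$long,
                   file.path(config$out_dir, "stay_long.csv"), row.names = FALSE)
  utils::write.csv(report$cumulative,
                   file.path(config$out_dir, "cumulative.csv"), row.names = FALSE)
  if (!is.null(report$fits)) {
    for (v in names(report$fits))
      utils::write.csv(report$fits[[v]],
                       file.path(config$out_dir, paste0("fits_", v, ".csv")),
                       row.names = FALSE)
  }
  keep <- report[setdiff(names(report), "factorial")]
  keep$factorial <- report$factorial[c("classification", "excluded")]
  jsonlite::write_json(serialize_report(keep),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

serialize_report <- function(x) {
  if (inherits(x, "bms_result")) return(unclass(x))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, serialize_report))
  x
}

#' Parameter-recovery experiment
#'
#' Draws true hybrid parameters for `n_subjects` from broad realistic ranges
#' (`alpha` U(0.1, 0.9), `beta` U(2, 10), `rho` U(-0.5, 1.5), `omega`
#' U(0, 1)), simulates each subject on both task valences, refits the hybrid
#' model jointly to the two sessions, and tabulates per-parameter recovery.
#'
#' @param config a [study_config()] (supplies task configs and restarts).
#' @param n_subjects number of simulated subjects.
#' @param seed integer seed.
#' @return data frame with columns `param`, `correlation`, `bias`, `rmse`
#'   (empty, same columns, when `n_subjects = 0`), with the per-subject
#'   true/estimated values in attribute `subjects`.
#' @export
run_parameter_recovery <- function(config = study_config(), n_subjects = 100L,
                                   seed = 1L) {
  empty <- data.frame(param = character(), correlation = numeric(),
                      bias = numeric(), rmse = numeric(),
                      stringsAsFactors = FALSE)
  if (n_subjects < 1) return(empty)
  model <- model_spec("hybrid")
  p_common <- config$configs$reward$p_common
  truth <- est <- matrix(NA_real_, n_subjects, 4,
                         dimnames = list(NULL, c("alpha", "beta", "rho", "omega")))
  for (i in seq_len(n_subjects)) {
    par <- with_local_seed(derive_seed(seed, i * 3L), {
      agent_params(alpha = stats::runif(1, 0.1, 0.9),
                   beta = stats::runif(1, 2, 10),
                   rho = stats::runif(1, -0.5, 1.5),
                   omega = stats::runif(1, 0, 1))
    })
    dss <- lapply(c("reward", "punishment"), function(v)
      simulate_subject(par, config$configs[[v]],
                       seed = derive_seed(seed, i * 3L + (v == "punishment") + 1L),
                       subject_id = sprintf("r%03d", i)))
    fit <- fit_subject(dss, model, n_restarts = config$n_restarts,
                       seed = derive_seed(seed, i * 3L + 2L), p_common = p_common)
    truth[i, ] <- unlist(unclass(par)[colnames(truth)])
    est[i, ] <- unlist(unclass(fit$estimates)[colnames(est)])
  }
  out <- do.call(rbind, lapply(colnames(truth), function(p) {
    data.frame(param = p, correlation = stats::cor(truth[, p], est[, p]),
               bias = mean(est[, p] - truth[, p]),
               rmse = sqrt(mean((est[, p] - truth[, p])^2)),
               stringsAsFactors = FALSE)
  }))
  attr(out, "subjects") <- list(truth = truth, estimates = est)
  out
}

#' Model-recovery experiment
#'
#' Generates cohorts under each candidate model (Q-SARSA: `omega = rho = 0`),
#' fits both models to every subject, runs random-effects BMS per cohort, and
#' tabulates which model wins (highest exceedance probability).
#'
#' @param config a [study_config()].
#' @param n_subjects subjects per cohort.
#' @param n_cohorts cohorts per generating model.
#' @param seed integer seed.
#' @return list with `confusion` (matrix, generating model x winning model)
#'   and `bms` (the per-cohort `bms_result`s).
#' @export
run_model_recovery <- function(config = study_config(), n_subjects = 20L,
                               n_cohorts = 1L, seed = 1L) {
  models <- list(qsarsa = model_spec("qsarsa"), hybrid = model_spec("hybrid"))
  p_common <- config$configs$reward$p_common
  confusion <- matrix(0L, 2, 2, dimnames = list(generator = names(models),
                                                winner = names(models)))
  all_bms <- list()
  for (gen in names(models)) {
    for (c_i in seq_len(n_cohorts)) {
      fits <- list()
      for (i in seq_len(n_subjects)) {
        s0 <- derive_seed(seed, 1000L * (gen == "hybrid") + 50L * c_i + i)
        par <- with_local_seed(s0, {
          if (gen == "hybrid") {
            agent_params(alpha = stats::runif(1, 0.3, 0.7),
                         beta = stats::runif(1, 4, 8),
                         rho = stats::runif(1, 0.3, 1.2),
                         omega = stats::runif(1, 0.4, 0.8))
          } else {
            agent_params(alpha = stats::runif(1, 0.3, 0.7),
                         beta = stats::runif(1, 4, 8), rho = 0, omega = 0)
          }
        })
        ds <- simulate_subject(par, config$configs$reward,
                               seed = derive_seed(s0, 1L),
                               subject_id = sprintf("%s%02d", gen, i))
        for (m in names(models)) {
          fits[[length(fits) + 1L]] <-
            fit_subject(ds, models[[m]], n_restarts = config$n_restarts,
                        seed = derive_seed(s0, 2L + (m == "hybrid")),
                        p_common = p_common)
        }
      }
      le <- log_evidence_matrix(fits)
      bms <- bms_random_effects(le, seed = derive_seed(seed, 77L + c_i))
      winner <- names(which.max(bms$exceedance_probability))
      confusion[gen, winner] <- confusion[gen, winner] + 1L
      all_bms[[paste(gen, c_i, sep = "_")]] <- bms
    }
  }
  list(confusion = confusion, bms = all_bms)
}
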
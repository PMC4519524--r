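# Hybrid model-based / model-free agent. The model-free component is SARSA
# temporal-difference learning with eligibility constant lam (fixed, default 1
# so the final outcome is credited directly to the first-stage value); the
# model-based component evaluates first-stage actions prospectively through
# the known 70/30 transition structure; the two are mixed by the weighting
# factor omega, and choices are softmax with inverse temperature beta plus a
# perseveration bonus rho for repeating the previous first-stage choice.

#' Parameters of the hybrid agent
#'
#' The winning model has four free parameters: learning rate `alpha`, softmax
#' inverse temperature `beta`, perseveration index `rho` (positive values bias
#' toward repeating the previous first-stage choice, negative toward
#' shifting), and the model-based weight `omega` (0 = purely model-free,
#' 1 = purely model-based). The eligibility constant `lam` is a fixed
#' constant, not a free parameter.
#'
#' @param alpha learning rate in `[0, 1]`.
#' @param beta softmax inverse temperature, `>= 0`.
#' @param rho perseveration index, any real.
#' @param omega model-based weight in `[0, 1]`.
#' @param lam eligibility constant in `[0, 1]`; fixed at 1 by default.
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(alpha, beta, rho = 0, omega = 0, lam = 1) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!is.numeric(beta) || beta < 0) stop("beta must be nonnegative")
  if (!is.numeric(omega) || omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  if (!is.numeric(lam) || lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  structure(list(alpha = alpha, beta = beta, rho = rho, omega = omega, lam = lam),
            class = "agent_params")
}

#' Fresh agent state
#'
#' All action values start at 0 (both valences) and there is no previous
#' first-stage choice, so the perseveration bonus is 0 on trial 1.
#'
#' @return list with `q_mf_stage1` (2 values, actions A/B), `q_mf_stage2`
#'   (2x2 matrix, states S1/S2 by choices a/b) and `prev_choice1` (`NA`).
#' @export
agent_state_init <- function() {
  list(q_mf_stage1 = c(A = 0, B = 0),
       q_mf_stage2 = matrix(0, 2, 2, dimnames = list(c("S1", "S2"), c("a", "b"))),
       prev_choice1 = NA_character_)
}

#' SARSA model-free update for one trial
#'
#' Applies the two temporal-difference updates of the trial:
#' `d1 = Q2(s2, c2) - Q1(c1)`; `Q1(c1) += alpha * d1`;
#' `d2 = outcome - Q2(s2, c2)`; `Q2(s2, c2) += alpha * d2`; and the
#' eligibility-carried outcome update `Q1(c1) += alpha * lam * d2`.
#'
#' @param state agent state from [agent_state_init()] or a previous update.
#' @param choice1 first-stage choice, `"A"`/`"B"`.
#' @param state2 second-stage state, `"S1"`/`"S2"`.
#' @param choice2 second-stage choice, `"a"`/`"b"`.
#' @param outcome trial outcome (0/+1 reward valence, -1/0 punishment).
#' @param alpha learning rate in `[0, 1]`.
#' @param lam eligibility constant in `[0, 1]`.
#' @return the updated agent state (with `prev_choice1` set to `choice1`).
#' @export
mf_update <- function(state, choice1, state2, choice2, outcome, alpha, lam = 1) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  d1 <- state$q_mf_stage2[state2, choice2] - state$q_mf_stage1[choice1]
  state$q_mf_stage1[choice1] <- state$q_mf_stage1[choice1] + alpha * d1
  d2 <- outcome - state$q_mf_stage2[state2, choice2]
  state$q_mf_stage2[state2, choice2] <- state$q_mf_stage2[state2, choice2] + alpha * d2
  state$q_mf_stage1[choice1] <- state$q_mf_stage1[choice1] + alpha * lam * d2
  state$prev_choice1 <- choice1
  state
}

#' Model-based first-stage values
#'
#' Evaluates each first-stage action prospectively with the true transition
#' structure: `Q_MB(a) = p_common * max_c Q2(linked(a), c) +
#' (1 - p_common) * max_c Q2(other, c)`. Subjects are instructed on the task
#' structure, so no transition learning is modelled.
#'
#' @param q_mf_stage2 2x2 matrix of second-stage values (states by choices).
#' @param p_common common-transition probability.
#' @return named numeric vector of 2 model-based values (actions A, B).
#' @export
mb_values <- function(q_mf_stage2, p_common = 0.7) {
  best <- apply(q_mf_stage2, 1, max) # per-state maxima, order S1, S2
  c(A = p_common * best[["S1"]] + (1 - p_common) * best[["S2"]],
    B = p_common * best[["S2"]] + (1 - p_common) * best[["S1"]])
}

#' Mixed first-stage values
#'
#' `Q_net = omega * Q_MB + (1 - omega) * Q_MF`, per action.
#'
#' @param q_mb model-based values (2).
#' @param q_mf_stage1 model-free first-stage values (2).
#' @param omega model-based weight in `[0, 1]`.
#' @return numeric vector of 2 net values.
#' @export
net_stage1_values <- function(q_mb, q_mf_stage1, omega) {
  if (!is.numeric(omega) || omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  omega * q_mb + (1 - omega) * q_mf_stage1
}

#' Softmax choice probabilities with perseveration
#'
#' `P(a)` is proportional to `exp(beta * value(a) + rho * [a == prev_choice])`.
#' At the second stage (`prev_choice = NULL`) the perseveration term is
#' omitted. On trial 1 or after an omission `prev_choice` is `NA` and the
#' bonus is 0 for both actions.
#'
#' @param values numeric vector of 2 action values.
#' @param beta softmax inverse temperature, `>= 0`.
#' @param rho perseveration bonus (first stage only).
#' @param prev_choice name of the previously chosen action, `NA`, or `NULL`
#'   to omit the perseveration term.
#' @return numeric vector of 2 probabilities summing to 1.
#' @export
choice_probs <- function(values, beta, rho = 0, prev_choice = NULL) {
  if (!is.numeric(beta) || beta < 0) stop("beta must be nonnegative")
  if (any(!is.finite(values))) stop("values must be finite")
  z <- beta * values
  if (!is.null(prev_choice) && !is.na(prev_choice)) {
    z <- z + rho * (names(values) == prev_choice)
  }
  z <- z - max(z)
  p <- exp(z)
  p / sum(p)
}

#' Simulate one subject on one task valence
#'
#' Runs the hybrid agent through `n_trials` of the task engine and records
#' every trial. Each subject gets its own freshly generated outcome schedule
#' by default; pass `schedule` to freeze the walks across subjects.
#'
#' @param params an [agent_params()].
#' @param config a [task_config()].
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param subject_id,group identifiers stored in the dataset.
#' @param schedule optional pre-generated [make_outcome_schedule()]; when
#'   `NULL` one is generated from `seed`.
#' @return a `subject_dataset`: list with `subject_id`, `group`, `valence`,
#'   `trials` (data frame, one row per trial, including the simulator's
#'   logged choice probabilities `p_choice1`/`p_choice2`) and `true_params`.
#' @export
simulate_subject <- function(params, config, seed,
                             subject_id = "s1", group = "BAL",
                             schedule = NULL) {
  stopifnot(inherits(params, "agent_params"), inherits(config, "task_config"))
  if (is.null(schedule)) schedule <- make_outcome_schedule(config, derive_seed(seed, 1L))
  sessions <- session_blocks(config)
  n <- config$n_trials
  acts1 <- c("A", "B"); acts2 <- c("a", "b")
  rec <- list(choice1 = character(n), transition = character(n),
              state2 = character(n), choice2 = character(n),
              outcome = numeric(n), p_choice1 = numeric(n), p_choice2 = numeric(n))
  with_local_seed(derive_seed(seed, 2L), {
    st <- agent_state_init()
    for (t in seq_len(n)) {
      q_mb <- mb_values(st$q_mf_stage2, config$p_common)
      q_net <- net_stage1_values(q_mb, st$q_mf_stage1, params$omega)
      p1 <- choice_probs(q_net, params$beta, params$rho, st$prev_choice1)
      c1 <- sample(acts1, 1, prob = p1)
      tr <- sample_transition(c1, config$p_common)
      q2 <- st$q_mf_stage2[tr$state2, ]
      p2 <- choice_probs(q2, params$beta)
      c2 <- sample(acts2, 1, prob = p2)
      out <- sample_outcome(tr$state2, c2, schedule, t, config$outcome_magnitude)
      rec$choice1[t] <- c1; rec$transition[t] <- tr$transition
      rec$state2[t] <- tr$state2; rec$choice2[t] <- c2; rec$outcome[t] <- out
      rec$p_choice1[t] <- p1[[c1]]; rec$p_choice2[t] <- p2[[c2]]
      st <- mf_update(st, c1, tr$state2, c2, out, params$alpha, params$lam)
    }
  })
  trials <- data.frame(trial = seq_len(n), session = sessions,
                       choice1 = rec$choice1, transition = rec$transition,
                       state2 = rec$state2, choice2 = rec$choice2,
                       outcome = rec$outcome, omitted = FALSE,
                       p_choice1 = rec$p_choice1, p_choice2 = rec$p_choice2,
                       stringsAsFactors = FALSE)
  structure(list(subject_id = subject_id, group = group, valence = config$valence,
                 trials = trials, true_params = params),
            class = "subject_dataset")
}

#' Specification of one simulated subject group
#'
#' Per-subject parameters are drawn from truncated normal distributions
#' (normal draws clipped post hoc: `alpha`/`omega` to `[0, 1]`, `beta` to
#' `>= 0`), separately per valence.
#'
#' @param n_subjects subjects in the group (22 by default, matching a
#'   two-arm study of 22 + 22 volunteers).
#' @param means,sds named lists with elements `reward` and `punishment`, each
#'   a named numeric vector over `alpha`, `beta`, `rho`, `omega`.
#' @param label group label (`"TD"` or `"BAL"`).
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(n_subjects = 22L, means, sds, label = "BAL") {
  stopifnot(n_subjects >= 1)
  for (v in c("reward", "punishment")) {
    stopifnot(all(c("alpha", "beta", "rho", "omega") %in% names(means[[v]])),
              all(c("alpha", "beta", "rho", "omega") %in% names(sds[[v]])))
  }
  structure(list(n_subjects = as.integer(n_subjects), means = means, sds = sds,
                 label = label), class = "group_spec")
}

#' Default group specifications for the TD/BAL scenario
#'
#' The control (BAL) group mixes model-based and model-free control
#' (mean omega 0.45) in both valences; the depleted (TD) group has its mean
#' omega shifted to the near-extremes — 0.08 in the reward valence (toward
#' model-free control) and 0.98 in the punishment valence (toward model-based
#' control). The shifts must be near-complete: at a group size of 22, any
#' appreciable residual weight on the other controller still produces a
#' detectable factorial effect, and the group's signature classifies as
#' mixed. Remaining means (alpha 0.5, beta 5, rho 0.5) are shared.
#'
#' @param n_subjects subjects per group.
#' @return list with `group_spec` elements `TD` and `BAL`.
#' @export
default_group_specs <- function(n_subjects = 22L) {
  base_mean <- c(alpha = 0.5, beta = 5, rho = 0.5, omega = 0.45)
  sds <- c(alpha = 0.15, beta = 1.5, rho = 0.3, omega = 0.12)
  bal <- list(reward = base_mean, punishment = base_mean)
  td <- list(reward = replace(base_mean, "omega", 0.08),
             punishment = replace(base_mean, "omega", 0.98))
  td_sds <- list(reward = replace(sds, "omega", 0.08),
                 punishment = replace(sds, "omega", 0.02))
  list(TD = group_spec(n_subjects, td, td_sds, label = "TD"),
       BAL = group_spec(n_subjects, bal, list(reward = sds, punishment = sds),
                        label = "BAL"))
}

# Draw one subject's parameters for one valence from a group spec.
draw_params <- function(spec, valence) {
  m <- spec$means[[valence]]; s <- spec$sds[[valence]]
  raw <- stats::rnorm(4, m[c("alpha", "beta", "rho", "omega")],
                      s[c("alpha", "beta", "rho", "omega")])
  agent_params(alpha = min(max(raw[1], 0), 1),
               beta = max(raw[2], 0),
               rho = raw[3],
               omega = min(max(raw[4], 0), 1))
}

#' Simulate a full two-group, two-valence study
#'
#' Samples per-subject parameters from each group's distributions and
#' simulates both task valences for every subject. Parameters are drawn
#' independently per valence (the default scenario encodes the
#' valence-dependent omega shift in the TD group's means).
#'
#' @param td,bal [group_spec()]s for the two groups.
#' @param configs named list of [task_config()]s, elements `reward` and
#'   `punishment`.
#' @param seed integer seed; all subject seeds are derived from it.
#' @param shared_schedules freeze one outcome schedule per valence across all
#'   subjects (`TRUE`) or regenerate the walks per subject (default).
#' @return list of `subject_dataset` objects (one per subject per valence),
#'   with attribute `subjects` giving the subject-level table.
#' @export
simulate_group_study <- function(td, bal, configs = NULL, seed = 1L,
                                 shared_schedules = FALSE) {
  if (is.null(configs)) {
    configs <- list(reward = task_config("reward"),
                    punishment = task_config("punishment"))
  }
  schedules <- if (shared_schedules) {
    list(reward = make_outcome_schedule(configs$reward, derive_seed(seed, 900L)),
         punishment = make_outcome_schedule(configs$punishment, derive_seed(seed, 901L)))
  } else list(reward = NULL, punishment = NULL)
  datasets <- list()
  info <- list()
  idx <- 0L
  for (spec in list(td, bal)) {
    for (i in seq_len(spec$n_subjects)) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", spec$label, i)
      for (valence in c("reward", "punishment")) {
        pseed <- derive_seed(seed, idx * 10L + (valence == "punishment"))
        par <- with_local_seed(derive_seed(pseed, 0L), draw_params(spec, valence))
        ds <- simulate_subject(par, configs[[valence]], seed = derive_seed(pseed, 3L),
                               subject_id = sid, group = spec$label,
                               schedule = schedules[[valence]])
        datasets[[paste(sid, valence, sep = "_")]] <- ds
      }
      info[[idx]] <- data.frame(subject_id = sid, group = spec$label,
                                stringsAsFactors = FALSE)
    }
  }
  attr(datasets, "subjects") <- do.call(rbind, info)
  datasets
}
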
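# Generative structure of the two-step task: two first-stage actions lead with
# fixed common/rare probabilities (70/30) to one of two second-stage states;
# each of the four second-stage stimuli pays a probabilistic outcome (+1 gain
# in the reward valence, -1 loss in the punishment valence) whose probability
# drifts slowly between reflecting bounds.

#' Configure one valence of the two-step task
#'
#' Builds the full generative specification for one task version: trial and
#' session counts, the fixed transition structure, and the Gaussian
#' random-walk outcome schedule with reflecting bounds.
#'
#' @param valence `"reward"` (outcomes 0/+1) or `"punishment"` (outcomes -1/0).
#' @param n_trials trials per valence; 201 by default, split across sessions.
#' @param n_sessions contiguous session blocks (sizes differ by at most 1).
#' @param p_common probability that a first-stage action leads to its linked
#'   second-stage state (the "common" transition); default 0.7.
#' @param outcome_low,outcome_high bounds of the drifting outcome
#'   probabilities; defaults 0.25 and 0.75.
#' @param walk_sd standard deviation of the per-trial Gaussian step of each
#'   outcome probability; default 0.025.
#' @param seed optional integer seed controlling the outcome schedule when one
#'   is generated from this config.
#'
#' @return an object of class `task_config` (a list with the fields above plus
#'   `outcome_magnitude`, +1 for reward and -1 for punishment).
#' @export
#' @examples
#' cfg <- task_config("reward")
#' session_blocks(cfg)
task_config <- function(valence = c("reward", "punishment"),
                        n_trials = 201L, n_sessions = 3L,
                        p_common = 0.7,
                        outcome_low = 0.25, outcome_high = 0.75,
                        walk_sd = 0.025, seed = NULL) {
  valence <- match.arg(valence)
  n_trials <- as.integer(n_trials)
  n_sessions <- as.integer(n_sessions)
  if (n_trials < 1L) stop("n_trials must be positive")
  if (n_sessions < 1L || n_sessions > n_trials) stop("invalid n_sessions")
  if (!(p_common > 0 && p_common < 1)) stop("p_common must lie strictly in (0, 1)")
  stop_if_not_prob(outcome_low, "outcome_low")
  stop_if_not_prob(outcome_high, "outcome_high")
  if (outcome_low > outcome_high) stop("outcome_low must not exceed outcome_high")
  if (!is.numeric(walk_sd) || walk_sd < 0) stop("walk_sd must be nonnegative")
  structure(list(
    valence = valence,
    n_trials = n_trials,
    n_sessions = n_sessions,
    p_common = p_common,
    outcome_low = outcome_low,
    outcome_high = outcome_high,
    walk_sd = walk_sd,
    outcome_magnitude = if (valence == "reward") 1 else -1,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "task_config")
}

#' Session index for every trial
#'
#' Trials are divided into `n_sessions` contiguous blocks whose sizes differ
#' by at most one (201 trials in 3 sessions gives 67 each). Outcome walks
#' continue across session boundaries.
#'
#' @param config a [task_config()].
#' @return integer vector of length `n_trials` with session labels `1..n_sessions`.
#' @export
session_blocks <- function(config) {
  sizes <- rep(config$n_trials %/% config$n_sessions, config$n_sessions)
  extra <- config$n_trials %% config$n_sessions
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(config$n_sessions), times = sizes)
}

#' Initial outcome probabilities
#'
#' Draws the four second-stage stimuli's starting outcome probabilities
#' uniformly within the configured bounds.
#'
#' @param config a [task_config()].
#' @return numeric vector of 4 probabilities in `[outcome_low, outcome_high]`.
#' @export
init_outcome_probs <- function(config) {
  stats::runif(4, config$outcome_low, config$outcome_high)
}

#' Reflect a value into an interval
#'
#' Folds `x` back into `[low, high]` by mirror reflection at the boundaries
#' (repeatedly, for steps larger than the interval). Reflection rather than
#' truncation keeps the random walk's stationary distribution from piling up
#' mass at the bounds.
#'
#' @param x numeric value(s).
#' @param low,high interval bounds, `low <= high`.
#' @return numeric value(s) in `[low, high]`.
#' @export
#' @examples
#' reflect_into_interval(0.77, 0.25, 0.75) # 0.73
reflect_into_interval <- function(x, low, high) {
  if (low > high) stop("low must not exceed high")
  if (low == high) return(rep(low, length(x)))
  width <- high - low
  y <- (x - low) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  y + low
}

#' One step of the drifting outcome probability
#'
#' Adds a Gaussian step of standard deviation `walk_sd` to `p` and reflects
#' the result at `low` and `high`, so the probability drifts slowly and stays
#' inside its dynamic range.
#'
#' @param p current probability, inside `[low, high]`.
#' @param walk_sd step standard deviation (nonnegative).
#' @param low,high reflecting bounds.
#' @return the next probability, inside `[low, high]`.
#' @export
step_outcome_prob <- function(p, walk_sd, low = 0.25, high = 0.75) {
  if (!is.numeric(walk_sd) || walk_sd < 0) stop("walk_sd must be nonnegative")
  reflect_into_interval(p + stats::rnorm(length(p), 0, walk_sd), low, high)
}

#' Generate a full outcome-probability schedule
#'
#' Produces the `n_trials x 4` matrix of outcome probabilities, one column
#' per second-stage stimulus (columns ordered S1a, S1b, S2a, S2b). Each column
#' evolves as an independent reflecting Gaussian walk started uniformly within
#' the bounds.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed; falls back to `config$seed`.
#' @return matrix of class `outcome_schedule`, `n_trials` rows by 4 columns.
#' @export
make_outcome_schedule <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  with_local_seed(seed, {
    probs <- matrix(NA_real_, nrow = config$n_trials, ncol = 4,
                    dimnames = list(NULL, c("S1a", "S1b", "S2a", "S2b")))
    probs[1, ] <- init_outcome_probs(config)
    if (config$n_trials > 1) {
      for (t in 2:config$n_trials) {
        probs[t, ] <- step_outcome_prob(probs[t - 1, ], config$walk_sd,
                                        config$outcome_low, config$outcome_high)
      }
    }
    structure(probs, class = c("outcome_schedule", "matrix"))
  })
}

#' Sample the second-stage state for a first-stage choice
#'
#' The mapping choice `"A"` -> state `"S1"`, choice `"B"` -> state `"S2"` is
#' the fixed common transition for all trials and subjects; it occurs with
#' probability `p_common`, otherwise the other state is reached (a rare
#' transition).
#'
#' @param choice1 `"A"` or `"B"`.
#' @param p_common common-transition probability.
#' @return list with `state2` (`"S1"`/`"S2"`) and `transition`
#'   (`"common"`/`"rare"`).
#' @export
sample_transition <- function(choice1, p_common = 0.7) {
  if (!choice1 %in% c("A", "B")) stop("choice1 must be 'A' or 'B'")
  linked <- if (choice1 == "A") "S1" else "S2"
  other <- if (linked == "S1") "S2" else "S1"
  common <- stats::runif(1) < p_common
  list(state2 = if (common) linked else other,
       transition = if (common) "common" else "rare")
}

#' Sample the outcome of a second-stage choice
#'
#' Pays `magnitude` (+1 gain or -1 loss) with the scheduled probability of the
#' chosen stimulus at the given trial, and 0 otherwise.
#'
#' @param state2 `"S1"` or `"S2"`.
#' @param choice2 `"a"` or `"b"`.
#' @param schedule an [make_outcome_schedule()] matrix.
#' @param trial 1-based trial index into the schedule.
#' @param magnitude outcome magnitude (+1 reward valence, -1 punishment).
#' @return numeric outcome, `magnitude` or 0.
#' @export
sample_outcome <- function(state2, choice2, schedule, trial, magnitude = 1) {
  if (trial < 1 || trial > nrow(schedule)) stop("trial index out of range")
  col <- schedule_column(state2, choice2)
  if (stats::runif(1) < schedule[trial, col]) magnitude else 0
}

# Column index of a (state, choice) stimulus in the schedule matrix.
schedule_column <- function(state2, choice2) {
  if (!state2 %in% c("S1", "S2")) stop("state2 must be 'S1' or 'S2'")
  if (!choice2 %in% c("a", "b")) stop("choice2 must be 'a' or 'b'")
  (if (state2 == "S1") 0L else 2L) + (if (choice2 == "a") 1L else 2L)
}

#' Write an outcome schedule to CSV for audit
#'
#' @param schedule an [make_outcome_schedule()] matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  df <- data.frame(trial = seq_len(nrow(schedule)), unclass(schedule)[, , drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
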
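# Independent oracles, written from the model equations directly; they share
# no code with the package implementation.

# Brute-force negative log-likelihood: re-derives every choice probability
# with plain arithmetic and multiplies them out.
oracle_nll <- function(trials, alpha, beta, rho, omega, lam = 1, p_common = 0.7) {
  q1 <- c(0, 0)                      # actions A, B
  q2 <- matrix(0, 2, 2)              # states S1, S2 x choices a, b
  prev <- 0L
  loglik <- 0
  n_obs <- 0L
  for (t in seq_len(nrow(trials))) {
    if (isTRUE(trials$omitted[t])) { prev <- 0L; next }
    c1 <- if (trials$choice1[t] == "A") 1L else 2L
    s2 <- if (trials$state2[t] == "S1") 1L else 2L
    c2 <- if (trials$choice2[t] == "a") 1L else 2L
    qmb <- c(p_common * max(q2[1, ]) + (1 - p_common) * max(q2[2, ]),
             p_common * max(q2[2, ]) + (1 - p_common) * max(q2[1, ]))
    z <- beta * (omega * qmb + (1 - omega) * q1)
    if (prev > 0L) z[prev] <- z[prev] + rho
    p1 <- exp(z) / sum(exp(z))
    w <- beta * q2[s2, ]
    p2 <- exp(w) / sum(exp(w))
    loglik <- loglik + log(p1[c1]) + log(p2[c2])
    n_obs <- n_obs + 2L
    d1 <- q2[s2, c2] - q1[c1]
    q1[c1] <- q1[c1] + alpha * d1
    d2 <- trials$outcome[t] - q2[s2, c2]
    q2[s2, c2] <- q2[s2, c2] + alpha * d2
    q1[c1] <- q1[c1] + alpha * lam * d2
    prev <- c1
  }
  list(nll = -loglik, n_obs = n_obs)
}

# Split-plot sums-of-squares oracle for a balanced design with one 2-level
# between factor (group) and two 2-level within factors (A, B), n subjects
# per group. Input: data frame with columns subj, group, A, B, y.
oracle_split_plot <- function(df) {
  df$group <- factor(df$group); df$A <- factor(df$A); df$B <- factor(df$B)
  df$subj <- factor(df$subj)
  N <- nlevels(df$subj)
  n_g <- table(unique(df[, c("subj", "group")])$group)
  M <- mean(df$y)
  G <- tapply(df$y, df$group, mean)
  S <- tapply(df$y, df$subj, mean)
  subj_group <- unique(df[, c("subj", "group")])
  gs <- setNames(as.character(subj_group$group), as.character(subj_group$subj))
  A <- tapply(df$y, df$A, mean); B <- tapply(df$y, df$B, mean)
  GA <- tapply(df$y, list(df$group, df$A), mean)
  GB <- tapply(df$y, list(df$group, df$B), mean)
  AB <- tapply(df$y, list(df$A, df$B), mean)
  GAB <- tapply(df$y, list(df$group, df$A, df$B), mean)
  AS <- tapply(df$y, list(df$subj, df$A), mean)
  BS <- tapply(df$y, list(df$subj, df$B), mean)

  n_g <- setNames(as.numeric(n_g), names(n_g))
  ss_group <- 4 * sum(n_g * (G - M)^2)
  ss_subj <- 4 * sum((S - G[gs[names(S)]])^2)
  ss_A <- 2 * N * sum((A - M)^2)
  ss_GA <- 2 * sum(n_g * unclass((GA - outer(G, A, `+`) + M)^2))
  ss_As <- 0
  for (s in rownames(AS)) for (a in colnames(AS)) {
    g <- gs[[s]]
    ss_As <- ss_As + 2 * (AS[s, a] - S[[s]] - GA[g, a] + G[[g]])^2
  }
  ss_B <- 2 * N * sum((B - M)^2)
  ss_GB <- 2 * sum(n_g * unclass((GB - outer(G, B, `+`) + M)^2))
  ss_Bs <- 0
  for (s in rownames(BS)) for (b in colnames(BS)) {
    g <- gs[[s]]
    ss_Bs <- ss_Bs + 2 * (BS[s, b] - S[[s]] - GB[g, b] + G[[g]])^2
  }
  ss_AB <- N * sum((AB - outer(A, B, `+`) + M)^2)
  ss_GAB <- 0
  for (g in names(G)) for (a in names(A)) for (b in names(B)) {
    ss_GAB <- ss_GAB + n_g[[g]] *
      (GAB[g, a, b] - GA[g, a] - GB[g, b] - AB[a, b] + G[[g]] + A[[a]] + B[[b]] - M)^2
  }
  ss_total <- sum((df$y - M)^2)
  ss_ABs <- ss_total - ss_group - ss_subj - ss_A - ss_GA - ss_As -
    ss_B - ss_GB - ss_Bs - ss_AB - ss_GAB

  dfe <- N - length(n_g)
  f <- function(ss_eff, ss_err) (ss_eff / 1) / (ss_err / dfe)
  list(group = f(ss_group, ss_subj),
       A = f(ss_A, ss_As), `group:A` = f(ss_GA, ss_As),
       B = f(ss_B, ss_Bs), `group:B` = f(ss_GB, ss_Bs),
       `A:B` = f(ss_AB, ss_ABs), `group:A:B` = f(ss_GAB, ss_ABs),
       df2 = dfe)
}

# Build a subject_dataset by hand from parallel vectors.
make_dataset <- function(choice1, transition, state2, choice2, outcome,
                         omitted = rep(FALSE, length(choice1)),
                         valence = "reward", subject_id = "h1", group = "BAL") {
  n <- length(choice1)
  structure(list(
    subject_id = subject_id, group = group, valence = valence,
    trials = data.frame(trial = seq_len(n), session = 1L,
                        choice1 = choice1, transition = transition,
                        state2 = state2, choice2 = choice2,
                        outcome = outcome, omitted = omitted,
                        stringsAsFactors = FALSE),
    true_params = NULL), class = "subject_dataset")
}

# Random observable trial sequence (choices/states/outcomes only).
random_trials <- function(n, valence = "reward", seed = 1) {
  set.seed(seed)
  mag <- if (valence == "reward") 1 else -1
  data.frame(trial = seq_len(n), session = 1L,
             choice1 = sample(c("A", "B"), n, TRUE),
             transition = sample(c("common", "rare"), n, TRUE, prob = c(0.7, 0.3)),
             state2 = sample(c("S1", "S2"), n, TRUE),
             choice2 = sample(c("a", "b"), n, TRUE),
             outcome = sample(c(0, mag), n, TRUE),
             omitted = FALSE, stringsAsFactors = FALSE)
}

# Seeded random but admissible hybrid parameter set.
with_seed_params <- function(seed) {
  set.seed(seed + 500)
  agent_params(alpha = runif(1), beta = runif(1, 0, 10),
               rho = rnorm(1), omega = runif(1))
}

trials_to_dataset <- function(trials, valence = "reward") {
  make_dataset(trials$choice1, trials$transition, trials$state2,
               trials$choice2, trials$outcome, trials$omitted,
               valence = valence)
}
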
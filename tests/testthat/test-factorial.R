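test_that("stay tables count hand-enumerable trial pairs", {
  ds <- make_dataset(choice1 = c("A", "A", "B", "B", "B"),
                     transition = c("common", "rare", "common", "common", "rare"),
                     state2 = c("S1", "S2", "S2", "S2", "S1"),
                     choice2 = c("a", "a", "b", "a", "b"),
                     outcome = c(1, 0, 1, 1, 0))
  st <- compute_stay_table(ds)
  # pairs: t1(better,common)->stay, t2(worse,rare)->shift,
  #        t3(better,common)->stay, t4(better,common)->stay
  expect_equal(st$n_pairs["better", "common"], 3L)
  expect_equal(st$n_pairs["worse", "rare"], 1L)
  expect_equal(sum(st$n_pairs), 4L)
  expect_equal(st$p_stay["better", "common"], 1)
  expect_equal(st$p_stay["worse", "rare"], 0)
  expect_true(is.nan(st$p_stay["better", "rare"]))
  expect_true(is.nan(st$p_stay["worse", "common"]))
})

test_that("omitted trials break pairs and punishment reverses the outcome mapping", {
  ds <- make_dataset(choice1 = c("A", "A", "B", "B", "B"),
                     transition = c("common", "rare", "common", "common", "rare"),
                     state2 = c("S1", "S2", "S2", "S2", "S1"),
                     choice2 = c("a", "a", "b", "a", "b"),
                     outcome = c(1, 0, 1, 1, 0),
                     omitted = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  st <- compute_stay_table(ds)
  expect_equal(sum(st$n_pairs), 2L) # pairs (1,2) and (4,5) survive
  # punishment valence: 0 is the better category, the loss is worse
  dp <- make_dataset(choice1 = c("A", "A", "A"),
                     transition = c("common", "rare", "common"),
                     state2 = c("S1", "S2", "S1"),
                     choice2 = c("a", "a", "a"),
                     outcome = c(0, -1, 0), valence = "punishment")
  stp <- compute_stay_table(dp)
  expect_equal(stp$n_pairs["better", "common"], 1L)
  expect_equal(stp$n_pairs["worse", "rare"], 1L)
  expect_error(compute_stay_table(make_dataset("A", "common", "S1", "a", 1)),
               "2 non-omitted")
})

test_that("an always-repeating chooser stays in every cell", {
  ds <- make_dataset(choice1 = rep("A", 9),
                     transition = rep(c("common", "rare", "common"), 3),
                     state2 = rep(c("S1", "S2", "S1"), 3),
                     choice2 = rep("a", 9),
                     outcome = c(1, 1, 0, 0, 1, 0, 1, 0, 1))
  st <- compute_stay_table(ds)
  expect_true(all(st$n_pairs > 0))
  expect_equal(unname(st$p_stay), matrix(1, 2, 2))
})

test_that("arcsine transform has its closed-form values and is increasing", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.5), pi / 4)
  expect_error(arcsine_transform(1.2), "0, 1")
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(arcsine_transform(p)) > 0))
})

test_that("mixed ANOVA matches an independent sums-of-squares oracle", {
  # 2 groups x 3 subjects x 2x2 within, hand-chosen cell responses
  set.seed(42)
  grid <- expand.grid(subj = paste0("s", 1:6),
                      A = c("a1", "a2"), B = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(grid$subj %in% paste0("s", 1:3), "g1", "g2")
  grid$y <- round(rnorm(nrow(grid)), 2) +
    2 * (grid$group == "g2") + 0.8 * (grid$A == "a2") +
    0.5 * (grid$A == "a2") * (grid$B == "b2")
  res <- mixed_anova(grid, "y", "subj", within = c("A", "B"), between = "group")
  orc <- oracle_split_plot(grid)
  for (eff in c("group", "A", "B")) {
    expect_equal(res$F[res$effect == eff], orc[[eff]], tolerance = 1e-10)
  }
  expect_equal(res$F[res$effect == "group:A"], orc[["group:A"]], tolerance = 1e-10)
  expect_equal(res$F[res$effect == "A:B"], orc[["A:B"]], tolerance = 1e-10)
  expect_equal(res$F[res$effect == "group:A:B"], orc[["group:A:B"]], tolerance = 1e-10)
  expect_true(all(res$df2[res$effect %in% c("group", "A", "A:B")] == orc$df2))
})

test_that("between-group p value agrees with a subject-permutation reference", {
  set.seed(7)
  n <- 8 # per group
  grid <- expand.grid(subj = sprintf("s%02d", 1:(2 * n)),
                      A = c("a1", "a2"), B = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(grid$subj %in% sprintf("s%02d", 1:n), "g1", "g2")
  subj_eff <- setNames(rnorm(2 * n, sd = 0.6), sprintf("s%02d", 1:(2 * n)))
  grid$y <- rnorm(nrow(grid), sd = 0.4) + subj_eff[grid$subj] +
    0.55 * (grid$group == "g2")
  res <- mixed_anova(grid, "y", "subj", within = c("A", "B"), between = "group")
  p_param <- res$p[res$effect == "group"]
  # permutation of subject group labels; F recomputed from subject means,
  # which is the exact between-subjects statistic in this balanced design
  sm <- tapply(grid$y, grid$subj, mean)
  glab <- tapply(grid$group, grid$subj, `[`, 1)[names(sm)]
  f_between <- function(lab) {
    g <- split(sm, lab)
    msb <- n * sum((vapply(g, mean, 0) - mean(sm))^2) / 1
    msw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0)) / (2 * n - 2)
    msb / msw
  }
  f_obs <- f_between(glab)
  expect_equal(f_obs, res$F[res$effect == "group"], tolerance = 1e-8)
  set.seed(99)
  f_perm <- replicate(10000, f_between(sample(glab)))
  p_perm <- mean(f_perm >= f_obs)
  expect_lt(abs(p_perm - p_param), 0.03)
})

test_that("degenerate and malformed factorial designs are handled", {
  grid <- expand.grid(subj = paste0("s", 1:4), A = c("a1", "a2"),
                      stringsAsFactors = FALSE)
  grid$y <- 1 # identical response everywhere: zero error SS, F undefined
  res <- mixed_anova(grid, "y", "subj", within = "A")
  expect_true(all(is.na(res$F)))
  # missing cell
  expect_error(mixed_anova(grid[-1, ], "y", "subj", within = "A"), "balanced")
  # too few subjects per group
  g2 <- expand.grid(subj = paste0("s", 1:2), A = c("a1", "a2"),
                    stringsAsFactors = FALSE)
  g2$group <- ifelse(g2$subj == "s1", "g1", "g2")
  g2$y <- rnorm(nrow(g2))
  expect_error(mixed_anova(g2, "y", "subj", within = "A", between = "group"),
               ">= 2 subjects")
})

test_that("one-within-factor ANOVA reduces to the paired F", {
  set.seed(5)
  d <- data.frame(subj = rep(paste0("s", 1:10), 2),
                  A = rep(c("a1", "a2"), each = 10),
                  y = c(rnorm(10), rnorm(10, 0.7)))
  res <- mixed_anova(d, "y", "subj", within = "A")
  tt <- t.test(d$y[d$A == "a2"], d$y[d$A == "a1"], paired = TRUE)
  expect_equal(res$F[res$effect == "A"], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p[res$effect == "A"], tt$p.value, tolerance = 1e-10)
})

test_that("signature classification follows the factorial logic", {
  fake <- function(p_out, p_int) {
    structure(data.frame(effect = c("outcome_cat", "transition",
                                    "outcome_cat:transition"),
                         df1 = 1L, df2 = 21L, F = 1,
                         p = c(p_out, 0.5, p_int), stringsAsFactors = FALSE),
              class = c("anova_result", "data.frame"))
  }
  expect_equal(classify_signature(fake(0.001, 0.9)), "model_free")
  expect_equal(classify_signature(fake(0.9, 0.001)), "model_based")
  expect_equal(classify_signature(fake(0.01, 0.04)), "mixed")
  expect_equal(classify_signature(fake(0.6, 0.7)), "neither")
  # custom alpha level and order-insensitive effect labels
  expect_equal(classify_signature(fake(0.02, 0.04), alpha_level = 0.01), "neither")
  reversed <- fake(0.001, 0.9)
  reversed$effect[3] <- "transition:outcome_cat"
  expect_equal(classify_signature(reversed), "model_free")
  expect_error(classify_signature(fake(0.5, 0.5)[1:2, ]), "not found")
})

test_that("cumulative outcome sums non-omitted trials", {
  ds <- make_dataset(choice1 = rep("A", 5), transition = rep("common", 5),
                     state2 = rep("S1", 5), choice2 = rep("a", 5),
                     outcome = c(1, 0, 1, 0, 1))
  expect_equal(cumulative_outcome(ds), 3)
  ds$trials$omitted[5] <- TRUE
  expect_equal(cumulative_outcome(ds), 2)
  ds$trials$outcome <- 0
  expect_equal(cumulative_outcome(ds), 0)
})

test_that("long table excludes subjects with empty cells and carries transforms", {
  cfg <- task_config("reward", n_trials = 80L, n_sessions = 1L)
  sts <- lapply(1:4, function(i)
    compute_stay_table(simulate_subject(agent_params(0.5, 3, 0.3, 0.5), cfg,
                                        seed = i, subject_id = paste0("s", i))))
  # a stay table with an empty cell is dropped and logged
  empty <- compute_stay_table(make_dataset(
    choice1 = c("A", "A", "B"), transition = c("common", "common", "rare"),
    state2 = c("S1", "S1", "S1"), choice2 = c("a", "a", "a"),
    outcome = c(1, 1, 0), subject_id = "bad"))
  long <- stay_long_table(c(sts, list(empty)))
  expect_equal(attr(long, "excluded"), "bad/reward")
  expect_equal(nrow(long), 16)
  expect_equal(long$stay_p_arcsine, arcsine_transform(long$stay_p))
})
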
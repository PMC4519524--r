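# Stay/shift factorial analysis: per-subject stay probabilities classified by
# the previous trial's outcome category and transition type, the arcsine
# variance-stabilising transform, mixed-design ANOVAs, and the model-free /
# model-based signature classification. Model-free learning predicts only a
# main effect of previous outcome on staying; the model-based signature is
# the outcome x transition interaction.

#' Per-subject 2x2 stay-probability table
#'
#' For each consecutive pair of non-omitted trials (t-1, t), trial t-1 is
#' classified by its outcome category and transition type, and the pair
#' scores a "stay" when the first-stage choice repeats. Outcome categories
#' unify the two valences as better/worse: rewarded vs unrewarded in the
#' reward valence, unpunished vs punished in the punishment valence. Pairs
#' spanning an omitted trial are skipped.
#'
#' @param dataset a `subject_dataset`.
#' @return a `stay_table`: list with `subject_id`, `group`, `valence`,
#'   `p_stay` (2x2 matrix, outcome better/worse x transition common/rare;
#'   `NaN` where no pairs contribute) and `n_pairs` (2x2 counts).
#' @export
compute_stay_table <- function(dataset) {
  tr <- dataset$trials[!dataset$trials$omitted, , drop = FALSE]
  if (nrow(tr) < 2) stop("need at least 2 non-omitted trials")
  consecutive <- diff(tr$trial) == 1
  prev <- tr[-nrow(tr), ][consecutive, , drop = FALSE]
  cur <- tr[-1, ][consecutive, , drop = FALSE]
  better <- if (dataset$valence == "reward") prev$outcome > 0 else prev$outcome == 0
  ocat <- factor(ifelse(better, "better", "worse"), levels = c("better", "worse"))
  tcat <- factor(prev$transition, levels = c("common", "rare"))
  stay <- as.numeric(cur$choice1 == prev$choice1)
  n_pairs <- table(ocat, tcat)
  stay_sum <- tapply(stay, list(ocat, tcat), sum)
  p_stay <- stay_sum / unclass(n_pairs)
  p_stay[unclass(n_pairs) == 0] <- NaN
  structure(list(subject_id = dataset$subject_id, group = dataset$group,
                 valence = dataset$valence,
                 p_stay = unclass(p_stay),
                 n_pairs = matrix(as.integer(n_pairs), 2, 2,
                                  dimnames = dimnames(p_stay))),
            class = "stay_table")
}

#' Arcsine variance-stabilising transform
#'
#' `arcsin(sqrt(p))`, applied to stay probabilities before ANOVA.
#'
#' @param p probability or vector of probabilities in `[0, 1]`.
#' @return transformed value(s) in `[0, pi/2]`.
#' @export
arcsine_transform <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p must lie in [0, 1]")
  asin(sqrt(p))
}

#' Long-format stay-probability observations for ANOVA
#'
#' Stacks per-subject stay tables into the observation table consumed by
#' [mixed_anova()], with both the raw and arcsine-transformed stay
#' probabilities. Subjects with any empty cell (no contributing pairs) are
#' excluded listwise and recorded in the `excluded` attribute.
#'
#' @param stay_tables list of `stay_table`s.
#' @return data frame with columns `subject_id`, `group`, `valence`,
#'   `outcome_cat`, `transition`, `stay_p`, `stay_p_arcsine`.
#' @export
stay_long_table <- function(stay_tables) {
  rows <- list(); excluded <- character()
  for (st in stay_tables) {
    if (any(!is.finite(st$p_stay))) {
      excluded <- c(excluded, paste(st$subject_id, st$valence, sep = "/"))
      next
    }
    grid <- expand.grid(outcome_cat = c("better", "worse"),
                        transition = c("common", "rare"),
                        stringsAsFactors = FALSE)
    p <- st$p_stay[cbind(grid$outcome_cat, grid$transition)]
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = st$subject_id, group = st$group, valence = st$valence,
      grid, stay_p = p, stay_p_arcsine = arcsine_transform(p),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- unique(excluded)
  out
}

#' Mixed-design ANOVA on a balanced factorial table
#'
#' Fully crossed design with an optional two-level between-subjects factor
#' and one to three two-level within-subject factors, fit with
#' subject-nested error strata. All within factors have two levels, so
#' sphericity holds automatically and no correction is applied. Requires a
#' complete balanced design: every subject must have exactly one observation
#' per within-cell, and with a between factor at least two subjects per
#' level.
#'
#' @param data long-format data frame.
#' @param response name of the response column.
#' @param subject name of the subject-identifier column.
#' @param within character vector of within-subject factor columns.
#' @param between optional between-subjects factor column.
#' @return an `anova_result` data frame: `effect`, `df1`, `df2`, `F`, `p`
#'   (F and p are `NA` when the error stratum has zero variance).
#' @export
mixed_anova <- function(data, response, subject, within, between = NULL) {
  stopifnot(length(within) >= 1, length(within) <= 3)
  df <- data
  df$.y <- df[[response]]
  df$.subj <- factor(df[[subject]])
  for (w in within) df[[w]] <- factor(df[[w]])
  cells <- do.call(table, c(list(df$.subj), lapply(within, function(w) df[[w]])))
  if (any(cells != 1)) stop("design not complete/balanced: every subject needs exactly one observation per within-cell")
  fixed <- paste(c(between, within), collapse = " * ")
  if (!is.null(between)) {
    df[[between]] <- factor(df[[between]])
    if (min(table(df[[between]])) / prod(vapply(within, function(w) nlevels(df[[w]]), 0L)) < 2)
      stop("need >= 2 subjects per between-factor level")
    per_subj <- unique(df[, c(".subj", between)])
    if (anyDuplicated(per_subj$.subj)) stop("subjects must belong to exactly one group")
  }
  err <- paste0("Error(.subj/(", paste(within, collapse = " * "), "))")
  form <- stats::as.formula(paste(".y ~", fixed, "+", err))
  fit <- stats::aov(form, data = df)
  # a response with no variance leaves only floating-point noise in every
  # stratum; F is then 0/0 and reported as undefined
  degenerate <- sum((df$.y - mean(df$.y))^2) < 1e-18 * nrow(df)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid_row <- terms == "Residuals"
    df2 <- tab$Df[resid_row]
    for (i in which(!resid_row)) {
      out[[length(out) + 1L]] <- data.frame(
        effect = terms[i], df1 = tab$Df[i],
        df2 = if (length(df2)) df2 else NA_integer_,
        F = if (length(df2) && !degenerate && !is.na(tab$`F value`[i]))
          tab$`F value`[i] else NA_real_,
        p = if (length(df2) && !degenerate && !is.na(tab$`Pr(>F)`[i]))
          tab$`Pr(>F)`[i] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("anova_result", "data.frame")
  res
}

# Pull the p value of one effect (term order-insensitive) from an anova_result.
effect_p <- function(result, effect) {
  want <- sort(strsplit(effect, ":", fixed = TRUE)[[1]])
  for (i in seq_len(nrow(result))) {
    have <- sort(strsplit(result$effect[i], ":", fixed = TRUE)[[1]])
    if (identical(want, have)) return(result$p[i])
  }
  stop("effect '", effect, "' not found in ANOVA result")
}

#' Classify the learning signature from an ANOVA result
#'
#' Model-free learning predicts only a main effect of the previous outcome on
#' staying; the model-based signature is the outcome x transition
#' interaction. A group showing both is classified `mixed`; neither,
#' `neither`.
#'
#' @param result an [mixed_anova()] result containing `outcome_cat` and
#'   `outcome_cat:transition` effects.
#' @param alpha_level significance level; default 0.05.
#' @param outcome_effect,interaction_effect effect labels in `result`.
#' @return one of `"model_free"`, `"model_based"`, `"mixed"`, `"neither"`.
#' @export
classify_signature <- function(result, alpha_level = 0.05,
                               outcome_effect = "outcome_cat",
                               interaction_effect = "outcome_cat:transition") {
  p_out <- effect_p(result, outcome_effect)
  p_int <- effect_p(result, interaction_effect)
  sig_out <- !is.na(p_out) && p_out < alpha_level
  sig_int <- !is.na(p_int) && p_int < alpha_level
  if (sig_out && sig_int) "mixed"
  else if (sig_out) "model_free"
  else if (sig_int) "model_based"
  else "neither"
}

#' Cumulative outcome of one dataset
#'
#' Total earned (reward valence) or lost (punishment valence) over all
#' non-omitted trials; used to compare cumulative learning between groups.
#'
#' @param dataset a `subject_dataset`.
#' @return numeric sum of outcomes.
#' @export
cumulative_outcome <- function(dataset) {
  sum(dataset$trials$outcome[!dataset$trials$omitted])
}
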
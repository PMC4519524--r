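# Reading and writing the trial-log CSV dialect and sidecar parameter files.

canonical_columns <- c("subject_id", "group", "valence", "session", "trial",
                       "choice1", "transition", "state2", "choice2",
                       "outcome", "omitted")

#' Write subject datasets to a trial-log CSV
#'
#' One row per trial with the canonical header: `subject_id, group, valence,
#' session, trial, choice1, transition, state2, choice2, outcome, omitted`.
#' When any dataset carries true generating parameters they are written to a
#' sidecar JSON next to `path` (same name, `.params.json`).
#'
#' @param datasets a `subject_dataset` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_subjects_csv <- function(datasets, path) {
  if (inherits(datasets, "subject_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(ds) {
    cbind(data.frame(subject_id = ds$subject_id, group = ds$group,
                     valence = ds$valence, stringsAsFactors = FALSE),
          ds$trials[, c("session", "trial", "choice1", "transition", "state2",
                        "choice2", "outcome", "omitted")])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  truth <- Filter(Negate(is.null), lapply(datasets, function(ds) {
    if (is.null(ds$true_params)) return(NULL)
    c(list(subject_id = ds$subject_id, valence = ds$valence),
      unclass(ds$true_params))
  }))
  if (length(truth)) {
    jsonlite::write_json(truth, sub("\\.csv$", ".params.json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read subject datasets from a trial-log CSV
#'
#' Inverse of [write_subjects_csv()]; splits rows into one `subject_dataset`
#' per subject x valence. True parameters are re-attached from the sidecar
#' JSON when it exists.
#'
#' @param path CSV path.
#' @return named list of `subject_dataset`s (names `subject_valence`).
#' @export
read_subjects_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(canonical_columns, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  sidecar <- sub("\\.csv$", ".params.json", path)
  truth <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  truth_key <- vapply(truth, function(x) paste(x$subject_id, x$valence, sep = "_"), "")
  out <- list()
  for (key in unique(paste(df$subject_id, df$valence, sep = "_"))) {
    rows <- df[paste(df$subject_id, df$valence, sep = "_") == key, , drop = FALSE]
    rows <- rows[order(rows$trial), , drop = FALSE]
    if (anyDuplicated(rows$trial)) stop("duplicate trial indices for ", key)
    tp <- NULL
    hit <- which(truth_key == key)
    if (length(hit) == 1) {
      x <- truth[[hit]]
      tp <- agent_params(x$alpha, x$beta, x$rho, x$omega, x$lam)
    }
    out[[key]] <- structure(list(
      subject_id = rows$subject_id[1], group = rows$group[1],
      valence = rows$valence[1],
      trials = data.frame(trial = as.integer(rows$trial),
                          session = as.integer(rows$session),
                          choice1 = rows$choice1, transition = rows$transition,
                          state2 = rows$state2, choice2 = rows$choice2,
                          outcome = as.numeric(rows$outcome),
                          omitted = as.logical(rows$omitted),
                          stringsAsFactors = FALSE),
      true_params = tp), class = "subject_dataset")
  }
  out
}

#' Serialize a task configuration to JSON
#'
#' @param config a [task_config()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to file).
#' @export
task_config_json <- function(config, path = NULL) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
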
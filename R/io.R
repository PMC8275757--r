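# CSV/JSON interchange with schema validation.
#
# Canonical interchange is UTF-8 CSV with a header row; nested results go to
# JSON. An EyeLink-ASC sample export can be ingested by renaming its columns
# to the pupil-sample schema below (see the converter mapping in
# read_pupil_csv's docs); parsing the native binary format is out of scope.

check_columns <- function(df, spec, file) {
  miss <- setdiff(names(spec), names(df))
  if (length(miss))
    pc_stop_data(file, ": missing column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), names(spec))
  if (length(extra))
    warning(file, ": unknown extra column(s) preserved: ",
            paste(extra, collapse = ", "))
  for (cl in names(spec)) {
    ok <- switch(spec[[cl]],
                 numeric = is.numeric(df[[cl]]),
                 integer = is.numeric(df[[cl]]),
                 character = is.character(df[[cl]]) || is.factor(df[[cl]]),
                 logical = is.logical(df[[cl]]) || all(df[[cl]] %in% c(0, 1, NA)))
    if (!ok) pc_stop_data(file, ": column ", cl, " must be ", spec[[cl]])
  }
  invisible(df)
}

check_range <- function(df, col, lo, hi, file, integer = FALSE) {
  x <- df[[col]][!is.na(df[[col]])]
  bad <- x < lo | x > hi | (integer & x != round(x))
  if (any(bad)) {
    row <- which(!is.na(df[[col]]))[which(bad)[1]]
    pc_stop_data(file, ": column ", col, " out of range [", lo, ", ", hi,
                 "] at row ", row, " (value ", x[which(bad)[1]], ")")
  }
  invisible(df)
}

#' Read / write pupil sample CSV
#'
#' Schema: \code{participant_id, t_ms, diameter, lost} (\code{lost} in
#' \{0, 1\}; if the column is absent all samples are taken as valid, with a
#' warning). For EyeLink ASC-derived exports map: sample time -> t_ms,
#' pupil size -> diameter, blink/missing marker -> lost.
#'
#' @param path CSV file.
#' @return a [pupil_run()]. The sampling rate is inferred from the (uniform)
#'   time grid.
#' @export
read_pupil_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"lost" %in% names(df)) {
    warning(path, ": no 'lost' column; assuming all samples valid")
    df$lost <- 0
  }
  check_columns(df, list(participant_id = "character", t_ms = "numeric",
                         diameter = "numeric", lost = "logical"), path)
  dt <- diff(df$t_ms)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-6))
    pc_stop_data(path, ": t_ms must be a strictly increasing uniform grid")
  fs <- 1000 / dt[1]
  pupil_run(ifelse(df$lost == 1, NA_real_, df$diameter), fs,
            loss_flags = df$lost == 1,
            participant_id = df$participant_id[1])
}

#' @rdname read_pupil_csv
#' @param run a [pupil_run()].
#' @export
write_pupil_csv <- function(run, path) {
  utils::write.csv(data.frame(participant_id = run$participant_id,
                              t_ms = pupil_time(run),
                              diameter = run$diameter,
                              lost = as.integer(run$loss_flags)),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write trial event CSV
#'
#' Schema: \code{participant_id, trial_id, block_type, condition, valence,
#' adaptation_onset_ms, stimulus_onset_ms, rating} (rating may be empty).
#'
#' @param path CSV file.
#' @return event data.frame (validated).
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, list(participant_id = "character", trial_id = "integer",
                         block_type = "character", condition = "character",
                         valence = "character",
                         adaptation_onset_ms = "numeric",
                         stimulus_onset_ms = "numeric", rating = "integer"),
                path)
  check_range(df, "rating", 1, 9, path, integer = TRUE)
  bad <- !df$condition %in% c("view", "reappraise")
  if (any(bad)) pc_stop_data(path, ": bad condition at row ", which(bad)[1])
  bad <- !df$valence %in% c("positive", "negative", "neutral")
  if (any(bad)) pc_stop_data(path, ": bad valence at row ", which(bad)[1])
  df
}

#' @rdname read_events_csv
#' @param events event data.frame; a \code{participant_id} column is added
#'   when absent.
#' @param participant_id id used when the table lacks the column.
#' @export
write_events_csv <- function(events, path, participant_id = NULL) {
  if (!"participant_id" %in% names(events))
    events <- cbind(participant_id = participant_id, events)
  utils::write.csv(events, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write post-task ratings CSV
#'
#' Schema: \code{participant_id, stimulus_id, valence, view_rating,
#' reappraise_rating} (ratings 1..9).
#'
#' @param path CSV file.
#' @return ratings data.frame (validated).
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, list(participant_id = "character", stimulus_id = "integer",
                         valence = "character", view_rating = "integer",
                         reappraise_rating = "integer"), path)
  check_range(df, "view_rating", 1, 9, path, integer = TRUE)
  check_range(df, "reappraise_rating", 1, 9, path, integer = TRUE)
  df
}

#' @rdname read_ratings_csv
#' @param ratings ratings data.frame.
#' @param participant_id id used when the table lacks the column.
#' @export
write_ratings_csv <- function(ratings, path, participant_id = NULL) {
  if (!"participant_id" %in% names(ratings))
    ratings <- cbind(participant_id = participant_id, ratings)
  utils::write.csv(ratings, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write dietary choice CSV
#'
#' Schema: \code{participant_id, trial_id, challenge_flag, food_type,
#' choice} (choice yes/no, empty = missed response).
#'
#' @param path CSV file.
#' @return choices data.frame (validated).
#' @export
read_choices_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, list(participant_id = "character", trial_id = "integer",
                         challenge_flag = "logical", food_type = "character",
                         choice = "character"), path)
  df$challenge_flag <- df$challenge_flag == 1 | df$challenge_flag == TRUE
  df$choice[df$choice == ""] <- NA
  bad <- !is.na(df$choice) & !df$choice %in% c("yes", "no")
  if (any(bad)) pc_stop_data(path, ": bad choice at row ", which(bad)[1])
  df
}

#' @rdname read_choices_csv
#' @param choices choices data.frame.
#' @param participant_id id used when the table lacks the column.
#' @export
write_choices_csv <- function(choices, path, participant_id = NULL) {
  if (!"participant_id" %in% names(choices))
    choices <- cbind(participant_id = participant_id, choices)
  df <- choices
  df$challenge_flag <- as.integer(df$challenge_flag)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write the per-participant score table CSV
#'
#' @param path CSV file.
#' @return a \code{score_table} data.frame.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, list(participant_id = "character", PDI = "numeric",
                         RS = "numeric", AffectiveDistance = "numeric",
                         HCS = "numeric", Age = "numeric",
                         TaskOrder = "character"), path)
  check_range(df, "HCS", 0, 100, path)
  class(df) <- c("score_table", "data.frame")
  df
}

#' @rdname read_scores_csv
#' @param scores a \code{score_table}.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a cluster test result to JSON (+ t-curve CSV side file)
#'
#' @param result a \code{cluster_test_result}.
#' @param path JSON output path; the t curve goes to the same path with
#'   extension \code{_tcurve.csv}.
#' @export
write_cluster_json <- function(result, path) {
  side <- sub("\\.json$", "_tcurve.csv", path)
  utils::write.csv(data.frame(time_ms = result$times_ms, t = result$t_curve),
                   side, row.names = FALSE)
  out <- result[c("threshold", "n_iterations", "flip_mode", "tail", "seed",
                  "alpha", "significant_window", "null_max_sizes")]
  out$clusters <- result$clusters
  out$t_curve_file <- basename(side)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
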
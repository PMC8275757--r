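#' Continuous pupil recording for one participant
#'
#' Container for a uniformly sampled pupil-diameter trace with a per-sample
#' signal-loss mask. Time is implicit: sample \code{i} is at
#' \code{(i-1) * 1000 / sampling_rate} ms since run start.
#'
#' @param diameter numeric vector, pupil diameter (device units, or z-units
#'   once standardised). Must be finite wherever \code{loss_flags} is FALSE;
#'   lost samples may carry the \code{NA} sentinel.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param loss_flags logical vector, TRUE where the sample is invalid
#'   (blink / tracker loss). Defaults to all-valid.
#' @param participant_id identifier string.
#' @param standardized logical flag, TRUE after [zscore_run()].
#' @param units_label free-text unit label.
#' @return an object of class \code{pupil_run}.
#' @seealso [pupil_time()], [detect_loss_segments()], [interpolate_loss()]
#' @export
pupil_run <- function(diameter, sampling_rate,
                      loss_flags = rep(FALSE, length(diameter)),
                      participant_id = "p01",
                      standardized = FALSE,
                      units_label = "a.u.") {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    pc_stop_config("sampling_rate must be a single positive number")
  if (length(loss_flags) != length(diameter))
    pc_stop_data("loss_flags and diameter must have equal length")
  loss_flags <- as.logical(loss_flags)
  if (anyNA(loss_flags)) pc_stop_data("loss_flags must not contain NA")
  bad <- !loss_flags & !is.finite(diameter)
  if (any(bad))
    pc_stop_data("diameter must be finite wherever loss_flags is FALSE (first offence at sample ",
                 which(bad)[1], ")")
  structure(
    list(participant_id = as.character(participant_id),
         sampling_rate = as.numeric(sampling_rate),
         diameter = as.numeric(diameter),
         loss_flags = loss_flags,
         standardized = isTRUE(standardized),
         units_label = as.character(units_label)),
    class = "pupil_run")
}

#' Sample times of a pupil run
#'
#' @param run a [pupil_run()].
#' @return numeric vector of times in ms since run start (uniform grid).
#' @export
pupil_time <- function(run) {
  stopifnot(inherits(run, "pupil_run"))
  (seq_along(run$diameter) - 1) * 1000 / run$sampling_rate
}

#' @export
print.pupil_run <- function(x, ...) {
  n <- length(x$diameter)
  cat(sprintf("<pupil_run> %s: %d samples @ %g Hz (%.1f min), %.2f%% lost%s\n",
              x$participant_id, n, x$sampling_rate,
              n / x$sampling_rate / 60, 100 * mean(x$loss_flags),
              if (x$standardized) ", z-scored" else ""))
  invisible(x)
}
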
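# Preprocessing: loss-mask widening + linear interpolation, within-run
# z-scoring, event-locked epoching with pre-stimulus baseline correction.

#' Detect (widened) signal-loss segments
#'
#' Implements the mask-widening chain used for blink handling: the binary
#' loss vector is convolved with a truncated Gaussian window (given FWHM),
#' the smoothed vector is ceiled back to a \{0,1\} box-car, and first
#' differences of the box-car give segment starts and ends. The returned
#' segments are therefore a superset of the raw loss spans (each widened by
#' the kernel half-support) and spans closer than the kernel support merge.
#'
#' @param loss_flags logical vector (TRUE = lost sample).
#' @param sampling_rate Hz.
#' @param fwhm_ms full width at half maximum of the Gaussian window, ms.
#'   The kernel is truncated at +/- 3 sigma, sigma = FWHM / 2.3548.
#' @return integer matrix with columns \code{start}, \code{end}: half-open,
#'   1-based sample index intervals \code{[start, end)}. Zero rows if no
#'   loss. If every sample is lost the single full-run segment carries the
#'   attribute \code{unrecoverable = TRUE}.
#' @export
detect_loss_segments <- function(loss_flags, sampling_rate, fwhm_ms = 200) {
  if (fwhm_ms <= 0) pc_stop_config("fwhm_ms must be positive")
  loss_flags <- as.logical(loss_flags)
  n <- length(loss_flags)
  if (n < 1) pc_stop_data("loss_flags must have length >= 1")
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (!any(loss_flags)) return(empty)
  if (all(loss_flags)) {
    seg <- matrix(c(1L, n + 1L), ncol = 2, dimnames = list(NULL, c("start", "end")))
    attr(seg, "unrecoverable") <- TRUE
    return(seg)
  }
  sigma_smp <- (fwhm_ms / 2.3548) * sampling_rate / 1000
  r <- as.integer(ceiling(3 * sigma_smp))
  # The truncated Gaussian is strictly positive on [-r, r], so the ceiled
  # smoothed mask is 1 exactly where some lost sample lies within r bins:
  # the convolve -> ceil -> diff chain reduces to dilating each raw loss
  # span by r and merging overlaps. Equivalence to the direct convolution
  # is covered by the test-suite oracle.
  d <- diff(c(0L, as.integer(loss_flags), 0L))
  starts <- pmax(1L, which(d == 1L) - r)
  ends <- pmin(n + 1L, which(d == -1L) + r)   # half-open [start, end)
  if (length(starts) > 1L) {
    keep <- c(TRUE, starts[-1L] > cummax(ends[-length(ends)]))
    grp <- cumsum(keep)
    starts <- as.integer(tapply(starts, grp, min))
    ends <- as.integer(tapply(ends, grp, max))
  }
  cbind(start = starts, end = ends)
}

#' Linearly interpolate loss segments
#'
#' Each segment is replaced by the straight line joining the last valid
#' sample before it and the first valid sample at/after its end; segments
#' touching a run boundary are filled with the nearest valid value.
#' \code{loss_flags} are preserved for audit.
#'
#' @param run a [pupil_run()].
#' @param segments segment matrix from [detect_loss_segments()]; defaults to
#'   detecting on \code{run$loss_flags} with the standard 200-ms FWHM.
#' @param fwhm_ms passed to [detect_loss_segments()] when \code{segments} is
#'   not supplied.
#' @return the run with interpolated diameter; attribute
#'   \code{"interpolated_fraction"} reports the fraction of samples replaced.
#' @export
interpolate_loss <- function(run, segments = NULL, fwhm_ms = 200) {
  stopifnot(inherits(run, "pupil_run"))
  if (is.null(segments))
    segments <- detect_loss_segments(run$loss_flags, run$sampling_rate, fwhm_ms)
  if (isTRUE(attr(segments, "unrecoverable")))
    pc_stop_data("run ", run$participant_id, ": no valid samples to interpolate from")
  x <- run$diameter
  n <- length(x)
  filled <- 0L
  if (nrow(segments)) {
    for (j in seq_len(nrow(segments))) {
      s <- segments[j, "start"]; e <- segments[j, "end"]
      span <- s:(e - 1L)
      if (s == 1L && e > n) pc_stop_data("segment covers the whole run")
      if (s == 1L) {
        x[span] <- x[e]
      } else if (e > n) {
        x[span] <- x[s - 1L]
      } else {
        w <- (seq_along(span)) / (e - (s - 1L))
        x[span] <- x[s - 1L] + w * (x[e] - x[s - 1L])
      }
      filled <- filled + length(span)
    }
  }
  if (anyNA(x)) pc_stop_data("sentinel values remain outside detected segments")
  run$diameter <- x
  attr(run, "interpolated_fraction") <- filled / n
  run
}

#' Z-score a pupil run across the whole recording
#'
#' Standardises the full continuous trace (mean 0, SD 1 over the entire
#' run), giving all participants a common frame of reference.
#'
#' @param run an interpolated [pupil_run()] (no sentinel values).
#' @return the standardised run (\code{standardized = TRUE}).
#' @export
zscore_run <- function(run) {
  stopifnot(inherits(run, "pupil_run"))
  if (anyNA(run$diameter))
    pc_stop_data("run contains sentinel values; interpolate first")
  s <- stats::sd(run$diameter)
  if (!is.finite(s) || s == 0) pc_stop_data("zero-variance run cannot be z-scored")
  run$diameter <- (run$diameter - mean(run$diameter)) / s
  run$standardized <- TRUE
  run$units_label <- "z"
  run
}

#' Epoch a run around stimulus onsets and baseline-correct
#'
#' Cuts one epoch per event-table row on the window \code{[window[1],
#' window[2])} ms relative to stimulus onset (the adaptation period is
#' negative time) and subtracts from each epoch its mean over the baseline
#' interval (default: the 500 ms before stimulus onset).
#'
#' @param run a standardised [pupil_run()].
#' @param events event table with at least \code{trial_id},
#'   \code{stimulus_onset_ms}, \code{condition}, \code{valence}.
#' @param window length-2 numeric, ms relative to stimulus onset (half-open).
#' @param baseline length-2 numeric, ms; the baseline interval
#'   \code{[baseline[1], baseline[2])}.
#' @param bin_width_ms optional epoch bin width, ms. Default: the native
#'   sample period. A finer grid (e.g. 1 ms at 500 Hz) is produced by linear
#'   interpolation of the trace.
#' @return object of class \code{trial_epochs}: list with \code{matrix}
#'   (trials x bins, z-units), \code{times_ms} (bin times relative to onset),
#'   \code{events}, \code{bin_width_ms}, \code{baseline_corrected}.
#' @export
epoch_and_baseline <- function(run, events, window = c(-500, 7000),
                               baseline = c(-500, 0), bin_width_ms = NULL) {
  stopifnot(inherits(run, "pupil_run"))
  need <- c("trial_id", "stimulus_onset_ms", "condition", "valence")
  miss <- setdiff(need, names(events))
  if (length(miss)) pc_stop_data("event table lacks column(s): ",
                                 paste(miss, collapse = ", "))
  native <- 1000 / run$sampling_rate
  bw <- bin_width_ms %||% native
  if (bw <= 0) pc_stop_config("bin_width_ms must be positive")
  times <- seq(window[1], window[2] - bw, by = bw)
  n <- length(run$diameter)
  t_run <- pupil_time(run)

  native_grid <- isTRUE(all.equal(bw, native)) &&
    all(abs(events$stimulus_onset_ms / native -
              round(events$stimulus_onset_ms / native)) < 1e-9)
  mat <- matrix(NA_real_, nrow(events), length(times))
  for (k in seq_len(nrow(events))) {
    t_abs <- events$stimulus_onset_ms[k] + times
    if (t_abs[1] < 0 || t_abs[length(t_abs)] > t_run[n])
      pc_stop_data("trial ", events$trial_id[k], ": epoch window exceeds run bounds")
    if (native_grid) {
      i0 <- as.integer(round(t_abs[1] / native)) + 1L
      mat[k, ] <- run$diameter[i0:(i0 + length(times) - 1L)]
    } else {
      mat[k, ] <- stats::approx(t_run, run$diameter, xout = t_abs)$y
    }
  }
  bl <- times >= baseline[1] & times < baseline[2]
  if (!any(bl)) pc_stop_config("baseline interval contains no bins")
  mat <- mat - rowMeans(mat[, bl, drop = FALSE])

  structure(list(matrix = mat, times_ms = times, events = events,
                 bin_width_ms = bw, baseline_corrected = TRUE,
                 participant_id = run$participant_id),
            class = "trial_epochs")
}

#' @export
print.trial_epochs <- function(x, ...) {
  cat(sprintf("<trial_epochs> %s: %d trials x %d bins (%g ms), window [%g, %g) ms%s\n",
              x$participant_id %||% "?", nrow(x$matrix), ncol(x$matrix),
              x$bin_width_ms, min(x$times_ms), max(x$times_ms) + x$bin_width_ms,
              if (isTRUE(x$baseline_corrected)) ", baseline-corrected" else ""))
  invisible(x)
}

#' Moving-average smoothing of trial epochs
#'
#' Centred boxcar smoothing of each epoch; at the edges the window shrinks
#' to the available bins. Optional: the cluster statistics are insensitive
#' to this step, so the pipeline default leaves it off.
#'
#' @param epochs a \code{trial_epochs} object.
#' @param width_ms boxcar width in ms (>= one bin).
#' @return smoothed \code{trial_epochs}.
#' @export
moving_average <- function(epochs, width_ms) {
  stopifnot(inherits(epochs, "trial_epochs"))
  w <- as.integer(round(width_ms / epochs$bin_width_ms))
  if (w < 1) pc_stop_config("width_ms must cover at least one bin")
  if (w == 1L) return(epochs)
  half <- w %/% 2
  M <- epochs$matrix
  B <- ncol(M)
  # cumulative-sum sliding mean with shrinking edge windows
  cs <- cbind(0, t(apply(M, 1, cumsum)))
  lo <- pmax(0L, seq_len(B) - half - 1L)
  hi <- pmin(B, seq_len(B) + (w - half - 1L))
  sm <- (cs[, hi + 1L, drop = FALSE] - cs[, lo + 1L, drop = FALSE]) /
    rep(hi - lo, each = nrow(M))
  epochs$matrix <- sm
  epochs
}

#' Full preprocessing of one run
#'
#' Chains [detect_loss_segments()], [interpolate_loss()], [zscore_run()] and
#' [epoch_and_baseline()].
#'
#' @inheritParams epoch_and_baseline
#' @inheritParams interpolate_loss
#' @param zscore set FALSE to skip within-run standardisation (amplitudes
#'   then stay in generative/device units; useful for exactness checks).
#' @return a \code{trial_epochs} object.
#' @export
preprocess_run <- function(run, events, window = c(-500, 7000),
                           baseline = c(-500, 0), bin_width_ms = NULL,
                           fwhm_ms = 200, zscore = TRUE) {
  segs <- detect_loss_segments(run$loss_flags, run$sampling_rate, fwhm_ms)
  run <- interpolate_loss(run, segs)
  if (zscore) run <- zscore_run(run)
  epoch_and_baseline(run, events, window, baseline, bin_width_ms)
}

#' Preprocess every participant of a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @inheritParams preprocess_run
#' @return named list of \code{trial_epochs}, one per participant.
#' @export
preprocess_cohort <- function(cohort, window = c(-500, 7000),
                              baseline = c(-500, 0), bin_width_ms = NULL,
                              fwhm_ms = 200, zscore = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  lapply(cohort$participants, function(p)
    preprocess_run(p$run, p$events, window, baseline, bin_width_ms, fwhm_ms, zscore))
}
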
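# Shared fixture builders. Everything is generated in code; no data files.

# small, fast cohort configuration (structure identical to the default task,
# only size/rate reduced)
tiny_config <- function(seed, n = 6, fs = 50, ...) {
  cohort_config(n_participants = n, sampling_rate = fs, seed = seed, ...)
}

# deterministic "clean" cohort: no noise, no drift, no blinks, no arousal
clean_config <- function(seed, n = 4, fs = 100, arousal_amplitude = 0, ...) {
  cohort_config(n_participants = n, sampling_rate = fs, seed = seed,
                noise_sd = 0, drift_sd = 0, blink_rate = 0,
                arousal_amplitude = arousal_amplitude, ...)
}

# wrap a plain matrix as a contrast on a given bin grid (ms)
as_contrast <- function(M, bin_ms = 20, t0 = 0) {
  structure(M, times_ms = t0 + (seq_len(ncol(M)) - 1) * bin_ms,
            bin_width_ms = bin_ms,
            class = c("pupil_contrast", class(M)))
}

# brute-force oracle for the loss-mask widening chain: direct truncated
# Gaussian convolution -> ceil -> diff (the construction the fast
# implementation must reproduce)
oracle_loss_segments <- function(flags, fs, fwhm_ms = 200) {
  n <- length(flags)
  sigma <- (fwhm_ms / 2.3548) * fs / 1000
  r <- as.integer(ceiling(3 * sigma))
  kern <- dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  x <- c(rep(0, r), as.numeric(flags), rep(0, r))
  sm <- vapply(seq_len(n), function(i) sum(x[i:(i + 2 * r)] * rev(kern)),
               numeric(1))
  box <- as.integer(ceiling(pmin(1, pmax(0, sm))) > 0)
  d <- diff(c(0L, box, 0L))
  cbind(start = which(d == 1L), end = which(d == -1L))
}

# score table with RS an exact linear function of the predictors
linear_scores <- function(n, b = c(1.8, 0.4, 0.3, 0.2), noise_sd = 0,
                          seed = 1) {
  set.seed(seed)
  pdi <- rnorm(n); ad <- runif(n, 1, 4)
  pdi_s <- (pdi - mean(pdi)) / sd(pdi)
  ad_s <- (ad - mean(ad)) / sd(ad)
  rs <- b[1] + b[2] * pdi_s + b[3] * ad_s + b[4] * pdi_s * ad_s +
    rnorm(n, 0, noise_sd)
  structure(data.frame(participant_id = sprintf("p%03d", seq_len(n)),
                       PDI = pdi, RS = rs, AffectiveDistance = ad,
                       HCS = runif(n, 30, 90),
                       Age = round(rnorm(n, 23, 2)),
                       TaskOrder = rep(c("emotion-first", "diet-first"),
                                       length.out = n),
                       stringsAsFactors = FALSE),
            class = c("score_table", "data.frame"))
}
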
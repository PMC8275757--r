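# Synthetic cohort generator.
#
# Emulates the structure of a combined emotion-reappraisal + dietary-choice
# session: five blocks (reappraise positive/negative, view positive/negative/
# neutral) of 20 trials each, 1 s phase-scrambled adaptation + 7 s stimulus,
# jittered 1-5 s ITIs, SAM ratings on a 1-9 scale, and a 100-trial dietary
# health-challenge run. A latent self-control capacity c_i ~ N(0, capacity_sd)
# drives (a) the amplitude of a regulation-locked pupil dilation component,
# (b) the rating shift toward neutral under reappraisal and (c) the
# probability of self-controlled dietary challenge choices.

#' Configuration of a synthetic self-control cohort
#'
#' All timing constants default to the task described in the package vignette:
#' 5 block types x 20 trials, 1 s adaptation, 7 s stimulus, 4 s rating window,
#' inter-trial intervals uniform on 1-5 s, 15 s block breaks, sampled at
#' 500 Hz (a run of ~26 min). Effect-size defaults are chosen so that a
#' default cohort of 34 participants produces a group-level
#' regulation cluster of realistic strength (group mean plateau 0.16 z,
#' between-participant SD 0.25 z).
#'
#' @param n_participants number of participants (>= 3).
#' @param sampling_rate pupil sampling rate, Hz.
#' @param n_trials_per_block trials per block (5 block types, one block each).
#' @param stimulus_duration stimulus (view/reappraise) period, s.
#' @param adaptation_duration phase-scrambled adaptation period, s.
#' @param rating_duration rating screen duration, s.
#' @param iti_range inter-trial interval range, s (uniform jitter).
#' @param block_break pause between blocks, s.
#' @param capacity_sd SD of the latent capacity c_i.
#' @param pdi_loading z-units of regulation plateau amplitude per unit c_i.
#' @param regulation_mean group-mean regulation plateau amplitude, z-units.
#' @param rs_loading SAM points of reappraisal rating shift per unit c_i.
#' @param rs_base group-mean reappraisal shift toward neutral, SAM points.
#' @param hcs_loading percentage points of challenge-success probability per
#'   unit c_i.
#' @param hcs_base group-mean challenge-success probability, percent.
#' @param regulation_onset regulation ramp onset, s after stimulus onset.
#' @param regulation_window numeric length-2, plateau of the regulation
#'   component, s after stimulus onset; must lie inside
#'   \code{[0, stimulus_duration]}.
#' @param arousal_amplitude amplitude of the stimulus-driven (emotional
#'   arousal) dilation transient, z-units; identical in view and reappraise
#'   trials of equal valence, absent for neutral stimuli.
#' @param arousal_peak time-to-peak of the arousal transient, s.
#' @param noise_sd stationary SD of the measurement/physiological noise,
#'   z-units.
#' @param noise_tau time constant of the noise autocorrelation, s. Pupil
#'   series are band-limited, so the noise is AR(1)-smooth; 0 gives white
#'   noise (unrealistic: it cannot produce cluster extents of the scale
#'   seen in real contrasts).
#' @param drift_sd stationary SD of the slow AR(1) baseline drift, z-units.
#' @param drift_tau time constant of the baseline drift, s.
#' @param blink_rate blink/loss events per minute.
#' @param blink_duration_mean mean loss-segment duration, ms.
#' @param blink_duration_shape gamma shape of the duration distribution.
#' @param rating_noise SD of pre-discretisation rating noise, SAM points.
#' @param n_choice_trials dietary-choice trials (half of them challenges).
#' @param choice_miss_rate probability a dietary response is not logged in
#'   time (missing).
#' @param reg_arousal_reduction optional fraction (0-1) by which the
#'   emotional-arousal component is attenuated on reappraise trials;
#'   default 0 (off).
#' @param seed integer RNG seed. Mandatory: reproducibility is part of the
#'   generator's contract.
#' @return a list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_participants = 34,
                          sampling_rate = 500,
                          n_trials_per_block = 20,
                          stimulus_duration = 7,
                          adaptation_duration = 1,
                          rating_duration = 4,
                          iti_range = c(1, 5),
                          block_break = 15,
                          capacity_sd = 1,
                          pdi_loading = 0.25,
                          regulation_mean = 0.16,
                          rs_loading = 0.5,
                          rs_base = 2,
                          hcs_loading = 12,
                          hcs_base = 62,
                          regulation_onset = 2.0,
                          regulation_window = c(3.4, 5.6),
                          arousal_amplitude = 0.5,
                          arousal_peak = 1.2,
                          noise_sd = 0.5,
                          noise_tau = 0.3,
                          drift_sd = 0.2,
                          drift_tau = 20,
                          blink_rate = 15,
                          blink_duration_mean = 150,
                          blink_duration_shape = 8,
                          rating_noise = 1,
                          n_choice_trials = 100,
                          choice_miss_rate = 0.02,
                          reg_arousal_reduction = 0,
                          seed = NULL) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (is.null(cfg$seed))
    pc_stop_config("seed is mandatory: a synthetic cohort must be reproducible")
  if (!is_count(cfg$seed)) pc_stop_config("seed must be a single integer")
  if (!is_count(cfg$n_participants) || cfg$n_participants < 3)
    pc_stop_config("n_participants must be an integer >= 3")
  for (f in c("sampling_rate", "stimulus_duration", "adaptation_duration",
              "rating_duration", "block_break"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      pc_stop_config(f, " must be positive")
  for (f in c("capacity_sd", "noise_sd", "noise_tau", "drift_sd", "rating_noise"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      pc_stop_config(f, " must be >= 0")
  if (cfg$blink_rate < 0) pc_stop_config("blink_rate must be >= 0")
  w <- cfg$regulation_window
  if (length(w) != 2 || w[1] >= w[2] || w[1] < 0 || w[2] > cfg$stimulus_duration)
    pc_stop_config("regulation_window must lie inside [0, stimulus_duration]")
  if (cfg$regulation_onset < 0 || cfg$regulation_onset > w[1])
    pc_stop_config("regulation_onset must lie in [0, regulation_window[1]]")
  if (length(cfg$iti_range) != 2 || cfg$iti_range[1] > cfg$iti_range[2] ||
      cfg$iti_range[1] < 0)
    pc_stop_config("iti_range must be a nondecreasing nonnegative pair")
  if (cfg$reg_arousal_reduction < 0 || cfg$reg_arousal_reduction > 1)
    pc_stop_config("reg_arousal_reduction must be in [0, 1]")
  invisible(cfg)
}

BLOCK_TYPES <- data.frame(
  block_type = c("ReappraisePositive", "ReappraiseNegative",
                 "ViewPositive", "ViewNegative", "ViewNeutral"),
  condition = c("reappraise", "reappraise", "view", "view", "view"),
  valence = c("positive", "negative", "positive", "negative", "neutral"),
  stringsAsFactors = FALSE)

VALENCE_MEAN <- c(negative = 2.25, positive = 7.25, neutral = 5)

# stimulus-driven arousal transient, peak 1 at t = peak (gamma-like bump)
arousal_bump <- function(t_s, peak) {
  ifelse(t_s <= 0, 0, (t_s / peak) * exp(1 - t_s / peak))
}

# regulation component: linear ramp from onset to the plateau start, flat
# plateau, linear decay from the plateau end to stimulus offset
regulation_shape <- function(t_s, onset, window, offset) {
  out <- numeric(length(t_s))
  ramp <- t_s >= onset & t_s < window[1]
  out[ramp] <- (t_s[ramp] - onset) / (window[1] - onset)
  out[t_s >= window[1] & t_s <= window[2]] <- 1
  decay <- t_s > window[2] & t_s <= offset
  out[decay] <- (offset - t_s[decay]) / (offset - window[2])
  out
}

discretize_sam <- function(x) pmin(9L, pmax(1L, as.integer(round(x))))

#' Generate a synthetic self-control cohort
#'
#' Deterministic given \code{config$seed}. Each participant receives a
#' continuous pupil run (baseline drift + arousal transient on emotional
#' trials + regulation component on reappraise trials + white noise, with
#' blink/loss segments injected), an event table, in-task and post-task SAM
#' ratings for the 40 reappraised stimuli, and a dietary choice table.
#'
#' @param config a [cohort_config()].
#' @return an object of class \code{synthetic_cohort}: list with elements
#'   \code{config}, \code{truth} (data.frame of latent capacity and the
#'   noiseless generative targets \code{true_pdi}, \code{true_rs},
#'   \code{true_hcs}, plus age and task order) and \code{participants}
#'   (named list of per-participant data).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_participants

  capacity <- stats::rnorm(n, 0, cfg$capacity_sd)
  reg_amp <- cfg$regulation_mean + cfg$pdi_loading * capacity
  shift <- pmax(0, cfg$rs_base + cfg$rs_loading * capacity)
  p_success <- pmin(0.98, pmax(0.02, (cfg$hcs_base + cfg$hcs_loading * capacity) / 100))
  age <- round(stats::rnorm(n, 22.6, 2.2))
  task_order <- sample(rep(c("emotion-first", "diet-first"), length.out = n))

  ids <- sprintf("p%02d", seq_len(n))
  participants <- vector("list", n)
  names(participants) <- ids
  for (i in seq_len(n)) {
    participants[[i]] <- simulate_participant(cfg, ids[i], capacity[i],
                                              reg_amp[i], shift[i], p_success[i])
  }

  truth <- data.frame(
    participant_id = ids,
    capacity = capacity,
    true_pdi = reg_amp,
    true_rs = shift,
    true_hcs = 100 * p_success,
    age = age,
    task_order = task_order,
    stringsAsFactors = FALSE)

  structure(list(config = cfg, truth = truth, participants = participants),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants, seed %d, %g Hz\n",
              nrow(x$truth), x$config$seed, x$config$sampling_rate))
  invisible(x)
}

simulate_participant <- function(cfg, id, c_i, reg_amp, shift, p_succ) {
  fs <- cfg$sampling_rate
  smp <- function(sec) as.integer(round(sec * fs))
  adapt_n <- smp(cfg$adaptation_duration)
  stim_n <- smp(cfg$stimulus_duration)
  rating_n <- smp(cfg$rating_duration)
  break_n <- smp(cfg$block_break)
  cue_n <- smp(1)
  lead_n <- smp(5)

  order_idx <- sample(nrow(BLOCK_TYPES))
  blocks <- BLOCK_TYPES[order_idx, , drop = FALSE]
  nt <- cfg$n_trials_per_block
  n_trials <- nt * nrow(blocks)

  adaptation_onset <- integer(n_trials)   # 0-based sample index
  stimulus_onset <- integer(n_trials)
  block_type <- character(n_trials)
  cursor <- lead_n
  k <- 0L
  for (b in seq_len(nrow(blocks))) {
    cursor <- cursor + cue_n
    for (tr in seq_len(nt)) {
      k <- k + 1L
      adaptation_onset[k] <- cursor
      cursor <- cursor + adapt_n
      stimulus_onset[k] <- cursor
      cursor <- cursor + stim_n + rating_n
      cursor <- cursor + smp(stats::runif(1, cfg$iti_range[1], cfg$iti_range[2]))
      block_type[k] <- blocks$block_type[b]
    }
    cursor <- cursor + break_n
  }
  n_samples <- cursor + smp(2)

  events <- data.frame(
    trial_id = seq_len(n_trials),
    block_type = block_type,
    stringsAsFactors = FALSE)
  events$condition <- BLOCK_TYPES$condition[match(block_type, BLOCK_TYPES$block_type)]
  events$valence <- BLOCK_TYPES$valence[match(block_type, BLOCK_TYPES$block_type)]
  events$adaptation_onset_ms <- adaptation_onset * 1000 / fs
  events$stimulus_onset_ms <- stimulus_onset * 1000 / fs

  # --- continuous trace -----------------------------------------------------
  ar1 <- function(sd, tau) {
    if (sd == 0) return(0)
    if (tau <= 0) return(stats::rnorm(n_samples, 0, sd))
    phi <- exp(-1 / (fs * tau))
    innov <- stats::rnorm(n_samples, 0, sd * sqrt(1 - phi^2))
    as.numeric(stats::filter(innov, phi, method = "recursive"))
  }
  diameter <- ar1(cfg$noise_sd, cfg$noise_tau) + ar1(cfg$drift_sd, cfg$drift_tau)
  if (length(diameter) == 1L) diameter <- numeric(n_samples)
  tt <- (seq_len(stim_n) - 1) / fs
  bump <- arousal_bump(tt, cfg$arousal_peak)
  regs <- regulation_shape(tt, cfg$regulation_onset, cfg$regulation_window,
                           cfg$stimulus_duration)
  for (k in seq_len(n_trials)) {
    idx <- stimulus_onset[k] + seq_len(stim_n)
    comp <- 0
    if (events$valence[k] != "neutral") {
      att <- if (events$condition[k] == "reappraise") 1 - cfg$reg_arousal_reduction else 1
      comp <- comp + att * cfg$arousal_amplitude * bump
    }
    if (events$condition[k] == "reappraise") comp <- comp + reg_amp * regs
    diameter[idx] <- diameter[idx] + comp
  }

  run <- pupil_run(diameter, fs, participant_id = id, units_label = "z (generative)")
  if (cfg$blink_rate > 0) {
    run <- inject_loss(run, cfg$blink_rate, cfg$blink_duration_mean,
                       cfg$blink_duration_shape)
  }

  # --- ratings --------------------------------------------------------------
  vmean <- VALENCE_MEAN[events$valence]
  rating_mu <- ifelse(
    events$condition == "reappraise",
    vmean + sign(5 - vmean) * pmin(shift, abs(5 - vmean)),
    vmean)
  events$rating <- discretize_sam(rating_mu + stats::rnorm(n_trials, 0, cfg$rating_noise))

  reap <- events[events$condition == "reappraise", ]
  ratings <- data.frame(
    stimulus_id = seq_len(nrow(reap)),
    valence = reap$valence,
    view_rating = discretize_sam(VALENCE_MEAN[reap$valence] +
                                   stats::rnorm(nrow(reap), 0, cfg$rating_noise)),
    reappraise_rating = reap$rating,
    stringsAsFactors = FALSE)
  rownames(ratings) <- NULL

  # --- dietary choices ------------------------------------------------------
  nc <- cfg$n_choice_trials
  n_ch <- nc %/% 2
  food_type <- sample(c(rep(c("tasty-unhealthy", "healthy-untasty"),
                            length.out = n_ch),
                        rep("aligned", nc - n_ch)))
  challenge <- food_type != "aligned"
  controlled <- stats::runif(nc) < p_succ
  choice <- ifelse(challenge,
                   ifelse(xor(food_type == "tasty-unhealthy", controlled), "yes", "no"),
                   sample(c("yes", "no"), nc, replace = TRUE))
  choice[stats::runif(nc) < cfg$choice_miss_rate] <- NA
  choices <- data.frame(trial_id = seq_len(nc), challenge_flag = challenge,
                        food_type = food_type, choice = choice,
                        stringsAsFactors = FALSE)

  list(participant_id = id, run = run, events = events,
       ratings = ratings, choices = choices, capacity = c_i)
}

#' Inject blink/signal-loss segments into a clean pupil run
#'
#' Loss events are placed by a Poisson process (\code{blink_rate} events per
#' minute) with gamma-distributed durations; lost samples get the \code{NA}
#' sentinel and \code{loss_flags = TRUE}.
#'
#' @param run a [pupil_run()] with no pre-existing loss.
#' @param blink_rate events per minute (>= 0; 0 returns \code{run} unchanged).
#' @param blink_duration_mean mean event duration, ms.
#' @param blink_duration_shape gamma shape parameter of the duration
#'   distribution.
#' @param seed optional seed; \code{NULL} (default) continues the current RNG
#'   stream, which is what [generate_cohort()] relies on.
#' @return the run with loss injected; the realised lost fraction is attached
#'   as attribute \code{"lost_fraction"}.
#' @export
inject_loss <- function(run, blink_rate, blink_duration_mean = 150,
                        blink_duration_shape = 8, seed = NULL) {
  stopifnot(inherits(run, "pupil_run"))
  if (blink_rate < 0) pc_stop_config("blink_rate must be >= 0")
  if (any(run$loss_flags)) pc_stop_data("run already contains loss segments")
  if (blink_rate == 0) return(run)
  if (!is.null(seed)) set.seed(seed)

  n <- length(run$diameter)
  fs <- run$sampling_rate
  minutes <- n / fs / 60
  n_ev <- stats::rpois(1, blink_rate * minutes)
  if (n_ev > 0) {
    starts <- sort(sample.int(n, n_ev, replace = TRUE))
    dur_ms <- stats::rgamma(n_ev, shape = blink_duration_shape,
                            scale = blink_duration_mean / blink_duration_shape)
    lens <- pmax(1L, as.integer(round(dur_ms / 1000 * fs)))
    for (j in seq_len(n_ev)) {
      span <- starts[j]:min(n, starts[j] + lens[j] - 1L)
      run$loss_flags[span] <- TRUE
    }
    run$diameter[run$loss_flags] <- NA_real_
  }
  attr(run, "lost_fraction") <- mean(run$loss_flags)
  run
}
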
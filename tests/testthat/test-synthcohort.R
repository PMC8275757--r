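test_that("configuration is validated", {
  expect_error(cohort_config(), class = "pc_config_error")            # no seed
  expect_error(cohort_config(seed = 1, stimulus_duration = -1),
               class = "pc_config_error")
  expect_error(cohort_config(seed = 1, n_participants = 2),
               class = "pc_config_error")
  expect_error(cohort_config(seed = 1, regulation_window = c(3, 9)),
               class = "pc_config_error")
  expect_error(cohort_config(seed = 1, noise_sd = -0.1),
               class = "pc_config_error")
  expect_s3_class(cohort_config(seed = 1), "cohort_config")
})

test_that("null generator yields flat traces and an identically zero contrast", {
  cfg <- clean_config(seed = 11, n = 4, fs = 50,
                      pdi_loading = 0, regulation_mean = 0)
  ch <- generate_cohort(cfg)
  for (p in ch$participants) expect_true(all(p$run$diameter == 0))
  ep <- preprocess_cohort(ch, zscore = FALSE)
  con <- build_contrast(ep)
  expect_true(all(con == 0))
})

test_that("task structure matches the stated trial grid", {
  cfg <- cohort_config(n_participants = 3, sampling_rate = 500, seed = 5,
                       blink_rate = 0)
  ch <- generate_cohort(cfg)
  p <- ch$participants[[1]]
  # 5 block types x 20 trials
  expect_equal(nrow(p$events), 100)
  expect_equal(sort(unique(p$events$block_type)),
               sort(c("ReappraisePositive", "ReappraiseNegative",
                      "ViewPositive", "ViewNegative", "ViewNeutral")))
  expect_true(all(table(p$events$block_type) == 20))
  # 1 s adaptation before each stimulus onset
  expect_equal(p$events$stimulus_onset_ms - p$events$adaptation_onset_ms,
               rep(1000, 100))
  # 7 s stimulus at 500 Hz -> 3500 samples per stimulus period
  ep <- preprocess_run(p$run, p$events)
  stim_bins <- sum(ep$times_ms >= 0 & ep$times_ms < 7000)
  expect_equal(stim_bins, 3500)
  # ITIs within the jitter range: successive adaptation onsets are at least
  # adaptation + stimulus + rating + 1 s apart
  gaps <- diff(p$events$adaptation_onset_ms)
  in_block <- which(gaps < 20000)  # exclude block-break transitions
  expect_true(all(gaps[in_block] >= (1 + 7 + 4 + 1) * 1000 - 1e-9))
  expect_true(all(gaps[in_block] <= (1 + 7 + 4 + 5) * 1000 + 1e-9))
  # 40 reappraised stimuli (20 per valence), ratings on the 9-point scale
  expect_equal(nrow(p$ratings), 40)
  expect_true(all(table(p$ratings$valence) == 20))
  expect_true(all(p$ratings$view_rating %in% 1:9))
  expect_true(all(p$ratings$reappraise_rating %in% 1:9))
  # 100 dietary trials, challenges only on non-aligned foods
  expect_equal(nrow(p$choices), 100)
  expect_true(all(p$choices$food_type[p$choices$challenge_flag] != "aligned"))
})

test_that("same seed gives bit-identical cohorts", {
  cfg <- tiny_config(seed = 99, n = 4)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- tiny_config(seed = 100, n = 4)
  expect_false(identical(generate_cohort(cfg)$participants[[1]]$run$diameter,
                         generate_cohort(cfg2)$participants[[1]]$run$diameter))
})

test_that("inject_loss matches its closed-form expectation and contracts", {
  run <- pupil_run(rnorm(26 * 60 * 100), sampling_rate = 100)   # 26-min run
  expect_identical(inject_loss(run, blink_rate = 0), run)
  expect_error(inject_loss(run, blink_rate = -1), class = "pc_config_error")

  out <- inject_loss(run, blink_rate = 15, blink_duration_mean = 150, seed = 7)
  # expected lost fraction = rate * mean duration = 15/min * 0.15 s = 3.75%;
  # ~390 events -> generous +/-4 SD band around the Poisson expectation
  expect_gt(attr(out, "lost_fraction"), 0.025)
  expect_lt(attr(out, "lost_fraction"), 0.050)
  expect_true(all(is.na(out$diameter[out$loss_flags])))
  expect_error(inject_loss(out, blink_rate = 5), class = "pc_data_error")
})

test_that("generated outcomes track the latent capacity", {
  ch <- generate_cohort(tiny_config(seed = 21, n = 34))
  sc <- build_score_table(ch)
  # HCS is a noisy monotone readout of capacity (binomial noise over 50
  # challenge trials caps the attainable correlation)
  expect_gt(cor(ch$truth$capacity, sc$HCS, method = "spearman"), 0.6)
  expect_gt(cor(ch$truth$capacity, sc$RS, method = "spearman"), 0.5)
  expect_true(all(sc$HCS >= 0 & sc$HCS <= 100))
})
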
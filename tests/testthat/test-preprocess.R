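test_that("loss-segment detection reproduces the convolution oracle", {
  fs <- 100
  expect_equal(nrow(detect_loss_segments(rep(FALSE, 500), fs)), 0)
  expect_error(detect_loss_segments(logical(0), fs), class = "pc_data_error")
  expect_error(detect_loss_segments(rep(TRUE, 5), fs, fwhm_ms = -1),
               class = "pc_config_error")

  # single lost sample widens to k +/- ceil(3 sigma fs)
  flags <- rep(FALSE, 400); flags[200] <- TRUE
  seg <- detect_loss_segments(flags, fs, fwhm_ms = 200)
  r <- ceiling(3 * (200 / 2.3548) * fs / 1000)
  expect_equal(unname(seg[1, ]), c(200 - r, 200 + r + 1))

  # two spans with a sub-kernel gap merge into one segment
  flags2 <- rep(FALSE, 400); flags2[100:105] <- TRUE; flags2[115:120] <- TRUE
  seg2 <- detect_loss_segments(flags2, fs)
  expect_equal(nrow(seg2), 1)

  # random masks: exact agreement with the brute-force convolution chain
  for (s in 1:8) {
    set.seed(s)
    fl <- runif(300) < 0.03
    if (all(!fl) || all(fl)) next
    expect_equal(unname(detect_loss_segments(fl, fs)),
                 unname(oracle_loss_segments(fl, fs)),
                 info = paste("mask seed", s))
  }

  # all-lost run: one unrecoverable full-run segment
  segall <- detect_loss_segments(rep(TRUE, 50), fs)
  expect_true(isTRUE(attr(segall, "unrecoverable")))
  expect_equal(unname(segall[1, ]), c(1, 51))
})

test_that("linear interpolation is exact on linear signals and bounded on smooth ones", {
  fs <- 100
  x <- seq(0, 10, length.out = 1000)       # linear signal
  fl <- rep(FALSE, 1000); fl[400:450] <- TRUE
  run <- pupil_run(ifelse(fl, NA, x), fs, loss_flags = fl)
  seg <- detect_loss_segments(fl, fs)
  out <- interpolate_loss(run, seg)
  expect_equal(out$diameter, x, tolerance = 1e-12)
  expect_identical(out$loss_flags, fl)     # audit flags preserved

  # boundary gap: constant fill with the nearest valid value
  fl2 <- rep(FALSE, 200); fl2[1:30] <- TRUE
  run2 <- pupil_run(ifelse(fl2, NA, x[1:200]), fs, loss_flags = fl2)
  out2 <- interpolate_loss(run2, detect_loss_segments(fl2, fs))
  first_valid <- max(which(out2$diameter != out2$diameter[1])[1] - 1, 1)
  expect_true(all(out2$diameter[1:first_valid] == out2$diameter[first_valid]))

  # sinusoid with a 200-ms gap: error bounded by |f''|_max (g/2)^2 / 2
  f_hz <- 2
  tt <- seq(0, 5, by = 1 / fs)
  y <- sin(2 * pi * f_hz * tt)
  fl3 <- rep(FALSE, length(tt)); gap <- 250:269; fl3[gap] <- TRUE  # 200 ms
  run3 <- pupil_run(ifelse(fl3, NA, y), fs, loss_flags = fl3)
  out3 <- interpolate_loss(run3, cbind(start = 250L, end = 270L))
  g <- length(gap) / fs
  bound <- (2 * pi * f_hz)^2 * (g / 2)^2 / 2
  expect_lt(max(abs(out3$diameter[gap] - y[gap])), bound + 1e-12)
})

test_that("z-scoring gives run-wide zero mean / unit SD and is affine invariant", {
  set.seed(3)
  run <- pupil_run(5 + rnorm(5000), 100)
  z <- zscore_run(run)
  expect_lt(abs(mean(z$diameter)), 1e-12)
  expect_equal(sd(z$diameter), 1, tolerance = 1e-12)
  expect_true(z$standardized)
  # a.x + b (a > 0) z-scores to the same trace
  run2 <- pupil_run(3.7 * run$diameter - 11, 100)
  expect_equal(zscore_run(run2)$diameter, z$diameter, tolerance = 1e-10)
  expect_error(zscore_run(pupil_run(rep(1, 100), 100)), class = "pc_data_error")
})

test_that("epoching and baseline correction behave per contract", {
  ch <- generate_cohort(tiny_config(seed = 31, n = 3, fs = 500, blink_rate = 0))
  p <- ch$participants[[1]]
  ep <- preprocess_run(p$run, p$events)
  expect_equal(nrow(ep$matrix), 100)             # one row per trial
  expect_equal(ncol(ep$matrix), 3750)            # [-500, 7000) at 2-ms bins
  bl <- ep$times_ms >= -500 & ep$times_ms < 0
  expect_lt(max(abs(rowMeans(ep$matrix[, bl]))), 1e-12)

  # correction subtracts the baseline mean m from every bin
  run <- zscore_run(interpolate_loss(p$run))
  raw <- epoch_and_baseline(run, p$events)
  i0 <- as.integer(p$events$stimulus_onset_ms[1] / 2) + 1L
  seg <- run$diameter[(i0 - 250):(i0 + 3499)]
  m <- mean(seg[1:250])
  expect_equal(raw$matrix[1, ], seg - m, tolerance = 1e-12,
               ignore_attr = TRUE)

  # adding a per-trial constant before correction changes nothing after it
  run_shift <- run
  tr2 <- p$events$stimulus_onset_ms[2]
  idx <- as.integer((tr2 - 500) / 2):(as.integer(tr2 / 2) + 3500)
  run_shift$diameter[idx + 1L] <- run_shift$diameter[idx + 1L] + 4.2
  ep2 <- epoch_and_baseline(run_shift, p$events)
  expect_equal(ep2$matrix[2, ], raw$matrix[2, ], tolerance = 1e-10)

  # out-of-bounds epoch names the trial
  bad <- p$events
  bad$stimulus_onset_ms[7] <- 1e9
  expect_error(epoch_and_baseline(run, bad), "trial 7",
               class = "pc_data_error")
})

test_that("1-ms resampling mode produces the finer grid", {
  ch <- generate_cohort(tiny_config(seed = 32, n = 3, fs = 500, blink_rate = 0))
  p <- ch$participants[[1]]
  ep <- preprocess_run(p$run, p$events, bin_width_ms = 1)
  expect_equal(ncol(ep$matrix), 7500)
  expect_equal(sum(ep$times_ms >= 0 & ep$times_ms < 7000), 7000)
})

test_that("moving average: identity at one bin, constant invariance, 1/w variance", {
  ch <- generate_cohort(clean_config(seed = 33, n = 3, fs = 50))
  ep <- preprocess_cohort(ch)[[1]]
  expect_equal(moving_average(ep, ep$bin_width_ms)$matrix, ep$matrix)
  cst <- ep; cst$matrix[] <- 2.5
  expect_equal(moving_average(cst, 7 * ep$bin_width_ms)$matrix, cst$matrix)
  expect_error(moving_average(ep, 0.1), class = "pc_config_error")

  set.seed(4)
  w <- 9L
  wn <- ep; wn$matrix <- matrix(rnorm(10 * 4000), 10, 4000)
  wn$times_ms <- seq(0, by = ep$bin_width_ms, length.out = 4000)
  sm <- moving_average(wn, w * ep$bin_width_ms)
  interior <- seq(50, 3950)
  ratio <- var(as.numeric(sm$matrix[, interior])) /
    var(as.numeric(wn$matrix[, interior]))
  expect_equal(ratio, 1 / w, tolerance = 0.1)
})

test_that("preprocessing is idempotent on a loss-free standardised run", {
  set.seed(6)
  run <- zscore_run(pupil_run(rnorm(4000), 100))
  again <- zscore_run(interpolate_loss(run, detect_loss_segments(run$loss_flags, 100)))
  expect_equal(again$diameter, run$diameter, tolerance = 1e-12)
})
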
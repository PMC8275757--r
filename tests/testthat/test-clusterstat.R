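test_that("contrast is zero when conditions coincide and cancels shared arousal", {
  # identical view/reappraise epochs -> zero rows
  ch <- generate_cohort(clean_config(seed = 41, n = 4, fs = 50,
                                     pdi_loading = 0, regulation_mean = 0,
                                     arousal_amplitude = 0.8))
  con <- build_contrast(preprocess_cohort(ch, zscore = FALSE))
  # the arousal transient is shared between conditions and cancels exactly
  expect_lt(max(abs(con)), 1e-12)
})

test_that("noiseless cohorts reproduce the generative regulation shape", {
  cfg <- clean_config(seed = 42, n = 5, fs = 100, pdi_loading = 0.3,
                      regulation_mean = 0.2, arousal_amplitude = 0.4)
  ch <- generate_cohort(cfg)
  con <- build_contrast(preprocess_cohort(ch, zscore = FALSE))
  tms <- attr(con, "times_ms") / 1000
  amp <- ch$truth$true_pdi
  plateau <- tms >= 3.4 & tms <= 5.6
  pre <- tms < 2.0
  for (i in seq_len(nrow(con))) {
    expect_equal(unname(con[i, plateau]), rep(amp[i], sum(plateau)),
                 tolerance = 1e-10)
    expect_true(all(abs(con[i, pre]) < 1e-12))
  }
  # ramp value halfway between onset (2.0 s) and plateau start (3.4 s)
  mid <- which.min(abs(tms - 2.7))
  expect_equal(unname(con[, mid]), amp * 0.5, tolerance = 1e-10)
})

test_that("pointwise t matches the textbook formula and its degenerate rules", {
  set.seed(43)
  X <- matrix(rnorm(34 * 60), 34)
  tc <- pointwise_t(as_contrast(X))
  oracle <- apply(X, 2, function(v) mean(v) / (sd(v) / sqrt(length(v))))
  expect_equal(tc, oracle, tolerance = 1e-12)

  same <- as_contrast(matrix(2, 5, 4))
  expect_true(all(pointwise_t(same) == Inf))
  expect_true(all(pointwise_t(as_contrast(matrix(-1, 5, 4))) == -Inf))
  expect_true(all(pointwise_t(as_contrast(matrix(0, 5, 4))) == 0))

  shifted <- pointwise_t(as_contrast(X + 0.5))
  expect_true(all(shifted > tc))
})

test_that("find_clusters agrees with an exhaustive scan", {
  expect_equal(nrow(find_clusters(c(0, 1, 2.9), 3)), 0)
  cl <- find_clusters(c(1, 4, 4, 2, 5), 3)
  expect_equal(cl$start, c(2, 5))
  expect_equal(cl$end, c(3, 5))
  expect_equal(cl$size, c(2, 1))

  scan_oracle <- function(tc, thr) {
    above <- tc > thr
    sizes <- integer(0); starts <- integer(0); cur <- 0L
    for (i in seq_along(above)) {
      if (above[i]) {
        if (cur == 0L) starts <- c(starts, i)
        cur <- cur + 1L
      } else if (cur > 0L) { sizes <- c(sizes, cur); cur <- 0L }
    }
    if (cur > 0L) sizes <- c(sizes, cur)
    list(starts = starts, sizes = sizes)
  }
  for (s in 1:10) {
    set.seed(s)
    tc <- rnorm(200, 2, 1.2)
    got <- find_clusters(tc, 3)
    want <- scan_oracle(tc, 3)
    expect_equal(got$start, want$starts, info = paste("seed", s))
    expect_equal(got$size, want$sizes, info = paste("seed", s))
  }
  # two-sided mode picks up negative excursions
  expect_equal(find_clusters(c(-5, 0, 5), 3, tail = "two")$size, c(1, 1))
})

test_that("permutation null: degenerate inputs, determinism and sign-flip exactness", {
  zero <- as_contrast(matrix(0, 8, 30))
  expect_true(all(permutation_null(zero, n_iter = 50, seed = 1) == 0))
  expect_error(permutation_null(zero, n_iter = 0, seed = 1),
               class = "pc_config_error")

  set.seed(44)
  con <- as_contrast(matrix(rnorm(12 * 40), 12))
  expect_identical(permutation_null(con, 100, seed = 7),
                   permutation_null(con, 100, seed = 7))
  expect_false(identical(permutation_null(con, 100, seed = 7),
                         permutation_null(con, 100, seed = 8)))

  # identical all-positive rows, n = 34: the observed t is +Inf everywhere,
  # so the observed cluster spans every bin; under sign flips a
  # whole-window null cluster needs >= 25 of 34 like signs
  # (P ~ 0.45% per iteration), so p stays tiny
  const <- as_contrast(matrix(2, 34, 25))
  ct <- cluster_test(const, n_iter = 500, seed = 9)
  expect_equal(ct$clusters$size[ct$clusters$primary], 25)
  expect_lte(ct$clusters$p[ct$clusters$primary], 0.02)
  expect_equal(ct$significant_window[1], 0)

  # per-bin flip mode honours the same degenerate contract
  expect_true(all(permutation_null(zero, n_iter = 20, seed = 1,
                                   flip_mode = "per_bin") == 0))
  pb <- permutation_null(con, 50, seed = 3, flip_mode = "per_bin")
  expect_length(pb, 50)
})

test_that("cluster p-values follow the counting definition", {
  expect_equal(cluster_p(5, c(5, 2, 9, 1)), 0.5)
  expect_equal(cluster_p(0, c(0, 3, 7)), 1)
  expect_equal(cluster_p(10, c(5, 2, 9, 1)), 0)
  expect_error(cluster_p(1, integer(0)), class = "pc_data_error")
})

test_that("PDI extraction: zero contrast, exact plateau recovery, window modes", {
  zero <- as_contrast(matrix(0, 6, 350))
  expect_true(all(compute_pdi(zero, NULL)$pdi == 0))
  expect_equal(compute_pdi(zero, NULL)$window_start_s[1], 3.4)
  expect_equal(compute_pdi(zero, NULL)$window_end_s[1], 5.6)

  cfg <- clean_config(seed = 45, n = 5, fs = 100, pdi_loading = 0.3,
                      regulation_mean = 0.2, capacity_sd = 0.1)
  ch <- generate_cohort(cfg)
  con <- build_contrast(preprocess_cohort(ch, zscore = FALSE))
  pdi <- compute_pdi(con, NULL)              # fixed window inside the plateau
  expect_equal(pdi$pdi, ch$truth$true_pdi, tolerance = 1e-10)

  # data-driven mode requires a significant cluster
  ct_zero <- cluster_test(zero, n_iter = 20, seed = 2)
  expect_null(ct_zero$significant_window)
  expect_error(compute_pdi(zero, ct_zero), class = "pc_data_error")

  strong <- cluster_test(con, n_iter = 200, seed = 3)
  est <- compute_pdi(con, strong)
  expect_equal(est$window_mode[1], "data_driven")
  expect_gt(cor(est$pdi, ch$truth$true_pdi), 0.999)
})

test_that("participants missing an emotional cell are dropped with a warning", {
  ch <- generate_cohort(clean_config(seed = 46, n = 4, fs = 50,
                                     pdi_loading = 0.3))
  ep <- preprocess_cohort(ch, zscore = FALSE)
  ev <- ep[[2]]$events
  keep <- !(ev$condition == "reappraise" & ev$valence == "positive")
  ep[[2]]$events <- ev[keep, ]
  ep[[2]]$matrix <- ep[[2]]$matrix[keep, ]
  expect_warning(con <- build_contrast(ep), "p02")
  expect_equal(nrow(con), 3)
})
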
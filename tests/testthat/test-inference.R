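test_that("standardisation contract: moments, idempotence, back-transform", {
  set.seed(61)
  d <- data.frame(a = rnorm(50, 10, 3), b = runif(50, -2, 9), y = rnorm(50))
  st <- standardize_predictors(d, c("a", "b"))
  expect_lt(abs(mean(st$data$a)), 1e-12)
  expect_equal(sd(st$data$b), 1, tolerance = 1e-12)
  st2 <- standardize_predictors(st$data, c("a", "b"))
  expect_equal(st2$data$a, st$data$a, tolerance = 1e-12)

  # slope on the standardised scale back-transforms to the raw OLS slope
  d$y <- 2 + 0.7 * d$a + rnorm(50, 0, 0.3)
  raw_slope <- unname(coef(lm(y ~ a, d))["a"])
  std_fit <- lm(d$y ~ st$data$a)
  expect_equal(unname(coef(std_fit)[2]) / st$scale["a"], raw_slope,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(standardize_predictors(data.frame(a = rep(1, 5)), "a"),
               class = "pc_data_error")
})

test_that("success model recovers generating betas and both engines agree", {
  b <- c(1.8, 0.34, 0.30, 0.21)
  sc <- linear_scores(500, b, noise_sd = 0.5, seed = 62)
  fit <- fit_success_model(sc)
  est <- fit$coefficients$estimate
  se <- fit$coefficients$sd
  # Monte-Carlo recovery: every coefficient within 4 posterior SDs of truth
  expect_true(all(abs(est - b) < 4 * se))
  # CIs contain the estimate
  expect_true(all(fit$coefficients$ci95_lower <= est &
                    est <= fit$coefficients$ci95_upper))
  ols <- fit_success_model(sc, engine = "ols", bf_engine = "none")
  expect_true(all(abs(est - ols$coefficients$estimate) < 0.02))

  # covariate variant adds Age and TaskOrder terms
  fit_b <- fit_success_model(sc, covariates = TRUE, bf_engine = "none")
  expect_setequal(fit_b$coefficients$term,
                  c("(Intercept)", "PDI", "AffectiveDistance", "Age",
                    "TaskOrder", "PDI:AffectiveDistance"))
})

test_that("null-effect credible intervals cover zero at the nominal rate", {
  covered <- vapply(1:100, function(s) {
    sc <- linear_scores(40, c(1.8, 0, 0.3, 0), noise_sd = 0.5, seed = 1000 + s)
    fit <- fit_success_model(sc, bf_engine = "none")
    row <- fit$coefficients[fit$coefficients$term == "PDI", ]
    row$ci95_lower <= 0 && 0 <= row$ci95_upper
  }, logical(1))
  expect_gte(mean(covered), 0.88)   # binomial 95% band around 0.95 for 100 draws
})

test_that("degenerate designs are rejected with a condition-number report", {
  sc <- linear_scores(30, seed = 63)
  sc$AffectiveDistance <- 2 * sc$PDI + 3      # collinear after standardisation
  expect_error(fit_success_model(sc), "condition number",
               class = "pc_data_error")
  expect_error(fit_success_model(linear_scores(4, seed = 1)),
               class = "pc_data_error")       # n < p + 2
})

test_that("HCS model: null loadings cover zero, coefficients in percent points", {
  set.seed(64)
  sc <- linear_scores(40, seed = 64)
  sc$HCS <- rnorm(40, 62, 10)                 # independent of PDI / task order
  fit <- fit_hcs_model(sc, bf_engine = "none")
  expect_setequal(fit$coefficients$term, c("(Intercept)", "PDI", "TaskOrder"))
  for (tm in c("PDI", "TaskOrder")) {
    row <- fit$coefficients[fit$coefficients$term == tm, ]
    expect_true(row$ci95_lower <= 0 && 0 <= row$ci95_upper, info = tm)
  }
  # a known loading is recovered on large samples
  sc2 <- linear_scores(800, seed = 65)
  pdi_s <- (sc2$PDI - mean(sc2$PDI)) / sd(sc2$PDI)
  sc2$HCS <- 62 + 12 * pdi_s + rnorm(800, 0, 5)
  fit2 <- fit_hcs_model(sc2, bf_engine = "none")
  expect_equal(fit2$coefficients$estimate[fit2$coefficients$term == "PDI"],
               12, tolerance = 0.1)
})

test_that("rank correlation: exact limits, Gaussian-copula closed form, engines", {
  x <- rnorm(30)
  expect_equal(rank_correlation(x, exp(x))$rho, 1)
  expect_equal(rank_correlation(x, -x)$rho, -1)
  expect_error(rank_correlation(x, rep(1, 30)), class = "pc_data_error")
  expect_error(rank_correlation(x[1:4], x[1:4]), class = "pc_data_error")

  # bivariate normal: population Spearman rho = 6/pi asin(rho/2)
  set.seed(66)
  n <- 10000; rho <- 0.6
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  expected <- 6 / pi * asin(rho / 2)
  rc <- rank_correlation(z1, z2)
  expect_equal(rc$rho, expected, tolerance = 0.02, ignore_attr = TRUE)
  expect_true(rc$ci95[1] < rc$rho && rc$rho < rc$ci95[2])
  expect_gt(rc$pp_positive, 0.999)
  expect_gt(rc$bf, 100)

  bs <- rank_correlation(z1[1:40], z2[1:40], engine = "bootstrap",
                         n_boot = 500, seed = 2)
  expect_equal(bs$rho, rank_correlation(z1[1:40], z2[1:40])$rho)
  expect_true(bs$ci95[1] <= bs$rho && bs$rho <= bs$ci95[2])
})

test_that("linear-model Bayes factors behave as evidence measures", {
  # pure-noise outcomes: BF < 1 in the vast majority of seeds
  noise_bf <- vapply(1:20, function(s) {
    set.seed(s)
    X <- cbind(1, rnorm(100), rnorm(100))
    colnames(X) <- c("(Intercept)", "a", "b")
    bayes_factor_vs_intercept(X, rnorm(100))$bf
  }, numeric(1))
  expect_gte(mean(noise_bf < 1), 0.8)

  # a fixed real effect: BF increases along an n grid
  bf_at_n <- vapply(c(20, 50, 120), function(n) {
    set.seed(67)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    bayes_factor_vs_intercept(cbind(`(Intercept)` = 1, x = x), y)$bf
  }, numeric(1))
  expect_true(all(diff(bf_at_n) > 0))

  # the BIC engine is labelled and in qualitative agreement
  set.seed(68)
  x <- rnorm(60); y <- 0.8 * x + rnorm(60)
  X <- cbind(`(Intercept)` = 1, x = x)
  jzs <- bayes_factor_vs_intercept(X, y, engine = "jzs")
  bic <- bayes_factor_vs_intercept(X, y, engine = "bic")
  expect_equal(bic$engine, "bic")
  expect_true(jzs$bf > 10 && bic$bf > 10)
})

test_that("paired shift test matches the flat-prior/frequentist equivalence", {
  a <- c(4, 5, 6, 5, 4)
  res0 <- paired_shift_test(a, a)
  expect_equal(res0$mean_diff, 0)
  expect_equal(res0$pp_positive, 0.5)

  res1 <- paired_shift_test(a + 1, a + rnorm(5, 0, 1e-8))
  expect_gt(res1$pp_positive, 1 - 1e-6)

  set.seed(69)
  x <- rnorm(34, 0.4, 1); y <- rnorm(34, 0, 1)
  res <- paired_shift_test(x, y)
  freq <- t.test(x - y, alternative = "greater")$p.value
  expect_equal(res$pp_positive, 1 - freq, tolerance = 0.01)
  expect_true(res$ci95[1] < res$mean_diff && res$mean_diff < res$ci95[2])
  expect_error(paired_shift_test(1:2, 2:1), class = "pc_data_error")
})
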
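# Regression and correlation models with evidence summaries.
#
# With the flat ("uninformative") priors contracted here, the linear-model
# posterior is available in closed form: beta | data follows a multivariate
# t around the OLS solution with scale s^2 (X'X)^-1 and n - p degrees of
# freedom. The "bayes" engine therefore reports analytic posterior
# summaries (no sampling), and by construction its point estimates coincide
# with OLS.

#' Standardise continuous predictors
#'
#' Mean-centres and scales each named column to SD 1 and records the
#' constants so fitted slopes can be back-transformed to the raw scale.
#'
#' @param data data.frame.
#' @param cols character vector of column names to standardise.
#' @return list with \code{data} (columns replaced), \code{center} and
#'   \code{scale} (named numeric vectors).
#' @export
standardize_predictors <- function(data, cols) {
  centers <- scales <- stats::setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    x <- data[[cl]]
    if (!is.numeric(x)) pc_stop_data("column ", cl, " is not numeric")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) pc_stop_data("column ", cl, " has zero SD")
    centers[cl] <- mean(x); scales[cl] <- s
    data[[cl]] <- (x - centers[cl]) / s
  }
  list(data = data, center = centers, scale = scales)
}

# Flat-prior Bayesian / OLS linear model on a prepared design matrix.
# Returns the coefficient table and fit summaries shared by both engines.
flat_prior_lm <- function(X, y, engine = c("bayes", "ols")) {
  engine <- match.arg(engine)
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)))
    pc_stop_data("design or outcome contains missing/non-finite values")
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2) pc_stop_data("need at least p + 2 observations (n = ", n,
                              ", p = ", p, ")")
  kp <- kappa(X, exact = TRUE)
  if (!is.finite(kp) || kp > 1e8)
    pc_stop_data("collinear design (condition number ", format(kp, digits = 3), ")")
  qr_x <- qr(X)
  est <- qr.coef(qr_x, y)
  res <- y - X %*% est
  nu <- n - p
  s2 <- sum(res^2) / nu
  XtXinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(s2 * diag(XtXinv))
  post_sd <- if (nu > 2) se * sqrt(nu / (nu - 2)) else rep(NA_real_, p)
  q95 <- stats::qt(0.975, nu); q90 <- stats::qt(0.95, nu)
  coefs <- data.frame(
    term = colnames(X),
    estimate = as.numeric(est),
    sd = if (engine == "bayes") post_sd else se,
    ci95_lower = as.numeric(est) - q95 * se,
    ci95_upper = as.numeric(est) + q95 * se,
    ci90_lower = as.numeric(est) - q90 * se,
    ci90_upper = as.numeric(est) + q90 * se,
    stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(coefficients = coefs, sigma = sqrt(s2), df = nu, n = n, p = p,
       r_squared = r2, engine = engine, condition_number = kp)
}

success_design <- function(scores, covariates) {
  need <- c("RS", "PDI", "AffectiveDistance")
  if (covariates) need <- c(need, "Age", "TaskOrder")
  miss <- setdiff(need, names(scores))
  if (length(miss)) pc_stop_data("score table lacks column(s): ",
                                 paste(miss, collapse = ", "))
  if (anyNA(scores[need[need != "TaskOrder"]]))
    pc_stop_data("score table contains missing values in model columns")
  cols <- c("PDI", "AffectiveDistance", if (covariates) "Age")
  st <- standardize_predictors(scores, cols)
  d <- st$data
  X <- cbind(`(Intercept)` = 1, PDI = d$PDI,
             AffectiveDistance = d$AffectiveDistance)
  if (covariates) {
    to <- as.integer(d$TaskOrder != "emotion-first")  # 0 = emotion-first
    X <- cbind(X, Age = d$Age, TaskOrder = to)
  }
  X <- cbind(X, `PDI:AffectiveDistance` = d$PDI * d$AffectiveDistance)
  list(X = X, y = scores$RS, scaling = st[c("center", "scale")])
}

#' Model reappraisal success from the PDI and affective distance
#'
#' Fits \code{RS ~ PDI + AffectiveDistance + PDI:AffectiveDistance} (plus
#' standardised Age and a 0/1 TaskOrder factor when
#' \code{covariates = TRUE}) with mean-centred, SD-scaled continuous
#' predictors; the interaction is the product of the standardised terms.
#' The flat-prior Bayesian engine and OLS give identical point estimates;
#' a JZS Bayes factor against the intercept-only model is attached.
#'
#' @param scores a [build_score_table()] data.frame (columns RS, PDI,
#'   AffectiveDistance, and Age/TaskOrder when \code{covariates}).
#' @param covariates add Age + TaskOrder control regressors.
#' @param engine \code{"bayes"} (analytic flat-prior posterior, default) or
#'   \code{"ols"}.
#' @param bf_engine \code{"jzs"} (default), \code{"bic"} or \code{"none"}.
#' @return object of class \code{pdi_regression}.
#' @export
fit_success_model <- function(scores, covariates = FALSE,
                              engine = c("bayes", "ols"),
                              bf_engine = c("jzs", "bic", "none")) {
  engine <- match.arg(engine); bf_engine <- match.arg(bf_engine)
  ds <- success_design(scores, covariates)
  fit <- flat_prior_lm(ds$X, ds$y, engine)
  fit$scaling <- ds$scaling
  fit$outcome <- "RS"
  fit$model <- if (covariates) "RS ~ PDI * AffectiveDistance + Age + TaskOrder"
               else "RS ~ PDI * AffectiveDistance"
  if (bf_engine != "none")
    fit$bayes_factor <- bayes_factor_vs_intercept(ds$X, ds$y, engine = bf_engine)
  class(fit) <- "pdi_regression"
  fit
}

#' Model dietary health-challenge success from the PDI
#'
#' Fits \code{HCS ~ PDI + TaskOrder}: HCS in percentage points, PDI
#' standardised, TaskOrder coded 0 (emotion-first) / 1 (diet-first).
#'
#' @inheritParams fit_success_model
#' @return object of class \code{pdi_regression}.
#' @export
fit_hcs_model <- function(scores, engine = c("bayes", "ols"),
                          bf_engine = c("jzs", "bic", "none")) {
  engine <- match.arg(engine); bf_engine <- match.arg(bf_engine)
  need <- c("HCS", "PDI", "TaskOrder")
  miss <- setdiff(need, names(scores))
  if (length(miss)) pc_stop_data("score table lacks column(s): ",
                                 paste(miss, collapse = ", "))
  st <- standardize_predictors(scores, "PDI")
  X <- cbind(`(Intercept)` = 1, PDI = st$data$PDI,
             TaskOrder = as.integer(scores$TaskOrder != "emotion-first"))
  fit <- flat_prior_lm(X, scores$HCS, engine)
  fit$scaling <- st[c("center", "scale")]
  fit$outcome <- "HCS"
  fit$model <- "HCS ~ PDI + TaskOrder"
  if (bf_engine != "none")
    fit$bayes_factor <- bayes_factor_vs_intercept(X, scores$HCS, engine = bf_engine)
  class(fit) <- "pdi_regression"
  fit
}

#' @export
print.pdi_regression <- function(x, digits = 3, ...) {
  cat(sprintf("<pdi_regression> %s  [engine: %s, n = %d]\n", x$model, x$engine, x$n))
  tab <- x$coefficients
  tab$ci95 <- sprintf("[%.*f; %.*f]", digits, tab$ci95_lower, digits, tab$ci95_upper)
  print(format(tab[, c("term", "estimate", "sd", "ci95")], digits = digits),
        row.names = FALSE)
  if (!is.null(x$bayes_factor))
    cat(sprintf("Bayes factor vs intercept-only: %.4g (%s engine)\n",
                x$bayes_factor$bf, x$bayes_factor$engine))
  invisible(x)
}

#' Bayes factor of a linear model against the intercept-only model
#'
#' Default engine: JZS (Zellner-Siow mixture-of-g) Bayes factor computed by
#' one-dimensional numerical integration over g. The labelled BIC
#' approximation \code{exp((BIC0 - BIC1)/2)} is available as a cheap
#' alternative; the two engines can disagree numerically, so the engine
#' used is always part of the result.
#'
#' @param X design matrix including an intercept column.
#' @param y outcome vector.
#' @param engine \code{"jzs"} or \code{"bic"}.
#' @return list with \code{bf} (BF10 vs intercept-only), \code{engine},
#'   \code{r_squared}.
#' @export
bayes_factor_vs_intercept <- function(X, y, engine = c("jzs", "bic")) {
  engine <- match.arg(engine)
  n <- nrow(X)
  p <- ncol(X) - 1L                    # effects beyond the intercept
  if (p < 1) pc_stop_config("model has no effect beyond the intercept")
  if (n <= ncol(X)) pc_stop_data("n must exceed the number of coefficients")
  fit <- stats::lm.fit(X, y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  if (engine == "bic") {
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum((y - mean(y))^2)
    bic1 <- n * log(rss1 / n) + (ncol(X) + 1) * log(n)
    bic0 <- n * log(rss0 / n) + 2 * log(n)
    return(list(bf = exp((bic0 - bic1) / 2), engine = "bic", r_squared = r2))
  }
  # Liang et al. (2008) g-integral with the Zellner-Siow prior
  # pi(g) = sqrt(n/2) / gamma(1/2) * g^{-3/2} exp(-n / (2 g))
  log_integrand <- function(g) {
    (n - 1 - p) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2)) +
      0.5 * log(n / 2) - lgamma(0.5) - 1.5 * log(g) - n / (2 * g)
  }
  # integrate on u = log(g) for stability
  f <- function(u) exp(log_integrand(exp(u)) + u)
  val <- stats::integrate(f, lower = -20, upper = 40, rel.tol = 1e-9,
                          subdivisions = 500L)
  list(bf = val$value, engine = "jzs", r_squared = r2)
}

#' Bayesian rank correlation
#'
#' Spearman's rho (mid-ranks for ties) with an approximate posterior built
#' on the Fisher-z transform (variance 1.06/(n-3), the standard variance
#' inflation for rank correlations), giving a 95% credible interval and the
#' posterior probability that rho > 0. The Bayes factor against rho = 0
#' uses the Savage-Dickey ratio under a uniform(-1, 1) prior on rho. A
#' nonparametric bootstrap engine is provided as a fallback.
#'
#' @param x,y paired numeric vectors (n >= 5).
#' @param engine \code{"fisher"} (default) or \code{"bootstrap"}.
#' @param n_boot bootstrap resamples (bootstrap engine).
#' @param seed seed for the bootstrap engine.
#' @return object of class \code{rank_correlation_result}: list with
#'   \code{rho}, \code{ci95}, \code{pp_positive}, \code{bf},
#'   \code{r_squared} (rho^2), \code{n}, \code{engine}.
#' @export
rank_correlation <- function(x, y, engine = c("fisher", "bootstrap"),
                             n_boot = 2000, seed = 1L) {
  engine <- match.arg(engine)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) pc_stop_data("rank correlation needs n >= 5 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    pc_stop_data("constant vector: rank correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  if (engine == "fisher") {
    z <- atanh(min(1 - 1e-12, max(-1 + 1e-12, rho)))
    sdz <- sqrt(1.06 / (n - 3))
    ci <- tanh(z + stats::qnorm(c(0.025, 0.975)) * sdz)
    pp <- stats::pnorm(z / sdz)
    # Savage-Dickey: prior density at 0 is 1/2; posterior density of rho at 0
    post0 <- stats::dnorm(0, mean = z, sd = sdz)   # |d atanh(r)/dr| = 1 at r = 0
    bf <- 0.5 / post0
  } else {
    set.seed(seed)
    rb <- replicate(n_boot, {
      i <- sample.int(n, replace = TRUE)
      suppressWarnings(stats::cor(x[i], y[i], method = "spearman"))
    })
    rb <- rb[is.finite(rb)]
    ci <- unname(stats::quantile(rb, c(0.025, 0.975)))
    pp <- mean(rb > 0)
    bf <- NA_real_
  }
  structure(list(rho = rho, ci95 = ci, pp_positive = pp, bf = bf,
                 r_squared = rho^2, n = n, engine = engine),
            class = "rank_correlation_result")
}

#' @export
print.rank_correlation_result <- function(x, ...) {
  cat(sprintf("<rank_correlation> rho = %.3f, 95%% CI [%.3f; %.3f], PP(rho>0) = %.4f",
              x$rho, x$ci95[1], x$ci95[2], x$pp_positive))
  if (is.finite(x$bf)) cat(sprintf(", BF = %.4g", x$bf))
  cat(sprintf(", R^2 = %.3f (n = %d, %s engine)\n", x$r_squared, x$n, x$engine))
  invisible(x)
}

#' Bayesian paired comparison of two rating vectors
#'
#' BEST-style paired test under the flat-prior t model: the posterior of
#' the mean paired difference is a scaled t distribution (location
#' mean(d), scale sd(d)/sqrt(n), df n-1). Reports the posterior
#' probability that the difference exceeds zero, a 95% credible interval
#' and a JZS one-sample Bayes factor.
#'
#' @param ratings_a,ratings_b paired per-participant means (n >= 3).
#' @return object of class \code{paired_shift_result}: list with
#'   \code{mean_diff}, \code{ci95}, \code{pp_positive}, \code{bf}, \code{n}.
#' @export
paired_shift_test <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    pc_stop_data("paired vectors must have equal length")
  d <- ratings_a - ratings_b
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 3) pc_stop_data("paired test needs n >= 3")
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    pp <- if (m > 0) 1 else if (m < 0) 0 else 0.5
    return(structure(list(mean_diff = m, ci95 = c(m, m), pp_positive = pp,
                          bf = if (m == 0) 0 else Inf, n = n),
                     class = "paired_shift_result"))
  }
  sem <- s / sqrt(n)
  tt <- m / sem
  pp <- stats::pt(tt, n - 1)
  ci <- m + stats::qt(c(0.025, 0.975), n - 1) * sem
  bf <- jzs_ttest_bf(tt, n)
  structure(list(mean_diff = m, ci95 = ci, pp_positive = pp, bf = bf, n = n),
            class = "paired_shift_result")
}

# JZS one-sample t Bayes factor: Cauchy(0, rscale) prior on the effect
# size, written as the scale mixture delta | g ~ N(0, g r^2),
# g ~ InvGamma(1/2, 1/2), which reduces BF10 to a 1-D integral over g.
jzs_ttest_bf <- function(t, n, rscale = sqrt(2) / 2) {
  nu <- n - 1
  log_den <- -(nu + 1) / 2 * log1p(t^2 / nu)
  log_num <- function(g) {
    a <- 1 + n * g * rscale^2
    -0.5 * log(a) - (nu + 1) / 2 * log1p(t^2 / (a * nu)) -
      0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g)
  }
  f <- function(u) exp(log_num(exp(u)) + u - log_den)   # u = log(g)
  val <- stats::integrate(f, -25, 25, rel.tol = 1e-8, subdivisions = 500L)
  val$value
}

#' @export
print.paired_shift_result <- function(x, ...) {
  cat(sprintf("<paired_shift> mean diff = %.3f, 95%% CI [%.3f; %.3f], PP(diff>0) = %.4f, BF = %.4g (n = %d)\n",
              x$mean_diff, x$ci95[1], x$ci95[2], x$pp_positive, x$bf, x$n))
  invisible(x)
}
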
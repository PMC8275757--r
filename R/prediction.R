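# Leave-2-participants-out pairwise prediction of regulation success and its
# permutation null.

#' Enumerate all leave-2-out splits
#'
#' @param n number of participants (>= 3).
#' @return integer matrix with \code{choose(n, 2)} rows and columns
#'   \code{i}, \code{j}: each row is one unordered test pair, the remaining
#'   \code{n - 2} participants form the training set.
#' @export
enumerate_splits <- function(n) {
  if (!is_count(n) || n < 3) pc_stop_config("n must be an integer >= 3")
  pairs <- t(utils::combn(n, 2))
  colnames(pairs) <- c("i", "j")
  pairs
}

# Per-split pieces reused by loo2_accuracy and the permutation null:
# training-standardised design, its least-squares projector, and the test
# design rows (scaled with the training constants).
loo2_prepare <- function(scores, interaction = TRUE) {
  need <- c("RS", "PDI", "AffectiveDistance")
  miss <- setdiff(need, names(scores))
  if (length(miss)) pc_stop_data("score table lacks column(s): ",
                                 paste(miss, collapse = ", "))
  if (anyNA(scores[need])) pc_stop_data("PDI, AffectiveDistance and RS must be complete")
  n <- nrow(scores)
  pairs <- enumerate_splits(n)
  design <- function(pdi, ad) {
    X <- cbind(1, pdi, ad)
    if (interaction) X <- cbind(X, pdi * ad)
    X
  }
  splits <- vector("list", nrow(pairs))
  for (s in seq_len(nrow(pairs))) {
    test <- pairs[s, ]
    tr <- setdiff(seq_len(n), test)
    mu <- c(mean(scores$PDI[tr]), mean(scores$AffectiveDistance[tr]))
    sg <- c(stats::sd(scores$PDI[tr]), stats::sd(scores$AffectiveDistance[tr]))
    if (any(sg == 0)) { splits[[s]] <- NULL; next }
    Xtr <- design((scores$PDI[tr] - mu[1]) / sg[1],
                  (scores$AffectiveDistance[tr] - mu[2]) / sg[2])
    qr_x <- qr(Xtr)
    if (qr_x$rank < ncol(Xtr)) { splits[[s]] <- NULL; next }
    P <- qr.solve(qr_x, diag(length(tr)))       # (X'X)^-1 X'
    Xte <- design((scores$PDI[test] - mu[1]) / sg[1],
                  (scores$AffectiveDistance[test] - mu[2]) / sg[2])
    splits[[s]] <- list(train = tr, test = test, P = P, Xte = Xte,
                        ytr = scores$RS[tr], yte = scores$RS[test])
  }
  skipped <- sum(vapply(splits, is.null, logical(1)))
  if (skipped > 0.05 * nrow(pairs))
    pc_stop_data(skipped, " of ", nrow(pairs), " training fits are singular (> 5%)")
  list(splits = splits, n_splits = nrow(pairs), skipped = skipped)
}

#' Leave-2-out pairwise prediction accuracy
#'
#' For each of the \code{choose(n, 2)} splits the success model (PDI,
#' affective distance and, by default, their interaction) is fit by OLS on
#' the \code{n - 2} training participants, with predictors standardised on
#' the training set only; the split counts as correct when the predicted
#' ordering of the two held-out participants' regulation success matches
#' the true ordering. Ties in predicted or true RS count as incorrect
#' (conservative; tallied in \code{tie_count}).
#'
#' @param scores a [build_score_table()] data.frame with complete PDI,
#'   AffectiveDistance and RS.
#' @param interaction include the PDI x AffectiveDistance term (default
#'   TRUE, the full success-model specification).
#' @return object of class \code{loo2_prediction}: list with
#'   \code{accuracy}, \code{n_splits}, \code{n_correct}, \code{tie_count},
#'   \code{skipped}.
#' @export
loo2_accuracy <- function(scores, interaction = TRUE) {
  prep <- loo2_prepare(scores, interaction)
  correct <- 0L; ties <- 0L; used <- 0L
  for (sp in prep$splits) {
    if (is.null(sp)) next
    used <- used + 1L
    beta <- sp$P %*% sp$ytr
    pred <- as.numeric(sp$Xte %*% beta)
    if (pred[1] == pred[2] || sp$yte[1] == sp$yte[2]) {
      ties <- ties + 1L
    } else if ((pred[1] > pred[2]) == (sp$yte[1] > sp$yte[2])) {
      correct <- correct + 1L
    }
  }
  structure(list(accuracy = correct / used, n_splits = prep$n_splits,
                 n_correct = correct, tie_count = ties,
                 skipped = prep$skipped, interaction = interaction),
            class = "loo2_prediction")
}

#' Permutation null for the leave-2-out accuracy
#'
#' On each iteration a random half (\code{floor(n/2)}) of the raw success
#' scores is multiplied by -1, every split's model is refit on these
#' permuted outcomes (each training set using the signs of its n - 2
#' members), and the leave-2-out accuracy against the true test ordering
#' is recorded. \code{p = count(null >= observed) / n_iter}.
#'
#' One sign assignment is shared by all splits within an iteration
#' (\code{flip_unit = "cohort"}, default): this preserves the between-split
#' correlation of the observed accuracy and gives a calibrated test. The
#' \code{"split"} variant redraws signs independently for every training
#' set, which makes split outcomes independent within an iteration,
#' under-disperses the null and is strongly anticonservative; it is
#' provided for comparison only.
#'
#' @inheritParams loo2_accuracy
#' @param n_iter iterations (default 1000).
#' @param seed integer seed (deterministic output contract).
#' @param flip_unit \code{"cohort"} (default) or \code{"split"}; see above.
#' @param centered_flip flip signs of mean-centred scores instead of raw
#'   scores (variant; default FALSE follows the raw-score construction).
#' @return object of class \code{loo2_permutation}: list with
#'   \code{observed} ([loo2_accuracy()] result), \code{null_accuracies},
#'   \code{p}, \code{n_iter}, \code{flip_unit}, \code{seed}.
#' @export
accuracy_permutation_null <- function(scores, n_iter = 1000, seed = 1L,
                                      interaction = TRUE,
                                      flip_unit = c("cohort", "split"),
                                      centered_flip = FALSE) {
  flip_unit <- match.arg(flip_unit)
  if (n_iter < 1) pc_stop_config("n_iter must be >= 1")
  obs <- loo2_accuracy(scores, interaction)
  prep <- loo2_prepare(scores, interaction)
  set.seed(seed)
  n <- nrow(scores)
  # exactly floor(k/2) flips per column: within-column ranks of a uniform
  # draw via one global rank call (columns offset to disjoint value ranges)
  sign_matrix <- function(k) {
    U <- matrix(stats::runif(k * n_iter), k, n_iter) +
      rep(seq_len(n_iter) - 1L, each = k)
    rk <- matrix(rank(U, ties.method = "first"), k, n_iter) -
      rep((seq_len(n_iter) - 1L) * k, each = k)
    ifelse(rk <= k %/% 2, -1, 1)
  }
  S_cohort <- if (flip_unit == "cohort") sign_matrix(n)
  used <- which(!vapply(prep$splits, is.null, logical(1)))
  correct <- matrix(FALSE, length(used), n_iter)
  row <- 0L
  for (s in used) {
    sp <- prep$splits[[s]]
    row <- row + 1L
    S <- if (flip_unit == "cohort") S_cohort[sp$train, , drop = FALSE]
         else sign_matrix(length(sp$ytr))
    ybase <- if (centered_flip) sp$ytr - mean(sp$ytr) else sp$ytr
    Y <- ybase * S                               # m x n_iter permuted outcomes
    beta <- sp$P %*% Y                           # p x n_iter
    pred <- sp$Xte %*% beta                      # 2 x n_iter
    if (sp$yte[1] == sp$yte[2]) next             # tie: never correct
    correct[row, ] <- (pred[1, ] > pred[2, ]) == (sp$yte[1] > sp$yte[2]) &
      pred[1, ] != pred[2, ]
  }
  null_acc <- colMeans(correct)
  structure(list(observed = obs, null_accuracies = null_acc,
                 p = mean(null_acc >= obs$accuracy),
                 n_iter = n_iter, flip_unit = flip_unit, seed = seed),
            class = "loo2_permutation")
}

#' @export
print.loo2_prediction <- function(x, ...) {
  cat(sprintf("<loo2_prediction> accuracy = %.4f (%d/%d splits correct, %d ties%s)\n",
              x$accuracy, x$n_correct, x$n_splits - x$skipped, x$tie_count,
              if (x$skipped) sprintf(", %d skipped", x$skipped) else ""))
  invisible(x)
}

#' @export
print.loo2_permutation <- function(x, ...) {
  print(x$observed)
  cat(sprintf("  permutation null (%d iterations): %s\n", x$n_iter,
              format_p(x$p, x$n_iter)))
  invisible(x)
}
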
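# Reappraise>View contrast, max-cluster sign-flip permutation test, and the
# Pupil Dilation Index.

#' Build the Reappraise>View contrast matrix
#'
#' Per participant: mean epoch over reappraise-positive and
#' reappraise-negative trials minus mean epoch over view-positive and
#' view-negative trials (valence means averaged with equal weight; neutral
#' view trials are excluded). Restricted to the stimulus window
#' \code{[0, 7000)} ms.
#'
#' @param epoch_list named list of \code{trial_epochs}, one per participant,
#'   on a common bin grid.
#' @param stimulus_window length-2 numeric, ms (half-open) to retain.
#' @return matrix of class \code{pupil_contrast}, participants x bins, with
#'   attribute \code{times_ms} (bin start times, ms since stimulus onset) and
#'   \code{bin_width_ms}. Participants missing one of the four emotional
#'   condition cells are dropped with a warning.
#' @export
build_contrast <- function(epoch_list, stimulus_window = c(0, 7000)) {
  stopifnot(length(epoch_list) >= 1)
  tms <- epoch_list[[1]]$times_ms
  keep <- tms >= stimulus_window[1] & tms < stimulus_window[2]
  rows <- list(); dropped <- character(0)
  for (id in names(epoch_list)) {
    ep <- epoch_list[[id]]
    if (!isTRUE(all.equal(ep$times_ms, tms)))
      pc_stop_data("participant ", id, " is on a different bin grid")
    ev <- ep$events
    cell <- function(cond, val) {
      sel <- ev$condition == cond & ev$valence == val
      if (!any(sel)) return(NULL)
      colMeans(ep$matrix[sel, keep, drop = FALSE])
    }
    rp <- cell("reappraise", "positive"); rn <- cell("reappraise", "negative")
    vp <- cell("view", "positive"); vn <- cell("view", "negative")
    if (is.null(rp) || is.null(rn) || is.null(vp) || is.null(vn)) {
      dropped <- c(dropped, id)
      next
    }
    rows[[id]] <- (rp + rn) / 2 - (vp + vn) / 2
  }
  if (length(dropped))
    warning("dropped participant(s) with a missing emotional condition cell: ",
            paste(dropped, collapse = ", "))
  if (!length(rows)) pc_stop_data("no participant has all four emotional cells")
  M <- do.call(rbind, rows)
  structure(M, times_ms = tms[keep],
            bin_width_ms = epoch_list[[1]]$bin_width_ms,
            class = c("pupil_contrast", class(M)))
}

#' Pointwise one-sample t statistic of a contrast
#'
#' One-sample t versus zero across participants, per time bin. Bins with
#' zero across-participant variance get \code{+Inf} (positive mean),
#' \code{-Inf} (negative mean) or 0 (zero mean).
#'
#' @param contrast a participants x bins matrix ([build_contrast()]).
#' @return numeric t curve, one value per bin.
#' @export
pointwise_t <- function(contrast) {
  X <- unclass(contrast)
  n <- nrow(X)
  if (n < 3) pc_stop_data("pointwise t needs >= 3 participants")
  m <- colMeans(X)
  s <- col_sds(X)
  tcurve <- numeric(length(m))
  zero <- s < .Machine$double.eps^0.5 * pmax(1, abs(m))
  tcurve[!zero] <- m[!zero] / (s[!zero] / sqrt(n))
  tcurve[zero] <- sign(m[zero]) * Inf
  tcurve[zero & m == 0] <- 0
  tcurve
}

#' Find threshold-exceeding clusters in a t curve
#'
#' Maximal runs of adjacent bins exceeding the cluster-forming threshold.
#'
#' @param t_curve numeric vector (may contain +/-Inf).
#' @param threshold cluster-forming threshold (t units), default 3.
#' @param tail \code{"positive"} (t > threshold, default) or \code{"two"}
#'   (|t| > threshold).
#' @return data.frame with 1-based inclusive \code{start}, \code{end},
#'   \code{size} (bin count) and \code{max_t}; zero rows if no bin exceeds
#'   the threshold.
#' @export
find_clusters <- function(t_curve, threshold = 3, tail = c("positive", "two")) {
  tail <- match.arg(tail)
  ok <- if (tail == "two") abs(t_curve) > threshold else t_curve > threshold
  ok[is.na(ok)] <- FALSE
  out <- data.frame(start = integer(0), end = integer(0),
                    size = integer(0), max_t = numeric(0))
  if (!any(ok)) return(out)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(start = starts[sel], end = ends[sel],
             size = r$lengths[sel],
             max_t = vapply(sel, function(j)
               max(abs(t_curve[starts[j]:ends[j]])), numeric(1)))
}

# max cluster size per column of a bins x iterations logical matrix,
# via a single rle over the flattened matrix with FALSE separators
max_cluster_sizes_bycol <- function(ok) {
  B <- nrow(ok); K <- ncol(ok)
  flat <- as.logical(rbind(FALSE, ok))      # column-major; runs cannot span cols
  r <- rle(flat)
  out <- integer(K)
  if (any(r$values)) {
    starts <- cumsum(r$lengths) - r$lengths + 1L
    sel <- which(r$values)
    col <- (starts[sel] - 1L) %/% (B + 1L) + 1L
    mx <- tapply(r$lengths[sel], col, max)
    out[as.integer(names(mx))] <- as.integer(mx)
  }
  out
}

#' Sign-flip permutation null of the maximum cluster size
#'
#' On each iteration, signs of the contrast are flipped (whole participant
#' rows for \code{flip_mode = "per_participant"}, the standard construction;
#' independent cells for \code{"per_bin"}), the pointwise t curve is
#' recomputed, clusters found at the same threshold, and the largest cluster
#' size (0 if none) stored.
#'
#' @inheritParams pointwise_t
#' @param n_iter number of iterations (default 1000).
#' @param threshold cluster-forming threshold.
#' @param flip_mode \code{"per_participant"} or \code{"per_bin"}.
#' @param tail as in [find_clusters()].
#' @param seed integer seed (deterministic output contract).
#' @return integer vector of \code{n_iter} maximum cluster sizes.
#' @export
permutation_null <- function(contrast, n_iter = 1000, threshold = 3,
                             flip_mode = c("per_participant", "per_bin"),
                             tail = c("positive", "two"), seed = 1L) {
  flip_mode <- match.arg(flip_mode)
  tail <- match.arg(tail)
  if (n_iter < 1) pc_stop_config("n_iter must be >= 1")
  X <- unclass(contrast)
  n <- nrow(X); B <- ncol(X)
  if (n < 3) pc_stop_data("permutation null needs >= 3 participants")
  set.seed(seed)
  Xt <- t(X)                             # bins x participants
  SS <- rowSums(Xt^2)                    # invariant under sign flips
  tiny <- .Machine$double.eps^0.5
  t_of_means <- function(M) {            # M: bins x iterations of means
    V <- (SS - n * M^2) / (n - 1)        # SS recycles down columns
    V[V < 0] <- 0
    Tm <- M / sqrt(V / n)                # 0-variance bins divide by 0 -> +/-Inf
    Tm[V < tiny^2 & M == 0] <- 0
    Tm
  }
  if (flip_mode == "per_participant") {
    Fm <- matrix(sample(c(-1, 1), n_iter * n, replace = TRUE), n, n_iter)
    # chunk to bound memory at ~ B x chunk doubles
    chunk <- max(1L, as.integer(4e6 / B))
    out <- integer(n_iter)
    i <- 1L
    while (i <= n_iter) {
      j <- min(n_iter, i + chunk - 1L)
      M <- (Xt %*% Fm[, i:j, drop = FALSE]) / n
      Tm <- t_of_means(M)
      ok <- if (tail == "two") abs(Tm) > threshold else Tm > threshold
      ok[is.na(ok)] <- FALSE
      out[i:j] <- max_cluster_sizes_bycol(ok)
      i <- j + 1L
    }
    out
  } else {
    out <- integer(n_iter)
    for (it in seq_len(n_iter)) {
      S <- matrix(sample(c(-1, 1), n * B, replace = TRUE), n, B)
      Xs <- S * X
      m <- colMeans(Xs)
      s <- col_sds(Xs)
      tcv <- ifelse(s < tiny, sign(m) * Inf, m / (s / sqrt(n)))
      tcv[s < tiny & m == 0] <- 0
      out[it] <- max_run_length(if (tail == "two") abs(tcv) > threshold
                                else tcv > threshold)
    }
    out
  }
}

#' Max-cluster permutation p value
#'
#' \code{p = count(null >= size) / length(null)}. A p of exactly 0 should be
#' rendered as \code{"< 1/n_iter"} in reports; it is stored as 0.
#'
#' @param observed_size observed cluster size (bins).
#' @param null_max_sizes integer vector from [permutation_null()].
#' @return numeric p in [0, 1].
#' @export
cluster_p <- function(observed_size, null_max_sizes) {
  if (!length(null_max_sizes)) pc_stop_data("empty null distribution")
  mean(null_max_sizes >= observed_size)
}

format_p <- function(p, n_iter) {
  if (p == 0) sprintf("p < %g", 1 / n_iter) else sprintf("p = %g", p)
}

#' Cluster-based permutation test of a contrast
#'
#' Runs [pointwise_t()], [find_clusters()], [permutation_null()] and
#' [cluster_p()] and assembles the result. Only the largest observed cluster
#' defines the significant window (conservative max-cluster logic); further
#' clusters receive p values against the same null and are flagged
#' exploratory. Ties in "largest" break by earliest start bin.
#'
#' @inheritParams permutation_null
#' @param alpha significance level for the window decision (default 0.05).
#' @return object of class \code{cluster_test_result}: list with
#'   \code{t_curve}, \code{threshold}, \code{clusters} (data.frame with
#'   \code{p} and \code{primary} flag), \code{null_max_sizes},
#'   \code{significant_window} (length-2 seconds, or NULL),
#'   \code{times_ms}, \code{n_iterations}, \code{flip_mode}, \code{tail},
#'   \code{seed}.
#' @export
cluster_test <- function(contrast, threshold = 3, n_iter = 1000,
                         flip_mode = c("per_participant", "per_bin"),
                         tail = c("positive", "two"), seed = 1L, alpha = 0.05) {
  flip_mode <- match.arg(flip_mode); tail <- match.arg(tail)
  tms <- attr(contrast, "times_ms")
  bw <- attr(contrast, "bin_width_ms")
  tcv <- pointwise_t(contrast)
  cl <- find_clusters(tcv, threshold, tail)
  null <- permutation_null(contrast, n_iter, threshold, flip_mode, tail, seed)
  win <- NULL
  if (nrow(cl)) {
    cl$p <- vapply(cl$size, cluster_p, numeric(1), null_max_sizes = null)
    cl$primary <- FALSE
    best <- which(cl$size == max(cl$size))[1]   # earliest start wins ties
    cl$primary[best] <- TRUE
    if (cl$p[best] <= alpha)
      win <- c(tms[cl$start[best]], tms[cl$end[best]] + bw) / 1000
  }
  structure(list(t_curve = tcv, threshold = threshold, clusters = cl,
                 null_max_sizes = null, significant_window = win,
                 times_ms = tms, bin_width_ms = bw, n_iterations = n_iter,
                 flip_mode = flip_mode, tail = tail, seed = seed,
                 alpha = alpha),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> threshold T = %g, %d iterations (%s flips)\n",
              x$threshold, x$n_iterations, x$flip_mode))
  if (!nrow(x$clusters)) {
    cat("  no cluster exceeds the threshold\n")
  } else {
    b <- x$clusters[x$clusters$primary, ]
    cat(sprintf("  largest cluster: %d bins, %.3g-%.3g s, max |t| = %.2f, %s\n",
                b$size, x$times_ms[b$start] / 1000,
                (x$times_ms[b$end] + x$bin_width_ms) / 1000, b$max_t,
                format_p(b$p, x$n_iterations)))
  }
  if (!is.null(x$significant_window))
    cat(sprintf("  significant window: [%.3g, %.3g] s\n",
                x$significant_window[1], x$significant_window[2]))
  invisible(x)
}

#' Pupil Dilation Index (PDI)
#'
#' Per-participant mean of the Reappraise>View contrast over a time window:
#' either the data-driven significant cluster window of a
#' [cluster_test()] result, or the fixed replication window 3.4-5.6 s.
#'
#' @inheritParams pointwise_t
#' @param window either a length-2 numeric window in seconds, or a
#'   \code{cluster_test_result} whose significant window is used
#'   (\code{window_mode = "data_driven"}). \code{NULL} selects the fixed
#'   replication window \code{c(3.4, 5.6)} s.
#' @return data.frame of class \code{pdi_table}: \code{participant_id},
#'   \code{pdi} (z-units), \code{window_start_s}, \code{window_end_s},
#'   \code{window_mode}.
#' @export
compute_pdi <- function(contrast, window = NULL) {
  tms <- attr(contrast, "times_ms") / 1000
  if (inherits(window, "cluster_test_result")) {
    if (is.null(window$significant_window))
      pc_stop_data("no significant cluster: use the fixed window mode ",
                   "(window = c(3.4, 5.6)) instead")
    mode <- "data_driven"
    win <- window$significant_window
  } else if (is.null(window)) {
    mode <- "fixed_paper"
    win <- c(3.4, 5.6)
  } else {
    mode <- "fixed"
    win <- as.numeric(window)
  }
  if (length(win) != 2 || win[1] >= win[2])
    pc_stop_config("window must be an increasing pair of seconds")
  eps <- 1e-9
  sel <- tms >= win[1] - eps & tms <= win[2] + eps
  if (!any(sel)) pc_stop_config("window contains no bins")
  X <- unclass(contrast)
  out <- data.frame(participant_id = rownames(X) %||% sprintf("p%02d", seq_len(nrow(X))),
                    pdi = rowMeans(X[, sel, drop = FALSE]),
                    window_start_s = win[1], window_end_s = win[2],
                    window_mode = mode, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pdi_table", "data.frame")
  out
}
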
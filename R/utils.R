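# Internal helpers: condition classes, hashing, small numeric utilities.

pc_stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("pc_config_error", "error")))
}

pc_stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("pc_data_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polynomial content hash of an R object
#'
#' FNV-1a-style 31-bit rolling hash over the JSON serialisation of `x`,
#' used to stamp pipeline outputs with a provenance fingerprint.
#'
#' @param x any jsonlite-serialisable object.
#' @return hex string.
#' @keywords internal
pc_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# maximal run length of TRUE in a logical vector (0 if none)
max_run_length <- function(ok) {
  if (!any(ok)) return(0L)
  r <- rle(ok)
  max(r$lengths[r$values])
}

# column sds of a matrix without apply()
col_sds <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  sqrt(pmax(v, 0))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
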
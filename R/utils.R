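# Internal validation and small numeric helpers.

stop_mgs <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "mgsynapse_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_mgs("`%s` must be a single positive finite number", name,
             class = "mgsynapse_validation_error")
  }
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop_mgs("`%s` must be a probability in [0, 1]", name,
             class = "mgsynapse_validation_error")
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_mgs("`%s` must be non-negative and finite", name,
             class = "mgsynapse_validation_error")
  }
  invisible(x)
}

#' Standard error of the mean
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return `sd(x)/sqrt(n)`, or `NA` when fewer than two values remain.
#' @export
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Derive a reproducible substream seed from a master seed and a stream label.
# Kept below 2^31 so it is always a valid R integer seed.
substream_seed <- function(seed, stream) {
  offsets <- c(scene = 0L, terminals = 101L, mito = 211L, render = 307L,
               noise = 401L, fm = 503L, em = 601L, misc = 701L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483629)
}

# Robust noise scale: MAD about the median, Gaussian-consistent.
robust_sd <- function(x) stats::mad(x, constant = 1.4826)
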
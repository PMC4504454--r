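# Regression, Gaussian bell fitting and two-sample tests.

new_fit_result <- function(kind, params, r_squared, n, converged = TRUE) {
  structure(c(list(kind = kind), params,
              list(r_squared = r_squared, n = n, converged = converged)),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  if (x$kind == "linear") {
    cat(sprintf("<FitResult linear> slope=%.4g intercept=%.4g R2=%.4f n=%d\n",
                x$slope, x$intercept, x$r_squared, x$n))
  } else {
    cat(sprintf(
      "<FitResult gaussian-bell> a=%.4g mu=%.4g sigma=%.4g b=%.4g R2=%s n=%d%s\n",
      x$amplitude, x$center, x$width, x$baseline,
      formatC(x$r_squared, format = "f", digits = 4), x$n,
      if (x$converged) "" else " (NOT converged)"))
  }
  invisible(x)
}

#' Ordinary least-squares line fit
#'
#' @param x,y Numeric series (n >= 3 after dropping non-finite pairs).
#' @return A `FitResult` with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linfit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop_mgs("linfit needs at least 3 finite points",
             class = "mgsynapse_validation_error")
  }
  if (stats::sd(x) < 1e-12 * (abs(mean(x)) + 1)) {
    stop_mgs("degenerate fit: x is constant",
             class = "mgsynapse_degenerate_fit_error")
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  new_fit_result("linear",
                 list(slope = unname(coef(fit)[2L]),
                      intercept = unname(coef(fit)[1L])),
                 r_squared = r2, n = length(x))
}

#' Gaussian bell-curve fit
#'
#' Fits `y = a exp(-(x - mu)^2 / (2 sigma^2)) + b` by nonlinear least
#' squares with data-driven initialization (`mu0` at the argmax of y, width
#' from the second moment of the baseline-subtracted curve). The baseline
#' term is included because empirical density curves need not decay to zero
#' at the range edges. Non-convergence is flagged in the result, never an
#' error.
#'
#' @param x,y Numeric series (n >= 5).
#' @return A `FitResult` with `amplitude`, `center`, `width`, `baseline`,
#'   `r_squared`, `converged`.
#' @export
gauss_bell_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) {
    stop_mgs("gauss_bell_fit needs at least 5 points",
             class = "mgsynapse_validation_error")
  }
  b0 <- min(y); a0 <- max(y) - b0
  mu0 <- x[which.max(y)]
  w <- pmax(y - b0, 0)
  sigma0 <- if (sum(w) > 0) sqrt(sum(w * (x - mu0)^2) / sum(w)) else
    diff(range(x)) / 4
  sigma0 <- max(sigma0, diff(range(x)) / (2 * n))
  df <- data.frame(x = x, y = y)
  try_fit <- function(mu_start) {
    tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * sg^2)) + b, data = df,
                        start = list(a = a0, mu = mu_start, sg = sigma0,
                                     b = b0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- try_fit(mu0)
  # a start exactly on a symmetry point can make the initial Jacobian
  # singular; nudge and retry
  if (is.null(fit)) fit <- try_fit(mu0 + diff(range(x)) / (7 * n))
  if (is.null(fit)) {
    return(new_fit_result("gaussian-bell",
                          list(amplitude = NA_real_, center = NA_real_,
                               width = NA_real_, baseline = NA_real_),
                          r_squared = NA_real_, n = n, converged = FALSE))
  }
  cf <- coef(fit)
  pred <- cf[["a"]] * exp(-(x - cf[["mu"]])^2 / (2 * cf[["sg"]]^2)) + cf[["b"]]
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  conv <- isTRUE(fit$convInfo$isConv) && is.finite(cf[["sg"]])
  new_fit_result("gaussian-bell",
                 list(amplitude = unname(cf[["a"]]), center = unname(cf[["mu"]]),
                      width = abs(unname(cf[["sg"]])),
                      baseline = unname(cf[["b"]])),
                 r_squared = r2, n = n, converged = conv)
}

#' Two-sample comparison
#'
#' Two-tailed Student's t test (pooled variance by default, Welch optional)
#' or two-sample Kolmogorov-Smirnov test.
#'
#' @param a,b Numeric samples (t: n >= 2 each; ks: n >= 5 each).
#' @param test `"t"` or `"ks"`.
#' @param welch Use the Welch correction for the t test (default FALSE).
#' @return `list(test, statistic, p_value, n_a, n_b)`.
#' @export
compare_groups <- function(a, b, test = c("t", "ks"), welch = FALSE) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  need <- if (test == "t") 2L else 5L
  if (length(a) < need || length(b) < need) {
    stop_mgs("compare_groups('%s') needs at least %d values per group",
             test, need, class = "mgsynapse_validation_error")
  }
  if (test == "t") {
    ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  } else {
    ht <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  }
  list(test = test, statistic = unname(ht$statistic),
       p_value = unname(ht$p.value), n_a = length(a), n_b = length(b))
}
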
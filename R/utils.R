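# Internal helpers shared across modules.

# Condition constructors so the CLI can map failure kinds to exit codes
# (2 = bad input, 3 = fit failure).
stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("msf_input_error", "msf_error")))
}

stop_fit <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("msf_fit_error", "msf_error")))
}

# Closed-form simple linear regression; weights optional. Used in inner
# loops where lm() overhead matters (anchor scans, refinement iterations,
# replicate studies).
ols2 <- function(x, y, w = NULL) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_fit("simple regression needs >= 2 points (got %d)", length(x))
  }
  if (is.null(w)) w <- rep(1, length(x))
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  if (sxx <= 0) stop_fit("regression abscissae are constant")
  slope <- sum(w * (x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  list(intercept = intercept, slope = slope, fitted = fitted,
       residuals = y - fitted)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a single finite number", name)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
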
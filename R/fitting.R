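# Model fitting: OLS for the linear model, the hybrid anchored procedure
# for the curved models, and R^2-based model selection.

usable_points <- function(series) {
  d <- series$data
  bad <- d$incidence <= 0
  if (any(bad)) {
    warning(sprintf(
      "series %s: excluding %d zero-incidence age class(es) (%s); log undefined",
      series_key(series), sum(bad),
      paste(d$age_class[bad], collapse = ", ")), call. = FALSE)
  }
  d[!bad, , drop = FALSE]
}

#' Coefficient of determination on the ln-incidence scale
#'
#' \code{R^2 = 1 - SS_res / SS_tot} of the observed against predicted
#' ln-incidence values. The observed values must have nonzero variance.
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 points).
#' @return A real number in \code{(-Inf, 1]}.
#' @examples
#' r_squared(c(0, 1, 2), c(0.1, 1, 1.9))  # 0.99
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop_input("`observed` and `predicted` must be equal length >= 2")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) stop_input("zero variance in `observed`: R^2 undefined")
  1 - sum((observed - predicted)^2) / ss_tot
}

new_fit_result <- function(series, model_kind, params, predicted, d,
                           anchor_size = NA_integer_) {
  obs <- log(d$incidence)
  res <- obs - predicted
  names(res) <- d$age_class
  # a constant series fitted exactly by a zero-slope line is a perfect
  # fit even though R^2 is formally 0/0 there
  r2 <- if (stats::var(obs) == 0 && sum(res^2) < 1e-20) {
    1
  } else {
    r_squared(obs, predicted)
  }
  structure(list(
    cancer = series$cancer, gender = series$gender,
    population = series$population,
    model_kind = model_kind, params = params,
    r_squared = r2,
    residuals = res, n_used = nrow(d), anchor_size = anchor_size),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s) for %s / %s / %s\n", x$model_kind, x$cancer,
              x$gender, x$population))
  print(x$params)
  cat(sprintf("  R^2 = %.6f on %d age classes%s\n", x$r_squared, x$n_used,
              if (!is.na(x$anchor_size))
                sprintf(" (anchor: %d)", x$anchor_size) else ""))
  invisible(x)
}

#' Fit the linear log-log model
#'
#' Ordinary least squares of \code{ln I} on \code{ln t}. The fitted slope
#' and intercept are stored as [linear_params] via \code{r = slope + 1},
#' \code{k = exp(intercept)}. Zero-incidence age classes are excluded with
#' a warning (their logarithm is undefined); at least three usable classes
#' are required.
#'
#' @param series An [incidence_series].
#' @return A \code{fit_result} with \code{model_kind = "linear"}.
#' @examples
#' s <- generate_series(series_spec(linear_params(3.644, exp(-1.236))))
#' fit_linear(s)
#' @export
fit_linear <- function(series) {
  stopifnot(inherits(series, "incidence_series"))
  d <- usable_points(series)
  if (nrow(d) < 3L) {
    stop_fit("series %s: need >= 3 age classes with positive incidence (got %d)",
             series_key(series), nrow(d))
  }
  fit <- ols2(log(d$age_class), log(d$incidence))
  params <- linear_params(r = fit$slope + 1, k = exp(fit$intercept))
  new_fit_result(series, "linear", params, fit$fitted, d)
}

# Transform later-point residuals from the anchor line into the linear
# form of the curvature term: if d_t = ln I - (a0 + a1 ln t) then under
# the model d_t = ln(1 -/+ a2 t^a3), so
#   convex:  ln(1 - e^{d_t}) = ln a2 + a3 ln t  (needs d_t < 0)
#   concave: ln(e^{d_t} - 1) = ln a2 + a3 ln t  (needs d_t > 0)
curvature_transform <- function(dres, curvature) {
  if (curvature == "convex") log(-expm1(dres)) else log(expm1(dres))
}

# Residual sum of squares of the full curved model with (a0, a1) profiled
# out by OLS, as a function of (log a2, a3). Invalid convex regions get a
# large penalty so derivative-free search stays inside the domain.
profiled_rss <- function(par, x, y, t, curvature) {
  a2 <- exp(par[1])
  a3 <- par[2]
  term <- a2 * t^a3
  if (any(!is.finite(term))) return(1e12)
  if (curvature == "convex" && any(term >= 1)) {
    return(1e10 * (1 + max(term)))
  }
  curv <- if (curvature == "convex") log1p(-term) else log1p(term)
  f <- ols2(x, y - curv)
  sum((y - f$fitted - curv)^2)
}

#' Fit a convex or concave log-log model by the hybrid procedure
#'
#' The curved models are fitted in stages rather than by simultaneous
#' four-parameter nonlinear least squares:
#'
#' 1. \emph{Anchor scan}: the earliest \code{m} age classes (scanning
#'    \code{m = 3 .. n-2}, keeping the \code{m} whose anchor OLS has the
#'    highest R^2) form the "distinct linear part" — earliest because the
#'    curvature term grows with age for the parameter regimes these models
#'    target.
#' 2. \emph{Anchor OLS}: \code{(a0, a1)} from OLS on the anchor points.
#' 3. \emph{Algebraic curvature solve}: residuals of the later points from
#'    the anchor line are transformed (\code{ln(1 - e^d)} for convex,
#'    \code{ln(e^d - 1)} for concave) and regressed on \code{ln t}, giving
#'    \code{ln a2} (intercept) and \code{a3} (slope); with exactly two
#'    later points this reduces to the exact two-equation solution. At
#'    least two later points with residual signs compatible with the
#'    requested curvature (negative for convex, positive for concave) are
#'    required; otherwise the data carry no such curvature and the fit
#'    fails with a curvature-mismatch error.
#' 4. \emph{Refinement} (default on): the initial estimates are polished
#'    by alternating the two linear solves over all points — OLS for
#'    \code{(a0, a1)} given the curvature term, then the transformed
#'    regression for \code{(ln a2, a3)} — followed by a derivative-free /
#'    quasi-Newton minimization of the residual sum of squares over
#'    \code{(ln a2, a3)} only, with \code{(a0, a1)} always profiled out by
#'    OLS. On noise-free model data this recovers the generating
#'    coefficients to near machine precision.
#'
#' @param series An [incidence_series] with at least 5 usable age classes.
#' @param curvature \code{"convex"} or \code{"concave"}.
#' @param refine Run stage 4 (default \code{TRUE}).
#' @param max_refine Maximum alternating iterations.
#' @return A \code{fit_result} with the [curved_params], the global R^2
#'   over all points, and the anchor size used.
#' @examples
#' cp <- curved_params(-0.036, 0.1405, 0.007, 2.1, "concave")
#' s <- generate_series(series_spec(cp))
#' fit_curved(s, "concave")
#' @export
fit_curved <- function(series, curvature = c("convex", "concave"),
                       refine = TRUE, max_refine = 100) {
  stopifnot(inherits(series, "incidence_series"))
  curvature <- match.arg(curvature)
  d <- usable_points(series)
  n <- nrow(d)
  if (n < 5L) {
    stop_fit("series %s: curved fits need >= 5 usable age classes (got %d)",
             series_key(series), n)
  }
  t <- d$age_class
  x <- log(t)
  y <- log(d$incidence)

  # stage 1: anchor scan over the earliest m points
  best_m <- NA_integer_
  best_r2 <- -Inf
  for (m in 3:(n - 2L)) {
    f <- ols2(x[1:m], y[1:m])
    r2 <- r_squared(y[1:m], f$fitted)
    if (r2 > best_r2) {
      best_r2 <- r2
      best_m <- m
    }
  }
  m <- best_m

  # stage 2: anchor OLS for (a0, a1)
  anchor <- ols2(x[1:m], y[1:m])
  a0 <- anchor$intercept
  a1 <- anchor$slope

  # stage 3: algebraic curvature solve on the later points
  later <- (m + 1L):n
  dres <- y[later] - (a0 + a1 * x[later])
  comp <- if (curvature == "convex") dres < 0 else dres > 0
  if (sum(comp) < 2L) {
    stop_fit(paste0(
      "series %s: later-point residuals incompatible with %s curvature ",
      "(need >= 2 points with %s residuals from the anchor line)"),
      series_key(series), curvature,
      if (curvature == "convex") "negative" else "positive")
  }
  cf <- ols2(x[later][comp], curvature_transform(dres[comp], curvature))
  la2 <- cf$intercept
  a3 <- cf$slope

  if (refine) {
    # alternate the two linear solves over all points
    for (it in seq_len(max_refine)) {
      term <- exp(la2) * t^a3
      if (curvature == "convex" && any(term >= 1)) break
      curv <- if (curvature == "convex") log1p(-term) else log1p(term)
      f01 <- ols2(x, y - curv)
      dres <- y - f01$fitted
      comp <- if (curvature == "convex") dres < 0 else dres > 0
      if (sum(comp) < 2L) break
      cf <- ols2(x[comp], curvature_transform(dres[comp], curvature))
      delta <- max(abs(c(cf$intercept - la2, cf$slope - a3)))
      la2 <- cf$intercept
      a3 <- cf$slope
      if (!is.finite(delta) || delta < 1e-12) break
    }
    # variable-projection polish of (ln a2, a3). The RSS surface has a
    # degenerate ridge (a3 -> 0 makes the curvature term a constant that
    # the intercept absorbs), so a coarse grid of extra starting points,
    # parametrized by the curvature magnitude u = a2 t_max^a3 at the last
    # age class, guards the local searches against it.
    starts <- list(c(la2, a3))
    lt_max <- log(max(t))
    u_grid <- if (curvature == "convex") {
      c(0.2, 0.5, 0.8, 0.95)
    } else {
      c(0.1, 0.5, 2, 10, 40)
    }
    for (a3_try in c(0.15, 0.5, 1, 2, 3)) {
      for (u in u_grid) {
        starts <- c(starts, list(c(log(u) - a3_try * lt_max, a3_try)))
      }
    }
    rss0 <- vapply(starts, profiled_rss, numeric(1), x = x, y = y, t = t,
                   curvature = curvature)
    starts <- starts[order(rss0)][seq_len(3L)]
    best <- NULL
    for (st in starts) {
      o1 <- stats::optim(st, profiled_rss, x = x, y = y, t = t,
                         curvature = curvature, method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-15))
      o2 <- tryCatch(
        stats::optim(o1$par, profiled_rss, x = x, y = y, t = t,
                     curvature = curvature, method = "BFGS",
                     control = list(maxit = 200, reltol = 1e-15)),
        error = function(e) o1)
      cand <- if (o2$value <= o1$value) o2 else o1
      if (is.null(best) || cand$value < best$value) best <- cand
    }
    # restart the simplex at the optimum with a fresh (small) scale to
    # squeeze out the last digits NM leaves behind
    for (i in 1:2) {
      o3 <- stats::optim(best$par, profiled_rss, x = x, y = y, t = t,
                         curvature = curvature, method = "Nelder-Mead",
                         control = list(maxit = 500, reltol = 1e-15))
      if (o3$value < best$value) best <- o3 else break
    }
    if (best$value <= profiled_rss(c(la2, a3), x, y, t, curvature)) {
      la2 <- best$par[1]
      a3 <- best$par[2]
    }
    term <- exp(la2) * t^a3
    curv <- if (curvature == "convex") log1p(-term) else log1p(term)
    f01 <- ols2(x, y - curv)
    a0 <- f01$intercept
    a1 <- f01$slope
  }

  # The concave form is exactly symmetric under (a0, a1, a2, a3) ->
  # (a0 + ln a2, a1 + a3, 1/a2, -a3); report the canonical branch with
  # a3 > 0 (curvature growing with age).
  if (curvature == "concave" && a3 < 0 && exp(la2) > 0) {
    a0 <- a0 + la2
    a1 <- a1 + a3
    la2 <- -la2
    a3 <- -a3
  }

  params <- curved_params(a0, a1, exp(la2), a3, curvature)
  predicted <- curved_log_incidence(t, params)
  new_fit_result(series, curvature, params, predicted, d, anchor_size = m)
}

#' Fit all three models and select the best by R^2
#'
#' Attempts the linear, convex and concave fits; curved-fit failures (for
#' instance a curvature mismatch) are recorded rather than fatal. The
#' chosen model maximizes R^2 on the ln scale, with one parsimony
#' tie-break: the two-parameter linear model is preferred whenever its R^2
#' is within \code{tie_tolerance} of the best curved R^2, so a curvature
#' term is only accepted when it buys a real improvement.
#'
#' @param series An [incidence_series].
#' @param tie_tolerance Linear-preference margin on R^2 (default 0.005).
#' @return An object of class \code{selection_result}: list with
#'   \code{fits} (named list of successful \code{fit_result}s),
#'   \code{failures} (named character vector of error messages),
#'   \code{chosen} (model kind) and \code{tie_tolerance}.
#' @export
select_model <- function(series, tie_tolerance = 0.005) {
  stopifnot(inherits(series, "incidence_series"))
  stopifnot_scalar_number(tie_tolerance, "tie_tolerance")
  attempts <- list(
    linear = function() fit_linear(series),
    convex = function() fit_curved(series, "convex"),
    concave = function() fit_curved(series, "concave"))
  fits <- list()
  failures <- character(0)
  for (kind in names(attempts)) {
    res <- tryCatch(attempts[[kind]](), error = function(e) e)
    if (inherits(res, "error")) {
      failures[kind] <- conditionMessage(res)
    } else {
      fits[[kind]] <- res
    }
  }
  if (length(fits) == 0L) {
    stop_fit("series %s: all model fits failed (%s)", series_key(series),
             paste(failures, collapse = "; "))
  }
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  best <- max(r2)
  chosen <- if ("linear" %in% names(fits) &&
                r2[["linear"]] >= best - tie_tolerance) {
    "linear"
  } else {
    names(fits)[which.max(r2)]
  }
  structure(list(fits = fits, failures = failures, chosen = chosen,
                 tie_tolerance = tie_tolerance),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Model selection:\n")
  for (kind in names(x$fits)) {
    marker <- if (kind == x$chosen) " <- chosen" else ""
    cat(sprintf("  %-7s R^2 = %.6f%s\n", kind, x$fits[[kind]]$r_squared,
                marker))
  }
  for (kind in names(x$failures)) {
    cat(sprintf("  %-7s failed: %s\n", kind, x$failures[kind]))
  }
  invisible(x)
}
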
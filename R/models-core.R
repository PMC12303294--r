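# Core model equations and the ordered-event probability calculus.

#' Evaluate the linear log-log model
#'
#' Computes \code{ln I(t) = (r - 1) ln t + ln k}.
#'
#' @param t Age class(es), strictly positive.
#' @param params A [linear_params] object.
#' @return Numeric vector of ln-incidence values.
#' @examples
#' linear_log_incidence(1, linear_params(r = 3.64, k = 0.29))
#' @export
linear_log_incidence <- function(t, params) {
  stopifnot(inherits(params, "linear_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop_input("`t` must be strictly positive and finite")
  }
  params$slope * log(t) + params$intercept
}

#' Evaluate a convex or concave log-log model
#'
#' Computes \code{a0 + a1 ln t + ln(1 - a2 t^a3)} for convex curvature or
#' \code{a0 + a1 ln t + ln(1 + a2 t^a3)} for concave curvature. The convex
#' form requires \code{a2 t^a3 < 1} at every evaluated age; violations are
#' an error naming the offending ages, since the model is undefined there.
#'
#' @param t Age class(es), strictly positive.
#' @param params A [curved_params] object.
#' @return Numeric vector of ln-incidence values.
#' @examples
#' curved_log_incidence(1, curved_params(-0.54, 2.797, 0.73, 0.14, "convex"))
#' @export
curved_log_incidence <- function(t, params) {
  stopifnot(inherits(params, "curved_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop_input("`t` must be strictly positive and finite")
  }
  term <- params$a2 * t^params$a3
  if (params$curvature == "convex") {
    bad <- term >= 1
    if (any(bad)) {
      stop_input(
        "convex model undefined (a2 * t^a3 >= 1) at t = %s",
        paste(signif(t[bad], 6), collapse = ", "))
    }
    params$a0 + params$a1 * log(t) + log1p(-term)
  } else {
    params$a0 + params$a1 * log(t) + log1p(term)
  }
}

#' Probability of the first r - 1 events occurring in any order
#'
#' Under the rare-event approximation, the probability that the first
#' \code{r - 1} of the required events have all occurred (in any order)
#' within time \code{t} is the product of the individual \code{k_i t}
#' probabilities: \code{(k_1 t)(k_2 t) ... (k_(r-1) t)}. With \code{r = 1}
#' the product is empty and the probability is 1.
#'
#' @param rates A [multistage_rates] object.
#' @param t Elapsed time (>= 0); may be a vector.
#' @return Numeric vector of probabilities (values can exceed 1 when the
#'   rare-event approximation is violated; see [check_event_rates()]).
#' @examples
#' unordered_event_probability(multistage_rates(c(0.1, 0.1, 0.5)), t = 2)
#' @export
unordered_event_probability <- function(rates, t) {
  stopifnot(inherits(rates, "multistage_rates"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_input("`t` must be non-negative and finite")
  }
  r <- rates$r
  prod(rates$rates[seq_len(r - 1L)]) * t^(r - 1L)
}

#' Probability of the first r - 1 events occurring in their required order
#'
#' Only one of the \code{(r-1)!} permutations of the first \code{r - 1}
#' events is the required order, so the ordered probability is the unordered
#' probability divided by \code{(r-1)!}.
#'
#' @inheritParams unordered_event_probability
#' @return Numeric vector of probabilities.
#' @examples
#' ordered_event_probability(multistage_rates(c(0.1, 0.1, 0.5)), t = 2)
#' @export
ordered_event_probability <- function(rates, t) {
  unordered_event_probability(rates, t) / factorial(rates$r - 1L)
}

#' Aggregated sequence probability k
#'
#' Collapses the per-event rates into the single constant \code{k} that
#' multiplies \code{t^(r-1)} in the hazard: the ordered completion
#' probability of the first \code{r - 1} events times the rate \code{k_r} of
#' the final event, i.e. \code{k = (k_1 k_2 ... k_(r-1)) k_r / (r-1)!}.
#' For \code{r = 1} the hazard is constant and \code{k = k_1}.
#'
#' @param rates A [multistage_rates] object.
#' @return The aggregated probability per unit time \code{k}.
#' @examples
#' aggregate_k(multistage_rates(c(1, 1, 1)))  # 0.5
#' @export
aggregate_k <- function(rates) {
  stopifnot(inherits(rates, "multistage_rates"))
  r <- rates$r
  prod(rates$rates[seq_len(r - 1L)]) * rates$rates[r] / factorial(r - 1L)
}

#' Rescale the time axis of a fitted linear model
#'
#' If age is measured in units \code{w} times larger, every per-event rate
#' is divided by \code{w}, which divides the aggregated \code{k} by
#' \code{w^(r-1)}. The log-log slope \code{r - 1} is unchanged; only the
#' intercept moves: \code{ln k' = ln k - (r - 1) ln w}. Consequently model
#' predictions are invariant: evaluating the rescaled parameters at
#' \code{t / w} reproduces the original \code{ln I(t)}.
#'
#' @param params A [linear_params] object.
#' @param w Positive rescaling factor for the time axis.
#' @return A new [linear_params] object.
#' @examples
#' rescale_time(linear_params(r = 3, k = 1), w = 2)
#' @export
rescale_time <- function(params, w) {
  stopifnot(inherits(params, "linear_params"))
  stopifnot_scalar_number(w, "w")
  if (w <= 0) stop_input("`w` must be > 0 (got %g)", w)
  linear_params(r = params$r, k = params$k / w^(params$r - 1))
}

#' Map curved-model coefficients to mechanistic quantities
#'
#' Translates the phenomenological coefficients \code{a0..a3} of a curved
#' model into biological quantities under one of two readings:
#'
#' \describe{
#'   \item{heterogeneity}{Two population subgroups (or pathways) with
#'     sequence probabilities \code{k_p}, \code{k_q} and age-scaling
#'     exponents \code{p}, \code{q} share \code{r} rate-limiting steps:
#'     \code{a0 = ln k_p}, \code{a1 = r + p - 1}, \code{a2 = k_q / k_p},
#'     \code{a3 = q - p}. Because \code{a1} determines only the sum
#'     \code{r + p}, exactly one of \code{p} or \code{r} must be supplied;
#'     the other is solved from \code{a1}.}
#'   \item{age_effect}{A single pathway with aggregated probability
#'     \code{k} is modified by a decelerating factor (convex; rate
#'     \code{k_d}, exponent \code{d}) or an accelerating factor (concave;
#'     rate \code{k_a}, exponent \code{a}): \code{a0 = ln k},
#'     \code{a1 = r - 1} (so \code{r = a1 + 1} directly),
#'     \code{a2 = k_d / k} (or \code{k_a / k}) and \code{a3 = d - r + 1}
#'     (or \code{a - r + 1}). Neither \code{p} nor \code{r} is accepted.}
#' }
#'
#' @param params A [curved_params] object.
#' @param mode \code{"heterogeneity"} or \code{"age_effect"}.
#' @param p,r Under the heterogeneity reading, supply exactly one: the
#'   assumed subgroup age exponent \code{p} or the assumed step count
#'   \code{r}.
#' @return An object of class \code{mechanistic_params}; see
#'   [mechanistic_to_curved()] for the inverse map.
#' @examples
#' cp <- curved_params(-0.54, 2.797, 0.73, 0.14, "convex")
#' map_curved_to_mechanistic(cp, "heterogeneity", p = 0)
#' @export
map_curved_to_mechanistic <- function(params,
                                      mode = c("heterogeneity", "age_effect"),
                                      p = NULL, r = NULL) {
  stopifnot(inherits(params, "curved_params"))
  mode <- match.arg(mode)
  if (mode == "heterogeneity") {
    if (is.null(p) == is.null(r)) {
      stop_input(paste0(
        "heterogeneity mode needs exactly one of `p` or `r`: ",
        "(r, p) are only jointly identified through a1 = r + p - 1"))
    }
    if (is.null(p)) {
      stopifnot_scalar_number(r, "r")
      p <- params$a1 - r + 1
    } else {
      stopifnot_scalar_number(p, "p")
      r <- params$a1 - p + 1
    }
    k_p <- exp(params$a0)
    out <- list(mode = "heterogeneity", curvature = params$curvature,
                k_p = k_p, k_q = params$a2 * k_p,
                p = p, q = params$a3 + p, r = r)
  } else {
    if (!is.null(p) || !is.null(r)) {
      stop_input("age_effect mode derives r from a1; do not supply `p` or `r`")
    }
    r <- params$a1 + 1
    k <- exp(params$a0)
    factor_rate <- params$a2 * k
    factor_exponent <- params$a3 + r - 1
    out <- list(mode = "age_effect", curvature = params$curvature,
                k = k, r = r,
                factor_rate = factor_rate,
                factor_exponent = factor_exponent)
    # conventional names: decelerating (k_d, d) for convex,
    # accelerating (k_a, a) for concave
    if (params$curvature == "convex") {
      out$k_d <- factor_rate
      out$d <- factor_exponent
    } else {
      out$k_a <- factor_rate
      out$a <- factor_exponent
    }
  }
  structure(out, class = "mechanistic_params")
}

#' Reassemble curved-model coefficients from mechanistic quantities
#'
#' Inverse of [map_curved_to_mechanistic()]: rebuilds \code{(a0, a1, a2,
#' a3)} from the mechanistic parametrization, so that the composition of the
#' two maps is the identity.
#'
#' @param mech A \code{mechanistic_params} object.
#' @return A [curved_params] object.
#' @export
mechanistic_to_curved <- function(mech) {
  stopifnot(inherits(mech, "mechanistic_params"))
  if (mech$mode == "heterogeneity") {
    curved_params(a0 = log(mech$k_p),
                  a1 = mech$r + mech$p - 1,
                  a2 = mech$k_q / mech$k_p,
                  a3 = mech$q - mech$p,
                  curvature = mech$curvature)
  } else {
    curved_params(a0 = log(mech$k),
                  a1 = mech$r - 1,
                  a2 = mech$factor_rate / mech$k,
                  a3 = mech$factor_exponent - mech$r + 1,
                  curvature = mech$curvature)
  }
}

#' @export
print.mechanistic_params <- function(x, ...) {
  if (x$mode == "heterogeneity") {
    cat("Mechanistic reading: population heterogeneity\n")
    cat(sprintf("  main subgroup:  k_p = %.4g, age exponent p = %.4g\n",
                x$k_p, x$p))
    cat(sprintf("  second subgroup: k_q = %.4g, age exponent q = %.4g\n",
                x$k_q, x$q))
    cat(sprintf("  shared rate-limiting steps: r = %.4g\n", x$r))
  } else {
    kind <- if (x$curvature == "convex") "decelerating" else "accelerating"
    nm <- if (x$curvature == "convex") c("k_d", "d") else c("k_a", "a")
    cat("Mechanistic reading: age-related effect\n")
    cat(sprintf("  aggregated sequence probability k = %.4g, r = %.4g\n",
                x$k, x$r))
    cat(sprintf("  %s factor: %s = %.4g, exponent %s = %.4g\n",
                kind, nm[1], x$factor_rate, nm[2], x$factor_exponent))
  }
  invisible(x)
}
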
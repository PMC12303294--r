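#' Parameters of the linear log-log incidence model
#'
#' The linear model is \code{ln I(t) = (r - 1) ln t + ln k}: on a log-log
#' plot the age-specific incidence rate is a straight line whose slope is
#' \code{r - 1} (one less than the number of rate-limiting events) and whose
#' intercept is \code{ln k}, the log of the aggregated probability per unit
#' time of the whole ordered event sequence.
#'
#' @param r Number of rate-limiting events (real, > 0; non-integer values
#'   arise from fitting and are kept as-is).
#' @param k Aggregated ordered-sequence probability per unit time (> 0).
#' @return An object of class \code{linear_params} with elements \code{r},
#'   \code{k}, \code{slope} (\code{r - 1}) and \code{intercept}
#'   (\code{ln k}).
#' @examples
#' linear_params(r = 3.64, k = exp(-1.24))
#' @export
linear_params <- function(r, k) {
  stopifnot_scalar_number(r, "r")
  stopifnot_scalar_number(k, "k")
  if (r <= 0) stop_input("`r` must be > 0 (got %g)", r)
  if (k <= 0) stop_input("`k` must be > 0 (got %g)", k)
  structure(list(r = r, k = k, slope = r - 1, intercept = log(k)),
            class = "linear_params")
}

#' @export
print.linear_params <- function(x, ...) {
  cat(sprintf("Linear log-log model: ln I(t) = %.4g ln t + (%.4g)\n",
              x$slope, x$intercept))
  cat(sprintf("  r = %.4g rate-limiting events, k = %.4g per unit time\n",
              x$r, x$k))
  invisible(x)
}

#' Parameters of the curved (convex/concave) log-log incidence models
#'
#' The curved generalizations add a curvature term to the linear model:
#' \code{ln I(t) = a0 + a1 ln t + ln(1 - a2 t^a3)} (convex upwards, incidence
#' decelerating at older ages) or \code{ln I(t) = a0 + a1 ln t +
#' ln(1 + a2 t^a3)} (concave upwards, accelerating). The coefficients map
#' onto mechanistic quantities via [map_curved_to_mechanistic()].
#'
#' For the convex model the argument of the logarithm must stay positive,
#' i.e. \code{a2 * t^a3 < 1} over the evaluated age range; this is checked at
#' evaluation time (not construction) because it depends on the ages used.
#'
#' @param a0,a1,a2,a3 Real coefficients; \code{a2 >= 0}.
#' @param curvature \code{"convex"} or \code{"concave"}.
#' @return An object of class \code{curved_params}.
#' @examples
#' curved_params(-0.54, 2.797, 0.73, 0.14, "convex")
#' @export
curved_params <- function(a0, a1, a2, a3, curvature = c("convex", "concave")) {
  curvature <- match.arg(curvature)
  for (nm in c("a0", "a1", "a2", "a3")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  if (a2 < 0) stop_input("`a2` must be >= 0 (got %g)", a2)
  structure(list(a0 = a0, a1 = a1, a2 = a2, a3 = a3, curvature = curvature),
            class = "curved_params")
}

#' @export
print.curved_params <- function(x, ...) {
  sign <- if (x$curvature == "convex") "-" else "+"
  label <- paste0(toupper(substring(x$curvature, 1, 1)),
                  substring(x$curvature, 2))
  cat(sprintf(
    "%s log-log model: ln I(t) = %.4g + %.4g ln t + ln(1 %s %.4g t^%.4g)\n",
    label, x$a0, x$a1, sign, x$a2, x$a3))
  invisible(x)
}

#' Per-event rates of an ordered multistage event sequence
#'
#' Holds the rates \code{k_1 .. k_r} (probability per unit time) of the
#' \code{r} discrete, irreversible, rate-limiting events whose ordered
#' completion triggers disease onset. The power-law approximation behind the
#' log-log models assumes each event is rare over the observation window
#' (\code{k_i * t << 1}); [check_event_rates()] warns when that assumption
#' is strained.
#'
#' @param rates Numeric vector of per-event rates, all > 0, in the order the
#'   events must occur.
#' @return An object of class \code{multistage_rates} with elements
#'   \code{rates} and \code{r = length(rates)}.
#' @examples
#' multistage_rates(c(0.01, 0.01, 0.01))
#' @export
multistage_rates <- function(rates) {
  if (!is.numeric(rates) || length(rates) < 1L || any(!is.finite(rates))) {
    stop_input("`rates` must be a non-empty finite numeric vector")
  }
  if (any(rates <= 0)) stop_input("all event rates must be > 0")
  structure(list(rates = as.numeric(rates), r = length(rates)),
            class = "multistage_rates")
}

#' @export
print.multistage_rates <- function(x, ...) {
  cat(sprintf("Ordered multistage event sequence: r = %d events\n", x$r))
  cat("  rates:", paste(signif(x$rates, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Warn when event rates violate the rare-event approximation
#'
#' The power-law hazard \code{k t^(r-1)} approximates the multistage process
#' only while every \code{k_i * t} stays well below 1. This check issues a
#' warning (not an error) when \code{k_i * t_max >= 1} for any event, since
#' validity depends on the follow-up horizon rather than the rates alone.
#'
#' @param rates A [multistage_rates] object.
#' @param t_max Largest time/age at which the approximation will be used.
#' @return \code{TRUE} (invisibly) if the rare-event condition holds,
#'   \code{FALSE} otherwise.
#' @export
check_event_rates <- function(rates, t_max) {
  stopifnot(inherits(rates, "multistage_rates"))
  stopifnot_scalar_number(t_max, "t_max")
  bad <- which(rates$rates * t_max >= 1)
  if (length(bad) > 0L) {
    warning(sprintf(
      "rare-event approximation strained: k_i * t_max >= 1 for event(s) %s",
      paste(bad, collapse = ", ")), call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
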
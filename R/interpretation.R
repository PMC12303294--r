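# Translate fitted coefficients into biological quantities.

#' Interpret a linear log-log fit mechanistically
#'
#' The fitted slope is \code{r - 1}, so \code{r = slope + 1} estimates the
#' number of sequential rate-limiting events; since fitted \code{r} is
#' rarely an integer it is reported both as the point value and as the
#' bracketing integer range (e.g. slope 2.64 reads as "3 to 4 steps"). The
#' intercept is \code{ln k}, so \code{k = exp(intercept)} estimates the
#' aggregated probability per unit time of the whole ordered sequence.
#'
#' @param fit A \code{fit_result} with \code{model_kind = "linear"}.
#' @return An object of class \code{interpretation} with \code{r_point},
#'   \code{r_range}, \code{k}, and narrative \code{notes}.
#' @examples
#' s <- generate_series(series_spec(linear_params(3.64, exp(-1.24))))
#' interpret_linear(fit_linear(s))
#' @export
interpret_linear <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$model_kind != "linear") {
    stop_input("interpret_linear needs a linear fit (got %s)", fit$model_kind)
  }
  r <- fit$params$r
  k <- fit$params$k
  r_range <- c(floor(r), ceiling(r))
  notes <- c(
    sprintf(paste0(
      "The log-log slope %.3f corresponds to r - 1, implying r = %.3f: ",
      "about %d to %d sequential rate-limiting events."),
      fit$params$slope, r, r_range[1], r_range[2]),
    sprintf(paste0(
      "The intercept ln k = %.3f gives k = %.4g, the aggregated ",
      "probability per unit time of the whole ordered event sequence."),
      fit$params$intercept, k))
  structure(list(r_point = r, r_range = r_range, k = k,
                 mechanistic = NULL, h = NULL, notes = notes),
            class = "interpretation")
}

#' Interpret a curved fit mechanistically
#'
#' Delegates the coefficient translation to [map_curved_to_mechanistic()]
#' and wraps it with narrative notes: under the heterogeneity reading the
#' curvature reflects a second population subgroup; under the age-effect
#' reading it reflects a decelerating factor (convex) or an accelerating
#' factor (concave) acting on a single pathway.
#'
#' @param fit A \code{fit_result} with a curved \code{model_kind}.
#' @param mode \code{"heterogeneity"} or \code{"age_effect"}.
#' @param p,r For heterogeneity, exactly one of the assumed subgroup age
#'   exponent \code{p} or step count \code{r} (the pair is not jointly
#'   identifiable from the slope coefficient alone).
#' @return An \code{interpretation} whose \code{mechanistic} element is
#'   the [map_curved_to_mechanistic()] result.
#' @export
interpret_curved <- function(fit, mode = c("heterogeneity", "age_effect"),
                             p = NULL, r = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$model_kind %in% c("convex", "concave")) {
    stop_input("interpret_curved needs a convex/concave fit (got %s)",
               fit$model_kind)
  }
  mode <- match.arg(mode)
  mech <- map_curved_to_mechanistic(fit$params, mode, p = p, r = r)
  a2 <- fit$params$a2
  notes <- if (a2 == 0) {
    "The curvature coefficient a2 = 0: the model reduces to the linear form."
  } else if (mode == "heterogeneity") {
    sprintf(paste0(
      "Heterogeneity reading: a main subgroup with k_p = %.4g (age exponent ",
      "p = %.3g) and a second subgroup with k_q = %.4g (q = %.3g) share ",
      "r = %.3g rate-limiting steps; the subgroup mixture produces the %s ",
      "curvature."), mech$k_p, mech$p, mech$k_q, mech$q, mech$r,
      fit$model_kind)
  } else {
    kind <- if (fit$model_kind == "convex") "decelerating" else "accelerating"
    sprintf(paste0(
      "Age-effect reading: a single pathway with k = %.4g and r = %.3g ",
      "steps is modified by a %s factor with probability %.4g and age ",
      "exponent %.3g."), mech$k, mech$r, kind, mech$factor_rate,
      mech$factor_exponent)
  }
  structure(list(r_point = mech$r, r_range = c(floor(mech$r),
                                               ceiling(mech$r)),
                 k = if (mode == "age_effect") mech$k else mech$k_p,
                 mechanistic = mech, h = NULL, notes = notes),
            class = "interpretation")
}

#' Decompose a log-log slope under a time-varying event rate
#'
#' If the rate of one rate-limiting event is itself proportional to
#' \code{t^h} (a violation of the constant-rate assumption), the log-log
#' slope becomes \code{h + r - 1} while remaining visually linear, so the
#' slope alone no longer counts events. Given an assumed \code{h}, this
#' recovers \code{r = slope - h + 1}; with \code{h = 0} it reduces to the
#' standard reading. Gender or population differences in slope for the
#' same cancer can then be attributed to different \code{h} rather than
#' different \code{r}. \code{h} is not estimable from a single series and
#' must be supplied.
#'
#' @param slope Fitted log-log slope.
#' @param h Assumed exponent of the time-dependence of the event rate
#'   (default 0: constant rates).
#' @return The implied number of rate-limiting events \code{r}.
#' @examples
#' decompose_slope(2.64, h = 0)    # 3.64
#' decompose_slope(2.64, h = 0.5)  # 3.14
#' @export
decompose_slope <- function(slope, h = 0) {
  stopifnot_scalar_number(slope, "slope")
  stopifnot_scalar_number(h, "h")
  slope - h + 1
}

#' @export
print.interpretation <- function(x, ...) {
  cat(sprintf("r = %.4g (%d to %d rate-limiting events), k = %.4g\n",
              x$r_point, x$r_range[1], x$r_range[2], x$k))
  for (n in x$notes) cat(strwrap(n, width = 76, exdent = 2), sep = "\n")
  invisible(x)
}
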
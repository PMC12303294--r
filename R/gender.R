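# Combined-gender series and the slope-intermediacy algebra.
#
# The both-genders incidence at an age class is the arithmetic mean of the
# female and male rates, I_fm = (I_f + I_m) / 2. Writing the pairwise
# log-log slope between two age classes t1 < t2 as
#   S = (ln I(t2) - ln I(t1)) / (ln t2 - ln t1),
# the combined slope can be expressed from either gender slope plus a
# correction driven by the male-to-female incidence ratio:
#   S_fm = S_f + ln[(1 + I_m2/I_f2) / (1 + I_m1/I_f1)] / dln t
#        = S_m + ln[(1 + I_f2/I_m2) / (1 + I_f1/I_m1)] / dln t.
# Both corrections have the sign that forces S_fm strictly between S_f and
# S_m whenever the two differ, and to equal them when the genders coincide.

#' Combine a female and a male series into a both-genders series
#'
#' The both-genders age-specific incidence rate is the unweighted
#' arithmetic mean of the female and male rates at each age class.
#'
#' @param female,male [incidence_series] objects with identical age
#'   classes.
#' @return An [incidence_series] with \code{gender = "both"}.
#' @export
combine_genders <- function(female, male) {
  stopifnot(inherits(female, "incidence_series"),
            inherits(male, "incidence_series"))
  if (!identical(female$data$age_class, male$data$age_class)) {
    stop_input("female and male series must share identical age classes")
  }
  lab <- female$data$age_label
  incidence_series(
    cancer = female$cancer, gender = "both",
    age_class = female$data$age_class,
    incidence = (female$data$incidence + male$data$incidence) / 2,
    age_label = if (all(is.na(lab))) NULL else lab,
    population = female$population)
}

#' Pairwise log-log slope between two age classes
#'
#' Computes \code{(ln I(t2) - ln I(t1)) / (ln t2 - ln t1)} for two age
#' classes of a series. Both incidences must be strictly positive and
#' \code{t2 > t1 > 0}.
#'
#' @param series An [incidence_series].
#' @param t1,t2 Age classes present in the series, \code{t1 < t2}.
#' @return The log-log slope (a real number).
#' @export
pairwise_slope <- function(series, t1, t2) {
  stopifnot(inherits(series, "incidence_series"))
  stopifnot_scalar_number(t1, "t1")
  stopifnot_scalar_number(t2, "t2")
  if (t1 <= 0 || t2 <= t1) stop_input("need t2 > t1 > 0")
  i1 <- series$data$incidence[match(t1, series$data$age_class)]
  i2 <- series$data$incidence[match(t2, series$data$age_class)]
  if (is.na(i1) || is.na(i2)) {
    stop_input("age class %g or %g not present in series %s", t1, t2,
               series_key(series))
  }
  if (i1 <= 0 || i2 <= 0) {
    stop_input("zero incidence at t = %g or %g: slope undefined", t1, t2)
  }
  (log(i2) - log(i1)) / (log(t2) - log(t1))
}

#' Female, male and combined slopes between two age classes
#'
#' Computes the three pairwise log-log slopes and verifies the combined
#' slope by two independent routes: directly from the combined series, and
#' through the correction-term identities (see the header of this file).
#' The two routes must agree to floating tolerance; disagreement indicates
#' corrupted input and is an error. When the gender slopes differ, the
#' combined slope is strictly intermediate; the \code{intermediate} flag
#' records this.
#'
#' @param female,male [incidence_series] objects with identical age
#'   classes.
#' @param t1,t2 Age classes, \code{t1 < t2}.
#' @return An object of class \code{slope_triple}: list with \code{s_f},
#'   \code{s_m}, \code{s_fm}, \code{s_fm_via_f}, \code{s_fm_via_m},
#'   \code{t_pair}, \code{intermediate}.
#' @examples
#' f <- incidence_series("x", "female", c(1, 3), c(1, 2))
#' m <- incidence_series("x", "male", c(1, 3), c(1, 8))
#' slope_triple(f, m, 1, 3)
#' @export
slope_triple <- function(female, male, t1, t2) {
  s_f <- pairwise_slope(female, t1, t2)
  s_m <- pairwise_slope(male, t1, t2)
  comb <- combine_genders(female, male)
  s_fm <- pairwise_slope(comb, t1, t2)

  if1 <- female$data$incidence[match(t1, female$data$age_class)]
  if2 <- female$data$incidence[match(t2, female$data$age_class)]
  im1 <- male$data$incidence[match(t1, male$data$age_class)]
  im2 <- male$data$incidence[match(t2, male$data$age_class)]
  dlt <- log(t2) - log(t1)
  s_fm_via_f <- s_f + log((1 + im2 / if2) / (1 + im1 / if1)) / dlt
  s_fm_via_m <- s_m + log((1 + if2 / im2) / (1 + if1 / im1)) / dlt

  tol <- 1e-8 * max(1, abs(s_fm))
  if (abs(s_fm - s_fm_via_f) > tol || abs(s_fm - s_fm_via_m) > tol) {
    stop_fit("combined-slope identity violated (direct %.12g vs %.12g / %.12g)",
             s_fm, s_fm_via_f, s_fm_via_m)
  }
  intermediate <- if (s_f == s_m) {
    s_fm == s_f
  } else {
    s_fm > min(s_f, s_m) && s_fm < max(s_f, s_m)
  }
  structure(list(s_f = s_f, s_m = s_m, s_fm = s_fm,
                 s_fm_via_f = s_fm_via_f, s_fm_via_m = s_fm_via_m,
                 t_pair = c(t1, t2), intermediate = intermediate),
            class = "slope_triple")
}

#' @export
print.slope_triple <- function(x, ...) {
  cat(sprintf("Log-log slopes over t = (%g, %g):\n", x$t_pair[1], x$t_pair[2]))
  cat(sprintf("  female %.4f | male %.4f | combined %.4f (intermediate: %s)\n",
              x$s_f, x$s_m, x$s_fm, x$intermediate))
  invisible(x)
}

#' Slope triples over all consecutive age-class pairs
#'
#' Applies [slope_triple()] to every consecutive pair of age classes of a
#' female/male pair and returns a table, one row per pair.
#'
#' @inheritParams slope_triple
#' @return A data frame with columns \code{t1}, \code{t2}, \code{s_f},
#'   \code{s_m}, \code{s_fm}, \code{intermediate}.
#' @export
slope_triples <- function(female, male) {
  cls <- female$data$age_class
  if (length(cls) < 2L) stop_input("need at least two age classes")
  rows <- lapply(seq_len(length(cls) - 1L), function(i) {
    tr <- slope_triple(female, male, cls[i], cls[i + 1L])
    data.frame(t1 = cls[i], t2 = cls[i + 1L], s_f = tr$s_f, s_m = tr$s_m,
               s_fm = tr$s_fm, intermediate = tr$intermediate)
  })
  do.call(rbind, rows)
}

#' OLS slope comparison between gender series and their combination
#'
#' Fits the linear log-log model to the female, male and combined series
#' and reports whether the combined OLS slope lies within the range of the
#' two gender OLS slopes. Unlike the two-point algebra, OLS intermediacy
#' is an empirical regularity rather than a theorem, so it is reported,
#' not asserted.
#'
#' @inheritParams slope_triple
#' @return A list with \code{slope_f}, \code{slope_m}, \code{slope_fm},
#'   \code{within_range}.
#' @export
gender_slope_summary <- function(female, male) {
  comb <- combine_genders(female, male)
  sf <- fit_linear(female)$params$slope
  sm <- fit_linear(male)$params$slope
  sfm <- fit_linear(comb)$params$slope
  list(slope_f = sf, slope_m = sm, slope_fm = sfm,
       within_range = sfm >= min(sf, sm) && sfm <= max(sf, sm))
}
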
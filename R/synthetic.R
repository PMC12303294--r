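# Synthetic incidence series and multistage cohort simulation.

#' Specification of a synthetic incidence series
#'
#' Describes a series to be generated from one of the three log-log models
#' plus additive Gaussian noise on the ln-incidence scale (equivalently,
#' multiplicative lognormal noise on the natural scale — the error model
#' conjugate to fitting on the log scale). The default eight age classes
#' mirror the usual registry age-group structure after integer renumbering.
#'
#' @param params A [linear_params] or [curved_params] object.
#' @param age_classes Strictly increasing positive integers (default 1:8).
#' @param noise_sd Standard deviation of the Gaussian noise on the ln scale
#'   (>= 0; 0 gives exact model values).
#' @param seed Optional integer seed; generation is deterministic given it.
#' @param cancer,gender,population Labels for the generated series.
#' @return An object of class \code{series_spec}.
#' @examples
#' series_spec(linear_params(r = 3.644, k = exp(-1.236)), noise_sd = 0.05,
#'             seed = 1)
#' @export
series_spec <- function(params, age_classes = 1:8, noise_sd = 0, seed = NULL,
                        cancer = "synthetic", gender = "both",
                        population = "synthetic") {
  if (!inherits(params, c("linear_params", "curved_params"))) {
    stop_input("`params` must be linear_params or curved_params")
  }
  if (!is.numeric(age_classes) || length(age_classes) < 1L ||
      any(age_classes < 1) || is.unsorted(age_classes, strictly = TRUE)) {
    stop_input("`age_classes` must be strictly increasing and >= 1")
  }
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  structure(list(params = params, age_classes = as.integer(age_classes),
                 noise_sd = noise_sd, seed = seed, cancer = cancer,
                 gender = gender, population = population),
            class = "series_spec")
}

#' Generate a synthetic incidence series
#'
#' Evaluates the model of the spec at its age classes, adds
#' \code{N(0, noise_sd^2)} noise on the ln-incidence scale, and returns the
#' series on the natural incidence scale. With \code{noise_sd = 0} the
#' series equals the model prediction exactly, so fitting the matching
#' model recovers the generating coefficients. Deterministic given the
#' spec's seed. For convex parameters the whole requested age range must
#' satisfy \code{a2 t^a3 < 1}; offending classes are reported otherwise.
#'
#' @param spec A [series_spec].
#' @return An [incidence_series].
#' @examples
#' s <- generate_series(series_spec(linear_params(3.644, exp(-1.236))))
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  t <- spec$age_classes
  ln_i <- if (inherits(spec$params, "linear_params")) {
    linear_log_incidence(t, spec$params)
  } else {
    curved_log_incidence(t, spec$params)  # errors list offending t
  }
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    ln_i <- ln_i + stats::rnorm(length(t), 0, spec$noise_sd)
  }
  incidence_series(cancer = spec$cancer, gender = spec$gender,
                   age_class = t, incidence = exp(ln_i),
                   population = spec$population)
}

#' Generate a paired female/male series plus their combined series
#'
#' Generates the two gender series from their specs and the both-genders
#' series, whose incidence at every age class is the arithmetic mean of
#' the female and male rates.
#'
#' @param female,male [series_spec] objects sharing identical age classes.
#' @return A list with elements \code{female}, \code{male}, \code{combined}.
#' @export
generate_gender_pair <- function(female, male) {
  stopifnot(inherits(female, "series_spec"), inherits(male, "series_spec"))
  if (!identical(female$age_classes, male$age_classes)) {
    stop_input("female and male specs must share identical age classes")
  }
  f <- generate_series(female)
  m <- generate_series(male)
  f$gender <- "female"
  m$gender <- "male"
  list(female = f, male = m, combined = combine_genders(f, m))
}

#' Specification of a simulated multistage cohort
#'
#' Describes a cohort of individuals who each accrue the \code{r} ordered
#' rate-limiting events as sequential exponential waiting times (each
#' event's clock starts when the previous event completes), with disease
#' onset at completion of the last event and administrative censoring at
#' \code{max_age}.
#'
#' @param rates A [multistage_rates] object.
#' @param n_individuals Cohort size (>= 1).
#' @param max_age Follow-up horizon (> 0), in the same time units as the
#'   rates.
#' @param n_bins Number of equal-width hazard-estimation bins on
#'   \code{(0, max_age]} (>= 2).
#' @param seed Optional integer seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(rates, n_individuals, max_age, n_bins = 10,
                        seed = NULL) {
  stopifnot(inherits(rates, "multistage_rates"))
  if (!is.numeric(n_individuals) || n_individuals < 1) {
    stop_input("`n_individuals` must be >= 1")
  }
  stopifnot_scalar_number(max_age, "max_age")
  if (max_age <= 0) stop_input("`max_age` must be > 0")
  if (!is.numeric(n_bins) || n_bins < 2) stop_input("`n_bins` must be >= 2")
  structure(list(rates = rates, n_individuals = as.integer(n_individuals),
                 max_age = max_age, n_bins = as.integer(n_bins), seed = seed),
            class = "cohort_spec")
}

#' Simulate onset ages for a multistage cohort
#'
#' Each individual's onset age is the sum of \code{r} independent
#' exponential waiting times with rates \code{k_1 .. k_r}, taken in order.
#' Onsets beyond \code{max_age} are censored (the individual contributes
#' \code{max_age} of person-time and no event). A warning is issued when
#' any \code{k_i * max_age >= 1}, i.e. when the power-law regime the
#' log-log models live in is no longer a good approximation.
#'
#' @param spec A [cohort_spec].
#' @return An object of class \code{cohort_sim}: list with \code{onset}
#'   (true onset ages), \code{censored} (logical), and the \code{spec}.
#' @examples
#' sim <- simulate_cohort(cohort_spec(multistage_rates(c(0.05, 0.05)),
#'                                    n_individuals = 1000, max_age = 10,
#'                                    seed = 1))
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_event_rates(spec$rates, spec$max_age)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_individuals
  onset <- numeric(n)
  for (k_i in spec$rates$rates) {
    onset <- onset + stats::rexp(n, rate = k_i)
  }
  structure(list(onset = onset, censored = onset > spec$max_age,
                 spec = spec),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "Multistage cohort: n = %d, r = %d events, %d onsets by age %g (%.3g%%)\n",
    length(x$onset), x$spec$rates$r, sum(!x$censored), x$spec$max_age,
    100 * mean(!x$censored)))
  invisible(x)
}

#' @export
as.data.frame.cohort_sim <- function(x, ...) {
  data.frame(onset_age = pmin(x$onset, x$spec$max_age),
             censored = x$censored)
}

#' Estimate the age-specific hazard from simulated onsets
#'
#' Partitions \code{(0, max_age]} into \code{n_bins} equal-width bins and
#' estimates the hazard in each as events divided by person-time at risk.
#' Censored individuals contribute person-time up to \code{max_age};
#' individuals with earlier onset contribute person-time up to onset. Bins
#' with zero person-time get an undefined (NA) hazard and are flagged via
#' the \code{defined} column rather than dropped.
#'
#' @param cohort A \code{cohort_sim} object from [simulate_cohort()].
#' @return A data frame with one row per bin: \code{bin}, \code{lower},
#'   \code{upper}, \code{t_mid}, \code{events}, \code{person_time},
#'   \code{hazard}, \code{defined}.
#' @export
estimate_hazard <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_sim"))
  spec <- cohort$spec
  if (all(cohort$censored)) {
    stop_fit("no uncensored onsets: hazard cannot be estimated")
  }
  breaks <- seq(0, spec$max_age, length.out = spec$n_bins + 1L)
  exposure <- pmin(cohort$onset, spec$max_age)
  event_age <- cohort$onset[!cohort$censored]
  lower <- breaks[-length(breaks)]
  upper <- breaks[-1]
  events <- integer(spec$n_bins)
  person_time <- numeric(spec$n_bins)
  for (b in seq_len(spec$n_bins)) {
    events[b] <- sum(event_age > lower[b] & event_age <= upper[b])
    person_time[b] <- sum(pmax(0, pmin(exposure, upper[b]) - lower[b]))
  }
  defined <- person_time > 0
  hazard <- ifelse(defined, events / person_time, NA_real_)
  data.frame(bin = seq_len(spec$n_bins), lower = lower, upper = upper,
             t_mid = (lower + upper) / 2, events = events,
             person_time = person_time, hazard = hazard, defined = defined)
}

#' Fit a power law to binned hazard estimates
#'
#' Regresses the log hazard on \code{ln t_mid} across bins. The regression
#' is fitted as a Poisson log-linear model for the bin event counts with
#' the log person-time as offset, \code{ln E[events_b] = ln PT_b +
#' intercept + slope ln t_mid_b}, which is the likelihood-correct form of
#' the log-log hazard regression: it keeps zero-event bins (dropping them
#' biases the slope towards zero) and avoids the downward bias of taking
#' logarithms of small counts. Under the multistage model the slope
#' estimates \code{r - 1} and the intercept estimates \code{ln k} with
#' \code{k} the aggregated sequence probability of [aggregate_k()].
#'
#' @param hazard A data frame from [estimate_hazard()].
#' @return A list with \code{slope}, \code{intercept}, \code{n_bins_used}.
#' @export
fit_hazard_powerlaw <- function(hazard) {
  use <- hazard$defined
  if (sum(use) < 2L || sum(hazard$events[use] > 0) < 2L) {
    stop_fit("need >= 2 usable bins with events to fit a hazard power law")
  }
  h <- hazard[use, , drop = FALSE]
  fit <- stats::glm(events ~ log(t_mid), offset = log(person_time),
                    family = stats::poisson(), data = h)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       n_bins_used = sum(use))
}
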
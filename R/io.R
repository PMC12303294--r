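# Incidence-series container, CSV readers/writers and the age-class
# renumbering convention.

#' Construct an age-specific incidence series
#'
#' One series holds the age-specific incidence rate (new cases per 100,000
#' individuals per age group) of a single cancer for one gender in one
#' population, indexed by integer age classes. Age classes are consecutive
#' integers with unit spacing; original registry age-group labels (which may
#' have unequal widths, e.g. 0-14 then 15-39 then 5-year bands) are carried
#' as metadata only and never used as numeric time.
#'
#' @param cancer Cancer-type label.
#' @param gender \code{"female"}, \code{"male"} or \code{"both"}.
#' @param age_class Strictly increasing positive integers.
#' @param incidence Non-negative rates per 100,000, one per age class.
#' @param age_label Optional character vector of original age-group labels.
#' @param population Population/registry label.
#' @return An object of class \code{incidence_series}.
#' @examples
#' incidence_series("bladder", "male", 1:4, c(0.3, 1.9, 5.2, 11.0))
#' @export
incidence_series <- function(cancer, gender, age_class, incidence,
                             age_label = NULL, population = "unspecified") {
  gender <- match.arg(gender, c("female", "male", "both"))
  if (!is.numeric(age_class) || length(age_class) < 1L ||
      any(!is.finite(age_class)) || any(age_class <= 0) ||
      any(age_class != round(age_class))) {
    stop_input("`age_class` must be positive integers")
  }
  if (is.unsorted(age_class, strictly = TRUE)) {
    stop_input("`age_class` must be strictly increasing")
  }
  if (!is.numeric(incidence) || length(incidence) != length(age_class) ||
      any(!is.finite(incidence)) || any(incidence < 0)) {
    stop_input("`incidence` must be non-negative, one value per age class")
  }
  if (!is.null(age_label) && length(age_label) != length(age_class)) {
    stop_input("`age_label` must match `age_class` in length")
  }
  structure(list(
    cancer = as.character(cancer)[1],
    gender = gender,
    population = as.character(population)[1],
    data = data.frame(
      age_class = as.integer(age_class),
      age_label = if (is.null(age_label)) NA_character_ else
        as.character(age_label),
      incidence = as.numeric(incidence),
      stringsAsFactors = FALSE)),
    class = "incidence_series")
}

series_key <- function(s) {
  paste(s$cancer, s$gender, s$population, sep = " / ")
}

#' @export
print.incidence_series <- function(x, ...) {
  cat(sprintf("Incidence series: %s (%d age classes)\n",
              series_key(x), nrow(x$data)))
  print(x$data, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.incidence_series <- function(x, ...) {
  data.frame(cancer = x$cancer, gender = x$gender,
             population = x$population, x$data,
             stringsAsFactors = FALSE)
}

parse_age_group_start <- function(label) {
  start <- suppressWarnings(as.numeric(sub("^\\s*(\\d+).*$", "\\1", label)))
  if (any(is.na(start))) {
    stop_input("cannot order age groups: unparsable label(s) %s",
               paste(unique(label[is.na(start)]), collapse = ", "))
  }
  start
}

#' Read incidence series from a CSV file
#'
#' Expects a header with columns \code{cancer}, \code{gender},
#' \code{incidence} and either \code{age_class} (positive integers) or
#' \code{age_group} (labels such as \code{"0-14"}, ordered by their starting
#' age and converted to consecutive integer classes). An optional
#' \code{population} column separates registries. Row order is irrelevant.
#'
#' @param path Path to a comma-separated file (UTF-8, \code{.} decimal).
#' @param tsv Set \code{TRUE} for tab-separated registry exports.
#' @return A named list of [incidence_series], keyed by
#'   \code{cancer / gender / population}.
#' @export
read_incidence_csv <- function(path, tsv = FALSE) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  sep <- if (tsv) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("cancer", "gender", "incidence")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L ||
      !any(c("age_class", "age_group") %in% names(raw))) {
    stop_input(
      "missing required column(s): %s",
      paste(c(missing_cols,
              if (!any(c("age_class", "age_group") %in% names(raw)))
                "age_class or age_group"),
            collapse = ", "))
  }
  inc <- suppressWarnings(as.numeric(raw$incidence))
  if (any(is.na(inc))) {
    stop_input("non-numeric incidence value(s) at row(s) %s",
               paste(which(is.na(inc)), collapse = ", "))
  }
  raw$incidence <- inc
  if (!"population" %in% names(raw)) raw$population <- "unspecified"
  raw$gender <- tolower(raw$gender)

  groups <- split(raw, list(raw$cancer, raw$gender, raw$population),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    if ("age_class" %in% names(g)) {
      cls <- suppressWarnings(as.numeric(g$age_class))
      if (any(is.na(cls))) stop_input("non-numeric age_class in series %s",
                                      g$cancer[1])
      lab <- if ("age_group" %in% names(g)) g$age_group else NULL
    } else {
      start <- parse_age_group_start(g$age_group)
      cls <- match(start, sort(unique(start)))
      lab <- g$age_group
    }
    if (anyDuplicated(cls)) {
      stop_input("duplicate age class in series %s / %s / %s",
                 g$cancer[1], g$gender[1], g$population[1])
    }
    o <- order(cls)
    incidence_series(cancer = g$cancer[1], gender = g$gender[1],
                     age_class = cls[o], incidence = g$incidence[o],
                     age_label = if (is.null(lab)) NULL else lab[o],
                     population = g$population[1])
  })
  names(out) <- vapply(out, series_key, character(1))
  out[order(names(out))]
}

#' Apply the leading-zero age-class renumbering convention
#'
#' Structural zeroes at the youngest ages (a cancer that essentially does
#' not occur in, say, the 0-14 group) would make the log-log plot undefined.
#' The convention: when the incidence is zero at the leading age class(es)
#' in \emph{both} genders, those classes are dropped and the remaining
#' classes renumbered 1, 2, 3, ... with unit spacing. A zero in one gender
#' only does not trigger the drop (that zero is excluded later, at fit
#' time). The operation is idempotent.
#'
#' @param series An [incidence_series].
#' @param partner Optional paired series of the other gender; when supplied,
#'   a leading class is dropped only if it is zero in both, and both series
#'   are renumbered consistently.
#' @return The renumbered series, or (when \code{partner} is given) a list
#'   with the two renumbered series under the original argument names.
#' @export
assign_age_classes <- function(series, partner = NULL) {
  stopifnot(inherits(series, "incidence_series"))
  inc <- series$data$incidence
  if (!is.null(partner)) {
    stopifnot(inherits(partner, "incidence_series"))
    if (!identical(series$data$age_class, partner$data$age_class)) {
      stop_input("paired series must share identical age classes")
    }
    inc <- pmax(series$data$incidence, partner$data$incidence)
  }
  if (all(inc == 0)) stop_input("all age classes have zero incidence")
  first_nonzero <- which(inc > 0)[1]
  keep <- seq(first_nonzero, length(inc))
  renumber <- function(s) {
    d <- s$data[keep, , drop = FALSE]
    incidence_series(cancer = s$cancer, gender = s$gender,
                     age_class = seq_along(keep), incidence = d$incidence,
                     age_label = if (all(is.na(d$age_label))) NULL else
                       d$age_label,
                     population = s$population)
  }
  if (is.null(partner)) {
    renumber(series)
  } else {
    list(series = renumber(series), partner = renumber(partner))
  }
}

#' Write fit results to CSV or JSON
#'
#' CSV output mirrors the usual reporting layout: linear fits in one table
#' (\code{intercept}, \code{slope}, \code{r_squared}) and curved fits in
#' another (\code{a0..a3}, \code{r_squared} plus the derived subgroup
#' probabilities \code{k_p = exp(a0)} and \code{k_q = a2 k_p}). A batch
#' mixing both kinds therefore produces two files, \code{<stem>_linear.csv}
#' and \code{<stem>_curved.csv}. JSON output serializes the full objects.
#'
#' @param results A [fit_result], [selection_result], or a list of them.
#' @param path Output path (for mixed CSV batches, used as the stem).
#' @param format \code{"csv"} or \code{"json"}.
#' @return Invisibly, the path(s) written.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(results, c("fit_result", "selection_result"))) {
    results <- list(results)
  }
  if (length(results) == 0L) stop_input("no results to write")
  fits <- lapply(results, function(x) {
    if (inherits(x, "selection_result")) x$fits[[x$chosen]] else x
  })
  ok <- vapply(fits, inherits, logical(1), "fit_result")
  if (!all(ok)) stop_input("`results` must contain fit or selection results")

  if (format == "json") {
    if (!dir.exists(dirname(path))) stop_input("cannot write to %s", path)
    plain <- lapply(fits, function(f) {
      f <- unclass(f)
      f$params <- unclass(f$params)
      f$residuals <- as.list(f$residuals)
      f
    })
    jsonlite::write_json(plain, path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
    return(invisible(path))
  }

  row_of <- function(f) {
    meta <- data.frame(cancer = f$cancer %||% NA_character_,
                       gender = f$gender %||% NA_character_,
                       population = f$population %||% NA_character_,
                       stringsAsFactors = FALSE)
    if (f$model_kind == "linear") {
      cbind(meta, data.frame(intercept = f$params$intercept,
                             slope = f$params$slope,
                             r_squared = f$r_squared))
    } else {
      kp <- exp(f$params$a0)
      cbind(meta, data.frame(curvature = f$model_kind,
                             a0 = f$params$a0, a1 = f$params$a1,
                             a2 = f$params$a2, a3 = f$params$a3,
                             r_squared = f$r_squared,
                             k_p = kp, k_q = f$params$a2 * kp))
    }
  }
  kinds <- vapply(fits, function(f) f$model_kind == "linear", logical(1))
  lin <- fits[kinds]
  crv <- fits[!kinds]
  written <- character(0)
  write_one <- function(rows, p) {
    if (!dir.exists(dirname(p))) stop_input("cannot write to %s", p)
    utils::write.csv(do.call(rbind, rows), p, row.names = FALSE)
    p
  }
  if (length(lin) > 0L && length(crv) > 0L) {
    stem <- sub("\\.csv$", "", path)
    written <- c(written,
                 write_one(lapply(lin, row_of), paste0(stem, "_linear.csv")),
                 write_one(lapply(crv, row_of), paste0(stem, "_curved.csv")))
  } else {
    rows <- lapply(fits, row_of)
    written <- write_one(rows, path)
  }
  invisible(written)
}

#' Reference model coefficients from a global registry analysis
#'
#' Bundled coefficient tables for the three incidence models as fitted to
#' multi-registry age-incidence data in the epidemiological literature: 15
#' cancer categories best described by the linear log-log model, and the
#' nasopharynx/pharynx (convex) and Hodgkin-lymphoma/leukemia (concave)
#' categories for the curved models, each with male, female and combined
#' coefficients. Used by examples, tests and the synthetic-data generator
#' as realistic parameter sets. The \code{coef_consistent} flag in the
#' curved table marks rows whose printed \code{k_p}/\code{k_q} cells agree
#' with the defining relations \code{k_p = exp(a0)}, \code{k_q = a2 k_p};
#' inconsistent rows are retained for completeness but should not be used
#' to check the parameter map.
#'
#' @param model \code{"linear"} or \code{"curved"}.
#' @return A data frame.
#' @examples
#' head(reference_coefficients("linear"))
#' @export
reference_coefficients <- function(model = c("linear", "curved")) {
  model <- match.arg(model)
  f <- system.file("extdata",
                   paste0(model, "_model_coefficients.csv"),
                   package = "multistagefit", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
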
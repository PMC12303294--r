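# Run configuration: documented defaults, JSON round-trip.

#' Analysis run configuration
#'
#' Collects the tunable settings of a batch run. Defaults:
#' \describe{
#'   \item{tie_tolerance (0.005)}{Parsimony margin on R^2 within which the
#'     linear model is preferred over a curved one.}
#'   \item{anchor_min (3)}{Smallest anchor size scanned by [fit_curved()].}
#'   \item{noise_sd (0)}{Default ln-scale noise for synthetic series.}
#'   \item{seed (1)}{Root random seed.}
#'   \item{out_dir (".")}{Output directory.}
#'   \item{log_level ("info")}{\code{"quiet"}, \code{"info"} or
#'     \code{"debug"}.}
#' }
#'
#' @param tie_tolerance,anchor_min,noise_sd,seed,out_dir,log_level See
#'   above.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(tie_tolerance = 0.005, anchor_min = 3, noise_sd = 0,
                       seed = 1, out_dir = ".", log_level = "info") {
  stopifnot_scalar_number(tie_tolerance, "tie_tolerance")
  stopifnot_scalar_number(anchor_min, "anchor_min")
  stopifnot_scalar_number(noise_sd, "noise_sd")
  stopifnot_scalar_number(seed, "seed")
  log_level <- match.arg(log_level, c("quiet", "info", "debug"))
  structure(list(tie_tolerance = as.numeric(tie_tolerance),
                 anchor_min = as.integer(anchor_min),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed),
                 out_dir = out_dir, log_level = log_level),
            class = "run_config")
}

#' Save or load a run configuration as JSON
#'
#' @param config A [run_config].
#' @param path File path.
#' @return \code{save_config} invisibly returns \code{path};
#'   \code{load_config} returns the [run_config].
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}
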
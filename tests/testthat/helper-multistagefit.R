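# Shared helpers: random parameter draws and series construction.

random_linear_params <- function() {
  linear_params(r = runif(1, 1.2, 4.5), k = exp(runif(1, -3, 1)))
}

# curved coefficients spanning the regimes the reference tables cover
random_curved_params <- function(curvature) {
  a3 <- runif(1, 0.1, 3)
  a2 <- if (curvature == "convex") {
    # keep a2 * 8^a3 < 1 with some margin so t = 1..8 stays in-domain
    runif(1, 0.2, 0.9) / 8^a3
  } else {
    runif(1, 0.005, 0.8)
  }
  curved_params(a0 = runif(1, -2, 1), a1 = runif(1, -2, 3),
                a2 = a2, a3 = a3, curvature = curvature)
}

series_from <- function(params, noise_sd = 0, seed = NULL,
                        age_classes = 1:8) {
  generate_series(series_spec(params, age_classes = age_classes,
                              noise_sd = noise_sd, seed = seed))
}

two_point_series <- function(gender, t_pair, incidence) {
  incidence_series("synthetic", gender, t_pair, incidence)
}

max_coef_error <- function(fit, params) {
  max(abs(c(fit$params$a0 - params$a0, fit$params$a1 - params$a1,
            fit$params$a2 - params$a2, fit$params$a3 - params$a3)))
}
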
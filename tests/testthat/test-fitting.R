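test_that("linear fitting inverts noise-free generation for random parameters", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_linear_params()
    fit <- fit_linear(series_from(p))
    expect_equal(fit$params$r, p$r, tolerance = 1e-9)
    expect_equal(fit$params$k, p$k, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("published bladder-male coefficients round-trip through generation", {
  fit <- fit_linear(series_from(linear_params(3.644, exp(-1.236))))
  expect_equal(fit$params$slope, 2.644, tolerance = 1e-9)
  expect_equal(fit$params$intercept, -1.236, tolerance = 1e-9)
})

test_that("a constant series fits as a flat hazard (r = 1, k = level)", {
  s <- incidence_series("flat", "both", 1:6, rep(4.2, 6))
  fit <- fit_linear(s)
  expect_equal(fit$params$slope, 0)
  expect_equal(fit$params$r, 1)
  expect_equal(fit$params$k, 4.2)
})

test_that("linear fitting rejects series with too few usable points", {
  expect_error(fit_linear(incidence_series("x", "both", 1:2, c(1, 2))),
               ">= 3")
  s <- incidence_series("x", "both", 1:4, c(0, 0, 1, 2))
  expect_warning(expect_error(fit_linear(s), ">= 3"), "zero-incidence")
})

test_that("R^2 follows its definition on the ln scale", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(r_squared(c(0, 1, 2), rep(1, 3)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0.1, 1, 1.9)), 0.99)
  expect_error(r_squared(rep(1, 3), c(1, 1, 1)), "zero variance")
  expect_error(r_squared(1:3, 1:2), "equal length")
})

test_that("curved fitting round-trips all reference coefficient rows", {
  rows <- reference_coefficients("curved")
  for (i in seq_len(nrow(rows))) {
    rw <- rows[i, ]
    cp <- curved_params(rw$a0, rw$a1, rw$a2, rw$a3, rw$curvature)
    fit <- fit_curved(series_from(cp), rw$curvature)
    expect_lt(max_coef_error(fit, cp), 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("curved fitting round-trips random coefficients across the regime", {
  set.seed(42)
  for (curvature in c("convex", "concave")) {
    for (i in 1:10) {
      cp <- random_curved_params(curvature)
      fit <- fit_curved(series_from(cp), curvature)
      expect_lt(max_coef_error(fit, cp), 1e-6)
    }
  }
})

test_that("curvature absent from the data errors or degenerates to a2 ~ 0", {
  # numerically exact linear data has sign-indeterminate residuals, so
  # either outcome is legitimate: a mismatch error, or a vanishing a2
  expect_no_curvature <- function(series, curvature) {
    res <- tryCatch(fit_curved(series, curvature), error = function(e) e)
    if (inherits(res, "error")) {
      expect_match(conditionMessage(res), "incompatible")
    } else {
      expect_lt(res$params$a2 * max(series$data$age_class)^res$params$a3,
                1e-8)
    }
  }
  lin <- series_from(linear_params(3, 0.5))
  expect_no_curvature(lin, "concave")
  expect_no_curvature(lin, "convex")
  # data curved the other way must never pass as the requested curvature
  cc <- series_from(curved_params(-0.036, 0.1405, 0.007, 2.1, "concave"))
  expect_error(fit_curved(cc, "convex"), "incompatible")
})

test_that("curved fitting needs at least five usable age classes", {
  s <- series_from(curved_params(-0.036, 0.1405, 0.007, 2.1, "concave"),
                   age_classes = 1:4)
  expect_error(fit_curved(s, "concave"), ">= 5")
})

test_that("model selection recognizes each generating family, noise-free", {
  sel_lin <- select_model(series_from(linear_params(3.644, exp(-1.236))))
  expect_identical(sel_lin$chosen, "linear")
  expect_equal(sel_lin$fits$linear$r_squared, 1, tolerance = 1e-12)

  cc <- curved_params(1.15, -0.8291, 0.09, 2.75, "concave")
  expect_identical(select_model(series_from(cc))$chosen, "concave")

  cv <- curved_params(-0.54, 2.797, 0.73, 0.14, "convex")
  expect_identical(select_model(series_from(cv))$chosen, "convex")
})

test_that("negligible curvature falls back to the parsimonious linear model", {
  cv <- curved_params(-0.5, 2.8, 1e-6, 0.14, "convex")
  sel <- select_model(series_from(cv))
  expect_identical(sel$chosen, "linear")
})

test_that("the chosen model is never beaten by more than the tie tolerance", {
  set.seed(42)
  for (i in 1:10) {
    s <- series_from(random_linear_params(), noise_sd = 0.1)
    sel <- select_model(s)
    r2 <- vapply(sel$fits, function(f) f$r_squared, numeric(1))
    expect_gte(sel$fits[[sel$chosen]]$r_squared,
               max(r2) - sel$tie_tolerance)
    if (sel$chosen != "linear" && "linear" %in% names(sel$fits)) {
      expect_gt(sel$fits[[sel$chosen]]$r_squared,
                sel$fits$linear$r_squared)
    }
  }
})

test_that("fit quality is invariant under integer rescaling of the age axis", {
  set.seed(42)
  p <- random_linear_params()
  s1 <- series_from(p, noise_sd = 0.08, seed = 9)
  s3 <- incidence_series(s1$cancer, s1$gender, s1$data$age_class * 3L,
                         s1$data$incidence)
  f1 <- fit_linear(s1)
  f3 <- fit_linear(s3)
  expect_equal(f1$r_squared, f3$r_squared, tolerance = 1e-12)
  expect_equal(f1$params$slope, f3$params$slope, tolerance = 1e-12)
  expect_equal(f3$params$intercept,
               f1$params$intercept - f1$params$slope * log(3),
               tolerance = 1e-12)
})
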
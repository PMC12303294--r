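test_that("linear log-incidence evaluates (r-1) ln t + ln k", {
  expect_equal(linear_log_incidence(1, linear_params(3.64, 0.29)),
               log(0.29))
  expect_equal(linear_log_incidence(1, linear_params(3.64, 0.29)),
               -1.238, tolerance = 1e-3)
  expect_equal(linear_log_incidence(c(1, 7, 123), linear_params(1, 1)),
               c(0, 0, 0))
  expect_equal(linear_log_incidence(exp(1), linear_params(3, 2)),
               2 + log(2))
  expect_error(linear_log_incidence(0, linear_params(3, 2)), "positive")
  expect_error(linear_log_incidence(-1, linear_params(3, 2)), "positive")
})

test_that("curved log-incidence evaluates both curvature signs", {
  cv <- curved_params(-0.54, 2.797, 0.73, 0.14, "convex")
  expect_equal(curved_log_incidence(1, cv), -0.54 + log(1 - 0.73))
  expect_equal(curved_log_incidence(1, cv), -1.8493, tolerance = 1e-4)
  cc <- curved_params(-0.036, 0.1405, 0.007, 2.1, "concave")
  expect_equal(curved_log_incidence(2, cc),
               -0.036 + 0.1405 * log(2) + log(1 + 0.007 * 2^2.1))
  expect_equal(curved_log_incidence(2, cc), 0.09096, tolerance = 1e-4)
})

test_that("zero curvature coefficient reduces both curved models to linear", {
  set.seed(42)
  for (curvature in c("convex", "concave")) {
    for (i in 1:10) {
      a0 <- runif(1, -3, 1)
      a1 <- runif(1, -0.9, 3)  # keep r = a1 + 1 positive for the linear twin
      cp <- curved_params(a0, a1, 0, runif(1, 0.1, 3), curvature)
      lp <- linear_params(r = a1 + 1, k = exp(a0))
      t <- sort(runif(5, 0.5, 20))
      expect_equal(curved_log_incidence(t, cp), linear_log_incidence(t, lp))
    }
  }
})

test_that("convex model refuses out-of-domain ages, naming them", {
  cv <- curved_params(0, 2, 0.5, 1, "convex")
  expect_error(curved_log_incidence(2, cv), "a2 \\* t\\^a3 >= 1")
  expect_error(curved_log_incidence(c(1, 5), cv), "5")
  expect_silent(curved_log_incidence(1.5, cv))
})

test_that("unordered and ordered event probabilities follow the product rule", {
  rates3 <- multistage_rates(c(0.1, 0.1, 0.5))
  expect_equal(unordered_event_probability(rates3, 2), 0.04)
  expect_equal(unordered_event_probability(rates3, 0), 0)
  expect_equal(unordered_event_probability(multistage_rates(0.3), 17), 1)
  expect_equal(ordered_event_probability(rates3, 2), 0.02)
  rates2 <- multistage_rates(c(0.2, 0.9))
  expect_equal(ordered_event_probability(rates2, 3),
               unordered_event_probability(rates2, 3))
  rates4 <- multistage_rates(c(0.1, 0.1, 0.1, 1))
  expect_equal(ordered_event_probability(rates4, 1), 0.001 / 6)
})

test_that("ordered x (r-1)! equals unordered exactly, for random rates", {
  set.seed(42)
  for (i in 1:25) {
    r <- sample(1:6, 1)
    rates <- multistage_rates(runif(r, 0.001, 0.5))
    t <- runif(1, 0, 30)
    expect_equal(
      ordered_event_probability(rates, t) * factorial(r - 1),
      unordered_event_probability(rates, t), tolerance = 1e-14)
  }
})

test_that("aggregate_k collapses the rate list and ignores order of the first r-1", {
  expect_equal(aggregate_k(multistage_rates(c(1, 1, 1))), 0.5)
  expect_equal(aggregate_k(multistage_rates(0.3)), 0.3)
  expect_equal(aggregate_k(multistage_rates(c(0.01, 0.01, 0.01))), 5e-7)
  set.seed(42)
  for (i in 1:10) {
    rates <- runif(4, 0.001, 0.5)
    k1 <- aggregate_k(multistage_rates(rates))
    k2 <- aggregate_k(multistage_rates(c(rates[c(3, 1, 2)], rates[4])))
    expect_equal(k1, k2)
  }
  expect_error(multistage_rates(numeric(0)), "non-empty")
})

test_that("time rescaling shifts only the intercept and preserves predictions", {
  p <- linear_params(3, 1)
  expect_equal(rescale_time(p, 1), p)
  p2 <- rescale_time(p, 2)
  expect_equal(p2$slope, 2)
  expect_equal(p2$intercept, -2 * log(2))
  expect_error(rescale_time(p, 0), "> 0")
  set.seed(42)
  for (i in 1:10) {
    p <- random_linear_params()
    w <- runif(1, 0.2, 5)
    back <- rescale_time(rescale_time(p, w), 1 / w)
    expect_equal(back$r, p$r)
    expect_equal(back$k, p$k, tolerance = 1e-12)
    t <- runif(5, 1, 10)
    expect_equal(linear_log_incidence(t * w, rescale_time(p, w)),
                 linear_log_incidence(t, p), tolerance = 1e-12)
  }
})

test_that("mechanistic map reproduces published subgroup probabilities", {
  cv <- curved_params(-0.54, 2.797, 0.73, 0.14, "convex")
  mech <- map_curved_to_mechanistic(cv, "heterogeneity", p = 0)
  expect_lt(abs(mech$k_p - 0.583), 1.01e-3)
  expect_lt(abs(mech$k_q - 0.425), 1.01e-3)
  cc <- curved_params(1.15, -0.8291, 0.09, 2.75, "concave")
  mech <- map_curved_to_mechanistic(cc, "heterogeneity", p = 0)
  expect_lt(abs(mech$k_p - 3.158), 1.01e-3)
  expect_lt(abs(mech$k_q - 0.284), 1.01e-3)
})

test_that("heterogeneity map needs exactly one of p or r; a2 = 0 degenerates", {
  cv <- curved_params(-0.5, 2.8, 0.7, 0.2, "convex")
  expect_error(map_curved_to_mechanistic(cv, "heterogeneity"), "exactly one")
  expect_error(map_curved_to_mechanistic(cv, "heterogeneity", p = 0, r = 3),
               "exactly one")
  m_p <- map_curved_to_mechanistic(cv, "heterogeneity", p = 0.5)
  expect_equal(m_p$r, 2.8 - 0.5 + 1)
  expect_equal(m_p$q, 0.2 + 0.5)
  m_r <- map_curved_to_mechanistic(cv, "heterogeneity", r = 3)
  expect_equal(m_r$p, 2.8 - 3 + 1)
  degenerate <- map_curved_to_mechanistic(
    curved_params(-0.5, 2.8, 0, 0.2, "convex"), "heterogeneity", p = 0)
  expect_equal(degenerate$k_q, 0)
})

test_that("age-effect map derives r from a1 and names the modifying factor", {
  cv <- curved_params(-0.5, 2, 0.1, 0.5, "convex")
  mech <- map_curved_to_mechanistic(cv, "age_effect")
  expect_equal(mech$r, 3)
  expect_equal(mech$k, exp(-0.5))
  expect_equal(mech$k_d, 0.1 * exp(-0.5))
  expect_equal(mech$d, 0.5 + 3 - 1)
  cc <- curved_params(0.2, 1, 0.05, 2, "concave")
  mech <- map_curved_to_mechanistic(cc, "age_effect")
  expect_equal(mech$k_a, 0.05 * exp(0.2))
  expect_equal(mech$a, 2 + 2 - 1)
  expect_error(map_curved_to_mechanistic(cv, "age_effect", p = 1),
               "do not supply")
})

test_that("mechanistic map composed with reassembly is the identity", {
  set.seed(42)
  for (curvature in c("convex", "concave")) {
    for (i in 1:10) {
      cp <- random_curved_params(curvature)
      m1 <- map_curved_to_mechanistic(cp, "heterogeneity",
                                      p = runif(1, -1, 1))
      back1 <- mechanistic_to_curved(m1)
      expect_equal(back1[c("a0", "a1", "a2", "a3", "curvature")],
                   cp[c("a0", "a1", "a2", "a3", "curvature")],
                   tolerance = 1e-12)
      m2 <- map_curved_to_mechanistic(cp, "age_effect")
      back2 <- mechanistic_to_curved(m2)
      expect_equal(back2[c("a0", "a1", "a2", "a3", "curvature")],
                   cp[c("a0", "a1", "a2", "a3", "curvature")],
                   tolerance = 1e-12)
    }
  }
})

test_that("rare-event validity check warns, not errors", {
  expect_warning(check_event_rates(multistage_rates(c(0.1, 0.02)), 20),
                 "k_i \\* t_max")
  expect_silent(check_event_rates(multistage_rates(c(0.01, 0.02)), 20))
})
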
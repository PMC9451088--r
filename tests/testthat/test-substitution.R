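test_that("reallocations are validated: zero net sum, cap, non-negativity", {
  r <- reallocation(c(screen = -60, physical_activity = 60))
  new <- apply_reallocation(reference_centre(), r)
  expect_equal(unname(new["screen"]), 115.0)
  expect_equal(unname(new["physical_activity"]), 176.9)
  expect_equal(unname(new["sleep"]), 709.7)
  expect_equal(sum(new), 1440)
  # zero deltas return the initial composition
  same <- apply_reallocation(reference_centre(), reallocation(numeric(7)))
  expect_equal(unclass(same)[1:7], unclass(reference_centre())[1:7])
  expect_error(reallocation(c(quiet = -80, screen = 80)), "cap")
  expect_error(apply_reallocation(reference_centre(),
                                  reallocation(c(quiet = -80, screen = 80),
                                               cap = 120)),
               "negative value")
  expect_error(reallocation(c(screen = -30)), "sum to zero")
})

test_that("random invalid reallocations are always rejected", {
  set.seed(31)
  init <- reference_centre()
  for (i in 1:60) {
    d <- stats::setNames(round(stats::rnorm(7, 0, 25)), activity_parts())
    kind <- sample(c("net", "negative", "cap"), 1)
    if (kind == "net") {
      d <- d - mean(d) + 5  # force nonzero net sum
      expect_error(reallocation(d, cap = Inf))
    } else if (kind == "cap") {
      d <- d - mean(d)
      d["sleep"] <- d["sleep"] + 100
      d["screen"] <- d["screen"] - 100
      expect_error(reallocation(d, cap = 60))
    } else {
      d[] <- 0
      d["passive_transport"] <- -(unclass(init)[["passive_transport"]] + 10)
      d["sleep"] <- -d["passive_transport"]
      expect_error(apply_reallocation(init, reallocation(d, cap = Inf)),
                   "negative value")
    }
  }
})

test_that("predictions use stored parameters: intercept-only model and MC oracle for the SE", {
  toy <- intercept_only_model(b0 = 5)
  cov <- default_profile()
  set.seed(32)
  for (i in 1:5) {
    p <- predict_outcome(toy, random_composition(), cov)
    expect_equal(p$estimate, 5)
  }
  # Monte-Carlo oracle: sd of x'beta over draws from MVN(beta, V)
  fx <- test_fit_fixture()
  p <- predict_outcome(fx$psy, reference_centre(), cov)
  x <- timeswap:::prediction_row(fx$psy, reference_centre(), cov)
  set.seed(33)
  L <- chol(fx$psy$vcov + diag(1e-12, 35))
  draws <- matrix(stats::rnorm(50000 * 35), 50000) %*% L
  mc_se <- stats::sd(draws %*% x)
  expect_lt(abs(mc_se - p$se) / p$se, 0.02)
})

test_that("linear differences equal prediction differences and mirror on reversal", {
  fx <- test_fit_fixture()
  cov <- default_profile()
  comp0 <- reference_centre()
  comp1 <- apply_reallocation(comp0, c(screen = -60, physical_activity = 60))
  est <- estimate_difference(fx$psy, comp0, comp1, cov)
  p0 <- predict_outcome(fx$psy, comp0, cov)
  p1 <- predict_outcome(fx$psy, comp1, cov)
  expect_equal(est$difference, p1$estimate - p0$estimate, tolerance = 1e-12)
  expect_true(est$ci_low <= est$difference && est$difference <= est$ci_high)
  rev <- estimate_difference(fx$psy, comp1, comp0, cov)
  expect_equal(rev$difference, -est$difference, tolerance = 1e-12)
  expect_equal(rev$ci_low, -est$ci_high, tolerance = 1e-12)
  expect_equal(rev$ci_high, -est$ci_low, tolerance = 1e-12)
  # percent difference uses the initial-composition prediction as denominator
  expect_equal(est$percent_difference, 100 * est$difference / p0$estimate)
  fake <- structure(list(difference = -0.8, estimate_initial = 20),
                    class = "substitution_estimate")
  expect_equal(percent_difference(fake), -4.0)
  expect_error(percent_difference(structure(
    list(difference = 1, estimate_initial = 0),
    class = "substitution_estimate")), "zero")
})

test_that("null reallocations give zero difference with zero-width intervals", {
  fx <- test_fit_fixture()
  cov <- default_profile()
  comp0 <- reference_centre()
  for (model in list(fx$psy, fx$bf)) {
    est <- estimate_difference(model, comp0, comp0, cov)
    expect_identical(est$difference, 0)
    expect_identical(c(est$ci_low, est$ci_high), c(0, 0))
    expect_identical(est$percent_difference, 0)
    expect_true(is.na(est$favourable))
  }
})

test_that("the MOVER interval matches a Monte-Carlo percentile oracle for independent lognormals", {
  m1 <- log(20); s1 <- 0.05
  m2 <- log(18); s2 <- 0.07
  z <- stats::qnorm(0.975)
  got <- mover_ci(exp(m1), exp(m1 - z * s1), exp(m1 + z * s1),
                  exp(m2), exp(m2 - z * s2), exp(m2 + z * s2), r = 0)
  set.seed(34)
  d <- exp(stats::rnorm(2e5, m1, s1)) - exp(stats::rnorm(2e5, m2, s2))
  mc <- unname(stats::quantile(d, c(0.025, 0.975)))
  width <- mc[2] - mc[1]
  expect_lt(abs(got[1] - mc[1]) / width, 0.03)
  expect_lt(abs(got[2] - mc[2]) / width, 0.03)
  expect_lt(abs((got[2] - got[1]) - width) / width, 0.03)
})

test_that("log-scale differences use the exponentiated predictions and flag direction", {
  fx <- test_fit_fixture()
  cov <- default_profile()
  comp0 <- reference_centre()
  comp1 <- apply_reallocation(comp0, c(screen = -60, physical_activity = 60))
  est <- estimate_difference(fx$bf, comp0, comp1, cov)
  p0 <- predict_outcome(fx$bf, comp0, cov)
  p1 <- predict_outcome(fx$bf, comp1, cov)
  expect_equal(est$difference, p1$estimate - p0$estimate, tolerance = 1e-12)
  expect_true(est$ci_low <= est$difference && est$difference <= est$ci_high)
  # body fat decrease is favourable (direction = "lower")
  expect_identical(est$favourable, est$difference < 0)
  expect_error(estimate_difference_lognormal(fx$psy, comp0, comp1, cov),
               "identity")
  expect_error(estimate_difference_linear(fx$bf, comp0, comp1, cov), "log")
})

test_that("substitution estimates are invariant to the choice of ilr basis", {
  fx <- test_fit_fixture()
  cov <- default_profile()
  comp0 <- reference_centre()
  comp1 <- apply_reallocation(comp0, c(screen = -60, physical_activity = 60))
  for (spec in list(list(y = fx$sim$data$psychosocial, transform = "identity"),
                    list(y = fx$sim$data$bodyfat, transform = "log"))) {
    mA <- fit_outcome_model(fx$comps, fx$sim$data, spec$y,
                            transform = spec$transform, sbp = sbp_pivot())
    mB <- fit_outcome_model(fx$comps, fx$sim$data, spec$y,
                            transform = spec$transform, sbp = sbp_balanced())
    eA <- estimate_difference(mA, comp0, comp1, cov)
    eB <- estimate_difference(mB, comp0, comp1, cov)
    expect_equal(eA$difference, eB$difference, tolerance = 1e-9)
    expect_equal(eA$ci_low, eB$ci_low, tolerance = 1e-9)
    expect_equal(eA$ci_high, eB$ci_high, tolerance = 1e-9)
    expect_equal(eA$estimate_initial, eB$estimate_initial, tolerance = 1e-9)
  }
})

test_that("with second-order terms the same reallocation differs across starting compositions", {
  fx <- test_fit_fixture()
  cov <- default_profile()
  realloc <- c(screen = -60, physical_activity = 60)
  start1 <- reference_centre()
  start2 <- composition(c(650, 235, 57, 130, 35.8, 189.1, 143.1))
  e1 <- estimate_difference(fx$psy, start1, apply_reallocation(start1, realloc), cov)
  e2 <- estimate_difference(fx$psy, start2, apply_reallocation(start2, realloc), cov)
  expect_gt(abs(e1$difference - e2$difference), 1e-6)
})
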
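# Shared fixtures, built in code. Expensive fits are cached per test run.

# An alternative valid SBP (balanced tree) for basis-invariance checks.
sbp_balanced <- function() {
  rbind(
    c( 1,  1,  1, -1, -1, -1, -1),
    c( 1, -1, -1,  0,  0,  0,  0),
    c( 0,  1, -1,  0,  0,  0,  0),
    c( 0,  0,  0,  1,  1, -1, -1),
    c( 0,  0,  0,  1, -1,  0,  0),
    c( 0,  0,  0,  0,  0,  1, -1))
}

random_composition <- function(total = 1440) {
  composition(stats::rgamma(7, shape = 2) + 0.05, total = total)
}

# One moderate synthetic dataset plus fitted models, reused across files.
fixture_env <- new.env(parent = emptyenv())

test_fit_fixture <- function() {
  if (!is.null(fixture_env$fit)) return(fixture_env$fit)
  cfg <- generator_config(n = 400, seed = 42)
  sim <- simulate_dataset(cfg)
  comps <- as.matrix(sim$data[, activity_parts()])
  psy <- fit_outcome_model(comps, sim$data, sim$data$psychosocial,
                           "psychosocial", "identity", "higher")
  bf <- fit_outcome_model(comps, sim$data, sim$data$bodyfat,
                          "bodyfat", "log", "lower")
  fixture_env$fit <- list(cfg = cfg, sim = sim, comps = comps,
                          psy = psy, bf = bf)
  fixture_env$fit
}

# A hand-built model whose only active coefficient is the intercept.
intercept_only_model <- function(b0 = 5, transform = "identity", se2 = 1e-4) {
  cn <- design_colnames()
  coef <- stats::setNames(numeric(35), cn)
  coef["(Intercept)"] <- b0
  vc <- diag(0, 35)
  vc[1, 1] <- se2
  dimnames(vc) <- list(cn, cn)
  structure(list(schema_version = 1L, outcome_name = "toy",
                 transform = transform, direction = "higher",
                 coef = coef, vcov = vc, residual_df = 100L, n = 135L,
                 rss = 1, sbp = unname(sbp_pivot()), parts = activity_parts(),
                 total = 1440,
                 covariate_coding = list(sex_reference = "male",
                                         pubertal_reference = "pre",
                                         pubertal_levels = c("pre", "early",
                                                             "mid", "late",
                                                             "post")),
                 trim_rule = NULL),
            class = "fitted_model")
}

default_profile <- function() covariate_profile("female", 12, 0.2, "mid")

# At small n a rare pubertal level can be absent, leaving its indicator
# column all-zero; simulations condition on an estimable design.
simulate_estimable <- function(cfg) {
  levels <- c("pre", "early", "mid", "late", "post")
  repeat {
    sim <- simulate_dataset(cfg)
    if (all(levels %in% sim$data$pubertal_status)) return(sim)
  }
}
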
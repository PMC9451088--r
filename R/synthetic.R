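#' Reference compositional mean of the study sample
#'
#' The compositional centre (min/day) used as the default starting
#' composition and as the centre of the synthetic generator: sleep 709.7,
#' screen 175.0, physical activity 116.9, quiet 70.2, passive transport
#' 35.8, school 129.1, domestic/self-care 203.3 (sums to 1440).
#'
#' @return A closed [composition()].
#' @export
reference_centre <- function() {
  composition(c(sleep = 709.7, screen = 175.0, physical_activity = 116.9,
                quiet = 70.2, passive_transport = 35.8, school = 129.1,
                domestic_selfcare = 203.3))
}

#' Default true coefficients for the synthetic generator
#'
#' Named length-35 coefficient vectors (one per outcome, in the
#' [design_colnames()] order) with nonzero linear, squared and interaction
#' ilr terms, so that simulated outcomes show genuine curvature and
#' starting-composition-dependent substitution effects. Intercepts are
#' calibrated so the expected outcome at the reference centre and
#' sample-average covariates matches the descriptive targets (body fat
#' around 19.9% on the raw scale, psychosocial score around 77.1, writing
#' score around 533.5).
#'
#' @return Named list `bodyfat` (log scale), `psychosocial`, `writing`.
#' @export
default_true_coefficients <- function() {
  cn <- design_colnames()
  zero <- stats::setNames(numeric(N_DESIGN_COLS), cn)
  mean_cov <- c(sex_female = 0.484, age = 12.0, ses_z = 0.20,
                pubertal_early = 0.258, pubertal_mid = 0.510,
                pubertal_late = 0.131, pubertal_post = 0.005)
  xbar <- c(1, polynomial_ilr_block(ilr(reference_centre()))[1L, ], mean_cov)
  names(xbar) <- cn
  calibrate <- function(beta, target) {
    beta["(Intercept)"] <- target - sum(beta[-1L] * xbar[-1L])
    beta
  }
  psy <- zero
  # linear terms partly offset the linear signal induced by the curvature
  # terms at the noncentral ilr mean, keeping the overall compositional
  # association at a realistic magnitude
  psy[paste0("z", 1:6)] <- c(18.6, -9.2, 3.2, 3.2, 7.2, -1.0)
  psy[paste0("z", 1:6, "_sq")] <- c(-5, 4, -3, 2, 3, -2)
  psy[c("z1_z2", "z2_z3", "z4_z5")] <- c(2, -1.5, 1)
  psy[c("sex_female", "age", "ses_z")] <- c(1.0, 0.5, 1.5)
  psy[paste0("pubertal_", PUBERTAL_LEVELS[-1L])] <- c(-0.5, -1, -1.5, -2)
  bf <- zero
  bf[paste0("z", 1:6)] <- c(-0.12, 0.10, -0.15, 0.05, 0.02, -0.03)
  bf[paste0("z", 1:6, "_sq")] <- c(0.02, -0.02, 0.03, 0, 0, 0)
  bf[c("z1_z3", "z2_z3")] <- c(-0.015, 0.01)
  bf[c("sex_female", "age", "ses_z")] <- c(0.15, 0.02, -0.03)
  bf[paste0("pubertal_", PUBERTAL_LEVELS[-1L])] <- c(0.02, 0.05, 0.08, 0.10)
  wr <- zero
  wr[paste0("z", 1:6)] <- c(25, -18, 8.5, 6.4, -2.5, 3)
  wr[paste0("z", 1:6, "_sq")] <- c(-3, 2, -2, 0, 1, 0)
  wr[c("z1_z2", "z3_z4")] <- c(2, -1.5)
  wr[c("sex_female", "age", "ses_z")] <- c(10, 4, 15)
  wr[paste0("pubertal_", PUBERTAL_LEVELS[-1L])] <- c(2, 4, 6, 8)
  list(bodyfat = calibrate(bf, log(19.9)),
       psychosocial = calibrate(psy, 77.1),
       writing = calibrate(wr, 533.5))
}

#' Configuration of the synthetic data generator
#'
#' Encodes the study conditions the generator emulates: sample size 1685;
#' activity compositions logistic-normal on the ilr scale around the
#' reference centre (coordinate SD 0.45 by default); sex ~ Bernoulli(0.484
#' female); age ~ Normal(12.0, 0.4); SES z-score ~ Normal(0.20, 0.99);
#' pubertal status multinomial (pre 9.6%, early 25.8%, mid 51.0%, late
#' 13.1%, post 0.5%); three outcomes (log-scale body fat plus two
#' identity-scale scores) generated from known true coefficients.
#'
#' @param n Sample size (default 1685).
#' @param centre Compositional centre (default [reference_centre()]).
#' @param ilr_sigma 6 x 6 ilr-scale covariance (default `diag(0.45^2, 6)`).
#' @param sex_prob_female,age_mean,age_sd,ses_mean,ses_sd Covariate
#'   distribution parameters.
#' @param pubertal_probs Named probabilities over the five pubertal levels.
#' @param beta Named list of true coefficient vectors (default
#'   [default_true_coefficients()]).
#' @param resid_sd Residual SDs: `bodyfat` on the log scale (default 0.40),
#'   `psychosocial` (default 13), `writing` (default 62).
#' @param zero_rate Probability that an eligible low-duration entry (quiet,
#'   passive transport) is recorded as zero (default 0).
#' @param trim_sd Trimming bound for the writing score, in SDs (default 4).
#' @param day_ilr_sd Day-level ilr noise SD for multi-day recalls.
#' @param weekend_part_factors Multiplicative weekend vs weekday part
#'   shifts (closed afterwards); defaults emulate more sleep/screen and
#'   much less school-related time on non-school days.
#' @param total Closure constant (default 1440).
#' @param seed Integer seed; all generator functions derive their streams
#'   from it (reproducible), or NULL to use the current RNG state.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n = 1685, centre = reference_centre(),
                             ilr_sigma = diag(0.45^2, 6),
                             sex_prob_female = 0.484,
                             age_mean = 12.0, age_sd = 0.4,
                             ses_mean = 0.20, ses_sd = 0.99,
                             pubertal_probs = c(pre = 0.096, early = 0.258,
                                                mid = 0.510, late = 0.131,
                                                post = 0.005),
                             beta = default_true_coefficients(),
                             resid_sd = c(bodyfat = 0.40, psychosocial = 11,
                                          writing = 62),
                             zero_rate = 0, trim_sd = 4,
                             day_ilr_sd = 0.15,
                             weekend_part_factors = c(sleep = 1.08,
                                                      screen = 1.35,
                                                      physical_activity = 1.10,
                                                      quiet = 1.20,
                                                      passive_transport = 0.90,
                                                      school = 0.15,
                                                      domestic_selfcare = 1.15),
                             total = 1440, seed = NULL) {
  if (abs(sum(pubertal_probs) - 1) > 1e-8)
    stop("pubertal_probs must sum to 1")
  ilr_sigma <- as.matrix(ilr_sigma)
  ev <- eigen(ilr_sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("ilr_sigma must be positive semi-definite")
  structure(list(n = n, centre = centre, ilr_sigma = ilr_sigma,
                 sex_prob_female = sex_prob_female,
                 age_mean = age_mean, age_sd = age_sd,
                 ses_mean = ses_mean, ses_sd = ses_sd,
                 pubertal_probs = pubertal_probs, beta = beta,
                 resid_sd = resid_sd, zero_rate = zero_rate,
                 trim_sd = trim_sd, day_ilr_sd = day_ilr_sd,
                 weekend_part_factors = weekend_part_factors,
                 total = total, seed = seed),
            class = "generator_config")
}

seed_stream <- function(cfg, offset) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + offset)
}

#' Generate synthetic activity compositions
#'
#' Draws ilr coordinates from a multivariate normal centred at
#' `ilr(centre)` with covariance `ilr_sigma` and back-transforms to closed
#' compositions (logistic-normal model on the simplex).
#'
#' @param cfg A [generator_config()].
#' @return n x 7 matrix of closed, strictly positive compositions.
#' @export
generate_compositions <- function(cfg) {
  seed_stream(cfg, 1L)
  mu <- ilr(cfg$centre)
  Z <- MASS::mvrnorm(cfg$n, mu = mu, Sigma = cfg$ilr_sigma)
  if (cfg$n == 1L) Z <- matrix(Z, nrow = 1L)
  ilr_inverse(Z, total = cfg$total)
}

#' Generate synthetic covariates
#'
#' @param cfg A [generator_config()].
#' @return Data frame with columns `sex`, `age`, `ses_z`,
#'   `pubertal_status`.
#' @export
generate_covariates <- function(cfg) {
  seed_stream(cfg, 2L)
  n <- cfg$n
  data.frame(
    sex = sample(c("male", "female"), n, replace = TRUE,
                 prob = c(1 - cfg$sex_prob_female, cfg$sex_prob_female)),
    age = stats::rnorm(n, cfg$age_mean, cfg$age_sd),
    ses_z = stats::rnorm(n, cfg$ses_mean, cfg$ses_sd),
    pubertal_status = sample(PUBERTAL_LEVELS, n, replace = TRUE,
                             prob = cfg$pubertal_probs),
    stringsAsFactors = FALSE)
}

#' Generate synthetic outcomes from known true coefficients
#'
#' `y = X beta_true + eps` with Gaussian residuals; body fat is generated
#' on the log scale and exponentiated; the writing score is trimmed at
#' +/- `trim_sd` sample SDs (one pass), trimmed values set to missing.
#'
#' @param comps n x 7 matrix of strictly positive compositions.
#' @param covs Covariate data frame (see [generate_covariates()]).
#' @param cfg A [generator_config()].
#' @return Data frame with columns `bodyfat`, `psychosocial`, `writing`.
#' @export
generate_outcomes <- function(comps, covs, cfg) {
  seed_stream(cfg, 3L)
  X <- build_design_matrix(ilr(as_part_matrix(comps)), covs)
  n <- nrow(X)
  out <- lapply(c("bodyfat", "psychosocial", "writing"), function(nm) {
    beta <- cfg$beta[[nm]]
    if (length(beta) != ncol(X))
      stop("true coefficient vector for ", nm, " must have length ", ncol(X))
    drop(X %*% beta) + stats::rnorm(n, 0, cfg$resid_sd[[nm]])
  })
  names(out) <- c("bodyfat", "psychosocial", "writing")
  out$bodyfat <- exp(out$bodyfat)
  wr <- out$writing
  keep <- abs(wr - mean(wr)) <= cfg$trim_sd * stats::sd(wr)
  wr[!keep] <- NA_real_
  out$writing <- wr
  as.data.frame(out)
}

#' Inject structural zeros into low-duration parts
#'
#' Sets randomly chosen quiet-time and passive-transport entries to zero
#' (emulating below-detection recalls) and re-closes the affected rows.
#' Sleep and the other high-duration parts are never zeroed.
#'
#' @param comps n x 7 composition matrix.
#' @param rate Per-entry zeroing probability in `[0, 0.2]`.
#' @param seed Optional integer seed.
#' @param parts Eligible parts (default quiet and passive transport).
#' @return Composition matrix with zeros, rows still closed.
#' @export
inject_zeros <- function(comps, rate, seed = NULL,
                         parts = c("quiet", "passive_transport")) {
  if (rate < 0 || rate > 0.2) stop("zero-injection rate must be in [0, 0.2]")
  if (!is.null(seed)) set.seed(seed)
  m <- as_part_matrix(comps)
  if (rate == 0) return(m)
  tot <- rowSums(m)
  for (p in parts) {
    hit <- stats::runif(nrow(m)) < rate
    m[hit, p] <- 0
  }
  s <- rowSums(m)
  m * tot / s
}

#' Generate a per-participant multi-day recall table
#'
#' Emulates a three-day recall (two weekdays, one weekend day per
#' participant): day-level compositions are drawn around each participant's
#' composition with ilr-scale noise `day_ilr_sd`, and weekend days are
#' shifted by the multiplicative `weekend_part_factors` before closure.
#' Output matches the day-level CSV schema of [read_timeuse_csv()].
#'
#' @param cfg A [generator_config()].
#' @return Data frame with columns `id`, `day_type` and the seven activity
#'   parts.
#' @export
generate_multiday <- function(cfg) {
  base <- generate_compositions(cfg)
  seed_stream(cfg, 5L)
  day_types <- c("weekday", "weekday", "weekend")
  rows <- vector("list", cfg$n * 3L)
  k <- 0L
  for (i in seq_len(cfg$n)) {
    for (d in day_types) {
      comp <- base[i, ]
      if (d == "weekend")
        comp <- comp * cfg$weekend_part_factors[activity_parts()]
      z <- ilr(close_composition(comp, cfg$total))
      if (cfg$day_ilr_sd > 0)
        z <- z + stats::rnorm(6L, 0, cfg$day_ilr_sd)
      k <- k + 1L
      rows[[k]] <- c(id = i, ilr_inverse(z, total = cfg$total))
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("id", activity_parts())
  out$day_type <- rep(day_types, cfg$n)
  out[, c("id", "day_type", activity_parts())]
}

#' Simulate a complete analysis-ready dataset with known truth
#'
#' Runs the full generator: compositions, covariates, outcomes (from the
#' pre-zero true compositions), then structural zero injection at
#' `cfg$zero_rate`. The returned `truth` element carries the true
#' coefficients and the zero-free compositions for recovery checks.
#'
#' @param cfg A [generator_config()].
#' @return List with `data` (data frame: id, the 7 parts as recorded,
#'   covariates, outcomes) and `truth` (true beta, residual SDs, true
#'   compositions, seed).
#' @export
simulate_dataset <- function(cfg = generator_config()) {
  comps_true <- generate_compositions(cfg)
  covs <- generate_covariates(cfg)
  outcomes <- generate_outcomes(comps_true, covs, cfg)
  comps_obs <- comps_true
  if (cfg$zero_rate > 0) {
    seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 4L
    comps_obs <- inject_zeros(comps_true, cfg$zero_rate, seed = seed)
  }
  data <- data.frame(id = seq_len(cfg$n), comps_obs, covs, outcomes,
                     stringsAsFactors = FALSE)
  list(data = data,
       truth = list(beta = cfg$beta, resid_sd = cfg$resid_sd,
                    compositions_true = comps_true, seed = cfg$seed))
}
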
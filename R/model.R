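PUBERTAL_LEVELS <- c("pre", "early", "mid", "late", "post")
N_COMPOSITION_COLS <- 27L  # 6 linear + 6 squared + 15 pairwise ilr terms
N_DESIGN_COLS <- 35L       # intercept + 27 + 7 covariate columns

#' Covariate profile for prediction
#'
#' Bundles the covariates entering the outcome models: sex, age, family
#' socioeconomic position (z-score) and pubertal status. When a user
#' supplies only sex and age, the remaining covariates default to the
#' sample-typical values: ses_z = 0 and mid-pubertal status.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years.
#' @param ses_z Socioeconomic position z-score (default 0).
#' @param pubertal_status One of `"pre"`, `"early"`, `"mid"`, `"late"`,
#'   `"post"` (default `"mid"`).
#' @return An object of class `covariate_profile`.
#' @export
covariate_profile <- function(sex, age, ses_z = 0, pubertal_status = "mid") {
  if (missing(sex)) stop("missing covariate: sex")
  if (missing(age)) stop("missing covariate: age")
  sex <- match.arg(sex, c("male", "female"))
  pubertal_status <- match.arg(pubertal_status, PUBERTAL_LEVELS)
  if (!is.finite(age) || age <= 0) stop("age must be a positive number of years")
  if (!is.finite(ses_z)) stop("missing covariate: ses_z")
  structure(list(sex = sex, age = age, ses_z = ses_z,
                 pubertal_status = pubertal_status),
            class = "covariate_profile")
}

covariate_colnames <- function() {
  c("sex_female", "age", "ses_z",
    paste0("pubertal_", PUBERTAL_LEVELS[-1L]))
}

interaction_pairs <- function() {
  pairs <- which(upper.tri(matrix(0, 6, 6)), arr.ind = TRUE)
  pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
}

#' Column names of the regression design matrix
#'
#' Fixed, documented column order: intercept; linear ilr terms `z1..z6`;
#' squared terms `z1_sq..z6_sq`; pairwise products `zj_zk` (j < k,
#' lexicographic); covariates (sex indicator, age, ses z-score, four
#' pubertal indicators against the pre-pubertal reference).
#'
#' @return Character vector of length 35.
#' @export
design_colnames <- function() {
  pairs <- interaction_pairs()
  c("(Intercept)", paste0("z", 1:6), paste0("z", 1:6, "_sq"),
    paste0("z", pairs[, 1], "_z", pairs[, 2]), covariate_colnames())
}

## Encode a covariate data frame as the 7 numeric covariate columns.
encode_covariates <- function(cov) {
  if (inherits(cov, "covariate_profile"))
    cov <- data.frame(sex = cov$sex, age = cov$age, ses_z = cov$ses_z,
                      pubertal_status = cov$pubertal_status)
  needed <- c("sex", "age", "ses_z", "pubertal_status")
  miss <- setdiff(needed, names(cov))
  if (length(miss)) stop("missing covariate: ", paste(miss, collapse = ", "))
  sex <- as.character(cov$sex)
  if (!all(sex %in% c("male", "female") | is.na(sex)))
    stop("sex must be 'male' or 'female'")
  pub <- as.character(cov$pubertal_status)
  if (!all(pub %in% PUBERTAL_LEVELS | is.na(pub)))
    stop("pubertal_status must be one of: ", paste(PUBERTAL_LEVELS, collapse = ", "))
  out <- cbind(
    sex_female = as.numeric(sex == "female"),
    age = as.numeric(cov$age),
    ses_z = as.numeric(cov$ses_z))
  for (lev in PUBERTAL_LEVELS[-1L])
    out <- cbind(out, as.numeric(pub == lev))
  colnames(out) <- covariate_colnames()
  out
}

## Quadratic expansion of ilr coordinates: 6 linear + 6 squared + 15 products.
polynomial_ilr_block <- function(Z) {
  Z <- if (is.null(dim(Z))) matrix(Z, nrow = 1L) else as.matrix(Z)
  if (ncol(Z) != 6L) stop("ilr coordinates must have length 6")
  pairs <- interaction_pairs()
  inter <- Z[, pairs[, 1], drop = FALSE] * Z[, pairs[, 2], drop = FALSE]
  cbind(Z, Z^2, inter)
}

#' Build a single regression design row
#'
#' @param z ilr coordinates (length 6) of one composition.
#' @param cov A [covariate_profile()].
#' @return Named numeric vector of length 35 in the [design_colnames()]
#'   order; the composition-derived block has exactly 27 entries.
#' @export
build_design_row <- function(z, cov) {
  if (!inherits(cov, "covariate_profile")) cov <- do.call(covariate_profile, as.list(cov))
  x <- c(1, polynomial_ilr_block(z)[1L, ], encode_covariates(cov)[1L, ])
  names(x) <- design_colnames()
  x
}

#' Build the full design matrix
#'
#' @param Z n x 6 matrix of ilr coordinates.
#' @param covariates Data frame with columns `sex`, `age`, `ses_z`,
#'   `pubertal_status`.
#' @return n x 35 design matrix in [design_colnames()] order.
#' @export
build_design_matrix <- function(Z, covariates) {
  X <- cbind(1, polynomial_ilr_block(Z), encode_covariates(covariates))
  colnames(X) <- design_colnames()
  X
}

ols_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop("rank-deficient design matrix (rank ", fit$rank, " < ", ncol(X),
         "); refusing to fit")
  p <- ncol(X)
  piv <- fit$qr$pivot
  Rinv <- chol2inv(qr.R(fit$qr))
  XtX_inv <- matrix(NA_real_, p, p)
  XtX_inv[piv, piv] <- Rinv
  rss <- sum(fit$residuals^2)
  df <- length(y) - p
  list(coef = fit$coefficients[colnames(X)], rss = rss, df = df,
       sigma2 = rss / df, XtX_inv = XtX_inv, fitted = fit$fitted.values)
}

#' Fit a compositional outcome model
#'
#' Ordinary least squares regression of a (possibly log-transformed) health
#' outcome on the second-order polynomial ilr expansion of the 24-h activity
#' composition plus covariates. Rows with any missing value are excluded
#' (complete-case analysis). The returned object stores only the regression
#' coefficients, their full covariance matrix and the residual degrees of
#' freedom -- no unit-level data.
#'
#' @param compositions n x 7 matrix of strictly positive compositions
#'   (apply zero replacement first).
#' @param covariates Data frame with columns `sex`, `age`, `ses_z`,
#'   `pubertal_status`.
#' @param outcome Numeric outcome vector of length n.
#' @param outcome_name Label stored in the model.
#' @param transform `"identity"` or `"log"` (natural log, for right-skewed
#'   outcomes such as percent body fat).
#' @param direction Direction of benefit for this outcome: `"lower"` or
#'   `"higher"`; stored as metadata and used to flag favourable changes.
#' @param sbp Sequential binary partition defining the ilr basis (default
#'   [sbp_pivot()]); serialized with the model so predictions are
#'   basis-consistent.
#' @param total Closure constant of the compositions (default 1440).
#' @param polynomial If `TRUE` (default) the design includes the squared
#'   and pairwise-product ilr terms (35 columns); if `FALSE` only the
#'   linear ilr terms enter (14 columns), which is used for AIC model
#'   comparison. Only polynomial models can be serialized.
#' @return An object of class `fitted_model` with elements `coef` (35),
#'   `vcov` (35 x 35), `residual_df` = n - 35, `n`, `rss`, `transform`,
#'   `sbp`, `parts`, `direction`.
#' @export
fit_outcome_model <- function(compositions, covariates, outcome,
                              outcome_name = "outcome",
                              transform = c("identity", "log"),
                              direction = c("higher", "lower"),
                              sbp = sbp_pivot(), total = 1440,
                              polynomial = TRUE) {
  transform <- match.arg(transform)
  direction <- match.arg(direction)
  comps <- as_part_matrix(compositions)
  cov_mat <- encode_covariates(covariates)
  ok <- stats::complete.cases(comps, cov_mat, outcome)
  comps <- comps[ok, , drop = FALSE]
  cov_mat <- cov_mat[ok, , drop = FALSE]
  y <- outcome[ok]
  if (any(comps <= 0))
    stop("compositions must be strictly positive; apply zero replacement first")
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires strictly positive outcomes")
    y <- log(y)
  }
  n <- length(y)
  Z <- ilr(comps, sbp = sbp)
  if (polynomial) {
    X <- cbind(1, polynomial_ilr_block(Z), cov_mat)
    colnames(X) <- design_colnames()
  } else {
    X <- cbind(1, Z, cov_mat)
    colnames(X) <- c("(Intercept)", paste0("z", 1:6), covariate_colnames())
  }
  if (n <= ncol(X))
    stop("need more than ", ncol(X), " complete cases; got ", n)
  fit <- ols_fit(X, y)
  vc <- fit$sigma2 * fit$XtX_inv
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(
    schema_version = 1L,
    outcome_name = outcome_name,
    transform = transform,
    direction = direction,
    coef = fit$coef,
    vcov = vc,
    residual_df = fit$df,
    n = n,
    rss = fit$rss,
    sbp = unname(as.matrix(sbp)),
    parts = activity_parts(),
    total = total,
    covariate_coding = list(sex_reference = "male",
                            pubertal_reference = "pre",
                            pubertal_levels = PUBERTAL_LEVELS),
    trim_rule = NULL
  ), class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("Compositional outcome model: ", x$outcome_name,
      " (", x$transform, " scale)\n", sep = "")
  cat("  n = ", x$n, ", residual df = ", x$residual_df,
      ", 35 coefficients stored with full covariance\n", sep = "")
  invisible(x)
}

#' Partial F-test for the compositional block
#'
#' Tests whether the 27 composition-derived design columns (linear, squared
#' and pairwise-product ilr terms) jointly improve on the covariate-only
#' model: `F = [(RSS_reduced - RSS_full) / 27] / [RSS_full / residual_df]`
#' with df1 = 27 and df2 = n - 35.
#'
#' @param model A `fitted_model` (supplies transform, SBP and expected n).
#' @param compositions,covariates,outcome The same data used to fit
#'   `model`.
#' @return List of class `f_stat_result` with `F`, `df1`, `df2`, `p`.
#' @export
compositional_f_test <- function(model, compositions, covariates, outcome) {
  comps <- as_part_matrix(compositions)
  cov_mat <- encode_covariates(covariates)
  ok <- stats::complete.cases(comps, cov_mat, outcome)
  comps <- comps[ok, , drop = FALSE]
  cov_mat <- cov_mat[ok, , drop = FALSE]
  y <- outcome[ok]
  if (model$transform == "log") y <- log(y)
  n <- length(y)
  if (n != model$n)
    stop("mismatched n between fits: model has ", model$n, ", data give ", n)
  Z <- ilr(comps, sbp = model$sbp)
  X_full <- cbind(1, polynomial_ilr_block(Z), cov_mat)
  X_red <- cbind(1, cov_mat)
  full <- ols_fit(X_full, y)
  red <- ols_fit(X_red, y)
  stat <- ((red$rss - full$rss) / N_COMPOSITION_COLS) / (full$rss / full$df)
  structure(list(F = stat, df1 = N_COMPOSITION_COLS, df2 = full$df,
                 p = stats::pf(stat, N_COMPOSITION_COLS, full$df,
                               lower.tail = FALSE)),
            class = "f_stat_result")
}

#' @export
print.f_stat_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.3g\n", x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Akaike information criterion of a fitted model
#'
#' Gaussian-likelihood AIC, `n (log(2 pi) + log(RSS/n) + 1) + 2 (k + 1)`
#' with k = 35 regression coefficients plus one variance parameter -- the
#' same convention as [stats::AIC()] on `lm` fits, so values are directly
#' comparable across models of the same data.
#'
#' @param object A `fitted_model`.
#' @param ... Ignored.
#' @return AIC value (smaller is better).
#' @export
AIC.fitted_model <- function(object, ..., k = 2) {
  n <- object$n
  p <- length(object$coef)
  n * (log(2 * pi) + log(object$rss / n) + 1) + k * (p + 1)
}
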
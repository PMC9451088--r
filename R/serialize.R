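MODEL_SCHEMA_FIELDS <- c(
  "schema_version", "outcome_name", "transform", "direction", "coef",
  "vcov", "residual_df", "n", "rss", "sbp", "parts", "total",
  "covariate_coding", "trim_rule")

#' Serialize a fitted model to JSON
#'
#' Writes a privacy-preserving model artifact: only the coefficient vector,
#' its full covariance matrix, the residual degrees of freedom and coding
#' metadata are stored -- never unit-level records. Numbers are written at
#' full precision so that the load/serialize round trip is lossless.
#'
#' @param model A `fitted_model`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @seealso [load_model()]
#' @export
serialize_model <- function(model, path) {
  if (!inherits(model, "fitted_model")) stop("not a fitted_model")
  if (length(model$coef) != N_DESIGN_COLS)
    stop("only full polynomial models (", N_DESIGN_COLS,
         " coefficients) can be serialized")
  obj <- unclass(model)[MODEL_SCHEMA_FIELDS]
  obj$coef <- list(names = names(model$coef), values = unname(model$coef))
  obj$vcov <- unname(model$vcov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' Validates the artifact against the model schema before returning it:
#' unknown fields (in particular any record-level arrays such as a
#' `participants` list) are rejected, the coefficient vector must have
#' length 35, and the covariance matrix must be 35 x 35, symmetric (within
#' 1e-8) and positive semi-definite (minimum eigenvalue >= -1e-8).
#'
#' @param path Path to a JSON model artifact written by [serialize_model()].
#' @return A `fitted_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(obj), MODEL_SCHEMA_FIELDS)
  if (length(extra))
    stop("model file rejected: unexpected field(s) ",
         paste(extra, collapse = ", "),
         " (unit-level data are not permitted in model artifacts)")
  miss <- setdiff(setdiff(MODEL_SCHEMA_FIELDS, "trim_rule"), names(obj))
  if (length(miss))
    stop("model file rejected: missing field(s) ", paste(miss, collapse = ", "))
  if (!identical(as.integer(obj$schema_version), 1L))
    stop("unsupported model schema version: ", obj$schema_version)
  coef <- as.numeric(obj$coef$values)
  names(coef) <- obj$coef$names
  if (length(coef) != N_DESIGN_COLS)
    stop("model file rejected: expected ", N_DESIGN_COLS, " coefficients, got ",
         length(coef))
  vc <- as.matrix(obj$vcov)
  if (!all(dim(vc) == c(N_DESIGN_COLS, N_DESIGN_COLS)))
    stop("model file rejected: covariance must be 35 x 35")
  if (max(abs(vc - t(vc))) > 1e-8)
    stop("model file rejected: covariance matrix is not symmetric")
  if (min(eigen(vc, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("model file rejected: covariance matrix is not positive semi-definite")
  dimnames(vc) <- list(names(coef), names(coef))
  if (!is.numeric(obj$residual_df) || obj$residual_df < 1)
    stop("model file rejected: invalid residual_df")
  sbp <- as.matrix(obj$sbp)
  sbp_basis(sbp)  # errors if the stored SBP is invalid
  structure(list(
    schema_version = 1L,
    outcome_name = obj$outcome_name,
    transform = match.arg(obj$transform, c("identity", "log")),
    direction = match.arg(obj$direction, c("higher", "lower")),
    coef = coef,
    vcov = vc,
    residual_df = as.integer(obj$residual_df),
    n = as.integer(obj$n),
    rss = as.numeric(obj$rss),
    sbp = unname(sbp),
    parts = as.character(obj$parts),
    total = as.numeric(obj$total),
    covariate_coding = obj$covariate_coding,
    trim_rule = obj$trim_rule
  ), class = "fitted_model")
}
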
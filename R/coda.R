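#' Canonical activity part names
#'
#' The seven superdomains of the 24-hour activity composition, in the fixed
#' order used throughout the package: sleep, screen time, physical activity,
#' quiet time, passive transport, school-related activities and
#' domestic/self-care activities.
#'
#' @return Character vector of length 7.
#' @export
activity_parts <- function() {
  c("sleep", "screen", "physical_activity", "quiet",
    "passive_transport", "school", "domestic_selfcare")
}

## Coerce a vector or matrix to an n x 7 matrix with canonical column order.
as_part_matrix <- function(x) {
  parts <- activity_parts()
  if (is.data.frame(x)) x <- as.matrix(x[, intersect(c(parts), names(x)), drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (ncol(x) != 7L) {
    if (!all(parts %in% colnames(x)))
      stop("expected 7 activity parts (", paste(parts, collapse = ", "), ")")
    x <- x[, parts, drop = FALSE]
  }
  if (is.null(colnames(x))) colnames(x) <- parts else x <- x[, parts, drop = FALSE]
  storage.mode(x) <- "double"
  x
}

#' Close a composition to a fixed daily total
#'
#' Rescales non-negative durations so that they sum to `total` (by default
#' 1440 min/day, the 24-hour constraint). Closure is idempotent.
#'
#' @param x Numeric vector of 7 non-negative durations (min/day), optionally
#'   named with [activity_parts()], or an n x 7 matrix of such rows.
#' @param total Closure constant in min/day (default 1440).
#' @return A named composition vector (or matrix) summing to `total`.
#' @export
close_composition <- function(x, total = 1440) {
  if (total <= 0) stop("closure total must be positive")
  m <- as_part_matrix(x)
  if (any(!is.finite(m))) stop("non-finite duration in composition")
  if (any(m < 0)) stop("negative duration in composition")
  s <- rowSums(m)
  if (any(s == 0)) stop("degenerate composition: all parts zero")
  out <- m / s * total
  if (is.null(dim(x))) out[1L, ] else out
}

#' Construct a single closed composition
#'
#' @inheritParams close_composition
#' @return Named numeric vector of length 7 with attribute `total`.
#' @export
composition <- function(x, total = 1440) {
  out <- close_composition(x, total = total)
  if (!is.null(dim(out))) {
    if (nrow(out) != 1L) stop("composition() expects a single row; see close_composition()")
    out <- out[1L, ]
  }
  attr(out, "total") <- total
  class(out) <- c("composition", "numeric")
  out
}

#' @export
print.composition <- function(x, ...) {
  cat("24-h activity composition (min/day, total ",
      format(attr(x, "total")), "):\n", sep = "")
  print(round(unclass(x)[seq_len(7L)], 2), ...)
  invisible(x)
}

#' Replace zero durations by a fixed small value
#'
#' Zero parts are replaced with a fixed fraction of the recall instrument's
#' sampling frame (default 65% of 5 minutes = 3.25 min); the remaining parts
#' are shrunk multiplicatively so the daily total is preserved. This is the
#' rule applied to user-supplied compositions before computing ilr
#' coordinates.
#'
#' @param comp A composition (vector or matrix rows; see
#'   [close_composition()]).
#' @param frame Sampling frame of the recall instrument, minutes (default 5).
#' @param fraction Fraction of the frame used as the imputed value
#'   (default 0.65, i.e. 3.25 min).
#' @return Strictly positive composition(s) with the same total.
#' @export
replace_zeros_fixed <- function(comp, frame = 5, fraction = 0.65) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  m <- as_part_matrix(comp)
  if (any(m < 0)) stop("negative duration in composition")
  imput <- frame * fraction
  tot <- rowSums(m)
  if (any(tot == 0)) stop("degenerate composition: all parts zero")
  for (i in seq_len(nrow(m))) {
    z <- m[i, ] == 0
    if (!any(z)) next
    nz_total <- tot[i] - imput * sum(z)
    if (nz_total <= 0)
      stop("imputed zeros exceed the daily total in row ", i)
    m[i, !z] <- m[i, !z] * nz_total / sum(m[i, !z])
    m[i, z] <- imput
  }
  if (is.null(dim(comp))) {
    out <- m[1L, ]
    attr(out, "total") <- tot[1L]
    class(out) <- c("composition", "numeric")
    out
  } else m
}

#' Dataset-level zero replacement by iterative log-scale regression
#'
#' Treats zeros as below-detection durations and imputes them from the
#' log-ratio relationship between parts, in the spirit of log-ratio
#' expectation-maximization: working in additive log-ratios against a
#' zero-free reference part, each part with zeros is regressed (OLS) on the
#' remaining log-ratios over the rows where it was observed, imputed rows
#' are predicted (clamped to the observed log-ratio range) and re-closed
#' multiplicatively, and the cycle is iterated to convergence. With a
#' single row (or too few zero-free rows to support a regression) it falls
#' back to the fixed-value rule of [replace_zeros_fixed()].
#'
#' @param table An n x 7 matrix or data frame of compositions (min/day).
#' @param frame,fraction Passed to the fixed-value fallback and used to
#'   initialize the iteration (default 3.25 min).
#' @param tol Convergence tolerance on the maximum relative change of
#'   imputed values (default 1e-6).
#' @param max_iter Maximum number of sweeps (default 50).
#' @return Matrix of strictly positive closed compositions; rows without
#'   zeros are returned unchanged up to closure.
#' @export
replace_zeros_dataset <- function(table, frame = 5, fraction = 0.65,
                                  tol = 1e-6, max_iter = 50L) {
  m <- as_part_matrix(table)
  all_zero <- rowSums(m) == 0
  if (any(all_zero))
    stop("rows with all parts zero: ", paste(which(all_zero), collapse = ", "))
  tot <- rowSums(m)
  zero <- m == 0
  if (!any(zero)) return(close_composition(m, total = tot[1L]) * (tot / tot[1L]))
  complete <- rowSums(zero) == 0
  ref <- which(colSums(zero) == 0)  # zero-free reference parts for the alr
  if (nrow(m) == 1L || sum(complete) < 10L || length(ref) == 0L)
    return(replace_zeros_fixed(m, frame = frame, fraction = fraction))
  ref <- ref[which.max(apply(m[, ref, drop = FALSE], 2, min))]
  ## initialize with the fixed rule, then iterate conditional-mean
  ## imputation of additive log-ratios (scale-invariant, so re-closing
  ## rows does not perturb the regression)
  m <- replace_zeros_fixed(m, frame = frame, fraction = fraction)
  zero_parts <- which(colSums(zero) > 0)
  alr <- function(rows) log(m[rows, -ref, drop = FALSE] / m[rows, ref])
  for (iter in seq_len(max_iter)) {
    prev <- m[zero]
    for (j in zero_parts) {
      jj <- match(colnames(m)[j], colnames(m)[-ref])
      obs <- which(!zero[, j])
      A <- alr(obs)
      fit <- stats::lm.fit(cbind(1, A[, -jj, drop = FALSE]), A[, jj])
      rows <- which(zero[, j])
      pred <- drop(cbind(1, alr(rows)[, -jj, drop = FALSE]) %*% fit$coefficients)
      ## keep imputations inside the observed log-ratio range
      pred <- pmin(pmax(pred, min(A[, jj])), max(A[, jj]))
      m[rows, j] <- m[rows, ref] * exp(pred)
      ## re-close affected rows, keeping observed parts' relative values
      for (i in rows) {
        oz <- zero[i, ]
        m[i, !oz] <- m[i, !oz] * (tot[i] - sum(m[i, oz])) / sum(m[i, !oz])
      }
    }
    delta <- max(abs(m[zero] - prev) / prev)
    if (delta < tol) break
  }
  m
}

#' Pivot-coordinate sequential binary partition
#'
#' The default sequential binary partition (SBP): row k contrasts part k
#' (+1) against all later parts (-1), giving pivot coordinates in the fixed
#' part order of [activity_parts()].
#'
#' @return A 6 x 7 matrix with entries in \{-1, 0, +1\}.
#' @export
sbp_pivot <- function() {
  sbp <- matrix(0L, 6L, 7L, dimnames = list(NULL, activity_parts()))
  for (k in 1:6) {
    sbp[k, k] <- 1L
    sbp[k, (k + 1):7] <- -1L
  }
  sbp
}

#' Orthonormal ilr basis from a sequential binary partition
#'
#' Converts an SBP sign matrix into the 7 x 6 contrast matrix V whose
#' columns are the orthonormal ilr basis vectors (clr coefficients), and
#' validates orthonormality.
#'
#' @param sbp A 6 x 7 matrix with entries in \{-1, 0, +1\}; each row must
#'   split its parent group into a +1 and a -1 set, forming a full binary
#'   tree over the 7 parts.
#' @return A 7 x 6 numeric matrix with `t(V) %*% V = I` (tol 1e-10).
#' @export
sbp_basis <- function(sbp) {
  sbp <- as.matrix(sbp)
  if (!all(dim(sbp) == c(6L, 7L))) stop("SBP must be a 6 x 7 matrix")
  if (!all(sbp %in% c(-1, 0, 1))) stop("SBP entries must be in {-1, 0, +1}")
  V <- matrix(0, 7L, 6L)
  for (k in 1:6) {
    plus <- sbp[k, ] == 1
    minus <- sbp[k, ] == -1
    r <- sum(plus); s <- sum(minus)
    if (r == 0 || s == 0) stop("SBP row ", k, " does not split into +1 and -1 groups")
    coef <- sqrt(r * s / (r + s))
    V[plus, k] <- coef / r
    V[minus, k] <- -coef / s
  }
  if (max(abs(crossprod(V) - diag(6))) > 1e-10)
    stop("SBP does not induce an orthonormal ilr basis; check the binary tree structure")
  rownames(V) <- colnames(sbp)
  V
}

#' Isometric log-ratio coordinates
#'
#' Maps strictly positive 7-part compositions to 6 unconstrained real
#' coordinates: `z_k = sqrt(r s / (r + s)) * ln(g(+group) / g(-group))`
#' where g() is the geometric mean and r, s are the group sizes of SBP
#' row k.
#'
#' @param comp A strictly positive composition vector, or an n x 7 matrix.
#' @param sbp Sequential binary partition (default [sbp_pivot()]).
#' @return Numeric vector of length 6 (or n x 6 matrix), columns named
#'   `z1..z6`.
#' @export
ilr <- function(comp, sbp = sbp_pivot()) {
  m <- as_part_matrix(comp)
  if (any(m <= 0))
    stop("composition has zero or negative parts; apply zero replacement ",
         "(replace_zeros_fixed or replace_zeros_dataset) first")
  V <- sbp_basis(sbp)
  z <- log(m) %*% V
  colnames(z) <- paste0("z", 1:6)
  if (is.null(dim(comp))) z[1L, ] else z
}

#' Inverse isometric log-ratio transform
#'
#' Maps ilr coordinates back to a strictly positive composition closed to
#' `total`. Exact inverse of [ilr()] under the same SBP; numerically stable
#' for large coordinates (the log-scale maximum is subtracted before
#' exponentiation).
#'
#' @param z Numeric vector of length 6, or an n x 6 matrix.
#' @param sbp Sequential binary partition (default [sbp_pivot()]).
#' @param total Closure constant (default 1440 min/day).
#' @return Composition vector (or matrix) summing to `total`.
#' @export
ilr_inverse <- function(z, sbp = sbp_pivot(), total = 1440) {
  zm <- if (is.null(dim(z))) matrix(z, nrow = 1L) else as.matrix(z)
  if (ncol(zm) != 6L) stop("ilr coordinates must have length 6")
  V <- sbp_basis(sbp)
  y <- zm %*% t(V)
  y <- y - apply(y, 1L, max)
  x <- exp(y)
  x <- x / rowSums(x) * total
  colnames(x) <- activity_parts()
  if (is.null(dim(z))) composition(x[1L, ], total = total) else x
}

#' Compositional mean (centre)
#'
#' The closure of the vector of per-part geometric means: the natural
#' average on the simplex, equal to `ilr_inverse` of the arithmetic mean of
#' the ilr coordinates.
#'
#' @param table An n x 7 matrix or data frame of strictly positive
#'   compositions.
#' @param total Closure constant (default 1440).
#' @return A single closed [composition()].
#' @export
compositional_mean <- function(table, total = 1440) {
  m <- as_part_matrix(table)
  if (nrow(m) == 0L) stop("empty composition table")
  if (any(m <= 0)) stop("apply zero replacement before computing the compositional mean")
  composition(exp(colMeans(log(m))), total = total)
}

#' Weekly composition from multi-day recalls, weighted 5:2
#'
#' Averages day-level compositions within day type (arithmetic, per part),
#' combines weekday and weekend means as (5 x weekday + 2 x weekend) / 7,
#' and closes the result. At least one weekday and one weekend recall are
#' required, matching a recall protocol of three days including at least
#' one school and one non-school day.
#'
#' @param day_comps An m x 7 matrix (or list of compositions), one row per
#'   recalled day.
#' @param day_types Character vector of length m with values `"weekday"` or
#'   `"weekend"`.
#' @param total Closure constant (default 1440).
#' @return A single closed [composition()].
#' @export
weighted_weekly_composition <- function(day_comps, day_types, total = 1440) {
  if (is.list(day_comps) && !is.data.frame(day_comps))
    day_comps <- do.call(rbind, day_comps)
  m <- as_part_matrix(day_comps)
  day_types <- match.arg(day_types, c("weekday", "weekend"), several.ok = TRUE)
  if (length(day_types) != nrow(m))
    stop("day_types must have one entry per recalled day")
  for (type in c("weekday", "weekend"))
    if (!any(day_types == type))
      stop("no ", type, " recall: at least one weekday and one weekend day are required")
  wk <- colMeans(m[day_types == "weekday", , drop = FALSE])
  we <- colMeans(m[day_types == "weekend", , drop = FALSE])
  composition((5 * wk + 2 * we) / 7, total = total)
}
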
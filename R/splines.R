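# Restricted cubic spline bases for covariates and for log time.
#
# The basis is the restricted (natural) truncated-power form used by
# flexible parametric survival models: with knots k_1 < ... < k_K the
# basis has K - 1 columns, the first being x itself and column j + 1
#
#   v_j(x) = [(x - k_j)_+^3 - lambda_j (x - k_1)_+^3
#             - (1 - lambda_j) (x - k_K)_+^3] / (k_K - k_1)^2,
#   lambda_j = (k_K - k_j) / (k_K - k_1),  j = 1, ..., K - 2,
#
# which is cubic between knots, has continuous value and first two
# derivatives everywhere, and is exactly linear beyond the boundary
# knots.  The (k_K - k_1)^2 normalisation keeps columns on a scale
# comparable to x; fits are invariant to this affine choice.

#' Restricted cubic spline specification
#'
#' Bundles an ordered knot vector with its implied degrees of freedom
#' (`df = length(knots) - 1`).
#'
#' @param knots Numeric vector of at least 3 strictly increasing knots;
#'   the first and last are the boundary knots.
#' @return An object of class `spline_spec` with elements `knots` and `df`.
#' @export
spline_spec <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L) {
    stop("a restricted cubic spline needs at least 3 knots", call. = FALSE)
  }
  if (any(!is.finite(knots)) || any(diff(knots) <= 0)) {
    stop("knots must be finite and strictly increasing", call. = FALSE)
  }
  structure(list(knots = knots, df = length(knots) - 1L), class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("Restricted cubic spline: ", x$df, " df, knots at ",
      paste(signif(x$knots, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Knot placement at Harrell's default percentiles
#'
#' Places knots at the conventional default quantiles for restricted
#' cubic splines: 10/50/90 for 2 df (3 knots), 5/35/65/95 for 3 df,
#' and 5/27.5/50/72.5/95 for 4 df.  Quantiles use linear interpolation
#' between order statistics (`stats::quantile()` type 7).
#'
#' @param x Numeric vector the spline will be applied to (missing values
#'   are dropped before computing quantiles).
#' @param df Degrees of freedom, one of 2, 3 or 4.
#' @return A [spline_spec()].
#' @export
default_knots <- function(x, df) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no non-missing values to place knots on", call. = FALSE)
  probs <- switch(as.character(df),
    "2" = c(0.10, 0.50, 0.90),
    "3" = c(0.05, 0.35, 0.65, 0.95),
    "4" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    stop("df must be 2, 3 or 4 for default knot placement", call. = FALSE)
  )
  k <- unname(stats::quantile(x, probs = probs, type = 7))
  if (anyDuplicated(k)) {
    stop("duplicate knots after placement; use fewer spline df for this variable",
         call. = FALSE)
  }
  spline_spec(k)
}

#' Evaluate a restricted cubic spline basis
#'
#' @param x Numeric vector of evaluation points; must be finite.
#' @param spec A [spline_spec()].
#' @return Numeric matrix with `length(x)` rows and `spec$df` columns.
#'   Column 1 is `x` (the linear term); the remaining columns are the
#'   restricted cubic terms, identically zero for `x` at or below the
#'   first knot.
#' @export
rcs_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (any(!is.finite(x))) stop("x must be finite for spline evaluation", call. = FALSE)
  k <- spec$knots
  K <- length(k)
  norm <- (k[K] - k[1])^2
  out <- matrix(0, nrow = length(x), ncol = K - 1L)
  out[, 1L] <- x
  cube <- function(u) pmax(u, 0)^3
  for (j in seq_len(K - 2L)) {
    kj <- k[j + 1L]  # internal knot j
    lam <- (k[K] - kj) / (k[K] - k[1])
    out[, j + 1L] <- (cube(x - kj) - lam * cube(x - k[1]) -
                        (1 - lam) * cube(x - k[K])) / norm
  }
  colnames(out) <- c("lin", paste0("rcs", seq_len(K - 2L)))[seq_len(K - 1L)]
  out
}

#' Derivative of a restricted cubic spline basis
#'
#' Analytic column-wise derivative of [rcs_basis()] with respect to `x`.
#'
#' @inheritParams rcs_basis
#' @return Matrix of the same shape as `rcs_basis(x, spec)`.
#' @export
rcs_deriv <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (any(!is.finite(x))) stop("x must be finite for spline evaluation", call. = FALSE)
  k <- spec$knots
  K <- length(k)
  norm <- (k[K] - k[1])^2
  out <- matrix(0, nrow = length(x), ncol = K - 1L)
  out[, 1L] <- 1
  sq <- function(u) pmax(u, 0)^2
  for (j in seq_len(K - 2L)) {
    kj <- k[j + 1L]  # internal knot j
    lam <- (k[K] - kj) / (k[K] - k[1])
    out[, j + 1L] <- 3 * (sq(x - kj) - lam * sq(x - k[1]) -
                            (1 - lam) * sq(x - k[K])) / norm
  }
  colnames(out) <- c("lin", paste0("rcs", seq_len(K - 2L)))[seq_len(K - 1L)]
  out
}

#' Spline basis of log time with its analytic derivative
#'
#' Evaluates the restricted cubic spline basis of log time used for the
#' baseline log cumulative hazard (and for time-dependent effects),
#' together with its derivative with respect to log time, which enters
#' the survival likelihood.  With `df = 1` (no internal knots) the basis
#' degenerates to `log(t)` itself and the derivative to 1: the Weibull
#' special case.
#'
#' @param log_t Numeric vector of log event/censoring times.
#' @param spec A [spline_spec()] on the log-time scale, or `NULL` for
#'   the 1-df (Weibull) basis.
#' @return A list with `basis` and `deriv`, both `length(log_t)` by `df`
#'   matrices.
#' @export
time_basis <- function(log_t, spec = NULL) {
  if (any(!is.finite(log_t))) {
    stop("log time must be finite; follow-up times must be positive", call. = FALSE)
  }
  if (is.null(spec)) {
    return(list(basis = matrix(log_t, ncol = 1, dimnames = list(NULL, "lin")),
                deriv = matrix(1, nrow = length(log_t), ncol = 1,
                               dimnames = list(NULL, "lin"))))
  }
  list(basis = rcs_basis(log_t, spec), deriv = rcs_deriv(log_t, spec))
}

# Knots for the baseline log-time spline: boundary knots at the extremes
# of the uncensored log event times, internal knots at equally spaced
# centiles of the same distribution (the convention of the flexible
# parametric survival literature).  df = 1 means no spline (Weibull).
baseline_time_knots <- function(log_event_times, df) {
  if (df < 1L) stop("baseline df must be >= 1", call. = FALSE)
  if (df == 1L) return(NULL)
  n_internal <- df - 1L
  probs <- seq_len(n_internal) / (n_internal + 1L)
  internal <- unname(stats::quantile(log_event_times, probs = probs, type = 7))
  k <- c(min(log_event_times), internal, max(log_event_times))
  if (anyDuplicated(k)) {
    stop("duplicate baseline time knots; too few distinct event times for this df",
         call. = FALSE)
  }
  spline_spec(k)
}
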
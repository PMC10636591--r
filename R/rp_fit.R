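# Likelihood and maximum-likelihood fitting of the flexible parametric
# proportional-hazards model on the log cumulative hazard scale.
#
# With eta_i = s(log t_i; gamma) + x_i' beta + sum_k z_ik s_k(log t_i),
# the cumulative hazard is H_i = exp(eta_i) and the log likelihood is
#
#   l = sum_i { d_i [ log(d eta_i / d log t) - log t_i + eta_i ] - exp(eta_i) }.
#
# Rows where d eta / d log t <= 0 at an event time have hazard <= 0 and
# contribute -Inf; the Newton line search never accepts such a point, so
# the reported log likelihood is always the exact value.

check_complete <- function(data, spec, extra = c("time", "event")) {
  vars <- c(names(spec$terms), extra)
  need_age <- any(vapply(spec$terms, function(tm) "age" %in% tm$by, logical(1)))
  need_sex <- any(vapply(spec$terms, function(tm) "sex" %in% tm$by, logical(1)))
  need_smok <- any(vapply(spec$terms, function(tm) "smoking_status" %in% tm$by,
                          logical(1)))
  vars <- unique(c(vars, if (need_age) "age_entry", if (need_sex) "sex",
                   if (need_smok) "smoking_status"))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_na <- vars[vapply(vars, function(v) anyNA(data[[v]]), logical(1))]
  if (length(has_na)) {
    stop("missing values in: ", paste(has_na, collapse = ", "),
         "; filter to complete cases first (see complete_case_filter())",
         call. = FALSE)
  }
  invisible(vars)
}

# Assemble the full design: M for eta, Mp for d eta / d log t.
# Column order: intercept, baseline time spline (baseline_df cols),
# static covariate columns, then one block per time-dependent term.
prepare_rp <- function(data, spec, info = NULL, time_spec = NULL,
                       tvc_specs = NULL) {
  check_complete(data, spec)
  t <- data$time
  d <- data$event
  if (any(t <= 0)) stop("follow-up times must be positive", call. = FALSE)
  if (!all(d %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  lt <- log(t)
  let <- lt[d == 1]

  if (is.null(info)) info <- build_term_info(data, spec)
  st <- build_static(data, spec, info)
  tvc_dfs <- unique(vapply(st$tvc, `[[`, integer(1), "df"))
  needs_knots <- (is.null(time_spec) && spec$baseline_df > 1L) ||
    (is.null(tvc_specs) && any(tvc_dfs > 1L))
  if (needs_knots && sum(d) < 2) {
    stop("at least two events are required to place log-time knots; ",
         "supply time_spec/tvc_specs explicitly otherwise", call. = FALSE)
  }
  if (is.null(time_spec) && spec$baseline_df > 1L) {
    time_spec <- baseline_time_knots(let, spec$baseline_df)
  }
  if (is.null(tvc_specs)) {
    tvc_specs <- lapply(tvc_dfs, function(df) {
      if (df == 1L) NULL else baseline_time_knots(let, df)
    })
    names(tvc_specs) <- as.character(tvc_dfs)
  }

  bt <- time_basis(lt, time_spec)
  Bt <- bt$basis; Btp <- bt$deriv
  colnames(Bt) <- colnames(Btp) <- paste0("time_s", seq_len(ncol(Bt)))

  M <- cbind(`(Intercept)` = 1, Bt, st$X)
  Mp <- cbind(0, Btp, matrix(0, nrow(data), ncol(st$X)))
  for (blk in st$tvc) {
    tb <- time_basis(lt, tvc_specs[[as.character(blk$df)]])
    cols <- blk$z * tb$basis
    colsp <- blk$z * tb$deriv
    nm <- paste0(blk$name, ":time_s", seq_len(ncol(cols)))
    colnames(cols) <- nm
    M <- cbind(M, cols)
    Mp <- cbind(Mp, colsp)
  }
  colnames(Mp) <- colnames(M)
  list(M = M, Mp = Mp, d = d, lt = lt, info = info, time_spec = time_spec,
       tvc_specs = tvc_specs, spec = spec, n = nrow(data), n_events = sum(d))
}

loglik_core <- function(par, prep) {
  eta <- drop(prep$M %*% par)
  D <- drop(prep$Mp %*% par)
  ev <- prep$d == 1
  # only event rows involve log(D): a non-positive hazard derivative on
  # a censored row is harmless and must not poison the sum
  D_ev <- D[ev]
  if (any(D_ev <= 0)) return(-Inf)
  sum(log(D_ev) - prep$lt[ev] + eta[ev]) - sum(exp(eta))
}

loglik_grad <- function(par, prep) {
  eta <- drop(prep$M %*% par)
  D <- drop(prep$Mp %*% par)
  d <- prep$d
  w <- numeric(length(D))
  w[d == 1] <- 1 / D[d == 1]
  drop(crossprod(prep$Mp, w) + crossprod(prep$M, d - exp(eta)))
}

# Analytic Hessian:  - Mp' diag(d / D^2) Mp  -  M' diag(exp(eta)) M.
# Both terms are negative semidefinite, so the log likelihood is
# concave wherever d eta / d log t > 0 at the event rows.
loglik_hess <- function(par, prep) {
  eta <- drop(prep$M %*% par)
  D <- drop(prep$Mp %*% par)
  d <- prep$d
  w <- numeric(length(D))
  w[d == 1] <- 1 / D[d == 1]^2
  -crossprod(prep$Mp * w, prep$Mp) - crossprod(prep$M * exp(eta), prep$M)
}

#' Log likelihood of a flexible parametric survival model
#'
#' Evaluates the exact log likelihood at a given parameter vector.
#' Rows whose log cumulative hazard is non-increasing in log time at an
#' event time have non-positive hazard and make the likelihood `-Inf`
#' (reported as such, never clipped).
#'
#' @param data Cohort table with `time`, `event` and the spec's
#'   variables, complete cases only.
#' @param spec An [rp_spec()].
#' @param params Numeric parameter vector in the order reported by
#'   [rp_fit()] / [rp_design()]: intercept, baseline time-spline
#'   coefficients, covariate coefficients, time-dependent blocks.
#' @return A scalar log likelihood.
#' @export
rp_loglik <- function(data, spec, params) {
  prep <- prepare_rp(data, spec)
  if (length(params) != ncol(prep$M)) {
    stop("expected ", ncol(prep$M), " parameters (see rp_design() for the ",
         "column order), got ", length(params), call. = FALSE)
  }
  loglik_core(params, prep)
}

#' Design matrices of a flexible parametric survival model
#'
#' Returns the full design matrix for the log cumulative hazard and its
#' derivative with respect to log time, as used by the likelihood.
#' Mostly useful for tests and diagnostics.
#'
#' @inheritParams rp_loglik
#' @return List with `M`, `Mp` (matrices) and the knot specifications.
#' @export
rp_design <- function(data, spec) {
  prep <- prepare_rp(data, spec)
  prep[c("M", "Mp", "time_spec", "tvc_specs")]
}

# Product-limit (Kaplan-Meier) survival estimate, used only to seed the
# baseline spline coefficients deterministically.
km_estimate <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time[event == 1])
  n <- length(time)
  at_risk <- n - findInterval(ut, time, left.open = TRUE)
  d_t <- vapply(ut, function(u) sum(time == u & event == 1), numeric(1))
  S <- cumprod(1 - d_t / at_risk)
  list(time = ut, surv = S)
}

init_params <- function(prep) {
  par <- numeric(ncol(prep$M))
  names(par) <- colnames(prep$M)
  km <- km_estimate(exp(prep$lt), prep$d)
  ok <- km$surv > 0 & km$surv < 1
  p_base <- 1L + ncol(time_basis(0, prep$time_spec)$basis)
  if (sum(ok) >= p_base) {
    z <- log(-log(km$surv[ok]))
    B <- cbind(1, time_basis(log(km$time[ok]), prep$time_spec)$basis)
    cf <- tryCatch(qr.coef(qr(B), z), error = function(e) NULL)
    if (!is.null(cf) && all(is.finite(cf))) par[seq_len(p_base)] <- cf
  }
  if (all(par[seq_len(p_base)] == 0)) {
    # crude exponential start: H(t) = rate * t
    rate <- prep$n_events / sum(exp(prep$lt))
    par[1L] <- log(rate); par[2L] <- 1
  }
  # guard against a non-positive initial derivative of eta in log time
  if (loglik_core(par, prep) == -Inf) par[2L] <- abs(par[2L]) + 0.1
  par
}

#' Fit a flexible parametric survival model
#'
#' Maximises the log likelihood by BFGS with analytic gradients,
#' followed by Newton polishing on the numerical Hessian.  The baseline
#' spline coefficients are initialised from a least-squares fit of
#' \eqn{\log(-\log \hat S_{KM})} on the time basis at event times;
#' covariate coefficients start at zero, so refitting identical inputs
#' is bit-stable.
#'
#' @inheritParams rp_loglik
#' @param init Optional named starting values (defaults to the
#'   deterministic initialisation above).
#' @param max_iter Maximum BFGS iterations.
#' @param compute_vcov If `TRUE` (default) the coefficient covariance is
#'   taken from the inverse numerical Hessian.
#' @param info,time_spec,tvc_specs Optional overrides for the per-term
#'   metadata (factor levels, covariate spline knots, centring) and the
#'   log-time spline specifications; by default these are derived from
#'   the analysis sample.  Supplying them pins the basis to known knots,
#'   e.g. to compare coefficients against a generating model.
#' @return An object of class `rp_fit` with coefficients, `loglik`,
#'   `df_model` (free parameters excluding the baseline intercept),
#'   `n_used`, `n_events`, `converged`, knot specifications and
#'   (optionally) `vcov`.  A fit whose log cumulative hazard is
#'   non-monotone in log time at some event time is flagged via
#'   `monotone_ok = FALSE` with a warning.
#' @export
rp_fit <- function(data, spec, init = NULL, max_iter = 200,
                   compute_vcov = TRUE, info = NULL, time_spec = NULL,
                   tvc_specs = NULL) {
  prep <- prepare_rp(data, spec, info = info, time_spec = time_spec,
                     tvc_specs = tvc_specs)
  if (prep$n_events < 1) {
    stop("at least one event is required to fit the model", call. = FALSE)
  }
  par_raw <- if (is.null(init)) init_params(prep) else init
  # Optimise in an internally standardised parameterisation: every
  # non-intercept column of the design is centred and scaled.  This is
  # an exact reparameterisation (the intercept absorbs the constant
  # shifts and the derivative design is unaffected by centring) that
  # keeps the Hessian well conditioned.
  ctr <- colMeans(prep$M); ctr[1] <- 0
  scl <- apply(prep$M, 2, stats::sd); scl[1] <- 1
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  prep_s <- prep
  prep_s$M <- sweep(sweep(prep$M, 2, ctr), 2, scl, "/")
  prep_s$Mp <- sweep(prep$Mp, 2, scl, "/")
  to_std <- function(p) {
    b <- p * scl
    b[1] <- p[1] + sum(p[-1] * ctr[-1])
    b
  }
  from_std <- function(b) {
    p <- b / scl
    p[1] <- b[1] - sum((b[-1] / scl[-1]) * ctr[-1])
    p
  }
  par <- to_std(par_raw)
  prep_fit <- prep_s
  # Damped Newton-Raphson on the analytic Hessian.  The likelihood is
  # concave wherever the hazard is positive at the event rows, so full
  # Newton steps with step-halving (to stay in that region and never
  # decrease the likelihood) converge quadratically.
  ll <- loglik_core(par, prep_fit)
  if (!is.finite(ll)) {
    stop("initial values give non-positive hazard at an event time; ",
         "supply different starting values", call. = FALSE)
  }
  H <- NULL
  iter <- 0L
  singular <- FALSE
  # Jacobi-preconditioned Newton solve: rescaling rows/columns of H by
  # 1/sqrt(|diag|) is exact algebra but removes the conditioning damage
  # done by covariate columns on very different scales.
  newton_step <- function(H, g) {
    s <- 1 / sqrt(pmax(abs(diag(H)), 1e-300))
    Hs <- H * tcrossprod(s)
    st <- tryCatch(solve(Hs, -g * s), error = function(e) NULL)
    if (is.null(st)) return(NULL)
    st * s
  }
  repeat {
    iter <- iter + 1L
    g <- loglik_grad(par, prep_fit)
    H <- loglik_hess(par, prep_fit)
    step <- newton_step(H, g)
    if (is.null(step)) {
      singular <- TRUE
      step <- newton_step(H - diag(1e-8 * max(abs(diag(H))), nrow(H)), g)
      if (is.null(step)) break
    }
    # fall back to steepest ascent if rounding destroyed the direction
    if (sum(step * g) <= 0) step <- g / max(abs(g))
    # fraction-to-boundary rule: d eta / d log t is linear in the
    # parameters, so the largest step keeping the hazard positive at
    # every event row is available in closed form; stepping to 99% of
    # it prevents the line search from stalling against the barrier.
    ev <- prep_fit$d == 1
    D_ev <- drop(prep_fit$Mp[ev, , drop = FALSE] %*% par)
    dD_ev <- drop(prep_fit$Mp[ev, , drop = FALSE] %*% step)
    shrinking <- dD_ev < 0
    sc_max <- if (any(shrinking)) {
      min(1, 0.99 * min(-D_ev[shrinking] / dD_ev[shrinking]))
    } else 1
    sc <- sc_max
    moved <- FALSE
    repeat {
      cand <- par + sc * step
      ll_cand <- loglik_core(cand, prep_fit)
      if (is.finite(ll_cand) && ll_cand >= ll) {
        moved <- abs(ll_cand - ll) > 1e-9 * (abs(ll) + 1e-9) || sc < 1
        par <- cand
        ll_prev <- ll
        ll <- ll_cand
        break
      }
      sc <- sc / 2
      if (sc < 1e-10) { ll_prev <- ll; break }
    }
    if (iter >= max_iter) break
    if (abs(ll - ll_prev) < 1e-9 * (abs(ll) + 1e-9) &&
        max(abs(loglik_grad(par, prep_fit))) / (1 + abs(ll)) < 1e-6) break
    if (!moved && sc < 1e-10) break
  }
  g <- loglik_grad(par, prep_fit)
  max_grad <- max(abs(g))
  converged <- is.finite(ll) && max_grad / (1 + abs(ll)) < 1e-6 &&
    iter < max_iter
  if (singular) {
    warning("singular information matrix; coefficients may be ",
            "non-identifiable", call. = FALSE)
  }
  if (!converged) {
    warning("model fit did not meet the convergence tolerance (max gradient ",
            signif(max_grad, 3), " after ", iter, " iterations)", call. = FALSE)
  }
  D <- drop(prep_fit$Mp %*% par)
  monotone_ok <- all(D[prep_fit$d == 1] > 0)
  if (!monotone_ok) {
    warning("log cumulative hazard non-monotone in log time at ",
            sum(D[prep_fit$d == 1] <= 0), " event time(s)", call. = FALSE)
  }
  vcov <- NULL
  if (compute_vcov) {
    Hf <- loglik_hess(par, prep_fit)
    sj <- 1 / sqrt(pmax(abs(diag(Hf)), 1e-300))
    Vs <- tryCatch(solve(-(Hf * tcrossprod(sj))), error = function(e) NULL)
    if (!is.null(Vs)) {
      V_std <- Vs * tcrossprod(sj)
      # delta-method back-transform to the raw parameterisation
      p <- length(par)
      J <- diag(1 / scl)
      J[1, 1] <- 1
      J[1, -1] <- -ctr[-1] / scl[-1]
      vcov <- J %*% V_std %*% t(J)
      dimnames(vcov) <- list(names(par), names(par))
    }
  }
  par <- from_std(par)
  structure(
    list(coefficients = par, loglik = ll, df_model = length(par) - 1L,
         n_used = prep$n, n_events = prep$n_events, converged = converged,
         max_grad = max_grad, monotone_ok = monotone_ok, vcov = vcov,
         spec = spec, info = prep$info, time_spec = prep$time_spec,
         tvc_specs = prep$tvc_specs),
    class = "rp_fit"
  )
}

#' @export
print.rp_fit <- function(x, ...) {
  cat("Flexible parametric survival model fit\n")
  cat("  n = ", x$n_used, " (", x$n_events, " events); log-likelihood ",
      format(x$loglik, digits = 8), "; ", x$df_model,
      " df (excluding baseline intercept)\n", sep = "")
  if (!x$converged) cat("  WARNING: not converged\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
logLik.rp_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_used, class = "logLik")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficients of a flexible parametric survival fit
#'
#' @param x An [rp_fit()].
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`
#'   (log hazard-ratio scale for covariate terms), `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.rp_fit <- function(x, conf_level = 0.95, ...) {
  est <- x$coefficients
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else rep(NA_real_, length(est))
  z <- est / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * stats::pnorm(-abs(z))),
    conf.low = unname(est - q * se), conf.high = unname(est + q * se)
  )
}

#' One-row summary of a flexible parametric survival fit
#'
#' @param x An [rp_fit()].
#' @param ... Unused.
#' @return A tibble with `logLik`, `df`, `AIC`, `nobs`, `n_events`,
#'   `converged`.
#' @export
glance.rp_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, df = length(x$coefficients),
    AIC = -2 * x$loglik + 2 * length(x$coefficients),
    nobs = x$n_used, n_events = x$n_events, converged = x$converged
  )
}

# eta(t | x) for new data, using the knots/centres stored in the fit.
rp_eta <- function(fit, newdata, t) {
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  lt <- rep_len(log(t), nrow(newdata))
  st <- build_static(newdata, fit$spec, fit$info)
  bt <- time_basis(lt, fit$time_spec)
  M <- cbind(1, bt$basis, st$X)
  for (blk in st$tvc) {
    tb <- time_basis(lt, fit$tvc_specs[[as.character(blk$df)]])
    M <- cbind(M, blk$z * tb$basis)
  }
  eta <- drop(M %*% fit$coefficients)
  extrap <- if (!is.null(fit$time_spec)) {
    any(lt < fit$time_spec$knots[1] | lt > fit$time_spec$knots[length(fit$time_spec$knots)])
  } else FALSE
  attr(eta, "extrapolated") <- extrap
  eta
}

#' Predicted risk at a time horizon
#'
#' Absolute risk \eqn{1 - S(t \mid x) = 1 - \exp(-\exp(\eta(t, x)))} for
#' each row of `newdata`.  Beyond the boundary knots the log cumulative
#' hazard is extrapolated linearly in log time (the natural tail of the
#' spline); the result carries an `extrapolated` attribute when this
#' happens.
#'
#' @param fit An [rp_fit()].
#' @param newdata Cohort table rows, complete for the model variables.
#' @param t Horizon in years (scalar, or one value per row).
#' @return Numeric vector of risks in (0, 1), with attribute
#'   `extrapolated`.
#' @export
predict_risk <- function(fit, newdata, t) {
  check_complete(newdata, fit$spec, extra = character())
  eta <- rp_eta(fit, newdata, t)
  risk <- -expm1(-exp(eta))  # 1 - S(t|x), accurate for tiny hazards
  attr(risk, "extrapolated") <- attr(eta, "extrapolated")
  risk
}

#' Likelihood ratio test between nested fits
#'
#' @param fit_nested,fit_full Two [rp_fit()] objects fitted to the same
#'   analysis rows, the first nested in the second.
#' @return A tibble with `chi2` (= 2 * difference in log likelihood),
#'   `df` (difference in free parameters) and `p.value` from the
#'   chi-square upper tail.
#' @export
lr_test <- function(fit_nested, fit_full) {
  if (fit_nested$n_used != fit_full$n_used ||
      fit_nested$n_events != fit_full$n_events) {
    stop("fits use different analysis rows; refit both on the identical ",
         "complete-case sample", call. = FALSE)
  }
  chi2 <- 2 * (fit_full$loglik - fit_nested$loglik)
  df <- length(fit_full$coefficients) - length(fit_nested$coefficients)
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else
    as.numeric(chi2 <= 0)
  tibble::tibble(chi2 = chi2, df = df, p.value = p)
}

#' Serialise a fitted model to JSON
#'
#' Writes the model structure, knots, coefficients and fit metadata so
#' a fit can be stored and reloaded without refitting.
#'
#' @param fit An [rp_fit()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rp_fit <- function(fit, path) {
  ser_spec <- function(s) if (is.null(s)) NULL else list(knots = s$knots)
  obj <- list(
    baseline_df = fit$spec$baseline_df,
    terms = lapply(fit$spec$terms, function(tm) tm[c("variable", "transform",
                                                     "rcs_df", "log_first",
                                                     "by", "tvc_df")]),
    info = lapply(fit$info, function(ti) {
      list(variable = ti$variable, type = ti$type, levels = ti$levels,
           knots = if (!is.null(ti$knots)) ti$knots$knots,
           age_center = ti$age_center)
    }),
    time_spec = ser_spec(fit$time_spec),
    tvc_specs = lapply(fit$tvc_specs, ser_spec),
    coefficients = as.list(fit$coefficients),
    loglik = fit$loglik, df_model = fit$df_model,
    n_used = fit$n_used, n_events = fit$n_events,
    converged = fit$converged, monotone_ok = fit$monotone_ok
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a fitted model from JSON
#'
#' @param path File written by [write_rp_fit()].
#' @return An `rp_fit` object (without `vcov`).
#' @export
read_rp_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- lapply(obj$terms, function(tm) {
    rp_term(tm$variable, transform = tm$transform,
            rcs_df = if (is.null(tm$rcs_df)) 3 else tm$rcs_df,
            log_first = isTRUE(tm$log_first),
            by = unlist(tm$by) %||% character(), tvc_df = tm$tvc_df %||% 0)
  })
  spec <- rp_spec(unname(terms), baseline_df = obj$baseline_df)
  info <- lapply(obj$info, function(ti) {
    out <- list(variable = ti$variable, type = ti$type)
    if (length(unlist(ti$levels))) out$levels <- unlist(ti$levels)
    if (length(unlist(ti$knots))) out$knots <- spline_spec(unlist(ti$knots))
    if (length(unlist(ti$age_center))) out$age_center <- ti$age_center
    out
  })
  des_spec <- function(s) if (length(unlist(s$knots)) < 3) NULL else
    spline_spec(unlist(s$knots))
  cf <- unlist(obj$coefficients)
  structure(
    list(coefficients = cf, loglik = obj$loglik, df_model = obj$df_model,
         n_used = obj$n_used, n_events = obj$n_events,
         converged = obj$converged, monotone_ok = obj$monotone_ok,
         vcov = NULL, spec = spec, info = info,
         time_spec = des_spec(obj$time_spec),
         tvc_specs = lapply(obj$tvc_specs, des_spec)),
    class = "rp_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
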
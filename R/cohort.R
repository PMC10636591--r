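# Synthetic cohort generator.
#
# Emulates a large UK population cohort recruited over a multi-year
# window with baseline demographics, smoking history, deprivation,
# anthropometry, spirometry and a blood panel (liver function tests and
# urate), followed for incident lung cancer at a rare (~0.5%) event
# fraction over a ~7-year median follow-up.  Event times are drawn from
# a user-specified flexible parametric hazard (spline baseline on log
# time, log/spline covariate effects, interactions, time-dependent
# effects) by inverse-transform sampling; censoring is administrative
# (uniform entry over the recruitment span, fixed end of follow-up)
# plus independent exponential mortality.  Missingness is injected
# completely at random per variable.

.logical_vars <- c("family_history_lung_cancer", "history_cancer", "asthma",
                   "allergy", "tuberculosis", "pneumonia", "emphysema",
                   "asbestos_exposure")

#' Default covariate distribution parameters
#'
#' Marginal distributions matched to the baseline characteristics of a
#' large UK volunteer cohort: right-skewed blood measurements are
#' log-normal with location/spread set from published medians and
#' interquartile ranges; categorical probabilities are the published
#' category fractions renormalised over non-missing values.  A small
#' set of explicit dependencies is built in: pack-years depend on
#' smoking status, FEV1 declines with age and pack-years, FVC is FEV1
#' divided by a ratio centred near 0.75 (lower for older and heavier
#' smokers), AST and ALT are correlated on the log scale, and emphysema
#' prevalence rises with smoking.
#'
#' @return A named list of per-variable parameters; see source for the
#'   exact fields.
#' @export
default_covariate_params <- function() {
  list(
    sex = c(female = 0.544, male = 0.456),
    age = list(mean = 58, sd = 8.7, min = 39.5, max = 70),
    ethnicity = c(White = 0.946, Asian = 0.0229, Black = 0.0161,
                  Mixed = 0.0059, Other = 0.0091),
    smoking = c(never = 0.5483, former = 0.3461, current = 0.1056),
    # pack-years for ever smokers, log-normal by status
    pack_years = list(former = c(meanlog = 2.85, sdlog = 0.85),
                      current = c(meanlog = 3.10, sdlog = 0.85)),
    alcohol = c(never = 0.0451, previous = 0.0361, current = 0.9188),
    townsend = list(offset = -4.5, meanlog = log(2.4), sdlog = 1.09),
    waist = list(mean = 90.3, sd = 13.5, min = 55),
    fev1 = list(intercept = 2.8, age_slope = -0.030, py_slope = -0.006,
                sd = 0.74, min = 0.3),
    fev1_fvc_ratio = list(intercept = 0.772, age_slope = -0.0010,
                          py_slope = -0.0010, sd = 0.055,
                          min = 0.35, max = 0.97),
    # log-normal blood measurements: location and spread on log scale
    bloods = list(
      bilirubin = c(meanlog = log(8.1), sdlog = 0.360),
      albumin = c(meanlog = log(45.2), sdlog = 0.0558),
      alt = c(meanlog = log(20.1), sdlog = 0.4272),
      ast = c(meanlog = log(24.4), sdlog = 0.2340),
      alp = c(meanlog = log(80.4), sdlog = 0.2637),
      ggt = c(meanlog = log(26.3), sdlog = 0.5880),
      urate = c(meanlog = log(302.9), sdlog = 0.2707)
    ),
    ast_alt_corr = 0.75,
    histories = c(family_history_lung_cancer = 0.124, history_cancer = 0.105,
                  asthma = 0.124, allergy = 0.243, tuberculosis = 0.005,
                  pneumonia = 0.014, asbestos_exposure = 0.05),
    emphysema_by_smoking = c(never = 0.005, former = 0.035, current = 0.090)
  )
}

#' Default per-variable missingness rates
#'
#' Missing-completely-at-random fractions matching the published
#' missing-data column of the emulated cohort; follow-up time and event
#' status are never missing.
#'
#' @return Named numeric vector of rates in \[0, 1\].
#' @export
default_missingness <- function() {
  c(waist = 0.004, townsend = 0.001, smoking_status = 0.006,
    alcohol_status = 0.003, ethnicity = 0.006, fev1 = 0.097, fvc = 0.097,
    alp = 0.065, alt = 0.066, ast = 0.069, ggt = 0.066,
    bilirubin = 0.069, urate = 0.067, albumin = 0.144)
}

#' Data-generating hazard model
#'
#' Bundles a model structure ([rp_spec()]) with fixed coefficient
#' values and fixed knot locations so it can serve as the true hazard
#' of the synthetic cohort.  Coefficient names must match the design
#' column names used by [rp_fit()]: `(Intercept)`, `time_s1..` for the
#' baseline log-time spline, the covariate/interaction column names,
#' then `"<col>:time_s.."` blocks for time-dependent terms.
#'
#' @param spec An [rp_spec()].
#' @param coefficients Named numeric vector.
#' @param time_knots Baseline log-time spline knots (numeric, on the
#'   log-time scale), or `NULL` for a 1-df (Weibull) baseline.
#' @param tvc_knots Named list of log-time knot vectors for
#'   time-dependent effects, named by their df (e.g. `"2"`); `NULL`
#'   entries give the 1-df (log-linear) sub-basis.
#' @param cov_knots Named list of knot vectors for covariate splines.
#' @param age_center Centring constant for age interaction columns.
#' @return An object of class `rp_truth`.
#' @export
true_model <- function(spec, coefficients, time_knots = NULL,
                       tvc_knots = list(), cov_knots = list(),
                       age_center = 57) {
  stopifnot(inherits(spec, "rp_spec"), is.numeric(coefficients),
            !is.null(names(coefficients)))
  if (any(!is.finite(coefficients))) {
    stop("true-model coefficients must be finite", call. = FALSE)
  }
  info <- list()
  for (tm in spec$terms) {
    v <- tm$variable
    ti <- list(variable = v)
    if (v %in% names(.rp_levels)) {
      ti$type <- "factor"; ti$levels <- .rp_levels[[v]]
    } else if (v %in% .logical_vars) {
      ti$type <- "factor"; ti$levels <- c("FALSE", "TRUE")
    } else {
      ti$type <- "numeric"
      if (tm$transform == "rcs") {
        if (is.null(cov_knots[[v]])) {
          stop("cov_knots missing for spline variable '", v, "'", call. = FALSE)
        }
        ti$knots <- spline_spec(cov_knots[[v]])
      }
    }
    if ("age" %in% tm$by) ti$age_center <- age_center
    info[[v]] <- ti
  }
  tvc_dfs <- unique(vapply(spec$terms, `[[`, integer(1), "tvc_df"))
  tvc_dfs <- tvc_dfs[tvc_dfs > 0]
  tvc_specs <- list()
  for (df in tvc_dfs) {
    k <- tvc_knots[[as.character(df)]]
    tvc_specs[[as.character(df)]] <- if (is.null(k)) NULL else spline_spec(k)
  }
  structure(list(spec = spec, coefficients = coefficients,
                 time_spec = if (is.null(time_knots)) NULL else
                   spline_spec(time_knots),
                 tvc_specs = tvc_specs, info = info),
            class = "rp_truth")
}

#' Default data-generating model
#'
#' The hazard used by the default synthetic cohort: a 2-df spline
#' baseline on log time with conventional risk factors (age, sex,
#' smoking status, pack-years, family history, emphysema, deprivation),
#' a log-bilirubin effect with a sex interaction and a 2-df
#' time-dependent effect, a log-urate effect interacting with smoking
#' status, and a linear FEV1 effect.  The baseline intercept is
#' calibrated so the marginal event fraction over the default follow-up
#' is close to 0.5%.
#'
#' @return An `rp_truth` object.
#' @export
default_true_model <- function() {
  spec <- rp_spec(list(
    rp_term("age_entry", "linear"),
    rp_term("sex"),
    rp_term("smoking_status"),
    rp_term("pack_years", "linear"),
    rp_term("family_history_lung_cancer"),
    rp_term("emphysema"),
    rp_term("townsend", "linear"),
    rp_term("bilirubin", "log", by = "sex", tvc_df = 2),
    rp_term("urate", "log", by = "smoking_status"),
    rp_term("fev1", "linear")
  ), baseline_df = 2)
  cf <- c(
    "(Intercept)" = -9.82, "time_s1" = 1.05, "time_s2" = 0.12,
    "age_entry" = 0.075, "sexmale" = 0.30,
    "smoking_statusformer" = 0.85, "smoking_statuscurrent" = 1.70,
    "pack_years" = 0.010,
    "family_history_lung_cancerTRUE" = 0.55, "emphysemaTRUE" = 0.55,
    "townsend" = 0.055,
    "log_bilirubin" = -0.45, "log_bilirubin:sexmale" = 0.25,
    "log_urate" = -0.35, "log_urate:smokformer" = 0.12,
    "log_urate:smokcurrent" = 0.28,
    "fev1" = -0.30,
    "log_bilirubin:time_s1" = -0.06, "log_bilirubin:time_s2" = 0.12
  )
  true_model(spec, cf, time_knots = log(c(0.08, 3, 12)),
             tvc_knots = list("2" = log(c(0.08, 2, 11))))
}

#' Synthetic cohort configuration
#'
#' @param n Number of participants (>= 1).
#' @param seed Integer seed; the same seed and configuration give a
#'   byte-identical cohort.
#' @param covariate_params See [default_covariate_params()].
#' @param missingness Named per-variable MCAR rates in \[0, 1\]
#'   (see [default_missingness()]); applied by [inject_missingness()].
#' @param true_model The data-generating hazard, an `rp_truth`
#'   (see [true_model()]).
#' @param censoring List with `recruit_span` (years of uniform entry),
#'   `max_follow` (years from the start of recruitment to the fixed
#'   administrative end of follow-up) and `death_rate` (rate of the
#'   independent exponential death/censoring process).  Potential
#'   follow-up is uniform on `[max_follow - recruit_span, max_follow]`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 50000, seed = 1,
                          covariate_params = default_covariate_params(),
                          missingness = default_missingness(),
                          true_model = default_true_model(),
                          censoring = list(recruit_span = 4, max_follow = 9,
                                           death_rate = 0.006)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  check_probs <- function(p, what) {
    if (any(p < 0 | p > 1)) stop(what, " probabilities outside [0,1]",
                                 call. = FALSE)
  }
  for (nm in c("sex", "ethnicity", "smoking", "alcohol")) {
    p <- covariate_params[[nm]]
    check_probs(p, nm)
    if (abs(sum(p) - 1) > 1e-6) {
      stop("category probabilities for '", nm, "' must sum to 1", call. = FALSE)
    }
  }
  check_probs(covariate_params$histories, "history")
  check_probs(covariate_params$emphysema_by_smoking, "emphysema")
  if (any(missingness < 0 | missingness > 1)) {
    stop("missingness rates must lie in [0,1]", call. = FALSE)
  }
  stopifnot(inherits(true_model, "rp_truth"))
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 covariate_params = covariate_params,
                 missingness = missingness, true_model = true_model,
                 censoring = censoring),
            class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

sample_cat <- function(n, probs) {
  names(probs)[1L + findInterval(stats::runif(n), cumsum(probs),
                                 left.open = TRUE)]
}

generate_covariates <- function(n, cp) {
  sex <- sample_cat(n, cp$sex)
  age <- rtrunc_norm(n, cp$age$mean, cp$age$sd, cp$age$min, cp$age$max)
  ethnicity <- sample_cat(n, cp$ethnicity)
  smoking <- sample_cat(n, cp$smoking)
  pack_years <- numeric(n)
  for (s in c("former", "current")) {
    idx <- smoking == s
    p <- cp$pack_years[[s]]
    pack_years[idx] <- stats::rlnorm(sum(idx), p["meanlog"], p["sdlog"])
  }
  pack_years <- pmin(pack_years, 150)
  alcohol <- sample_cat(n, cp$alcohol)
  townsend <- cp$townsend$offset +
    stats::rlnorm(n, cp$townsend$meanlog, cp$townsend$sdlog)
  townsend <- pmin(townsend, 12)
  waist <- pmax(stats::rnorm(n, cp$waist$mean, cp$waist$sd), cp$waist$min)
  f <- cp$fev1
  fev1 <- pmax(f$intercept + f$age_slope * (age - 57) + f$py_slope * pack_years +
                 stats::rnorm(n, 0, f$sd), f$min)
  r <- cp$fev1_fvc_ratio
  ratio <- r$intercept + r$age_slope * (age - 50) + r$py_slope * pack_years +
    stats::rnorm(n, 0, r$sd)
  ratio <- pmin(pmax(ratio, r$min), r$max)
  fvc <- fev1 / ratio
  b <- cp$bloods
  # AST and ALT share a latent factor on the log scale
  z_alt <- stats::rnorm(n)
  z_ast <- cp$ast_alt_corr * z_alt + sqrt(1 - cp$ast_alt_corr^2) * stats::rnorm(n)
  bloods <- list(
    bilirubin = stats::rlnorm(n, b$bilirubin["meanlog"], b$bilirubin["sdlog"]),
    albumin = stats::rlnorm(n, b$albumin["meanlog"], b$albumin["sdlog"]),
    alt = exp(b$alt["meanlog"] + b$alt["sdlog"] * z_alt),
    ast = exp(b$ast["meanlog"] + b$ast["sdlog"] * z_ast),
    alp = stats::rlnorm(n, b$alp["meanlog"], b$alp["sdlog"]),
    ggt = stats::rlnorm(n, b$ggt["meanlog"], b$ggt["sdlog"]),
    urate = stats::rlnorm(n, b$urate["meanlog"], b$urate["sdlog"])
  )
  hh <- cp$histories
  hist_cols <- lapply(hh, function(p) stats::runif(n) < p)
  emph_p <- unname(cp$emphysema_by_smoking[smoking])
  emphysema <- stats::runif(n) < emph_p
  tibble::tibble(
    id = seq_len(n), age_entry = age, sex = sex, ethnicity = ethnicity,
    smoking_status = smoking, pack_years = pack_years,
    alcohol_status = alcohol, townsend = townsend, waist = waist,
    fev1 = fev1, fvc = fvc,
    bilirubin = bloods$bilirubin, albumin = bloods$albumin,
    alt = bloods$alt, ast = bloods$ast, alp = bloods$alp, ggt = bloods$ggt,
    urate = bloods$urate,
    family_history_lung_cancer = hist_cols$family_history_lung_cancer,
    history_cancer = hist_cols$history_cancer, asthma = hist_cols$asthma,
    allergy = hist_cols$allergy, tuberculosis = hist_cols$tuberculosis,
    pneumonia = hist_cols$pneumonia, emphysema = emphysema,
    asbestos_exposure = hist_cols$asbestos_exposure
  )
}

# Split a named true-model coefficient vector into the pieces needed to
# evaluate eta(log t) subject-wise: intercept, baseline gamma, static
# xb contribution and time-dependent blocks.
truth_lp <- function(covdata, truth) {
  st <- build_static(covdata, truth$spec, truth$info)
  cf <- truth$coefficients
  base_df <- if (is.null(truth$time_spec)) 1L else truth$time_spec$df
  need <- c("(Intercept)", paste0("time_s", seq_len(base_df)), colnames(st$X))
  for (blk in st$tvc) {
    need <- c(need, paste0(blk$name, ":time_s", seq_len(blk$df)))
  }
  miss <- setdiff(need, names(cf))
  if (length(miss)) {
    stop("true-model coefficients missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  gamma <- cf[paste0("time_s", seq_len(base_df))]
  xb <- if (ncol(st$X)) drop(st$X %*% cf[colnames(st$X)]) else numeric(nrow(covdata))
  tvc <- lapply(st$tvc, function(blk) {
    list(z = blk$z, spec = truth$tvc_specs[[as.character(blk$df)]],
         gamma = cf[paste0(blk$name, ":time_s", seq_len(blk$df))])
  })
  list(
    eta = function(lnt) {
      out <- cf[["(Intercept)"]] +
        drop(time_basis(lnt, truth$time_spec)$basis %*% gamma) + xb
      for (b in tvc) {
        out <- out + b$z * drop(time_basis(lnt, b$spec)$basis %*% b$gamma)
      }
      out
    },
    deta = function(lnt) {
      out <- drop(time_basis(lnt, truth$time_spec)$deriv %*% gamma)
      if (length(out) == 1L) out <- rep(out, nrow(covdata))
      for (b in tvc) {
        out <- out + b$z * drop(time_basis(lnt, b$spec)$deriv %*% b$gamma)
      }
      out
    }
  )
}

# Inverse-transform sampling of event times: solve eta(log t) =
# log(-log U) for each subject by vectorised bisection.  eta must be
# increasing in log time over the support; this is checked on a grid
# and violations reject the configuration.
sample_event_times <- function(covdata, truth, t_max = 600) {
  n <- nrow(covdata)
  lp <- truth_lp(covdata, truth)
  grid <- seq(log(0.001), log(60), length.out = 40)
  for (g in grid) {
    if (any(lp$deta(rep(g, n)) <= 0)) {
      stop("non-invertible cumulative hazard: eta is non-monotone in log ",
           "time under the supplied true model; reduce the time-dependent ",
           "coefficients or change the baseline spline", call. = FALSE)
    }
  }
  u <- stats::runif(n)
  target <- log(-log(u))
  lo <- rep(log(1e-8), n)
  hi <- rep(log(t_max), n)
  possible <- lp$eta(hi) >= target
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    above <- lp$eta(mid) >= target
    hi[above] <- mid[above]
    lo[!above] <- mid[!above]
  }
  tt <- exp(hi)
  tt[!possible] <- Inf
  tt
}

#' Generate a synthetic cohort
#'
#' Draws covariates, event times from the configured true hazard, and
#' censoring times, returning the complete table (no missing values).
#' Apply [inject_missingness()] afterwards to add the configured
#' missingness.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per participant: covariates, `time`
#'   (years of follow-up, positive) and `event` (0/1 lung cancer
#'   diagnosis).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  covs <- generate_covariates(config$n, config$covariate_params)
  t_event <- sample_event_times(covs, config$true_model)
  cs <- config$censoring
  admin <- stats::runif(config$n, cs$max_follow - cs$recruit_span, cs$max_follow)
  cens <- if (cs$death_rate > 0) {
    pmin(admin, stats::rexp(config$n, cs$death_rate))
  } else admin
  covs$time <- pmin(t_event, cens)
  covs$event <- as.integer(t_event <= cens)
  covs
}

#' Inject missing values completely at random
#'
#' Sets each listed variable to `NA` independently at its configured
#' rate.  Follow-up time and event status are never made missing.
#'
#' @param data Cohort table.
#' @param rates Named per-variable rates in \[0, 1\].
#' @param seed Integer seed for the masking draws.
#' @return The table with missing values injected.
#' @export
inject_missingness <- function(data, rates = default_missingness(), seed = 1) {
  if (any(rates < 0 | rates > 1)) {
    stop("missingness rates must lie in [0,1]", call. = FALSE)
  }
  if (any(names(rates) %in% c("time", "event"))) {
    stop("time and event can never be missing", call. = FALSE)
  }
  unknown <- setdiff(names(rates), names(data))
  if (length(unknown)) {
    stop("missingness configured for unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  for (v in names(rates)) {
    if (rates[[v]] > 0) {
      mask <- stats::runif(nrow(data)) < rates[[v]]
      data[[v]][mask] <- NA
    }
  }
  data
}

#' Filter to complete cases for a set of variables
#'
#' @param data Cohort table.
#' @param variables Column names that must be non-missing.
#' @return The rows of `data` with no missing value in `variables`.
#' @export
complete_case_filter <- function(data, variables) {
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols)) {
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- !Reduce(`|`, lapply(variables, function(v) is.na(data[[v]])),
                  accumulate = FALSE, init = logical(nrow(data)))
  data[keep, , drop = FALSE]
}

#' Write / read a cohort table as CSV
#'
#' UTF-8 comma-separated text with a header row and `NA` for missing
#' values; column names and types follow the cohort schema.
#'
#' @param data Cohort table.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a tibble.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, na.strings = "NA", stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (v in intersect(.logical_vars, names(df))) df[[v]] <- as.logical(df[[v]])
  tibble::as_tibble(df)
}
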
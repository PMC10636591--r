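# Model-comparison statistics: Harrell's concordance index for censored
# survival data, the fraction of new information carried by an expanded
# model, the heuristic shrinkage factor, and predicted-risk summaries.

# Pair conventions (documented precisely because several exist):
#  * a pair is comparable when the earlier time is an event
#    (t_i < t_j and d_i = 1), or when times are tied and exactly one is
#    an event (the event is known to have the shorter survival);
#  * tied-score comparable pairs count 1/2;
#  * pairs with tied times and two events have no defined ordering and
#    count 1/2 (the score-tie convention applied to the outcome).
concordance_sums <- function(time, event, score, chunk = 256L) {
  n <- length(time)
  conc_k <- numeric(n)   # concordance weight of pairs containing k
  pair_k <- numeric(n)   # comparable pairs containing k
  ev <- event == 1
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n)
    Ti <- time[idx]; Di <- ev[idx]; Si <- score[idx]
    # matrices: rows = chunk members i, cols = all subjects j
    lt <- outer(Ti, time, `<`)
    eq <- outer(Ti, time, `==`)
    # direction i earlier: i is an event before j, or tied with j censored
    A <- (lt & Di) | (eq & Di & matrix(!ev, length(idx), n, byrow = TRUE))
    # tied event times, both events (symmetric; each unordered pair is
    # seen twice across the full loop, so weight by 1/2 here)
    B <- eq & Di & matrix(ev, length(idx), n, byrow = TRUE)
    diag_cells <- cbind(seq_along(idx), idx)
    B[diag_cells] <- FALSE
    sg <- outer(Si, score, `>`)
    se_ <- outer(Si, score, `==`)
    wA <- A * (sg + 0.5 * se_)
    # accumulate both orientations so each unordered pair contributes
    # once to each member
    pair_k[idx] <- pair_k[idx] + rowSums(A) + rowSums(B) / 2
    pair_k <- pair_k + colSums(A) + colSums(B) / 2
    conc_k[idx] <- conc_k[idx] + rowSums(wA) + rowSums(B) / 4
    conc_k <- conc_k + colSums(wA) + colSums(B) / 4
  }
  list(conc_k = conc_k, pair_k = pair_k,
       concordant = sum(conc_k) / 2, pairs = sum(pair_k) / 2)
}

#' Harrell's c-index for censored survival data
#'
#' Concordance between a risk score (higher = higher risk, i.e. shorter
#' survival) and observed survival: the fraction of comparable pairs in
#' which the higher-scored subject fails first, with tied scores (and
#' tied-event-time pairs) counting one half.  A pair is comparable when
#' the earlier time is an event.  The confidence interval uses a
#' leave-one-subject-out jackknife standard error by default; a seeded
#' nonparametric bootstrap is available.
#'
#' @param data Data frame with the survival outcome and score.
#' @param time,event,score Column names (unquoted or character) of the
#'   follow-up time, 0/1 event indicator and risk score.
#' @param se_method `"jackknife"` (default), `"bootstrap"` or `"none"`.
#' @param conf_level Confidence level.
#' @param n_boot,seed Bootstrap replicates and seed (bootstrap only).
#' @return A one-row tibble: `c_index`, `se`, `conf_low`, `conf_high`,
#'   `n`, `n_events`, `n_pairs`.
#' @export
harrell_c <- function(data, time = "time", event = "event", score = "score",
                      se_method = c("jackknife", "bootstrap", "none"),
                      conf_level = 0.95, n_boot = 200, seed = 1) {
  se_method <- match.arg(se_method)
  tv <- data[[rlang::as_name(rlang::enquo(time))]]
  dv <- data[[rlang::as_name(rlang::enquo(event))]]
  sv <- data[[rlang::as_name(rlang::enquo(score))]]
  if (is.null(tv) || is.null(dv) || is.null(sv)) {
    stop("time/event/score columns not found in data", call. = FALSE)
  }
  if (any(!is.finite(sv))) stop("scores must be finite", call. = FALSE)
  cs <- concordance_sums(tv, dv, sv)
  if (cs$pairs == 0) {
    stop("no comparable pairs: cannot compute a concordance index",
         call. = FALSE)
  }
  cval <- cs$concordant / cs$pairs
  se <- NA_real_
  if (se_method == "jackknife") {
    n <- length(tv)
    c_minus <- (cs$concordant - cs$conc_k) / (cs$pairs - cs$pair_k)
    ok <- is.finite(c_minus)
    c_minus[!ok] <- cval
    se <- sqrt((n - 1) / n * sum((c_minus - mean(c_minus))^2))
  } else if (se_method == "bootstrap") {
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(length(tv), replace = TRUE)
      csb <- concordance_sums(tv[i], dv[i], sv[i])
      csb$concordant / csb$pairs
    }, numeric(1))
    se <- stats::sd(reps)
  }
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    c_index = cval, se = se,
    conf_low = if (is.na(se)) NA_real_ else max(0, cval - q * se),
    conf_high = if (is.na(se)) NA_real_ else min(1, cval + q * se),
    n = length(tv), n_events = sum(dv == 1), n_pairs = cs$pairs
  )
}

#' Fraction of new information
#'
#' One minus the ratio of the reference model's likelihood-ratio
#' chi-square to the expanded model's: the proportion of the expanded
#' model's prognostic information that the reference model lacks.
#'
#' @param chi2_ref,chi2_alt Positive model likelihood-ratio chi-square
#'   statistics (each model versus the null model) for the reference
#'   and the alternative (expanded) model.
#' @return `1 - chi2_ref / chi2_alt`.
#' @export
fraction_new_information <- function(chi2_ref, chi2_alt) {
  if (any(chi2_ref <= 0) || any(chi2_alt <= 0)) {
    stop("chi-square statistics must be positive", call. = FALSE)
  }
  1 - chi2_ref / chi2_alt
}

#' Heuristic shrinkage factor
#'
#' `(chi2 - df) / chi2`: a gauge of the optimism of fitted coefficients;
#' values near 1 indicate little overfitting.
#'
#' @param chi2 Positive model likelihood-ratio chi-square.
#' @param df Model degrees of freedom.
#' @return The shrinkage factor (at most 1).
#' @export
shrinkage_factor <- function(chi2, df) {
  if (any(chi2 <= 0)) stop("chi-square must be positive", call. = FALSE)
  (chi2 - df) / chi2
}

#' Median and interquartile range of predicted risks
#'
#' @param risks Numeric vector of predicted risks in (0, 1).
#' @param digits Decimal places for the percentage summaries.
#' @return A one-row tibble with `median_pct`, `q25_pct`, `q75_pct`.
#' @export
risk_summary <- function(risks, digits = 2) {
  if (!length(risks)) stop("no risks supplied", call. = FALSE)
  if (any(risks <= 0 | risks >= 1)) {
    stop("risks must lie strictly in (0, 1)", call. = FALSE)
  }
  q <- stats::quantile(risks, c(0.25, 0.5, 0.75), type = 7)
  tibble::tibble(
    median_pct = round(100 * q[[2]], digits),
    q25_pct = round(100 * q[[1]], digits),
    q75_pct = round(100 * q[[3]], digits)
  )
}

#' Model comparison report across screening scenarios
#'
#' For each fitted scenario model: Harrell's c-index with confidence
#' interval, the model likelihood-ratio chi-square versus the shared
#' null (baseline-only) model, the likelihood-ratio p-value versus the
#' reference scenario, the fraction of new information, the heuristic
#' shrinkage factor, and median/IQR predicted risk at the requested
#' horizons.
#'
#' @param data The complete-case analysis table all models were fitted
#'   on (also used to compute risk scores for the c-index).
#' @param fits Named list of [rp_fit()] objects; the first is the
#'   reference scenario.
#' @param null_fit Baseline-only [rp_fit()] on the same rows.
#' @param horizons Risk horizons in years for the risk summaries.
#' @param risk_data Optional table (e.g. the screening-eligible subset)
#'   on which predicted-risk summaries are computed; defaults to `data`.
#' @return A tibble with one row per scenario, mirroring the usual
#'   model-comparison table layout.
#' @export
performance_report <- function(data, fits, null_fit, horizons = c(2, 6),
                               risk_data = NULL) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  if (is.null(risk_data)) risk_data <- data
  ref <- fits[[1]]
  rows <- purrr::imap(fits, function(fit, nm) {
    chi2 <- lr_test(null_fit, fit)
    score <- predict_risk(fit, data, t = 6)
    cc <- harrell_c(tibble::tibble(time = data$time, event = data$event,
                                   score = score))
    p_ref <- if (identical(fit, ref)) NA_real_ else lr_test(ref, fit)$p.value
    chi2_ref <- lr_test(null_fit, ref)$chi2
    chi2_val <- chi2$chi2
    fni <- if (identical(fit, ref)) NA_real_ else
      fraction_new_information(chi2_ref, chi2_val)
    shrink <- shrinkage_factor(chi2_val, fit$df_model)
    out <- tibble::tibble(
      scenario = nm,
      c_index = cc$c_index, c_conf_low = cc$conf_low,
      c_conf_high = cc$conf_high,
      df = fit$df_model, chi2 = chi2_val, p_vs_reference = p_ref,
      fni = fni, shrinkage = shrink
    )
    for (h in horizons) {
      r <- predict_risk(fit, risk_data, t = h)
      rs <- risk_summary(r)
      out[[paste0("risk", h, "y_median_pct")]] <- rs$median_pct
      out[[paste0("risk", h, "y_q25_pct")]] <- rs$q25_pct
      out[[paste0("risk", h, "y_q75_pct")]] <- rs$q75_pct
    }
    out
  })
  dplyr::bind_rows(rows)
}
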
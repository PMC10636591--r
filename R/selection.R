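# Information-criterion selection of functional forms and interaction
# terms, and the four screening-scenario model specifications.
#
# The search is deliberately simple and deterministic: each continuous
# variable's transform is chosen by refitting the base model with the
# candidate transforms (all other continuous variables held at their
# current form) and keeping the candidate with the lowest criterion;
# interactions are then selected by forward steps over the partners in
# the fixed order sex, age, smoking status, timescale, keeping a
# partner only if it lowers the criterion.

#' Selection configuration
#'
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @param bic_n `"events"` (default) or `"rows"`: the effective sample
#'   size in the BIC penalty `log(n) * k`.  With rare events the number
#'   of events is the conventional choice.
#' @param candidate_transforms Transforms tried for continuous
#'   variables; any of `"linear"`, `"log"`, `"rcs2"`, `"rcs3"`.
#' @param candidate_partners Interaction partners tried, in order; any
#'   of `"sex"`, `"age"`, `"smoking_status"`, `"timescale"`.
#' @param tvc_df Degrees of freedom of the log-time sub-basis used when
#'   a timescale (non-proportional hazards) interaction is selected.
#' @param sample_mode `"full"` (default) or `"split"`: with `"split"`,
#'   selection uses a random half (fraction `split_fraction`) and the
#'   reported fit should use the held-out half.
#' @param split_fraction,seed Split fraction in (0, 1) and seed for the
#'   split draw.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(criterion = c("AIC", "BIC"),
                             bic_n = c("events", "rows"),
                             candidate_transforms = c("linear", "log",
                                                      "rcs2", "rcs3"),
                             candidate_partners = c("sex", "age",
                                                    "smoking_status",
                                                    "timescale"),
                             tvc_df = 2, sample_mode = c("full", "split"),
                             split_fraction = 0.5, seed = 1) {
  criterion <- match.arg(criterion)
  bic_n <- match.arg(bic_n)
  sample_mode <- match.arg(sample_mode)
  if (sample_mode == "split" &&
      (split_fraction <= 0 || split_fraction >= 1)) {
    stop("split_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(criterion = criterion, bic_n = bic_n,
                 candidate_transforms = candidate_transforms,
                 candidate_partners = candidate_partners,
                 tvc_df = tvc_df, sample_mode = sample_mode,
                 split_fraction = split_fraction, seed = seed),
            class = "selection_config")
}

criterion_value <- function(fit, config) {
  k <- length(fit$coefficients)
  if (config$criterion == "AIC") {
    -2 * fit$loglik + 2 * k
  } else {
    n_eff <- if (config$bic_n == "events") fit$n_events else fit$n_used
    -2 * fit$loglik + log(n_eff) * k
  }
}

#' Split rows into selection and estimation halves
#'
#' @param data Analysis table.
#' @param config A [selection_config()] with `sample_mode = "split"`.
#' @return List with `selection` and `estimation` tibbles; no row
#'   appears in both.
#' @export
selection_split <- function(data, config) {
  set.seed(config$seed)
  n <- nrow(data)
  idx <- sample.int(n, size = floor(config$split_fraction * n))
  list(selection = data[idx, , drop = FALSE],
       estimation = data[-idx, , drop = FALSE])
}

candidate_term <- function(variable, transform, base_term = NULL) {
  by <- if (is.null(base_term)) character() else base_term$by
  tvc <- if (is.null(base_term)) 0 else base_term$tvc_df
  switch(transform,
    linear = rp_term(variable, "linear", by = by, tvc_df = tvc),
    log = rp_term(variable, "log", by = by, tvc_df = tvc),
    rcs2 = rp_term(variable, "rcs", rcs_df = 2, by = by, tvc_df = tvc),
    rcs3 = rp_term(variable, "rcs", rcs_df = 3, by = by, tvc_df = tvc),
    stop("unknown candidate transform: ", transform, call. = FALSE)
  )
}

fit_quietly <- function(data, spec) {
  warned <- FALSE
  fit <- withCallingHandlers(
    tryCatch(rp_fit(data, spec, compute_vcov = FALSE),
             error = function(e) NULL),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (!is.null(fit) && (!fit$converged)) fit <- NULL
  if (is.null(fit) && warned) {
    warning("candidate fit failed to converge and was excluded", call. = FALSE)
  }
  fit
}

#' Select the functional form of a continuous variable
#'
#' Refits the model once per candidate transform and keeps the one with
#' the lowest information criterion; exact ties go to the candidate
#' with fewer parameters.  Non-converged candidates are excluded with a
#' warning.
#'
#' @param data Complete-case analysis table.
#' @param base_spec An [rp_spec()] containing all other terms (and
#'   possibly a current term for `variable`, whose interactions are
#'   retained across candidates).
#' @param variable Continuous variable whose transform is chosen.
#' @param config A [selection_config()].
#' @return List with `transform` (the winning candidate label), `term`
#'   (the winning [rp_term()]), `spec` (the updated spec) and `trace`
#'   (a tibble with one row per candidate: df, loglik, criterion,
#'   selected flag).
#' @export
select_transform <- function(data, base_spec, variable, config = selection_config()) {
  if (!is.numeric(data[[variable]])) {
    stop("'", variable, "' is not continuous", call. = FALSE)
  }
  base_term <- base_spec$terms[[variable]]
  rows <- list()
  best <- NULL
  for (cand in config$candidate_transforms) {
    tm <- candidate_term(variable, cand, base_term)
    spec_c <- spec_update(base_spec, tm)
    fit <- fit_quietly(data, spec_c)
    if (is.null(fit)) next
    val <- criterion_value(fit, config)
    k <- length(fit$coefficients)
    rows[[cand]] <- tibble::tibble(variable = variable, candidate = cand,
                                   df = k, loglik = fit$loglik,
                                   criterion = val, selected = FALSE)
    if (is.null(best) || val < best$val - 1e-9 ||
        (abs(val - best$val) <= 1e-9 && k < best$k)) {
      best <- list(cand = cand, val = val, k = k, term = tm, spec = spec_c)
    }
  }
  if (is.null(best)) {
    stop("no candidate transform converged for '", variable, "'",
         call. = FALSE)
  }
  trace <- dplyr::bind_rows(rows)
  trace$selected <- trace$candidate == best$cand
  list(transform = best$cand, term = best$term, spec = best$spec,
       trace = trace)
}

#' Forward selection of interaction partners
#'
#' Starting from a spec containing the variable's main effect, tries
#' the partners in the configured fixed order (sex, age, smoking
#' status, timescale); a partner is kept iff adding it lowers the
#' criterion.  The timescale partner is a time-dependent effect with a
#' `config$tvc_df`-df log-time sub-basis.
#'
#' @inheritParams select_transform
#' @param spec An [rp_spec()] already containing `variable`'s main
#'   effect.
#' @return List with `partners` (character vector kept), `spec`
#'   (updated) and `trace` (one row per candidate partner).
#' @export
select_interactions <- function(data, spec, variable, config = selection_config()) {
  if (is.null(spec$terms[[variable]])) {
    stop("spec must already contain a main effect for '", variable, "'",
         call. = FALSE)
  }
  current <- spec
  cur_fit <- fit_quietly(data, current)
  if (is.null(cur_fit)) stop("base model did not converge", call. = FALSE)
  cur_val <- criterion_value(cur_fit, config)
  kept <- character()
  rows <- list()
  for (p in config$candidate_partners) {
    tm <- current$terms[[variable]]
    tm2 <- if (p == "timescale") {
      rp_term(variable, tm$transform, rcs_df = tm$rcs_df,
              log_first = tm$log_first, by = tm$by, tvc_df = config$tvc_df)
    } else {
      rp_term(variable, tm$transform, rcs_df = tm$rcs_df,
              log_first = tm$log_first, by = union(tm$by, p),
              tvc_df = tm$tvc_df)
    }
    cand_spec <- spec_update(current, tm2)
    fit <- fit_quietly(data, cand_spec)
    if (is.null(fit)) next
    val <- criterion_value(fit, config)
    keep <- val < cur_val - 1e-9
    rows[[p]] <- tibble::tibble(variable = variable, candidate = p,
                                df = length(fit$coefficients),
                                loglik = fit$loglik, criterion = val,
                                selected = keep)
    if (keep) {
      current <- cand_spec
      cur_val <- val
      kept <- c(kept, p)
    }
  }
  list(partners = kept, spec = current, trace = dplyr::bind_rows(rows))
}

# ---- scenario specifications -------------------------------------------

#' Conventional risk-factor terms (reference scenario)
#'
#' Age, sex, ethnicity, smoking status, pack-years, family history of
#' lung cancer, social deprivation and the respiratory/cancer history
#' flags: the variables a conventional lung cancer risk tool collects
#' by questionnaire or telephone.
#'
#' @return List of [rp_term()] objects.
#' @export
conventional_terms <- function() {
  list(
    rp_term("age_entry", "linear"),
    rp_term("sex"),
    rp_term("ethnicity"),
    rp_term("smoking_status"),
    rp_term("pack_years", "linear"),
    rp_term("family_history_lung_cancer"),
    rp_term("townsend", "linear"),
    rp_term("history_cancer"),
    rp_term("asthma"),
    rp_term("allergy"),
    rp_term("tuberculosis"),
    rp_term("pneumonia"),
    rp_term("emphysema"),
    rp_term("asbestos_exposure")
  )
}

#' Default expansion terms: spirometry, alcohol, waist
#'
#' FEV1 enters linearly with a 3-df restricted cubic spline; alcohol
#' status as a categorical; waist circumference log-transformed.
#'
#' @return List of [rp_term()] objects.
#' @export
spirometry_terms <- function() {
  list(
    rp_term("fev1", "rcs", rcs_df = 3),
    rp_term("alcohol_status"),
    rp_term("waist", "log")
  )
}

#' Default expansion terms: liver blood tests and urate
#'
#' The default functional forms and interactions for the blood panel:
#' all measurements log-transformed; bilirubin with a sex interaction
#' and a 2-df time-dependent effect; AST with a 2-df spline on the log
#' scale, a sex interaction and a 2-df time-dependent effect; ALP with
#' sex and age interactions and a 2-df time-dependent effect; ALT with
#' sex and smoking interactions; GGT with a sex interaction; urate with
#' sex and smoking-status interactions.
#'
#' @return List of [rp_term()] objects.
#' @export
blood_terms <- function() {
  list(
    rp_term("bilirubin", "log", by = "sex", tvc_df = 2),
    rp_term("albumin", "log"),
    rp_term("ast", "rcs", rcs_df = 2, log_first = TRUE, by = "sex",
            tvc_df = 2),
    rp_term("alp", "log", by = c("sex", "age"), tvc_df = 2),
    rp_term("alt", "log", by = c("sex", "smoking_status")),
    rp_term("ggt", "log", by = "sex"),
    rp_term("urate", "log", by = c("sex", "smoking_status"))
  )
}

#' Build the four screening-scenario model specifications
#'
#' Scenario 1 contains the conventional predictors only; Scenario 2
#' adds spirometry (FEV1), alcohol status and waist circumference;
#' Scenario 3 adds the liver blood tests and urate; Scenario 4 contains
#' everything.  The scenarios are nested by construction.
#'
#' @param baseline_df Baseline log-time spline df shared by all four.
#' @param conventional,spirometry,blood Term lists, overridable with
#'   selection results (see [select_transform()] /
#'   [select_interactions()]).
#' @return Named list of four [rp_spec()] objects
#'   (`scenario1` ... `scenario4`).
#' @export
scenario_specs <- function(baseline_df = 3,
                           conventional = conventional_terms(),
                           spirometry = spirometry_terms(),
                           blood = blood_terms()) {
  list(
    scenario1 = rp_spec(conventional, baseline_df = baseline_df),
    scenario2 = rp_spec(c(conventional, spirometry),
                        baseline_df = baseline_df),
    scenario3 = rp_spec(c(conventional, blood), baseline_df = baseline_df),
    scenario4 = rp_spec(c(conventional, spirometry, blood),
                        baseline_df = baseline_df)
  )
}

#' Variables required by a model specification
#'
#' @param spec An [rp_spec()] (or list of them).
#' @return Character vector of cohort columns the spec needs, including
#'   interaction partners and `time`/`event`.
#' @export
spec_variables <- function(spec) {
  specs <- if (inherits(spec, "rp_spec")) list(spec) else spec
  out <- c("time", "event")
  for (s in specs) {
    for (tm in s$terms) {
      out <- c(out, tm$variable,
               if ("age" %in% tm$by) "age_entry",
               if ("sex" %in% tm$by) "sex",
               if ("smoking_status" %in% tm$by) "smoking_status")
    }
  }
  unique(out)
}
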
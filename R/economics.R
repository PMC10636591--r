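# Health-economic model of targeted LDCT lung cancer screening: cost
# per lung cancer case detected after a single screen, under scenarios
# that differ in the follow-up tests (spirometry and/or blood panel)
# used to re-calculate risk before referral.
#
# Cost structure per scenario:
#   contact   = n_contacted x cost of a telephone risk assessment
#   follow-up = n above the reference-model threshold x per-patient
#               cost of the scenario's follow-up tests
#   LDCT      = n referred (above threshold under the scenario's own
#               model) x cost of one scan
# Expected detections at first screen = detect_fraction x cases among
# referred; the cost-per-case denominator uses the UNROUNDED expected
# detections, while the reported case count is rounded.

#' Economic parameters for the screening model
#'
#' Defaults are 2022 UK unit costs: telephone risk assessment 20.57,
#' LDCT scan (one body region) 92.77, spirometry appointment 63.42,
#' blood panel 7.16, both tests 70.58 (their sum), all GBP; 20% of
#' cases detected at the first screen; referral threshold 1.51%
#' predicted 6-year risk; eligibility ever-smokers aged 55-74.
#'
#' @param cost_phone,cost_ldct,cost_spiro_visit,cost_blood,cost_both
#'   Unit costs in GBP.
#' @param detect_fraction Fraction of prevalent cases detected by a
#'   single LDCT screen, in (0, 1].
#' @param risk_threshold Referral threshold on predicted risk.
#' @param horizon Risk horizon in years.
#' @param age_range Inclusive eligibility bounds on age in whole years.
#' @return A list of class `econ_params`.
#' @export
econ_params <- function(cost_phone = 20.57, cost_ldct = 92.77,
                        cost_spiro_visit = 63.42, cost_blood = 7.16,
                        cost_both = cost_spiro_visit + cost_blood,
                        detect_fraction = 0.20, risk_threshold = 0.0151,
                        horizon = 6, age_range = c(55, 74)) {
  costs <- c(cost_phone, cost_ldct, cost_spiro_visit, cost_blood, cost_both)
  if (any(costs < 0)) stop("costs must be non-negative", call. = FALSE)
  if (detect_fraction <= 0 || detect_fraction > 1) {
    stop("detect_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (risk_threshold <= 0 || risk_threshold >= 1) {
    stop("risk_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(cost_phone = cost_phone, cost_ldct = cost_ldct,
                 cost_spiro_visit = cost_spiro_visit,
                 cost_blood = cost_blood, cost_both = cost_both,
                 detect_fraction = detect_fraction,
                 risk_threshold = risk_threshold, horizon = horizon,
                 age_range = age_range),
            class = "econ_params")
}

#' Screening-eligible subset
#'
#' Ever smokers (former or current) aged within the inclusive age
#' bounds, with age taken in whole years (floored) at contact.
#'
#' @param data Cohort table with `age_entry` and `smoking_status`.
#' @param params An [econ_params()].
#' @return The eligible rows.
#' @export
eligible <- function(data, params = econ_params()) {
  age <- floor(data$age_entry)
  ok <- !is.na(data$smoking_status) &
    data$smoking_status %in% c("former", "current") &
    !is.na(age) & age >= params$age_range[1] & age <= params$age_range[2]
  data[ok, , drop = FALSE]
}

check_scenario_inputs <- function(inputs) {
  need <- c("n_contacted", "followup_cost_per_patient", "n_followup",
            "n_referred", "n_cases")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) {
    stop("scenario inputs missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  with(inputs, {
    if (any(n_referred > n_followup) || any(n_followup > n_contacted)) {
      stop("expected n_referred <= n_followup <= n_contacted", call. = FALSE)
    }
    if (any(n_cases > n_referred)) {
      stop("expected n_cases <= n_referred", call. = FALSE)
    }
  })
  invisible(inputs)
}

#' Run the economic model for one or more scenarios
#'
#' @param inputs Data frame with one row per scenario: `n_contacted`,
#'   `followup_cost_per_patient` (0 when no follow-up tests are used),
#'   `n_followup` (participants above the reference-model threshold,
#'   who receive the follow-up tests), `n_referred` (above threshold
#'   under the scenario's own model), `n_cases` (referred participants
#'   diagnosed within the horizon).  An optional `scenario` column is
#'   carried through.
#' @param params An [econ_params()].
#' @return A tibble with, per scenario: the three cost components,
#'   unrounded and rounded expected detections, percentage of screens
#'   finding a case, and `cost_per_case` in GBP rounded to the pound.
#'   Scenarios with zero cases get `NA` cost per case with a warning
#'   (never infinity).
#' @export
run_scenario <- function(inputs, params = econ_params()) {
  inputs <- tibble::as_tibble(inputs)
  check_scenario_inputs(inputs)
  out <- dplyr::mutate(inputs,
    cost_contact_total = .data$n_contacted * params$cost_phone,
    cost_followup_total = .data$n_followup * .data$followup_cost_per_patient,
    cost_ldct_total = .data$n_referred * params$cost_ldct,
    cost_total = .data$cost_contact_total + .data$cost_followup_total +
      .data$cost_ldct_total,
    cases_detected_unrounded = params$detect_fraction * .data$n_cases,
    cases_detected = round(.data$cases_detected_unrounded),
    pct_referred_with_cancer = round(100 * .data$n_cases / .data$n_referred, 1),
    pct_screens_detecting = round(100 * .data$cases_detected_unrounded /
                                    .data$n_referred, 2),
    cost_per_case = ifelse(.data$cases_detected_unrounded > 0,
                           round(.data$cost_total /
                                   .data$cases_detected_unrounded),
                           NA_real_)
  )
  if (any(out$cases_detected_unrounded == 0)) {
    warning("scenario with zero detected cases: cost per case undefined",
            call. = FALSE)
  }
  out
}

#' Scenario inputs from predicted risks
#'
#' Translates per-participant predicted risks into the counts the
#' economic model consumes.  Everyone in the (already
#' eligibility-filtered) table is contacted; those whose
#' reference-model risk meets the threshold receive the scenario's
#' follow-up tests; those ALSO meeting the threshold under the
#' scenario's own model are referred for LDCT; referred participants
#' whose diagnosis falls within the horizon are the detectable cases.
#'
#' @param data Eligible subset with `time` and `event`.
#' @param risks_base Predicted risks under the reference model.
#' @param risks_scenario Predicted risks under the scenario model
#'   (equal to `risks_base` for the reference scenario itself).
#' @param followup_cost_per_patient Per-patient cost of the scenario's
#'   follow-up tests (0 for the reference scenario).
#' @param params An [econ_params()].
#' @param scenario Optional scenario label.
#' @return A one-row tibble of scenario inputs for [run_scenario()].
#' @export
scenario_inputs_from_risks <- function(data, risks_base, risks_scenario,
                                       followup_cost_per_patient,
                                       params = econ_params(),
                                       scenario = NULL) {
  n <- nrow(data)
  if (length(risks_base) != n || length(risks_scenario) != n) {
    stop("risk vectors must have one value per row of data", call. = FALSE)
  }
  above_base <- risks_base >= params$risk_threshold
  referred <- above_base & (risks_scenario >= params$risk_threshold)
  cases <- referred & data$event == 1 & data$time <= params$horizon
  tibble::tibble(
    scenario = scenario %||% NA_character_,
    n_contacted = n,
    followup_cost_per_patient = followup_cost_per_patient,
    n_followup = sum(above_base),
    n_referred = sum(referred),
    n_cases = sum(cases)
  )
}

#' Referral-threshold sensitivity analysis
#'
#' Re-runs the economic model over a grid of referral thresholds.
#' Referral counts are monotone non-increasing in the threshold.
#'
#' @inheritParams scenario_inputs_from_risks
#' @param thresholds Numeric vector of risk thresholds.
#' @return A tibble with one row per threshold.
#' @export
threshold_sensitivity <- function(data, risks_base, risks_scenario,
                                  followup_cost_per_patient,
                                  params = econ_params(),
                                  thresholds = c(0.0151, 0.02, 0.025)) {
  if (!length(thresholds)) stop("no thresholds supplied", call. = FALSE)
  purrr::map_dfr(thresholds, function(thr) {
    p <- params
    p$risk_threshold <- thr
    inp <- scenario_inputs_from_risks(data, risks_base, risks_scenario,
                                      followup_cost_per_patient, p)
    res <- suppressWarnings(run_scenario(inp, p))
    dplyr::bind_cols(tibble::tibble(threshold = thr),
                     res[setdiff(names(res), "scenario")])
  })
}

#' Per-subgroup screening costs
#'
#' Applies the economic model within each level of a grouping variable
#' (e.g. deprivation quintile); telephone-contact costs are allocated
#' to each group by its own size.  Empty groups are skipped with a
#' warning.
#'
#' @inheritParams scenario_inputs_from_risks
#' @param group Vector (one value per row of `data`) defining the
#'   subgroups.
#' @return A tibble with one row per group.
#' @export
subgroup_costs <- function(data, risks_base, risks_scenario,
                           followup_cost_per_patient, group,
                           params = econ_params()) {
  if (length(group) != nrow(data)) {
    stop("group must have one value per row of data", call. = FALSE)
  }
  levels <- sort(unique(group[!is.na(group)]))
  purrr::map_dfr(levels, function(g) {
    idx <- !is.na(group) & group == g
    if (!sum(idx)) {
      warning("empty subgroup '", g, "' skipped", call. = FALSE)
      return(NULL)
    }
    inp <- scenario_inputs_from_risks(data[idx, , drop = FALSE],
                                      risks_base[idx], risks_scenario[idx],
                                      followup_cost_per_patient, params)
    res <- suppressWarnings(run_scenario(inp, params))
    dplyr::bind_cols(tibble::tibble(group = g),
                     res[setdiff(names(res), "scenario")])
  })
}

#' Incidental findings from follow-up tests
#'
#' Among a screened subset: the proportion with an AST/ALT ratio above
#' 2 (suggesting alcohol-related liver damage) and the proportion with
#' FEV1/FVC below 0.7 (suggesting airway obstruction) among
#' participants without a lung disease diagnosis (emphysema, asthma,
#' tuberculosis or pneumonia) at entry.  Rows with zero or missing
#' denominators are excluded and counted.
#'
#' @param data Table with `ast`, `alt`, `fev1`, `fvc` and the lung
#'   disease history flags.
#' @return A one-row tibble with the two proportions (as percentages)
#'   and the numbers excluded.
#' @export
incidental_findings <- function(data) {
  ratio_ok <- !is.na(data$ast) & !is.na(data$alt) & data$alt > 0
  ast_alt_flag <- data$ast[ratio_ok] / data$alt[ratio_ok] > 2
  no_lung_disease <- !(data$emphysema | data$asthma | data$tuberculosis |
                         data$pneumonia)
  spiro_ok <- no_lung_disease & !is.na(data$fev1) & !is.na(data$fvc) &
    data$fvc > 0
  obstruction_flag <- data$fev1[spiro_ok] / data$fvc[spiro_ok] < 0.7
  tibble::tibble(
    pct_ast_alt_over_2 = 100 * mean(ast_alt_flag),
    n_ratio_evaluable = sum(ratio_ok),
    n_ratio_excluded = nrow(data) - sum(ratio_ok),
    pct_fev1_fvc_under_0.7 = 100 * mean(obstruction_flag),
    n_spiro_evaluable = sum(spiro_ok),
    n_spiro_excluded = sum(no_lung_disease, na.rm = TRUE) - sum(spiro_ok)
  )
}

#' Reference screening scenario inputs
#'
#' The published counts and per-patient follow-up costs for the four
#' screening scenarios applied to 106,738 ever-smoking UK cohort
#' participants aged 55-74, shipped as a plain-text fixture so the
#' economic model can be replayed without any cohort data.
#'
#' @return A tibble of scenario inputs for [run_scenario()].
#' @export
reference_scenarios <- function() {
  path <- system.file("extdata", "uk_screening_scenarios.csv",
                      package = "lungrisk", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Replay the reference screening analysis
#'
#' Runs the economic model on the shipped reference scenario inputs and
#' adds the incremental cost per case detected relative to the first
#' (conventional-model) scenario.
#'
#' @param params An [econ_params()].
#' @return The [run_scenario()] tibble plus `incremental_cost_per_case`.
#' @export
replay_reference_scenarios <- function(params = econ_params()) {
  res <- run_scenario(reference_scenarios(), params)
  dplyr::mutate(res, incremental_cost_per_case =
                  .data$cost_per_case - .data$cost_per_case[1])
}
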
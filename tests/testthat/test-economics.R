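# Screening health-economics: cost structure, thresholds, subgroups,
# incidental findings, and the published-inputs replay.

test_that("default economic parameters are internally consistent", {
  p <- econ_params()
  expect_equal(p$cost_both, p$cost_spiro_visit + p$cost_blood)
  expect_error(econ_params(cost_ldct = -1), "non-negative")
  expect_error(econ_params(detect_fraction = 0), "detect_fraction")
  expect_error(econ_params(risk_threshold = 1.2), "risk_threshold")
})

test_that("replaying the published scenario inputs reproduces the costs", {
  res <- replay_reference_scenarios()
  expect_equal(res$cost_per_case, c(25926, 34993, 26944, 35701))
  expect_equal(res$incremental_cost_per_case, c(0, 9067, 1018, 9775))
  expect_equal(res$cases_detected, c(164, 153, 151, 151))
})

test_that("cost decomposition is exact", {
  res <- run_scenario(reference_scenarios())
  expect_equal(res$cost_total,
               res$cost_contact_total + res$cost_followup_total +
                 res$cost_ldct_total)
  expect_equal(res$cost_contact_total, res$n_contacted * 20.57)
  expect_equal(res$cost_ldct_total, res$n_referred * 92.77)
  expect_equal(res$cost_followup_total,
               res$n_followup * res$followup_cost_per_patient)
})

test_that("cost per case scales exactly inversely with the detection fraction", {
  inp <- reference_scenarios()
  r1 <- run_scenario(inp, econ_params(detect_fraction = 0.2))
  r2 <- run_scenario(inp, econ_params(detect_fraction = 0.4))
  expect_equal(r1$cost_total / (0.2 * r1$n_cases) * 0.2 / 0.4,
               r2$cost_total / (0.4 * r2$n_cases))
  expect_equal(round(r1$cost_total / (0.2 * r1$n_cases) / 2),
               r2$cost_per_case)
})

test_that("degenerate cost inputs behave per the stated conventions", {
  inp <- tibble::tibble(n_contacted = 10, followup_cost_per_patient = 0,
                        n_followup = 10, n_referred = 10, n_cases = 10)
  res <- run_scenario(inp, econ_params(cost_phone = 0, cost_ldct = 1,
                                       detect_fraction = 1))
  expect_equal(res$cost_per_case, 1)
  # zero cases: explicit NA with warning, never infinity
  inp0 <- dplyr::mutate(inp, n_cases = 0)
  expect_warning(res0 <- run_scenario(inp0), "zero detected")
  expect_true(is.na(res0$cost_per_case))
  # invariant violations are rejected
  bad <- dplyr::mutate(inp, n_referred = 11)
  expect_error(run_scenario(bad), "n_referred")
})

test_that("eligibility applies inclusive whole-year age bounds to ever smokers", {
  d <- tibble::tibble(
    age_entry = c(60, 55, 54.9, 74.9, 75, 60),
    smoking_status = c("never", "former", "current", "current", "former",
                       "current")
  )
  el <- eligible(d)
  expect_equal(nrow(el), 3)
  expect_true(all(el$smoking_status %in% c("former", "current")))
  expect_false(54.9 %in% el$age_entry)  # floors to 54
  expect_true(74.9 %in% el$age_entry)   # floors to 74
})

test_that("scenario inputs from risks equal a brute-force filter", {
  set.seed(12)
  n <- 500
  d <- tibble::tibble(time = stats::runif(n, 0.5, 9),
                      event = stats::rbinom(n, 1, 0.3))
  rb <- stats::runif(n, 0, 0.05)
  rs <- rb * stats::runif(n, 0.5, 1.5)
  p <- econ_params()
  inp <- scenario_inputs_from_risks(d, rb, rs, 7.16, p, scenario = "alt")
  thr <- p$risk_threshold
  expect_equal(inp$n_followup, sum(rb >= thr))
  expect_equal(inp$n_referred, sum(rb >= thr & rs >= thr))
  expect_equal(inp$n_cases,
               sum(rb >= thr & rs >= thr & d$event == 1 & d$time <= 6))
  expect_lte(inp$n_referred, inp$n_followup)
  # same risks under both models: everyone followed up is referred
  same <- scenario_inputs_from_risks(d, rb, rb, 0, p)
  expect_equal(same$n_referred, same$n_followup)
  expect_error(scenario_inputs_from_risks(d, rb[-1], rs, 0, p), "one value")
})

test_that("referrals are monotone non-increasing in the threshold", {
  set.seed(21)
  n <- 400
  d <- tibble::tibble(time = stats::runif(n, 0.5, 9),
                      event = stats::rbinom(n, 1, 0.4))
  r <- stats::runif(n, 0, 0.06)
  sens <- threshold_sensitivity(d, r, r, 0, econ_params(),
                                thresholds = c(0.0151, 0.02, 0.025, 0.04))
  expect_true(all(diff(sens$n_referred) <= 0))
  # threshold ~0 refers everyone; threshold ~1 nobody
  all_in <- threshold_sensitivity(d, r, r, 0, econ_params(),
                                  thresholds = 1e-12)
  expect_equal(all_in$n_referred, n)
  none <- suppressWarnings(threshold_sensitivity(d, r, r, 0, econ_params(),
                                                 thresholds = 0.999))
  expect_equal(none$n_referred, 0)
  expect_error(threshold_sensitivity(d, r, r, 0, econ_params(),
                                     thresholds = numeric(0)), "threshold")
})

test_that("subgroup costs respond to the subgroup event rate", {
  set.seed(30)
  n <- 2000
  g <- rep(c("low", "high"), each = n / 2)
  event <- c(stats::rbinom(n / 2, 1, 0.1), stats::rbinom(n / 2, 1, 0.2))
  d <- tibble::tibble(time = stats::runif(n, 0.5, 5.9), event = event)
  r <- rep(0.02, n)  # everyone above threshold
  res <- subgroup_costs(d, r, r, 0, g, econ_params())
  expect_equal(nrow(res), 2)
  hi <- res$cost_per_case[res$group == "high"]
  lo <- res$cost_per_case[res$group == "low"]
  # roughly double the event rate -> roughly half the cost per case
  expect_lt(hi / lo, 0.75)
  # two identical groups give identical costs
  d2 <- d[1:1000, ]
  res2 <- subgroup_costs(dplyr::bind_rows(d2, d2), rep(0.02, 2000),
                         rep(0.02, 2000), 0,
                         rep(c("a", "b"), each = 1000), econ_params())
  expect_equal(res2$cost_per_case[1], res2$cost_per_case[2])
})

test_that("incidental findings flag the stated ratio rules", {
  base <- tibble::tibble(
    ast = 30, alt = 30, fev1 = 3, fvc = 3.8,
    emphysema = FALSE, asthma = FALSE, tuberculosis = FALSE,
    pneumonia = FALSE
  )
  d <- base[rep(1, 200), ]
  d$ast[1:9] <- 60; d$alt[1:9] <- 25        # ratio 2.4 -> flagged
  out <- incidental_findings(d)
  expect_equal(out$pct_ast_alt_over_2, 4.5)
  d2 <- base[rep(1, 10), ]
  d2$fev1[1] <- 2.0; d2$fvc[1] <- 3.2       # ratio 0.625 -> flagged
  d2$asthma[2] <- TRUE                      # excluded from denominator
  out2 <- incidental_findings(d2)
  expect_equal(out2$n_spiro_evaluable, 9)
  expect_equal(out2$pct_fev1_fvc_under_0.7, 100 / 9, tolerance = 1e-10)
  # zero-denominator rows are excluded and counted
  d3 <- base[rep(1, 5), ]
  d3$alt[1] <- 0
  out3 <- incidental_findings(d3)
  expect_equal(out3$n_ratio_excluded, 1)
})
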
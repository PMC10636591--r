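# Concordance, fraction of new information, shrinkage, risk summaries.

test_that("perfectly ranking scores give c = 1 and constant scores 0.5", {
  d <- tibble::tibble(time = c(1, 2, 3, 4, 5), event = 1L,
                      score = c(5, 4, 3, 2, 1))
  expect_equal(harrell_c(d)$c_index, 1)
  d$score <- 2
  expect_equal(harrell_c(d)$c_index, 0.5)
})

test_that("implementation equals the exhaustive pair oracle, ties included", {
  for (s in 1:6) {
    d <- make_toy_surv(n = 40, seed = s, tie_prob = 0.5)
    got <- harrell_c(d, se_method = "none")$c_index
    expect_equal(got, c_index_oracle(d$time, d$event, d$score),
                 info = paste("seed", s))
  }
})

test_that("c-index is invariant to increasing transforms and flips on negation", {
  d <- make_toy_surv(n = 60, seed = 10, tie_prob = 0)
  d$score <- d$score + stats::runif(60, 0, 1e-4)  # break score ties
  c0 <- harrell_c(d, se_method = "none")$c_index
  d2 <- d; d2$score <- exp(d$score)
  expect_equal(harrell_c(d2, se_method = "none")$c_index, c0)
  d3 <- d; d3$score <- -d$score
  expect_equal(harrell_c(d3, se_method = "none")$c_index, 1 - c0)
})

test_that("c-index agrees with survival::concordance on tie-free data", {
  skip_if_not_installed("survival")
  set.seed(3)
  n <- 300
  d <- tibble::tibble(time = stats::rexp(n, 0.2) + stats::runif(n, 0, 1e-6),
                      event = stats::rbinom(n, 1, 0.5),
                      score = stats::rnorm(n))
  ref <- survival::concordance(survival::Surv(time, event) ~ score,
                               data = d, reverse = TRUE)
  expect_equal(harrell_c(d, se_method = "none")$c_index,
               as.numeric(ref$concordance), tolerance = 1e-12)
})

test_that("jackknife and bootstrap standard errors are coherent", {
  set.seed(8)
  n <- 150
  d <- tibble::tibble(time = stats::rexp(n, 0.2),
                      event = stats::rbinom(n, 1, 0.6),
                      score = stats::rnorm(n))
  jk <- harrell_c(d)
  expect_true(jk$se > 0 && jk$conf_low < jk$c_index &&
                jk$c_index < jk$conf_high)
  bs <- harrell_c(d, se_method = "bootstrap", n_boot = 100, seed = 2)
  expect_lt(abs(jk$se - bs$se) / jk$se, 0.6)
})

test_that("error paths: no comparable pairs, non-finite scores", {
  d <- tibble::tibble(time = c(1, 2), event = c(0L, 0L), score = c(1, 2))
  expect_error(harrell_c(d), "comparable")
  d2 <- tibble::tibble(time = 1:2, event = c(1L, 1L), score = c(NaN, 1))
  expect_error(harrell_c(d2), "finite")
})

test_that("fraction of new information reproduces the published values", {
  expect_equal(round(fraction_new_information(3613, 3781), 2), 0.04)
  expect_equal(round(fraction_new_information(3613, 3830), 2), 0.06)
  expect_equal(round(fraction_new_information(3613, 3966), 2), 0.09)
  expect_equal(fraction_new_information(1234, 1234), 0)
  expect_error(fraction_new_information(-1, 10), "positive")
  # monotone increasing in the expanded model's chi-square
  f <- fraction_new_information(100, c(110, 150, 400))
  expect_true(all(diff(f) > 0))
})

test_that("shrinkage factor reproduces the published values", {
  expect_equal(round(shrinkage_factor(3613, 24), 2), 0.99)
  expect_equal(round(shrinkage_factor(3830, 70), 2), 0.98)
  expect_equal(shrinkage_factor(100, 100), 0)
  expect_error(shrinkage_factor(0, 5), "positive")
})

test_that("risk summaries match a direct sort-based quantile computation", {
  expect_equal(risk_summary(c(0.001, 0.005, 0.013))$median_pct, 0.5)
  expect_equal(with(risk_summary(rep(0.02, 10)), q75_pct - q25_pct), 0)
  set.seed(5)
  r <- stats::rbeta(10000, 1, 60)
  r <- pmin(pmax(r, 1e-8), 1 - 1e-8)
  rs <- risk_summary(r, digits = 6)
  # independent interpolated quantile from the sorted sample
  manual_q <- function(p) {
    s <- sort(r); h <- (length(s) - 1) * p + 1
    lo <- floor(h); s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  }
  expect_equal(rs$median_pct, round(100 * manual_q(0.5), 6))
  expect_equal(rs$q25_pct, round(100 * manual_q(0.25), 6))
  expect_error(risk_summary(numeric(0)), "no risks")
  expect_error(risk_summary(c(0.2, 1)), "strictly")
})

test_that("performance report orders nested scenarios coherently", {
  tm <- boosted_truth()
  coh <- generate_cohort(cohort_config(n = 10000, seed = 41,
                                       true_model = tm))
  small <- rp_spec(list(rp_term("age_entry", "linear"), rp_term("sex"),
                        rp_term("smoking_status")), baseline_df = 2)
  big <- spec_update(small, rp_term("bilirubin", "log", by = "sex"),
                     rp_term("urate", "log"), rp_term("fev1", "linear"))
  null_fit <- rp_fit(coh, rp_spec(list(), baseline_df = 2),
                     compute_vcov = FALSE)
  fits <- list(reference = rp_fit(coh, small, compute_vcov = FALSE),
               expanded = rp_fit(coh, big, compute_vcov = FALSE))
  rep <- performance_report(coh, fits, null_fit)
  expect_equal(rep$scenario, c("reference", "expanded"))
  # nesting: the expanded model cannot lose likelihood chi-square
  expect_gte(rep$chi2[2], rep$chi2[1])
  expect_true(is.na(rep$fni[1]))
  expect_gt(rep$fni[2], 0)
  expect_true(all(rep$shrinkage <= 1))
  expect_true(all(rep$c_index > 0.5))
  expect_true(all(c("risk2y_median_pct", "risk6y_median_pct") %in% names(rep)))
})
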
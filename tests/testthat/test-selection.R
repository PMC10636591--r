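# Information-criterion selection of functional forms and interactions.

# data whose hazard is log-linear in a skewed covariate
make_log_effect_data <- function(n, seed, beta = -1.2) {
  spec <- rp_spec(list(rp_term("bilirubin", "log")), baseline_df = 1)
  tm <- true_model(spec, c("(Intercept)" = -2.9, "time_s1" = 1,
                           "log_bilirubin" = beta))
  cfg <- cohort_config(n = n, seed = seed, true_model = tm)
  generate_cohort(cfg)
}

test_that("criterion arithmetic matches 2*dloglik vs penalty exactly", {
  dat <- make_log_effect_data(4000, seed = 2)
  res <- select_transform(dat, rp_spec(list(), baseline_df = 1), "bilirubin",
                          selection_config())
  tr <- res$trace
  expect_equal(tr$criterion, -2 * tr$loglik + 2 * tr$df)
  res_b <- select_transform(dat, rp_spec(list(), baseline_df = 1), "bilirubin",
                            selection_config(criterion = "BIC"))
  trb <- res_b$trace
  n_ev <- sum(dat$event)
  expect_equal(trb$criterion, -2 * trb$loglik + log(n_ev) * trb$df)
})

test_that("a log-linear effect is recognised as log at moderate n", {
  hits <- vapply(1:3, function(s) {
    dat <- make_log_effect_data(10000, seed = 200 + s)
    res <- select_transform(dat, rp_spec(list(), baseline_df = 1),
                            "bilirubin", selection_config())
    res$transform
  }, character(1))
  expect_gte(sum(hits == "log"), 2)
})

test_that("a U-shaped effect is recognised as a spline at large n", {
  # hazard quadratic in centred log bilirubin: neither linear nor log
  set.seed(55)
  n <- 12000
  b <- stats::rlnorm(n, log(8.1), 0.36)
  u <- (log(b) - log(8.1))^2
  tt <- stats::rexp(n, 0.02 * exp(1.5 * u))
  cens <- stats::runif(n, 5, 9)
  dat <- tibble::tibble(time = pmin(tt, cens),
                        event = as.integer(tt <= cens), bilirubin = b)
  res <- select_transform(dat, rp_spec(list(), baseline_df = 1),
                          "bilirubin", selection_config())
  expect_true(res$transform %in% c("rcs2", "rcs3"))
})

test_that("interaction selection keeps a true partner and respects BIC <= AIC", {
  spec <- rp_spec(list(rp_term("sex"), rp_term("bilirubin", "log")),
                  baseline_df = 1)
  tm <- true_model(spec, c("(Intercept)" = -3.4, "time_s1" = 1,
                           "sexmale" = 0.3, "log_bilirubin" = -0.3,
                           "log_bilirubin:sexmale" = -0.9),
                   tvc_knots = list())
  tm2 <- true_model(spec_update(spec, rp_term("bilirubin", "log", by = "sex")),
                    tm$coefficients)
  dat <- generate_cohort(cohort_config(n = 15000, seed = 77,
                                       true_model = tm2))
  base <- rp_spec(list(rp_term("sex"), rp_term("bilirubin", "log")),
                  baseline_df = 1)
  res_aic <- select_interactions(dat, base, "bilirubin", selection_config())
  expect_true("sex" %in% res_aic$partners)
  res_bic <- select_interactions(dat, base, "bilirubin",
                                 selection_config(criterion = "BIC"))
  # the BIC penalty dominates the AIC penalty, so BIC keeps a subset
  expect_true(all(res_bic$partners %in% res_aic$partners))
})

test_that("timescale partner adds a 2-df time-dependent block", {
  dat <- make_log_effect_data(6000, seed = 9)
  base <- rp_spec(list(rp_term("bilirubin", "log")), baseline_df = 2)
  res <- select_interactions(dat, base, "bilirubin",
                             selection_config(candidate_partners = "timescale"))
  tr <- res$trace
  expect_equal(nrow(tr), 1)
  # the candidate adds exactly tvc_df parameters
  base_fit <- rp_fit(dat, base, compute_vcov = FALSE)
  expect_equal(tr$df, length(base_fit$coefficients) + 2)
})

test_that("split-sample mode partitions rows without overlap", {
  dat <- make_log_effect_data(1000, seed = 4)
  dat$id <- seq_len(nrow(dat))
  halves <- selection_split(dat, selection_config(sample_mode = "split",
                                                  split_fraction = 0.5,
                                                  seed = 3))
  expect_equal(nrow(halves$selection) + nrow(halves$estimation), nrow(dat))
  expect_length(intersect(halves$selection$id, halves$estimation$id), 0)
})

test_that("scenario specs are nested and follow the default forms", {
  sp <- scenario_specs()
  v1 <- names(sp$scenario1$terms)
  v2 <- names(sp$scenario2$terms)
  v3 <- names(sp$scenario3$terms)
  v4 <- names(sp$scenario4$terms)
  expect_true(all(v1 %in% v2) && all(v1 %in% v3))
  expect_true(all(v2 %in% v4) && all(v3 %in% v4))
  # reference scenario carries no blood or spirometry terms
  expect_false(any(c("bilirubin", "fev1", "urate", "ggt") %in% v1))
  # default functional forms for key expansion variables
  bil <- sp$scenario3$terms$bilirubin
  expect_equal(bil$transform, "log")
  expect_true("sex" %in% bil$by)
  expect_equal(bil$tvc_df, 2L)
  fev <- sp$scenario2$terms$fev1
  expect_equal(fev$transform, "rcs")
  expect_equal(fev$rcs_df, 3L)
  expect_false(fev$log_first)
  ur <- sp$scenario3$terms$urate
  expect_equal(ur$transform, "log")
  expect_setequal(ur$by, c("sex", "smoking_status"))
})

test_that("spec_variables collects every column a spec needs", {
  sp <- scenario_specs()$scenario3
  v <- spec_variables(sp)
  expect_true(all(c("time", "event", "bilirubin", "sex", "age_entry",
                    "smoking_status") %in% v))
})
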
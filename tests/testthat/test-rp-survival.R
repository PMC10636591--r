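# Unit tests for the flexible parametric survival model: likelihood
# closed forms, fitting, prediction and nested-model testing.

weibull_fit_obj <- function(gamma0, gamma1) {
  # hand-built fit object for closed-form prediction checks
  structure(list(coefficients = c("(Intercept)" = gamma0,
                                  "time_s1" = gamma1),
                 spec = rp_spec(list(), baseline_df = 1),
                 info = list(), time_spec = NULL, tvc_specs = list()),
            class = "rp_fit")
}

test_that("log likelihood matches the Weibull closed form on one subject", {
  # event at t = 1, H(1) = 1, h(1) = 1: l = log h - H = -1
  d1 <- tibble::tibble(time = 1, event = 1L)
  expect_equal(rp_loglik(d1, rp_spec(list(), baseline_df = 1), c(0, 1)), -1)
  # censored at t = 1: l = -H(1) = -1
  d0 <- tibble::tibble(time = 1, event = 0L)
  expect_equal(rp_loglik(d0, rp_spec(list(), baseline_df = 1), c(0, 1)), -1)
})

test_that("a zero covariate coefficient leaves the likelihood unchanged", {
  dat <- make_exp_data(500, seed = 11)
  ll0 <- rp_loglik(dat, rp_spec(list(), baseline_df = 1), c(-4.5, 0.9))
  ll1 <- rp_loglik(dat, rp_spec(list(rp_term("x", "linear")), baseline_df = 1),
                   c(-4.5, 0.9, 0))
  expect_equal(ll0, ll1)
})

test_that("non-positive hazard at an event time gives -Inf, not a clip", {
  d1 <- tibble::tibble(time = 2, event = 1L)
  expect_identical(rp_loglik(d1, rp_spec(list(), baseline_df = 1), c(0, -1)),
                   -Inf)
})

test_that("fit recovers exponential baseline parameters", {
  dat <- make_exp_data(20000, rate = exp(-5), seed = 21)
  fit <- rp_fit(dat, rp_spec(list(), baseline_df = 1))
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - (-5)), 3 * se[1])
  expect_lt(abs(fit$coefficients[["time_s1"]] - 1), 3 * se[2])
})

test_that("fit recovers a binary covariate log hazard ratio", {
  dat <- make_exp_data(20000, rate = exp(-5), beta = 0.7, seed = 22)
  fit <- rp_fit(dat, rp_spec(list(rp_term("x", "linear")), baseline_df = 1))
  se <- sqrt(diag(fit$vcov))[["x"]]
  expect_lt(abs(fit$coefficients[["x"]] - 0.7), 3 * se)
})

test_that("refitting identical inputs is bit-stable", {
  dat <- make_exp_data(3000, seed = 13)
  f1 <- rp_fit(dat, rp_spec(list(rp_term("x", "linear")), baseline_df = 2))
  f2 <- rp_fit(dat, rp_spec(list(rp_term("x", "linear")), baseline_df = 2))
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("1-df baseline equals an independent Weibull MLE", {
  dat <- make_exp_data(8000, rate = 0.01, seed = 5)
  fit <- rp_fit(dat, rp_spec(list(), baseline_df = 1))
  oracle <- weibull_mle(dat$time, dat$event)
  expect_lt(abs(fit$loglik - oracle$loglik), 1e-6)
  expect_lt(abs(fit$coefficients[["time_s1"]] - oracle$gamma1), 1e-4)
})

test_that("spline-baseline fit agrees with an independent implementation", {
  skip_if_not_installed("flexsurv")
  set.seed(9)
  n <- 4000
  x <- stats::rbinom(n, 1, 0.4)
  tt <- stats::rweibull(n, shape = 1.3, scale = 60 * exp(-0.5 * x / 1.3))
  cens <- stats::runif(n, 4, 9)
  dat <- tibble::tibble(time = pmin(tt, cens),
                        event = as.integer(tt <= cens), x = x)
  fit <- rp_fit(dat, rp_spec(list(rp_term("x", "linear")), baseline_df = 2))
  ref <- flexsurv::flexsurvspline(survival::Surv(time, event) ~ x,
                                  data = dat, k = 1, scale = "hazard")
  # same model space (1 internal knot at the median log event time),
  # so the maximised log likelihoods must agree
  expect_lt(abs(fit$loglik - ref$loglik), 1e-3)
})

test_that("predicted risk matches the closed form and its limits", {
  fit <- weibull_fit_obj(-3, 1)
  nd <- tibble::tibble(dummy = 1)
  expect_equal(as.numeric(predict_risk(fit, nd, 6)), 1 - exp(-6 * exp(-3)),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(predict_risk(fit, nd, 6)), 4), 0.2582)
  expect_lt(as.numeric(predict_risk(fit, nd, 1e-10)), 1e-11)
  expect_error(predict_risk(fit, nd, 0), "positive")
  # monotone in t under proportional hazards
  r <- vapply(c(1, 2, 4, 6, 8), function(t)
    as.numeric(predict_risk(fit, nd, t)), numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("proportional hazards shift log(-log survival) by exactly beta", {
  dat <- make_exp_data(5000, beta = 0.7, seed = 3)
  fit <- rp_fit(dat, rp_spec(list(rp_term("x", "linear")), baseline_df = 2))
  beta <- fit$coefficients[["x"]]
  nd <- tibble::tibble(x = c(0, 1))
  for (t in c(1, 3, 6)) {
    r <- as.numeric(predict_risk(fit, nd, t))
    expect_equal(log(-log(1 - r[2])) - log(-log(1 - r[1])), beta,
                 tolerance = 1e-10)
  }
})

test_that("recentring and rescaling a covariate is an exact reparameterisation", {
  dat <- make_exp_data(4000, beta = 0.5, seed = 17)
  dat$xs <- dat$x * 10 + 5
  f1 <- rp_fit(dat, rp_spec(list(rp_term("x", "linear")), baseline_df = 2))
  f2 <- rp_fit(dat, rp_spec(list(rp_term("xs", "linear")), baseline_df = 2))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f2$coefficients[["xs"]], f1$coefficients[["x"]] / 10,
               tolerance = 1e-6)
  r1 <- as.numeric(predict_risk(f1, dat[1:50, ], 6))
  r2 <- as.numeric(predict_risk(f2, dat[1:50, ], 6))
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("likelihood ratio test gives the expected chi-square tails", {
  mkfit <- function(ll, k) {
    structure(list(loglik = ll, coefficients = stats::setNames(
      rep(0, k), paste0("p", 1:k)), n_used = 100, n_events = 10),
      class = "rp_fit")
  }
  same <- lr_test(mkfit(-50, 3), mkfit(-50, 3))
  expect_equal(same$chi2, 0)
  expect_equal(same$p.value, 1)
  near5pct <- lr_test(mkfit(-50, 3), mkfit(-50 + 3.84 / 2, 4))
  expect_equal(near5pct$p.value, 0.05, tolerance = 1e-3)
  big <- lr_test(mkfit(-500, 4), mkfit(-500 + 217 / 2, 50))
  expect_lt(big$p.value, 1e-20)
  expect_error(lr_test(mkfit(-50, 3),
                       structure(list(loglik = -40, coefficients = 1:5,
                                      n_used = 99, n_events = 10),
                                 class = "rp_fit")),
               "different analysis rows")
})

test_that("missing covariate values are rejected with guidance", {
  dat <- make_exp_data(100, seed = 1)
  dat$x[3] <- NA
  expect_error(rp_fit(dat, rp_spec(list(rp_term("x", "linear")),
                                   baseline_df = 1)),
               "complete case")
})

test_that("fits serialise to JSON and back without changing predictions", {
  tm <- boosted_truth()
  coh <- generate_cohort(cohort_config(n = 4000, seed = 6, true_model = tm))
  spec <- rp_spec(list(rp_term("age_entry", "linear"), rp_term("sex"),
                       rp_term("bilirubin", "log", by = "sex", tvc_df = 2)),
                  baseline_df = 2)
  fit <- rp_fit(coh, spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_rp_fit(fit, path)
  back <- read_rp_fit(path)
  expect_equal(back$loglik, fit$loglik)
  expect_equal(as.numeric(predict_risk(back, coh[1:20, ], 6)),
               as.numeric(predict_risk(fit, coh[1:20, ], 6)),
               tolerance = 1e-12)
})

test_that("tidy and glance summarise a fit in broom style", {
  dat <- make_exp_data(2000, beta = 0.5, seed = 30)
  fit <- rp_fit(dat, rp_spec(list(rp_term("x", "linear")), baseline_df = 1))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_equal(nrow(td), length(fit$coefficients))
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$loglik)
  expect_equal(gl$AIC, -2 * fit$loglik + 2 * length(fit$coefficients))
  expect_equal(stats::AIC(fit), gl$AIC)
})
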
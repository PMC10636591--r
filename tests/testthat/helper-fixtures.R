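# Shared fixtures: small survival datasets and reduced cohort configs
# built in code at test time.

# Exponential survival data with an optional binary covariate effect.
make_exp_data <- function(n, rate = exp(-5), beta = 0, seed = 1,
                          cens_lo = 4, cens_hi = 8) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  tt <- stats::rexp(n, rate * exp(beta * x))
  cens <- stats::runif(n, cens_lo, cens_hi)
  tibble::tibble(time = pmin(tt, cens), event = as.integer(tt <= cens),
                 x = x)
}

# Random censored toy data for concordance checks.
make_toy_surv <- function(n, seed = 1, tie_prob = 0.2) {
  set.seed(seed)
  time <- sample(1:5, n, replace = TRUE) + ifelse(stats::runif(n) < tie_prob,
                                                  0, stats::runif(n))
  tibble::tibble(time = time,
                 event = stats::rbinom(n, 1, 0.6),
                 score = round(stats::rnorm(n), 1))
}

# Exhaustive O(n^2) concordance oracle: a direct transcription of the
# pair conventions, independent of the vectorised implementation.
c_index_oracle <- function(time, event, score) {
  n <- length(time)
  conc <- 0; pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- i; b <- j
      if (time[b] < time[a] ||
          (time[b] == time[a] && event[b] == 1 && event[a] == 0)) {
        a <- j; b <- i
      }
      # now a is the candidate earlier subject
      if (time[a] < time[b]) {
        if (event[a] == 1) {
          pairs <- pairs + 1
          if (score[a] > score[b]) conc <- conc + 1
          else if (score[a] == score[b]) conc <- conc + 0.5
        }
      } else {  # tied times
        if (event[a] == 1 && event[b] == 1) {
          pairs <- pairs + 1
          conc <- conc + 0.5
        } else if (event[a] == 1 && event[b] == 0) {
          pairs <- pairs + 1
          if (score[a] > score[b]) conc <- conc + 1
          else if (score[a] == score[b]) conc <- conc + 0.5
        }
      }
    }
  }
  if (pairs == 0) return(NA_real_)
  conc / pairs
}

# A small data-generating truth with log, interaction and
# time-dependent terms, boosted to a ~4-5% event fraction so tests get
# enough events at modest n.
boosted_truth <- function() {
  tm0 <- default_true_model()
  cf <- tm0$coefficients
  cf["(Intercept)"] <- cf["(Intercept)"] + log(10)
  true_model(tm0$spec, cf, time_knots = tm0$time_spec$knots,
             tvc_knots = list("2" = tm0$tvc_specs[["2"]]$knots))
}

# Recovery-study truth: the boosted model with an additional covariate
# spline (FEV1, 2 df at fixed knots) so the generating hazard exercises
# log, spline, interaction and time-dependent terms together.
recovery_truth <- function() {
  tm0 <- default_true_model()
  spec <- spec_update(tm0$spec, rp_term("fev1", "rcs", rcs_df = 2))
  cf <- tm0$coefficients
  cf["(Intercept)"] <- cf["(Intercept)"] + log(15.5)
  cf <- cf[setdiff(names(cf), "fev1")]
  cf <- c(cf, fev1 = -0.45, fev1_ns1 = 0.35)
  true_model(spec, cf, time_knots = tm0$time_spec$knots,
             tvc_knots = list("2" = tm0$tvc_specs[["2"]]$knots),
             cov_knots = list(fev1 = c(1.6, 2.8, 4.0)))
}

# Minimal Weibull truth with no covariates.
weibull_truth <- function(gamma0 = -5.3, gamma1 = 1) {
  true_model(rp_spec(list(), baseline_df = 1),
             c("(Intercept)" = gamma0, "time_s1" = gamma1))
}

# Direct Weibull maximum-likelihood (log cumulative hazard
# parameterisation, H(t) = exp(g0) t^g1), independent of the package's
# spline machinery: closed-form log likelihood maximised with optim.
weibull_mle <- function(time, event) {
  nll <- function(p) {
    g0 <- p[1]; g1 <- exp(p[2])
    H <- exp(g0) * time^g1
    h <- exp(g0) * g1 * time^(g1 - 1)
    -(sum(event * log(h)) - sum(H))
  }
  opt <- stats::optim(c(-1, 0), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  list(gamma0 = opt$par[1], gamma1 = exp(opt$par[2]),
       loglik = -opt$value)
}
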
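# End-to-end orchestration: simulate -> (optionally select) -> fit ->
# evaluate -> economic model, with deterministic sub-seeds derived from
# one master seed and diff-able CSV/JSON artifacts.

#' Pipeline configuration
#'
#' @param n Cohort size to simulate.
#' @param seed Master seed; all stochastic stages derive their own
#'   sub-seed from it deterministically.
#' @param cohort A [cohort_config()]; built from `n` and the master
#'   seed when `NULL`.
#' @param scenarios Named list of four [rp_spec()]s (default
#'   [scenario_specs()]).
#' @param econ An [econ_params()].
#' @param run_selection If `TRUE`, re-select the functional forms of
#'   the blood/spirometry variables by information criterion before
#'   fitting (slower); by default the preset scenario specs are used.
#' @param selection A [selection_config()] for the selection stage.
#' @param c_index_max_n Cap on the number of rows used for the c-index
#'   (all events are kept and non-events subsampled, which leaves the
#'   concordance estimate unbiased while bounding the pairwise cost).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 100000, seed = 1, cohort = NULL,
                            scenarios = scenario_specs(),
                            econ = econ_params(), run_selection = FALSE,
                            selection = selection_config(),
                            c_index_max_n = 30000) {
  seeds <- derive_seeds(seed)
  if (is.null(cohort)) cohort <- cohort_config(n = n, seed = seeds["cohort"])
  structure(list(n = n, seed = seed, seeds = seeds, cohort = cohort,
                 scenarios = scenarios, econ = econ,
                 run_selection = run_selection, selection = selection,
                 c_index_max_n = c_index_max_n),
            class = "pipeline_config")
}

# Small deterministic seed schedule below 2^31.
derive_seeds <- function(master) {
  base <- (as.integer(master) %% 1000003L)
  c(cohort = base * 1009L %% 2147483L + 1L,
    missing = base * 2003L %% 2147483L + 7L,
    subsample = base * 3001L %% 2147483L + 13L,
    selection = base * 4001L %% 2147483L + 19L)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, injects missingness, filters to complete cases
#' for the union of scenario variables, fits the null and four
#' scenario models, computes the model-comparison report and the
#' screening economic model, and (optionally) writes all artifacts to
#' `outdir` as CSV plus a provenance JSON.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return A list: `cohort` (with missingness), `analysis`
#'   (complete-case), `fits`, `performance` (tibble),
#'   `econ` (tibble), `incidental` (tibble), `selection_trace`
#'   (tibble or NULL), `provenance` (list).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- config$seeds

  say("simulating cohort (n = ", config$cohort$n, ") ...")
  complete <- generate_cohort(config$cohort)
  cohort <- inject_missingness(complete, config$cohort$missingness,
                               seed = seeds["missing"])

  vars <- spec_variables(config$scenarios)
  analysis <- complete_case_filter(cohort, vars)
  say("complete cases: ", nrow(analysis), " (", sum(analysis$event),
      " events)")

  scenarios <- config$scenarios
  selection_trace <- NULL
  if (config$run_selection) {
    say("selecting functional forms ...")
    sel_cfg <- config$selection
    sel_cfg$seed <- seeds["selection"]
    sel_data <- if (sel_cfg$sample_mode == "split") {
      selection_split(analysis, sel_cfg)$selection
    } else analysis
    traces <- list()
    base <- scenarios$scenario4
    for (v in c("fev1", "waist", "bilirubin", "albumin", "ast", "alp",
                "alt", "ggt", "urate")) {
      st <- select_transform(sel_data, base, v, sel_cfg)
      base <- st$spec
      si <- select_interactions(sel_data, base, v, sel_cfg)
      base <- si$spec
      traces[[v]] <- dplyr::bind_rows(st$trace, si$trace)
    }
    selection_trace <- dplyr::bind_rows(traces)
    sel_terms <- base$terms
    scenarios <- scenario_specs(
      baseline_df = base$baseline_df,
      spirometry = unname(sel_terms[c("fev1", "alcohol_status", "waist")]),
      blood = unname(sel_terms[c("bilirubin", "albumin", "ast", "alp",
                                 "alt", "ggt", "urate")])
    )
  }

  say("fitting models ...")
  null_fit <- rp_fit(analysis,
                     rp_spec(list(),
                             baseline_df = scenarios[[1]]$baseline_df),
                     compute_vcov = FALSE)
  fits <- purrr::imap(scenarios, function(sp, nm) {
    say("  ", nm)
    rp_fit(analysis, sp, compute_vcov = FALSE)
  })
  bad <- names(fits)[!vapply(fits, `[[`, logical(1), "converged")]
  if (length(bad)) {
    stop("required fit(s) did not converge: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  say("evaluating ...")
  elig <- eligible(analysis, config$econ)
  eval_data <- subsample_for_c(analysis, config$c_index_max_n,
                               seeds["subsample"])
  performance <- performance_report(eval_data, fits, null_fit,
                                    horizons = c(2, config$econ$horizon),
                                    risk_data = elig)

  say("economic model ...")
  risks <- lapply(fits, function(f) {
    as.numeric(predict_risk(f, elig, t = config$econ$horizon))
  })
  followup_costs <- c(0, config$econ$cost_spiro_visit,
                      config$econ$cost_blood, config$econ$cost_both)
  inputs <- purrr::imap_dfr(risks, function(r, nm) {
    i <- match(nm, names(risks))
    scenario_inputs_from_risks(elig, risks[[1]], r, followup_costs[i],
                               config$econ, scenario = nm)
  })
  econ <- suppressWarnings(run_scenario(inputs, config$econ))
  above <- risks[[1]] >= config$econ$risk_threshold
  incidental <- incidental_findings(elig[above, , drop = FALSE])

  provenance <- list(
    seed = config$seed, sub_seeds = as.list(seeds),
    n_simulated = config$cohort$n, n_complete = nrow(analysis),
    n_events = sum(analysis$event), n_eligible = nrow(elig),
    config_hash = rlang::hash(config[c("n", "seed", "econ",
                                       "run_selection")]),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  out <- list(cohort = cohort, analysis = analysis, fits = fits,
              null_fit = null_fit, performance = performance, econ = econ,
              incidental = incidental, selection_trace = selection_trace,
              provenance = provenance)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

# Keep all events, subsample non-events: pair counts scale uniformly so
# the concordance estimate is unchanged in expectation.
subsample_for_c <- function(data, max_n, seed) {
  if (nrow(data) <= max_n) return(data)
  set.seed(seed)
  ev <- which(data$event == 1)
  cen <- which(data$event == 0)
  keep <- c(ev, sample(cen, max_n - length(ev)))
  data[sort(keep), , drop = FALSE]
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$performance, file.path(outdir, "performance_report.csv"),
                   row.names = FALSE)
  utils::write.csv(out$econ, file.path(outdir, "econ_report.csv"),
                   row.names = FALSE)
  utils::write.csv(out$incidental, file.path(outdir, "incidental_findings.csv"),
                   row.names = FALSE)
  if (!is.null(out$selection_trace)) {
    utils::write.csv(out$selection_trace,
                     file.path(outdir, "selection_trace.csv"),
                     row.names = FALSE)
  }
  write_cohort(out$cohort, file.path(outdir, "cohort.csv"))
  jsonlite::write_json(out$provenance, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
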
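# Model specification for the flexible parametric survival model:
# a baseline restricted cubic spline of log time plus covariate terms,
# each with a functional-form transform, optional interaction partners
# and an optional time-dependent (non-proportional hazards) effect.

#' Define a covariate term of a flexible parametric survival model
#'
#' @param variable Column name in the cohort table.  Character, factor
#'   and logical columns enter as dummy variables (first level is the
#'   reference); numeric columns are transformed according to
#'   `transform`.
#' @param transform Functional form for numeric variables: `"linear"`,
#'   `"log"` (natural log) or `"rcs"` (restricted cubic spline with
#'   `rcs_df` degrees of freedom, knots at Harrell's default
#'   percentiles of the analysis sample).
#' @param rcs_df Spline degrees of freedom when `transform = "rcs"`
#'   (2, 3 or 4).
#' @param log_first If `TRUE` and `transform = "rcs"`, the spline is
#'   applied to `log(variable)` rather than the raw scale.
#' @param by Interaction partners, a subset of
#'   `c("sex", "age", "smoking_status")`: each main-effect column is
#'   multiplied by the partner's dummy (sex, smoking status) or
#'   centred linear (age) columns.
#' @param tvc_df Degrees of freedom of a time-dependent effect: the
#'   first main-effect column is multiplied by a `tvc_df`-df restricted
#'   cubic spline of log time, relaxing proportional hazards for this
#'   variable.  `0` (the default) keeps the effect proportional.
#' @return An object of class `rp_term`.
#' @export
rp_term <- function(variable, transform = c("linear", "log", "rcs"),
                    rcs_df = 3, log_first = FALSE,
                    by = character(), tvc_df = 0) {
  transform <- match.arg(transform)
  stopifnot(is.character(variable), length(variable) == 1L)
  bad <- setdiff(by, c("sex", "age", "smoking_status"))
  if (length(bad)) {
    stop("unsupported interaction partner(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (tvc_df < 0) stop("tvc_df must be >= 0", call. = FALSE)
  structure(
    list(variable = variable, transform = transform,
         rcs_df = as.integer(rcs_df), log_first = isTRUE(log_first),
         by = by, tvc_df = as.integer(tvc_df)),
    class = "rp_term"
  )
}

#' Define a flexible parametric survival model
#'
#' A model on the log cumulative hazard scale,
#' \eqn{\log H(t \mid x) = s(\log t; \gamma) + x'\beta + \sum_k z_k\, s_k(\log t)},
#' where \eqn{s} is a restricted cubic spline of log time with
#' `baseline_df` degrees of freedom (1 df = Weibull), \eqn{x} collects
#' the covariate and interaction columns of `terms`, and the optional
#' \eqn{z_k s_k(\log t)} products carry time-dependent effects.
#'
#' @param terms List of [rp_term()] objects (at most one per variable).
#' @param baseline_df Degrees of freedom of the baseline log-time
#'   spline (>= 1).
#' @return An object of class `rp_spec`.
#' @export
rp_spec <- function(terms = list(), baseline_df = 3) {
  if (inherits(terms, "rp_term")) terms <- list(terms)
  stopifnot(all(vapply(terms, inherits, logical(1), "rp_term")))
  vars <- vapply(terms, `[[`, character(1), "variable")
  if (anyDuplicated(vars)) {
    stop("duplicate terms for variable(s): ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "), call. = FALSE)
  }
  if (baseline_df < 1) stop("baseline_df must be >= 1", call. = FALSE)
  names(terms) <- vars
  structure(list(terms = terms, baseline_df = as.integer(baseline_df)),
            class = "rp_spec")
}

#' @export
print.rp_spec <- function(x, ...) {
  cat("Flexible parametric survival model spec\n")
  cat("  baseline log-time spline: ", x$baseline_df, " df\n", sep = "")
  for (tm in x$terms) {
    tr <- switch(tm$transform,
                 linear = "linear",
                 log = "log",
                 rcs = paste0(if (tm$log_first) "log + " else "",
                              "rcs(", tm$rcs_df, " df)"))
    extras <- c(
      if (length(tm$by)) paste0("x ", paste(tm$by, collapse = ", x ")),
      if (tm$tvc_df > 0) paste0("time-dependent (", tm$tvc_df, " df)")
    )
    cat("  ", tm$variable, ": ", tr,
        if (length(extras)) paste0(" [", paste(extras, collapse = "; "), "]"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Add or replace terms in a model spec
#'
#' @param spec An [rp_spec()].
#' @param ... [rp_term()] objects to add; a term for a variable already
#'   in the spec replaces the existing one.
#' @return The updated `rp_spec`.
#' @export
spec_update <- function(spec, ...) {
  stopifnot(inherits(spec, "rp_spec"))
  new_terms <- list(...)
  if (length(new_terms) == 1L && is.list(new_terms[[1]]) &&
      !inherits(new_terms[[1]], "rp_term")) {
    new_terms <- new_terms[[1]]
  }
  terms <- spec$terms
  for (tm in new_terms) {
    stopifnot(inherits(tm, "rp_term"))
    terms[[tm$variable]] <- tm
  }
  rp_spec(unname(terms), baseline_df = spec$baseline_df)
}

#' Drop a variable's term from a model spec
#'
#' @param spec An [rp_spec()].
#' @param variable Variable name to remove.
#' @return The updated `rp_spec`.
#' @export
spec_drop <- function(spec, variable) {
  stopifnot(inherits(spec, "rp_spec"))
  terms <- spec$terms[setdiff(names(spec$terms), variable)]
  rp_spec(unname(terms), baseline_df = spec$baseline_df)
}

# Fixed level orders for the categorical cohort variables; the first
# level is the reference in dummy coding.
.rp_levels <- list(
  sex = c("female", "male"),
  smoking_status = c("never", "former", "current"),
  alcohol_status = c("never", "previous", "current"),
  ethnicity = c("White", "Asian", "Black", "Mixed", "Other")
)

# Per-term metadata needed to rebuild design columns on new data:
# factor levels, spline knots, centring constants for age partners.
build_term_info <- function(data, spec) {
  info <- list()
  for (tm in spec$terms) {
    v <- tm$variable
    if (!v %in% names(data)) {
      stop("variable '", v, "' not found in the cohort table", call. = FALSE)
    }
    x <- data[[v]]
    ti <- list(variable = v)
    if (is.numeric(x)) {
      ti$type <- "numeric"
      if (tm$transform == "log" || (tm$transform == "rcs" && tm$log_first)) {
        if (any(x <= 0, na.rm = TRUE)) {
          stop("variable '", v, "' has non-positive values; log transform invalid",
               call. = FALSE)
        }
      }
      if (tm$transform == "rcs") {
        xt <- if (tm$log_first) log(x) else x
        ti$knots <- default_knots(xt, tm$rcs_df)
      }
    } else {
      ti$type <- "factor"
      lev <- .rp_levels[[v]]
      if (is.null(lev)) {
        lev <- if (is.logical(x)) c("FALSE", "TRUE") else sort(unique(as.character(x)))
      }
      ti$levels <- lev
    }
    if ("age" %in% tm$by) ti$age_center <- mean(data$age_entry, na.rm = TRUE)
    info[[v]] <- ti
  }
  info
}

# Partner columns used for interactions.
partner_columns <- function(data, partner, term_info) {
  switch(partner,
    sex = {
      m <- matrix(as.numeric(as.character(data$sex) == "male"), ncol = 1)
      colnames(m) <- "sexmale"
      m
    },
    age = {
      m <- matrix(data$age_entry - term_info$age_center, ncol = 1)
      colnames(m) <- "age_c"
      m
    },
    smoking_status = {
      s <- as.character(data$smoking_status)
      m <- cbind(smokformer = as.numeric(s == "former"),
                 smokcurrent = as.numeric(s == "current"))
      m
    },
    stop("unknown partner: ", partner, call. = FALSE)
  )
}

# Main-effect columns for a single term.
term_main_block <- function(data, tm, ti) {
  v <- tm$variable
  x <- data[[v]]
  if (ti$type == "factor") {
    lev <- ti$levels
    xc <- if (is.logical(x)) as.character(x) else as.character(x)
    blk <- vapply(lev[-1], function(l) as.numeric(xc == l),
                  numeric(nrow(data)))
    blk <- matrix(blk, nrow = nrow(data))
    colnames(blk) <- paste0(v, lev[-1])
    return(blk)
  }
  switch(tm$transform,
    linear = {
      m <- matrix(as.numeric(x), ncol = 1); colnames(m) <- v; m
    },
    log = {
      m <- matrix(log(as.numeric(x)), ncol = 1); colnames(m) <- paste0("log_", v); m
    },
    rcs = {
      xt <- if (tm$log_first) log(as.numeric(x)) else as.numeric(x)
      b <- rcs_basis(xt, ti$knots)
      colnames(b) <- paste0(if (tm$log_first) paste0("log_", v) else v,
                            c("", paste0("_ns", seq_len(ncol(b) - 1L))))
      b
    }
  )
}

# Static (time-constant) design matrix and the z vectors that carry
# time-dependent effects.  Returns list(X, tvc = list of (z, name, df)).
build_static <- function(data, spec, info) {
  blocks <- list()
  tvc <- list()
  for (tm in spec$terms) {
    ti <- info[[tm$variable]]
    main <- term_main_block(data, tm, ti)
    blocks[[length(blocks) + 1L]] <- main
    for (p in tm$by) {
      pc <- partner_columns(data, p, ti)
      for (j in seq_len(ncol(pc))) {
        inter <- main * pc[, j]
        colnames(inter) <- paste0(colnames(main), ":", colnames(pc)[j])
        blocks[[length(blocks) + 1L]] <- inter
      }
    }
    if (tm$tvc_df > 0) {
      tvc[[length(tvc) + 1L]] <- list(z = main[, 1L], name = colnames(main)[1L],
                                      df = tm$tvc_df)
    }
  }
  X <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  list(X = X, tvc = tvc)
}
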
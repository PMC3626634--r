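# Group modelling: two-way ANCOVA with an age covariate, the
# callosal-disconnection validation test, subgroup post-hoc t-tests, and
# demographic tests.
#
# The group model is the additive Gaussian linear model
#   y = ybar + bASD * ASD + bTSC * TSC + bage * age
# fit by ordinary least squares; coefficient t-tests (two-sided, residual
# df = n - 4) assess whether the ASD and TSC effects differ from zero. No
# interaction term is included, so purely non-additive subgroup effects are
# not captured by the main model (the post-hoc subgroup t-tests probe them).
# Raw p-values are reported without multiple-testing correction; correcting
# over correlated network measures would require their joint distribution.

#' Fit the two-way ANCOVA with age covariate
#'
#' Ordinary least-squares fit of
#' `measure ~ ASD + TSC + age` on a cohort table. Rows with non-finite
#' measure values (e.g. undefined ratios) are excluded listwise and counted.
#' Covariates that are constant in the data (e.g. a single-age cohort, or a
#' design with only one group factor) are dropped from the design and
#' recorded in `dropped_terms`; a rank-deficient design among the remaining
#' terms is an error naming the aliased columns.
#'
#' @param table Cohort table: one row per subject with columns `ASD`, `TSC`
#'   (0/1), `age`, and the measure columns.
#' @param measure Measure column name, or a base measure name to be combined
#'   with `band`.
#' @param band Optional band name; the column used is `
#'   paste(measure, band, sep = ".")`.
#' @return Object of class `ancova_result`: list with `measure`, `band`,
#'   `n`, `n_excluded`, `df`, `dropped_terms` and `coefficients` (data
#'   frame: `term`, `estimate`, `se`, `t`, `p`).
#' @export
fit_ancova <- function(table, measure, band = NULL) {
  col <- if (is.null(band)) measure else paste(measure, band, sep = ".")
  if (!col %in% names(table)) stop("no such measure column: ", col)
  stopifnot(all(c("ASD", "TSC", "age") %in% names(table)))
  d <- data.frame(y = as.numeric(table[[col]]),
                  ASD = as.numeric(table$ASD),
                  TSC = as.numeric(table$TSC),
                  age = as.numeric(table$age))
  ok <- is.finite(d$y) & is.finite(d$age)
  n_excluded <- sum(!ok)
  d <- d[ok, , drop = FALSE]
  if (nrow(d) < 8) stop("fewer than 8 usable subjects")

  terms <- c("ASD", "TSC", "age")
  constant <- vapply(terms, function(t) length(unique(d[[t]])) < 2, logical(1))
  if (all(constant[c("ASD", "TSC")]))
    stop("both group flags are constant: no group effect is estimable")
  dropped <- terms[constant]
  used <- terms[!constant]
  fml <- stats::reformulate(used, response = "y")
  X <- stats::model.matrix(fml, d)
  if (qr(X)$rank < ncol(X)) {
    fit0 <- stats::lm(fml, data = d)
    aliased <- names(which(is.na(stats::coef(fit0))))
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      t = sm[, 3], p = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  coefs$term[coefs$term == "(Intercept)"] <- "baseline"
  structure(list(measure = measure, band = band, n = nrow(d),
                 n_excluded = n_excluded, df = fit$df.residual,
                 dropped_terms = dropped, coefficients = coefs),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA: %s%s (n = %d, residual df = %d)\n", x$measure,
              if (is.null(x$band)) "" else paste0(" [", x$band, "]"),
              x$n, x$df))
  print(x$coefficients, digits = 4)
  if (length(x$dropped_terms))
    cat("dropped constant term(s):", paste(x$dropped_terms, collapse = ", "), "\n")
  invisible(x)
}

ancova_term <- function(res, term) {
  row <- res$coefficients[res$coefficients$term == term, , drop = FALSE]
  if (nrow(row) == 0)
    data.frame(term = term, estimate = NA_real_, se = NA_real_,
               t = NA_real_, p = NA_real_)
  else row
}

#' ANCOVA results grid over measures and bands
#'
#' Fits the two-way ANCOVA for every measure x band combination and returns
#' the long-format coefficient table for the two group terms — the
#' machine-readable form of a per-condition p-value grid.
#'
#' @param table Cohort table (see [fit_ancova()]).
#' @param measures Character vector of base measure names.
#' @param bands Character vector of band names.
#' @return Data frame: `measure`, `band`, `term` (ASD/TSC), `estimate`,
#'   `se`, `t`, `p`, `n`.
#' @export
ancova_grid <- function(table, measures, bands) {
  rows <- list()
  for (m in measures) for (b in bands) {
    res <- fit_ancova(table, m, b)
    for (term in c("ASD", "TSC")) {
      r <- ancova_term(res, term)
      rows[[length(rows) + 1]] <- data.frame(
        measure = m, band = b, term = term, estimate = r$estimate,
        se = r$se, t = r$t, p = r$p, n = res$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pivot an ANCOVA grid into a p-value table
#'
#' Reshapes the long grid from [ancova_grid()] into one row per measure and
#' one column per condition x band (cells: raw p-values).
#'
#' @param grid Output of [ancova_grid()].
#' @return Data frame, measures as rows.
#' @export
grid_pvalue_table <- function(grid) {
  grid$cell <- paste(grid$term, grid$band, sep = "_")
  measures <- unique(grid$measure)
  cells <- unique(grid$cell)
  out <- data.frame(measure = measures, stringsAsFactors = FALSE)
  for (cl in cells)
    out[[cl]] <- vapply(measures, function(m) {
      v <- grid$p[grid$measure == m & grid$cell == cl]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
  out
}

#' Callosal-disconnection validation test
#'
#' One-tailed two-sample pooled-variance t-test of the inter- over
#' intra-hemispheric coherence ratio, alternative: the disconnection (ACC)
#' group mean is below the control mean.
#'
#' @param acc_ratios,control_ratios Numeric vectors of per-subject ratios.
#' @return An `htest` object (`alternative = "less"`).
#' @export
acc_validation_test <- function(acc_ratios, control_ratios) {
  acc_ratios <- acc_ratios[is.finite(acc_ratios)]
  control_ratios <- control_ratios[is.finite(control_ratios)]
  stopifnot(length(acc_ratios) >= 2, length(control_ratios) >= 2)
  if (stats::sd(c(acc_ratios, control_ratios)) == 0)
    warning("degenerate variance: both groups are constant")
  stats::t.test(acc_ratios, control_ratios, alternative = "less",
                var.equal = TRUE)
}

#' Post-hoc subgroup t-test
#'
#' Two-sided two-sample t-test of a measure between the two subgroups
#' carrying a condition (e.g. for `condition = "ASD"`: ASD with TSC versus
#' ASD without TSC), probing whether a condition effect is consistent across
#' its subgroups rather than driven by one of them.
#'
#' @param table Cohort table.
#' @param measure,band As in [fit_ancova()].
#' @param condition `"ASD"` or `"TSC"`.
#' @return An `htest` object, or `NULL` (with a message) if a subgroup is
#'   empty.
#' @export
subgroup_posthoc <- function(table, measure, band = NULL,
                             condition = c("ASD", "TSC")) {
  condition <- match.arg(condition)
  other <- if (condition == "ASD") "TSC" else "ASD"
  col <- if (is.null(band)) measure else paste(measure, band, sep = ".")
  carrier <- table[table[[condition]] == 1, , drop = FALSE]
  y1 <- carrier[[col]][carrier[[other]] == 1]
  y0 <- carrier[[col]][carrier[[other]] == 0]
  y1 <- y1[is.finite(y1)]; y0 <- y0[is.finite(y0)]
  if (length(y1) < 2 || length(y0) < 2) {
    message("subgroup post-hoc skipped for ", col, ": empty subgroup")
    return(NULL)
  }
  stats::t.test(y1, y0, var.equal = TRUE)
}

#' Demographic test battery
#'
#' Fisher's exact test for binary contrasts (sex by group flag) and
#' two-sample t-tests for age contrasts, for each of the two conditions.
#'
#' @param table Cohort table with `ASD`, `TSC`, `age` and `sex` columns.
#' @return Data frame: `variable`, `condition`, `test`, `p`.
#' @export
demographic_tests <- function(table) {
  rows <- list()
  for (cond in c("ASD", "TSC")) {
    flag <- table[[cond]]
    if (length(unique(flag)) < 2) next
    if ("sex" %in% names(table)) {
      tab <- table(table$sex, flag)
      if (all(dim(tab) == c(2, 2))) {
        p <- stats::fisher.test(tab)$p.value
        rows[[length(rows) + 1]] <- data.frame(
          variable = "sex", condition = cond, test = "fisher", p = p)
      }
    }
    tt <- stats::t.test(table$age[flag == 1], table$age[flag == 0])
    rows[[length(rows) + 1]] <- data.frame(
      variable = "age", condition = cond, test = "t", p = tt$p.value)
  }
  do.call(rbind, rows)
}

#' Simulate a measure table from the additive group model
#'
#' Draws a cohort table whose single measure column follows the ANCOVA data
#' model exactly: `y = baseline + beta_asd*ASD + beta_tsc*TSC + beta_age*age
#' + N(0, sigma)`. Used for estimator calibration (type-I error, power, and
#' sign-recovery checks) without simulating signals.
#'
#' The default effect sizes are the injected-effect conditions used for
#' recovery checks: effects of 0.8 residual SDs at the default cell sizes.
#'
#' @param n_per_subgroup Cell sizes, order (control, TSC-only, ASD-only,
#'   TSC+ASD).
#' @param baseline Intercept.
#' @param beta_asd,beta_tsc,beta_age Model coefficients.
#' @param sigma Residual SD.
#' @param age_range Uniform age range in years.
#' @param measure Name of the measure column in the output.
#' @return Data frame: `ASD`, `TSC`, `age`, and the measure column.
#' @export
simulate_cohort_table <- function(n_per_subgroup = c(46, 29, 16, 14),
                                  baseline = 1, beta_asd = -0.8,
                                  beta_tsc = -0.8, beta_age = 0.05,
                                  sigma = 1, age_range = c(1, 16),
                                  measure = "y") {
  n <- as.integer(n_per_subgroup)
  TSC <- c(rep(0, n[1]), rep(1, n[2]), rep(0, n[3]), rep(1, n[4]))
  ASD <- c(rep(0, n[1]), rep(0, n[2]), rep(1, n[3]), rep(1, n[4]))
  age <- stats::runif(sum(n), age_range[1], age_range[2])
  y <- baseline + beta_asd * ASD + beta_tsc * TSC + beta_age * age +
    stats::rnorm(sum(n), 0, sigma)
  out <- data.frame(ASD = ASD, TSC = TSC, age = age)
  out[[measure]] <- y
  out
}
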
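#' Univariable screening, backward selection and association tests
#'
#' The multivariable workflow mirrors common clinical-epidemiology
#' practice: every candidate prognostic factor is screened in its own
#' univariable Cox model; factors significant at `alpha` enter a
#' multivariable model; backward selection then removes, one at a time,
#' the weakest non-forced factor (largest block Wald p >= alpha),
#' refitting until all remaining adjusters are significant. Categorical
#' factors move as whole dummy blocks. The pre-selection (full) model is
#' retained alongside the selected one.
#'
#' @name selection
NULL

#' Univariable Cox screen over candidate factors
#'
#' @param cohort data.frame.
#' @param time,event column names of the outcome.
#' @param factors character vector of candidate covariate columns.
#' @param alpha significance threshold for selection; default 0.05.
#' @param ties tie handling passed to [cox_fit()].
#' @return list: `fits` (named list of `cox_fit`), `table` (one row per
#'   coefficient: term, HR, CI, Wald p, plus the factor's block p),
#'   `selected` (factors with block Wald p < alpha).
#' @export
univariable_screen <- function(cohort, time, event, factors, alpha = 0.05,
                               ties = "efron") {
  stopifnot(all(c(time, event) %in% names(cohort)))
  if (length(factors) == 0L)
    return(list(fits = list(), table = NULL, selected = character(0)))
  miss <- setdiff(factors, names(cohort))
  if (length(miss)) stop("factors absent from cohort: ",
                         paste(miss, collapse = ", "))
  fits <- lapply(factors, function(f) {
    fml <- stats::reformulate(f, sprintf("survival::Surv(%s, %s)", time, event))
    cox_fit(fml, cohort, ties = ties)
  })
  names(fits) <- factors
  rows <- Map(function(f, fit) {
    s <- summary(fit)$table
    s$factor <- f
    s$block_p <- wald_test(fit)$p[1]
    s
  }, factors, fits)
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  block_p <- vapply(fits, function(fit) wald_test(fit)$p[1], numeric(1))
  list(fits = fits, table = table,
       selected = factors[block_p < alpha])
}

#' Multivariable Cox model with backward selection
#'
#' @param cohort data.frame.
#' @param time,event column names of the outcome.
#' @param factors adjuster factors (typically the univariable-significant
#'   ones).
#' @param forced term always retained (the immunoscore or an individual
#'   marker score); may be NULL.
#' @param alpha removal threshold: the non-forced factor with the largest
#'   block Wald p is dropped while that p >= alpha.
#' @param ties tie handling passed to [cox_fit()].
#' @return list: `full` (`cox_fit` with every factor, as reported
#'   alongside the selected model), `final` (`cox_fit` after selection),
#'   `dropped` (factors removed, in order), `kept`.
#' @export
backward_selection <- function(cohort, time, event, factors, forced = NULL,
                               alpha = 0.05, ties = "efron") {
  terms_all <- union(forced, factors)
  if (length(terms_all) == 0L) stop("no model terms")
  lhs <- sprintf("survival::Surv(%s, %s)", time, event)
  fit_with <- function(tms) cox_fit(stats::reformulate(tms, lhs), cohort,
                                    ties = ties)
  full <- fit_with(terms_all)
  current <- terms_all
  fit <- full
  dropped <- character(0)
  repeat {
    removable <- setdiff(current, forced)
    if (length(removable) == 0L) break
    wt <- wald_test(fit, removable)
    worst <- which.max(wt$p)
    if (wt$p[worst] < alpha) break
    dropped <- c(dropped, wt$term[worst])
    current <- setdiff(current, wt$term[worst])
    if (length(current) == 0L) { fit <- NULL; break }
    fit <- fit_with(current)
  }
  list(full = full, final = fit, dropped = dropped, kept = current)
}

#' Association test for an r x c contingency table
#'
#' Pearson chi-square (Yates continuity correction only for 2 x 2
#' tables), switching to Fisher's exact test for 2 x 2 tables with any
#' expected count below 5.
#'
#' @param table matrix of non-negative integer counts, r, c >= 2.
#' @return list: `statistic` (chi-square; NA for Fisher), `p`, `method`.
#' @export
association_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2L, ncol(table) >= 2L,
            all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero row or column margin")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  two_by_two <- nrow(table) == 2L && ncol(table) == 2L
  if (two_by_two && any(expected < 5)) {
    ft <- stats::fisher.test(table)
    list(statistic = NA_real_, p = ft$p.value, method = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = two_by_two))
    list(statistic = unname(ct$statistic), p = ct$p.value,
         method = "chi-square")
  }
}
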
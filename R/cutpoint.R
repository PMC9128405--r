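#' Survival-optimised density cutpoints and the CD3/CD8 immunoscore
#'
#' High/low density cutoffs are chosen by maximally selected rank
#' statistics: every admissible split of the observed densities is scored
#' by the absolute standardized two-group log-rank statistic and the
#' best-separating cutoff wins. Because the cutoff is selected to maximise
#' separation, the statistic is inflated relative to a nominal N(0,1) and
#' is reported for ranking only, never as a test.
#'
#' @name cutpoint
NULL

#' Maximally selected rank statistic cutpoint
#'
#' Candidate cutoffs are midpoints between consecutive distinct order
#' statistics of `values` whose induced groups (value > cutoff vs <=) each
#' hold at least `ceil(minprop * n)` patients. Each candidate is scored by
#' the absolute standardized log-rank statistic of the induced two-group
#' comparison; the maximising candidate is returned, ties resolved to the
#' smallest cutoff.
#'
#' @param values per-patient marker densities (cells/mm^2).
#' @param time,event follow-up (months) and event indicator; by
#'   convention the overall-survival outcome, the resulting cutoff being
#'   reused for event-free survival analyses.
#' @param minprop minimum proportion of patients on each side of a
#'   candidate split; default 0.1.
#' @param marker optional label carried on the result.
#' @return object of class `maxstat_cutpoint`: `cutoff`, `statistic`
#'   (max |z|), `candidate_count`, `marker`, and the per-candidate scan
#'   (`candidates`, `stats`).
#' @export
maxstat_cutpoint <- function(values, time, event, minprop = 0.1,
                             marker = NA_character_) {
  n <- length(values)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 10L) stop("need at least 10 observations")
  if (sum(event) < 1L) stop("degenerate outcome: no events")
  if (!(minprop > 0 && minprop < 0.5)) stop("minprop must be in (0, 0.5)")
  if (anyNA(values)) stop("missing densities: exclude flagged patients first")

  sv <- sort(unique(values))
  if (length(sv) < 2L) stop("no candidate cutoffs: all values identical")
  mins <- ceiling(minprop * n)
  mids <- (sv[-length(sv)] + sv[-1L]) / 2
  n_low <- vapply(mids, function(c0) sum(values <= c0), numeric(1))
  ok <- n_low >= mins & (n - n_low) >= mins
  cands <- mids[ok]
  if (length(cands) == 0L) stop("no candidate cutoffs under minprop constraint")

  zs <- vapply(cands, function(c0) {
    z <- .logrank_z(time, event, values > c0)
    if (is.na(z)) 0 else abs(z)
  }, numeric(1))
  best <- which.max(zs)                     # first max = smallest cutoff
  structure(list(cutoff = cands[best], statistic = zs[best],
                 candidate_count = length(cands),
                 marker = marker, candidates = cands, stats = zs,
                 minprop = minprop, n = n, n_events = sum(event)),
            class = "maxstat_cutpoint")
}

#' @export
print.maxstat_cutpoint <- function(x, ...) {
  cat(sprintf(
    "maxstat cutpoint%s: cutoff = %.4g (|z| = %.3f over %d candidates, n = %d)\n",
    if (is.na(x$marker)) "" else paste0(" [", x$marker, "]"),
    x$cutoff, x$statistic, x$candidate_count, x$n))
  invisible(x)
}

#' Binarize densities at a cutoff
#'
#' Score 1 ("high", +) iff the density is strictly greater than the
#' cutoff, 0 ("low", -) otherwise; missing densities yield NA and the
#' patient is excluded downstream.
#'
#' @param values densities.
#' @param cutoff finite cutoff (e.g. from [maxstat_cutpoint()]).
#' @return integer vector of 0/1 scores (NA where the density is missing).
#' @export
binarize <- function(values, cutoff) {
  stopifnot(is.finite(cutoff))
  if (length(values) == 0L) return(integer(0))
  ifelse(is.na(values), NA_integer_, as.integer(values > cutoff))
}

#' Four-level CD3/CD8 immunoscore groups
#'
#' Maps the pair of binary scores one-to-one onto the four groups
#' CD3+CD8+, CD3+CD8-, CD3-CD8+, CD3-CD8- ("+" = high density). CD45RO
#' is deliberately not part of the immunoscore (it carries no event-free
#' survival signal).
#'
#' @param cd3_score,cd8_score 0/1 vectors from [binarize()].
#' @return factor with levels `CD3+CD8+`, `CD3+CD8-`, `CD3-CD8+`,
#'   `CD3-CD8-` (reference first); NA where either score is missing.
#' @export
immunoscore <- function(cd3_score, cd8_score) {
  stopifnot(length(cd3_score) == length(cd8_score))
  lev <- immunoscore_levels()
  lab <- ifelse(is.na(cd3_score) | is.na(cd8_score), NA_character_,
                paste0("CD3", ifelse(cd3_score == 1, "+", "-"),
                       "CD8", ifelse(cd8_score == 1, "+", "-")))
  factor(lab, levels = lev)
}

#' @rdname immunoscore
#' @export
immunoscore_levels <- function() c("CD3+CD8+", "CD3+CD8-", "CD3-CD8+", "CD3-CD8-")

#' Derive cutpoints and scores for a whole cohort
#'
#' Runs [maxstat_cutpoint()] per marker on the overall-survival outcome,
#' binarizes all three densities, and attaches the immunoscore.
#'
#' @param cohort data.frame with `cd3_density`, `cd8_density`,
#'   `cd45ro_density`, `os_months`, `os_event`.
#' @param minprop minimum group proportion for the cutpoint scan.
#' @return list: `cutpoints` (named list of `maxstat_cutpoint`), `cohort`
#'   (input plus `cd3_score`, `cd8_score`, `cd45ro_score`, `immunoscore`).
#' @export
score_cohort <- function(cohort, minprop = 0.1) {
  need <- c("cd3_density", "cd8_density", "cd45ro_density",
            "os_months", "os_event")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  markers <- c(CD3 = "cd3_density", CD8 = "cd8_density", CD45RO = "cd45ro_density")
  cuts <- lapply(names(markers), function(mk) {
    v <- cohort[[markers[[mk]]]]
    use <- !is.na(v)
    maxstat_cutpoint(v[use], cohort$os_months[use], cohort$os_event[use],
                     minprop = minprop, marker = mk)
  })
  names(cuts) <- names(markers)
  cohort$cd3_score <- binarize(cohort$cd3_density, cuts$CD3$cutoff)
  cohort$cd8_score <- binarize(cohort$cd8_density, cuts$CD8$cutoff)
  cohort$cd45ro_score <- binarize(cohort$cd45ro_density, cuts$CD45RO$cutoff)
  cohort$immunoscore <- immunoscore(cohort$cd3_score, cohort$cd8_score)
  list(cutpoints = cuts, cohort = cohort)
}
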
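#' Two-stage analysis pipeline
#'
#' Stage one turns image tiles plus annotations into a per-patient
#' density table; stage two turns a density/outcome cohort table into the
#' full prognostic report (cutpoints, immunoscore, Kaplan-Meier curves,
#' log-rank tests, univariable and multivariable Cox tables). The CSV
#' contract between the stages means real cohorts can enter at either
#' point.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' All tunables in one serialisable object (YAML round-trip via
#' [read_run_config()] / [write_run_config()]).
#'
#' @param mpp microns per pixel of the input tiles; default 0.5 (typical
#'   x200 scan). Must be set to the true scan resolution for real data.
#' @param stain_h,stain_dab RGB optical-density stain vectors; defaults
#'   are the standard H-DAB pair.
#' @param i0 white level of the scanner; default 255.
#' @param dab_od_cutoff DAB optical density above which a pixel counts as
#'   positive; default 0.3 (calibrate on control slides with
#'   [calibrate_dab_cutoff()] when available).
#' @param ring_width_um perinuclear ring width for membranous scoring.
#' @param min_overlap_fraction minimum DAB-positive fraction of the
#'   scoring compartment for a positive cell call.
#' @param min_area_um2,max_area_um2 nucleus area filter.
#' @param minprop minimum group proportion for the cutpoint scan.
#' @param alpha significance level for screening/backward selection.
#' @param ties Cox tie handling, `"efron"` or `"breslow"`.
#' @param seed seed recorded with the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(mpp = 0.5,
                       stain_h = c(0.650, 0.704, 0.286),
                       stain_dab = c(0.269, 0.568, 0.779),
                       i0 = 255,
                       dab_od_cutoff = 0.3,
                       ring_width_um = 2,
                       min_overlap_fraction = 0.05,
                       min_area_um2 = 8,
                       max_area_um2 = 120,
                       minprop = 0.1,
                       alpha = 0.05,
                       ties = c("efron", "breslow"),
                       seed = 1L) {
  ties <- match.arg(ties)
  stopifnot(mpp > 0, i0 > 0, dab_od_cutoff > 0, ring_width_um > 0,
            min_overlap_fraction >= 0, min_overlap_fraction <= 1,
            min_area_um2 > 0, max_area_um2 > min_area_um2,
            minprop > 0, minprop < 0.5, alpha > 0, alpha <= 1)
  cfg <- list(mpp = mpp, stain_h = stain_h, stain_dab = stain_dab, i0 = i0,
              dab_od_cutoff = dab_od_cutoff, ring_width_um = ring_width_um,
              min_overlap_fraction = min_overlap_fraction,
              min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
              minprop = minprop, alpha = alpha, ties = ties,
              seed = as.integer(seed))
  cfg$stain_matrix <- stain_matrix(cfg$stain_h, cfg$stain_dab)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file.
#' @export
write_run_config <- function(config, path) {
  drop <- setdiff(names(config), "stain_matrix")
  yaml::write_yaml(unclass(config)[drop], path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Stage one: quantify image tiles into per-patient densities
#'
#' @param manifest data.frame with columns `patient_id`, `marker`
#'   (`CD3`/`CD8`/`CD45RO`), `image` (PNG/TIFF path) and `annotations`
#'   (GeoJSON path).
#' @param config a [run_config()].
#' @param output_dir if given, writes `cells.csv` (per-cell calls) and
#'   `densities.csv` there.
#' @param quiet suppress per-slide progress messages.
#' @return list: `densities` (one row per manifest row), `cells`
#'   (per-cell calls, with patient/marker columns), `skipped` (manifest
#'   rows without a readable annotation file).
#' @export
run_image_stage <- function(manifest, config = run_config(),
                            output_dir = NULL, quiet = FALSE) {
  need <- c("patient_id", "marker", "image", "annotations")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  densities <- list(); cells <- list(); skipped <- integer(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    if (!file.exists(row$annotations)) {
      warning("skipping ", row$patient_id, "/", row$marker,
              ": missing annotation file ", row$annotations)
      skipped <- c(skipped, i)
      next
    }
    q <- quantify_tile(row$image, row$annotations, row$marker, config,
                       patient_id = row$patient_id)
    if (!quiet)
      message(sprintf("[image] %s %s: %d cells, %d positive, %.4g mm2",
                      row$patient_id, row$marker, nrow(q$cells),
                      q$density$positive_count, q$density$roi_area_mm2))
    densities[[i]] <- q$density
    if (nrow(q$cells)) {
      q$cells$patient_id <- row$patient_id
      q$cells$marker <- row$marker
      cells[[i]] <- q$cells
    }
  }
  densities <- do.call(rbind, densities)
  cells <- do.call(rbind, cells)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.csv(densities, file.path(output_dir, "densities.csv"),
                     row.names = FALSE)
    utils::write.csv(cells, file.path(output_dir, "cells.csv"),
                     row.names = FALSE)
  }
  list(densities = densities, cells = cells, skipped = skipped)
}

#' Reshape a long density table into the cohort's wide density columns
#'
#' @param densities output of [run_image_stage()] (`patient_id`, `marker`,
#'   `density` long format).
#' @return data.frame: `patient_id`, `cd3_density`, `cd8_density`,
#'   `cd45ro_density`.
#' @export
densities_to_wide <- function(densities) {
  wide <- stats::reshape(
    densities[, c("patient_id", "marker", "density")],
    idvar = "patient_id", timevar = "marker", direction = "wide")
  names(wide) <- sub("^density\\.", "", names(wide))
  out <- data.frame(patient_id = wide$patient_id,
                    cd3_density = wide$CD3,
                    cd8_density = wide$CD8,
                    cd45ro_density = wide$CD45RO)
  out
}

#' Stage two: cohort analysis report
#'
#' Derives overall-survival-optimised cutpoints for each marker, scores
#' and groups the patients, and reports: Kaplan-Meier curves and log-rank
#' tests for the high/low split of each marker and for the four
#' immunoscore groups (OS and EFS), 3- and 5-year OS/EFS with confidence
#' intervals, the univariable Cox screen, and multivariable Cox models
#' with backward selection (one forcing the individual marker scores, one
#' forcing the immunoscore), adjusted for the univariable-significant
#' clinical factors.
#'
#' @param cohort data.frame in the interchange schema, or a CSV path.
#' @param config a [run_config()].
#' @param output_dir if given, writes `cutpoints.json`,
#'   `scored_cohort.csv`, `km_curves.csv` and `cox_tables.csv` there.
#' @param quiet suppress progress messages.
#' @return list of class `cohort_report`; see Details.
#' @details Components: `cutpoints`, `cohort` (scored), `km` (named list
#'   of `km_fit`), `logrank` (named list), `surv_at` (3y/5y OS and EFS),
#'   `univariable` (per outcome), `multivariable` (per outcome: marker
#'   model and immunoscore model, each with full and selected fits),
#'   `config`.
#' @export
run_cohort_stage <- function(cohort, config = run_config(),
                             output_dir = NULL, quiet = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  validate_cohort(cohort)
  if (sum(cohort$os_event) == 0L || sum(cohort$efs_event) == 0L)
    stop("degenerate outcome: no events")
  if (!is.factor(cohort$cog_risk))
    cohort$cog_risk <- factor(cohort$cog_risk,
                              levels = c("high", "intermediate", "low"))

  sc <- score_cohort(cohort, minprop = config$minprop)
  cohort <- sc$cohort
  for (mk in c("cd3", "cd8", "cd45ro")) {
    s <- cohort[[paste0(mk, "_score")]]
    cohort[[paste0(mk, "_group")]] <-
      factor(ifelse(s == 1, "high", "low"), levels = c("high", "low"))
  }
  n_excl <- sum(is.na(cohort$immunoscore))
  if (!quiet) {
    for (ct in sc$cutpoints) message(sprintf(
      "[cohort] %s cutoff %.4g cells/mm2 (|z| = %.2f)",
      ct$marker, ct$cutoff, ct$statistic))
    if (n_excl) message("[cohort] ", n_excl,
                        " patient(s) excluded from immunoscore (missing score)")
  }

  km <- list(); lr <- list()
  groupings <- c(cd3_group = "cd3_group", cd8_group = "cd8_group",
                 cd45ro_group = "cd45ro_group", immunoscore = "immunoscore")
  for (oc in c("os", "efs")) {
    tcol <- paste0(oc, "_months"); ecol <- paste0(oc, "_event")
    km[[oc]] <- list()
    lr[[oc]] <- list()
    km[[oc]][["overall"]] <- km_fit(
      stats::as.formula(sprintf("survival::Surv(%s, %s) ~ 1", tcol, ecol)),
      cohort)
    for (g in names(groupings)) {
      use <- !is.na(cohort[[groupings[g]]])
      km[[oc]][[g]] <- km_fit(
        stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                                  tcol, ecol, groupings[g])),
        cohort[use, ])
      lr[[oc]][[g]] <- logrank_test(cohort[[tcol]][use], cohort[[ecol]][use],
                                    cohort[[groupings[g]]][use])
    }
  }
  surv_at <- rbind(
    cbind(outcome = "os", survival_at(km$os$overall, c(36, 60))),
    cbind(outcome = "efs", survival_at(km$efs$overall, c(36, 60))))

  clinical <- c("age_ge18", "sex", "grade", "mki", "mycn_amplified",
                "inss_advanced", "cog_risk")
  markers <- c("cd3_group", "cd8_group", "cd45ro_group")
  uni <- list(); multi <- list()
  for (oc in c("os", "efs")) {
    tcol <- paste0(oc, "_months"); ecol <- paste0(oc, "_event")
    uni[[oc]] <- univariable_screen(cohort, tcol, ecol,
                                    c(clinical, markers, "immunoscore"),
                                    alpha = config$alpha, ties = config$ties)
    adjusters <- intersect(uni[[oc]]$selected, clinical)
    multi[[oc]] <- list(
      markers = backward_selection(cohort, tcol, ecol, adjusters,
                                   forced = intersect(
                                     c(markers, uni[[oc]]$selected), markers),
                                   alpha = config$alpha, ties = config$ties),
      immunoscore = backward_selection(cohort, tcol, ecol, adjusters,
                                       forced = "immunoscore",
                                       alpha = config$alpha,
                                       ties = config$ties))
  }

  report <- structure(list(cutpoints = sc$cutpoints, cohort = cohort,
                           km = km, logrank = lr, surv_at = surv_at,
                           univariable = uni, multivariable = multi,
                           config = config, n_excluded = n_excl),
                      class = "cohort_report")
  if (!is.null(output_dir)) write_cohort_report(report, output_dir)
  report
}

#' Write a cohort report to disk
#'
#' @param report a `cohort_report`.
#' @param output_dir destination directory (created if needed).
#' @export
write_cohort_report <- function(report, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  cuts <- lapply(report$cutpoints, function(ct)
    list(marker = ct$marker, cutoff = ct$cutoff, statistic = ct$statistic,
         candidate_count = ct$candidate_count))
  jsonlite::write_json(cuts, file.path(output_dir, "cutpoints.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$cohort, file.path(output_dir, "scored_cohort.csv"),
                   row.names = FALSE)
  km_rows <- list()
  for (oc in names(report$km))
    for (g in names(report$km[[oc]])) {
      s <- summary(report$km[[oc]][[g]])
      if (nrow(s)) km_rows[[paste(oc, g)]] <-
          cbind(outcome = oc, grouping = g, s)
    }
  utils::write.csv(do.call(rbind, km_rows),
                   file.path(output_dir, "km_curves.csv"), row.names = FALSE)
  cox_rows <- list()
  for (oc in names(report$univariable)) {
    u <- report$univariable[[oc]]$table
    cox_rows[[paste0("uni_", oc)]] <- cbind(outcome = oc, model = "univariable", u)
    m <- report$multivariable[[oc]]$immunoscore$full
    s <- summary(m)$table
    s$factor <- NA; s$block_p <- NA
    cox_rows[[paste0("multi_", oc)]] <-
      cbind(outcome = oc, model = "multivariable_immunoscore", s)
  }
  utils::write.csv(do.call(rbind, cox_rows),
                   file.path(output_dir, "cox_tables.csv"), row.names = FALSE)
  utils::write.csv(report$surv_at, file.path(output_dir, "survival_at.csv"),
                   row.names = FALSE)
  invisible(output_dir)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort analysis report:", nrow(x$cohort), "patients\n\n")
  cat("Cutpoints (cells/mm2, OS-optimised):\n")
  for (ct in x$cutpoints)
    cat(sprintf("  %-7s %8.4g  (|z| = %.2f)\n", ct$marker, ct$cutoff,
                ct$statistic))
  cat("\nImmunoscore groups:\n")
  print(table(x$cohort$immunoscore))
  s36 <- x$surv_at[x$surv_at$time == 36, ]
  cat(sprintf("\n3-year OS  %.1f%% (%.1f-%.1f)\n3-year EFS %.1f%% (%.1f-%.1f)\n",
              100 * s36$surv[1], 100 * s36$lower[1], 100 * s36$upper[1],
              100 * s36$surv[2], 100 * s36$lower[2], 100 * s36$upper[2]))
  for (oc in c("os", "efs")) {
    lr <- x$logrank[[oc]]$immunoscore
    cat(sprintf("\nImmunoscore log-rank (%s): chisq = %.2f, df = %d, p = %.3g\n",
                toupper(oc), lr$chisq, lr$df, lr$p))
    fit <- x$multivariable[[oc]]$immunoscore$full
    tab <- summary(fit)$table
    is_rows <- grepl("^immunoscore", tab$term)
    cat(sprintf("Multivariable %s (vs CD3+CD8+):\n", toupper(oc)))
    for (i in which(is_rows))
      cat(sprintf("  %-10s HR %5.2f (%.2f-%.2f) p = %.3g\n",
                  sub("immunoscore", "", tab$term[i]), tab$hr[i],
                  tab$hr_lower[i], tab$hr_upper[i], tab$p[i]))
  }
  invisible(x)
}
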
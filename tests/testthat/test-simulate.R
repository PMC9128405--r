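S <- survival::Surv

test_that("image generator honours the empty, seeded and exact-count contracts", {
  # empty tile
  p0 <- ihc_sim_params(n_cells = 0, seed = 3)
  sim0 <- generate_ihc_image(p0)
  expect_equal(nrow(sim0$truth$centroids), 0L)
  expect_true(all(sim0$image > 200))        # near-white background
  # seeded determinism, bit-identical
  p <- ihc_sim_params(n_cells = 30, positive_fraction = 0.3, seed = 7)
  s1 <- generate_ihc_image(p); s2 <- generate_ihc_image(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
  # exact positive count by construction
  p50 <- ihc_sim_params(n_cells = 50, positive_fraction = 0.2, seed = 1)
  expect_equal(sum(generate_ihc_image(p50)$truth$positive), 10L)
})

test_that("overcrowded tiles raise a placement error", {
  p <- ihc_sim_params(width = 64, height = 64, n_cells = 500, seed = 1)
  expect_error(generate_ihc_image(p), "placement")
})

test_that("ground-truth invariants hold across seeds", {
  for (seed in 1:4) {
    p <- ihc_sim_params(n_cells = 41, positive_fraction = 0.37, seed = seed)
    tr <- generate_ihc_image(p)$truth
    expect_equal(length(tr$positive), nrow(tr$centroids))
    expect_equal(sum(tr$positive), round(41 * 0.37))
    expect_gt(tr$roi_area_mm2, 0)
    # minimum spacing respected
    d <- as.matrix(dist(tr$centroids))
    diag(d) <- Inf
    expect_gte(min(d), 2.5 * max(p$nucleus_radius_range) / p$mpp - 1e-9)
  }
})

test_that("cohort covariate frequencies track the published proportions", {
  # age < 18 months: published 114/244 = 46.7%; 3 binomial SDs at n=244
  p_ref <- 114 / 244
  band <- 3 * sqrt(p_ref * (1 - p_ref) / 244)
  for (seed in 1:5) {
    co <- generate_cohort(cohort_sim_params(seed = seed))
    expect_lt(abs(mean(co$age_ge18 == 0) - p_ref), band)
  }
})

test_that("density distributions bracket the published medians and ranges", {
  co <- generate_cohort(cohort_sim_params(n_patients = 4000, seed = 11))
  expect_lt(abs(median(co$cd3_density) - 156) / 156, 0.15)
  expect_lt(abs(median(co$cd8_density) - 90) / 90, 0.15)
  expect_lt(abs(median(co$cd45ro_density) - 14) / 14, 0.25)
  # zero inflation emulates the printed 0/mm^2 minima
  expect_gt(mean(co$cd3_density == 0), 0.01)
  expect_lt(mean(co$cd3_density == 0), 0.10)
  expect_true(all(co$cd3_density >= 0))
})

test_that("degenerate and inconsistent simulation configs are rejected", {
  expect_error(cohort_sim_params(censoring = 0), "degenerate")
  expect_error(cohort_sim_params(true_log_hazard_ratios =
    list(os = list(bogus_factor = 1), efs = list())), "config error")
  expect_error(cohort_sim_params(immunoscore_proportions = c(0.5, 0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(cohort_sim_params(n_patients = 5), "n_patients")
})

test_that("null simulations give nominal log-rank type-I error", {
  null_p <- function(seed) {
    p <- cohort_sim_params(
      true_log_hazard_ratios = list(os = list(), efs = list()),
      confounder_tilt = 0, seed = seed)
    co <- generate_cohort(p)
    logrank_test(co$os_months, co$os_event, co$age_ge18)$p
  }
  n_sim <- 400
  rej <- mean(vapply(seq_len(n_sim), null_p, numeric(1)) < 0.05)
  # 3 binomial SDs around 0.05 at 400 simulations
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("Cox fits on large generated cohorts recover the planted log-HRs", {
  # n = 2000, light censoring, the full default coefficient set
  truth <- c(`imm_groupCD3+CD8-` = log(2.50), `imm_groupCD3-CD8+` = log(1.07),
             `imm_groupCD3-CD8-` = log(6.04), age_ge18 = log(3.00),
             mycn_amplified = -log(0.64), inss_advanced = -log(0.68),
             cog_riskintermediate = log(0.48), cog_risklow = log(0.14))
  errs <- list(); cover <- 0
  n_seeds <- 10
  for (seed in seq_len(n_seeds)) {
    p <- cohort_sim_params(n_patients = 2000,
                           calibrate = list(type = "events", value = 0.85),
                           seed = seed)
    co <- generate_cohort(p)
    fit <- cox_fit(S(os_months, os_event) ~ imm_group + age_ge18 +
                     mycn_amplified + inss_advanced + cog_risk, co)
    errs[[seed]] <- coef(fit)[names(truth)] - truth
    ci <- confint(fit)[names(truth), ]
    cover <- cover + (ci[, 1] <= truth & truth <= ci[, 2])
  }
  mean_err <- Reduce(`+`, errs) / n_seeds
  # within 10% of each true log-HR, with an absolute floor for the
  # near-null coefficients where a relative band is meaningless
  expect_true(all(abs(mean_err) <= pmax(0.10 * abs(truth), 0.1)))
  expect_true(all(cover >= 8))              # 95% CI covers truth >= 8/10
})

test_that("cohort CSV schema round-trips and validates", {
  co <- generate_cohort(cohort_sim_params(seed = 5))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(back$cd3_density, co$cd3_density)
  expect_equal(back$os_months, co$os_months, tolerance = 1e-12)
  bad <- co; bad$os_event <- NULL
  expect_error(write_cohort_csv(bad, path), "os_event")
  bad2 <- co; bad2$efs_event[3] <- 2
  expect_error(validate_cohort(bad2), "efs_event")
})
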
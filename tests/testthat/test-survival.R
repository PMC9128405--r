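S <- survival::Surv

test_that("product-limit estimates match hand-computed examples", {
  # one event at t=1, one censored at t=2
  f1 <- km_fit(S(t, e) ~ 1, data.frame(t = c(1, 2), e = c(1, 0)))
  expect_equal(survival_at(f1, c(1, 2))$surv, c(0.5, 0.5))
  # all events at 1, 2, 3: S(2) = (2/3) * (1/2) = 1/3
  f2 <- km_fit(S(t, e) ~ 1, data.frame(t = 1:3, e = rep(1, 3)))
  expect_equal(survival_at(f2, 2)$surv, 1 / 3)
  expect_equal(survival_at(f2, 2.5)$surv, 1 / 3)   # step function
  expect_equal(survival_at(f2, 0.5)$surv, 1)       # before first event
  # all censored: S identically 1, degenerate CI
  f3 <- km_fit(S(t, e) ~ 1, data.frame(t = 1:4, e = rep(0, 4)))
  at <- survival_at(f3, 3)
  expect_equal(c(at$surv, at$lower, at$upper), c(1, 1, 1))
  expect_error(km_fit(S(t, e) ~ 1, data.frame(t = numeric(0), e = integer(0))),
               "empty")
})

test_that("evaluation beyond follow-up carries forward with a flag", {
  f <- km_fit(S(t, e) ~ 1, data.frame(t = c(2, 5, 9), e = c(1, 1, 0)))
  at <- survival_at(f, c(6, 20))
  expect_equal(at$surv, rep(survival_at(f, 9)$surv, 2))
  expect_identical(at$truncated, c(FALSE, TRUE))
})

test_that("KM equals the empirical survival function without censoring", {
  for (seed in 1:5) {
    set.seed(seed)
    t <- round(rexp(40, 0.1), 1) + 0.1
    f <- km_fit(S(t, e) ~ 1, data.frame(t = t, e = 1))
    at <- sort(unique(t))
    expect_equal(survival_at(f, at)$surv,
                 vapply(at, function(x) mean(t > x), numeric(1)))
  }
})

test_that("Greenwood log-log intervals match the reference implementation", {
  d <- sim_surv(150, beta = 0, seed = 3)
  mine <- summary(km_fit(S(time, event) ~ 1, d))
  ref <- survival::survfit(S(time, event) ~ 1, d, conf.type = "log-log")
  keep <- ref$n.event > 0
  expect_equal(mine$surv, ref$surv[keep], tolerance = 1e-10)
  expect_equal(mine$lower, ref$lower[keep], tolerance = 1e-10)
  expect_equal(mine$upper, ref$upper[keep], tolerance = 1e-10)
  expect_equal(mine$n_risk, ref$n.risk[keep])
})

test_that("log-rank test: symmetry, hand tally, df contract", {
  # duplicated data in two groups carries no signal
  lr0 <- logrank_test(rep(c(2, 4, 6), 2), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(lr0$chisq, 0)
  expect_equal(lr0$p, 1)
  # manual hypergeometric tally: A events at 1,2; B events at 3,4
  # t=1: risk {A,A,B,B}: O_A=1, E_A=2/4, V=(1/2)(1/2)(3/3)=1/4
  # t=2: risk {A,B,B}:   O_A=1, E_A=1/3, V=(1/3)(2/3)(2/2)=2/9
  # t=3: risk {B,B}:     O_A=0, E_A=0,   V=0
  # t=4: risk {B}:       O_A=0, E_A=0,   V=0
  time <- c(1, 2, 3, 4); event <- rep(1, 4); grp <- c("A", "A", "B", "B")
  lr <- logrank_test(time, event, grp)
  o_minus_e <- (1 - 2 / 4) + (1 - 1 / 3)
  v <- 1 / 4 + 2 / 9
  expect_equal(lr$chisq, o_minus_e^2 / v, tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  # k-group df
  lr4 <- logrank_test(1:12, rep(1, 12), rep(letters[1:4], 3))
  expect_equal(lr4$df, 3L)
  expect_error(logrank_test(1:4, rep(1, 4), factor(rep("a", 4),
                                                   levels = c("a", "b"))),
               "grouping")
})

test_that("k-group log-rank matches the reference implementation", {
  set.seed(12)
  n <- 120
  g <- sample(c("a", "b", "c"), n, TRUE)
  t_true <- rexp(n, 0.05 * exp(0.5 * (g == "c")))
  cens <- runif(n, 5, 40)
  d <- data.frame(time = pmin(t_true, cens),
                  event = as.integer(t_true <= cens), g = g)
  mine <- logrank_test(d$time, d$event, d$g)
  ref <- survival::survdiff(S(time, event) ~ g, d)
  expect_equal(mine$chisq, ref$chisq, tolerance = 1e-10)
  expect_equal(unname(mine$observed), unname(ref$obs), tolerance = 1e-10)
  expect_equal(unname(mine$expected), unname(ref$exp), tolerance = 1e-10)
})

test_that("Cox coefficient matches brute-force partial likelihood maximization", {
  # independent oracle: hand-coded Breslow log partial likelihood on
  # tie-free data, maximised by golden-section search
  for (seed in 1:5) {
    d <- sim_surv(30, beta = 0.7, seed = seed)
    d$time <- d$time + seq_len(30) * 1e-6     # break ties
    loglik <- function(b) {
      lp <- b * d$x
      ord <- order(d$time)
      ll <- 0
      for (i in ord[d$event[ord] == 1]) {
        risk <- d$time >= d$time[i]
        ll <- ll + lp[i] - log(sum(exp(lp[risk])))
      }
      ll
    }
    b_brute <- stats::optimize(loglik, c(-5, 5), maximum = TRUE,
                               tol = 1e-9)$maximum
    fit <- cox_fit(S(time, event) ~ x, d)
    expect_equal(unname(coef(fit)), b_brute, tolerance = 1e-4)
  }
})

test_that("Cox estimates and standard errors match the reference fitter", {
  set.seed(31)
  n <- 250
  d <- data.frame(x = rbinom(n, 1, 0.4), z = rnorm(n),
                  g = factor(sample(c("lo", "mid", "hi"), n, TRUE),
                             levels = c("lo", "mid", "hi")))
  t_true <- rexp(n, 0.05 * exp(0.6 * d$x - 0.4 * d$z + 0.3 * (d$g == "hi")))
  cens <- runif(n, 5, 50)
  d$time <- round(pmin(t_true, cens), 1) + 0.1   # induce ties
  d$event <- as.integer(t_true <= cens)
  for (ties in c("efron", "breslow")) {
    mine <- cox_fit(S(time, event) ~ x + z + g, d, ties = ties)
    ref <- survival::coxph(S(time, event) ~ x + z + g, d, ties = ties)
    expect_equal(coef(mine), coef(ref), tolerance = 1e-7)
    expect_equal(mine$se, sqrt(diag(vcov(ref))), tolerance = 1e-7,
                 ignore_attr = TRUE)
    expect_equal(logLik(mine)[1], ref$loglik[2], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("Efron and Breslow agree on tie-free data", {
  d <- sim_surv(100, beta = 0.5, seed = 8)
  d$time <- d$time + runif(100) * 1e-8
  e <- cox_fit(S(time, event) ~ x, d, ties = "efron")
  b <- cox_fit(S(time, event) ~ x, d, ties = "breslow")
  expect_equal(coef(e), coef(b), tolerance = 1e-6)
})

test_that("Cox symmetry and degenerate designs", {
  d <- sim_surv(80, beta = 0.9, seed = 5)
  hr <- exp(coef(cox_fit(S(time, event) ~ x, d)))
  d$x_flip <- 1 - d$x
  hr_flip <- exp(coef(cox_fit(S(time, event) ~ x_flip, d)))
  expect_equal(unname(hr), unname(1 / hr_flip), tolerance = 1e-8)
  d$const <- 1
  expect_error(cox_fit(S(time, event) ~ const, d), "zero-variance")
  d0 <- d; d0$event <- 0
  expect_error(cox_fit(S(time, event) ~ x, d0), "no events")
})

test_that("perfect separation is reported as non-convergence naming the term", {
  d <- data.frame(time = c(1, 2, 3, 10, 11, 12), event = rep(1, 6),
                  x = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_fit(S(time, event) ~ x, d), "non-convergence.*x")
})

test_that("linear predictor and risk predictions are consistent", {
  d <- sim_surv(60, beta = 0.5, seed = 9)
  fit <- cox_fit(S(time, event) ~ x, d)
  lp <- predict(fit, d, type = "lp")
  expect_equal(exp(lp), predict(fit, d, type = "risk"))
  expect_equal(diff(sort(unique(lp))), unname(abs(coef(fit))),
               tolerance = 1e-10)
})

test_that("confidence interval brackets the hazard ratio", {
  d <- sim_surv(120, beta = 0.8, seed = 13)
  fit <- cox_fit(S(time, event) ~ x, d)
  s <- summary(fit)$table
  expect_true(s$hr_lower < s$hr & s$hr < s$hr_upper)
  expect_gt(s$hr, 0)
})
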
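# shared fixtures, all generated in code

# small simulated tile + its unmixed planes and masks
quantified_tile <- function(seed = 1, n_cells = 20, positive_fraction = 0.5,
                            stain_pattern = "nuclear", width = 256,
                            height = 256, ...) {
  p <- ihc_sim_params(width = width, height = height, n_cells = n_cells,
                      positive_fraction = positive_fraction,
                      stain_pattern = stain_pattern, seed = seed, ...)
  sim <- generate_ihc_image(p)
  od <- deconvolve(rgb_to_od(sim$image), mpp = p$mpp)
  nuclei <- segment_nuclei(od, mpp = p$mpp)
  list(params = p, sim = sim, od = od, nuclei = nuclei)
}

# simple exponential-PH survival sample with a binary covariate
sim_surv <- function(n, beta = 0, seed = 1, p_x = 0.5, rate = 0.08,
                     cmin = 5, cmax = 40) {
  set.seed(seed)
  x <- rbinom(n, 1, p_x)
  t_true <- rexp(n, rate * exp(beta * x))
  cens <- runif(n, cmin, cmax)
  data.frame(time = pmin(t_true, cens), event = as.integer(t_true <= cens),
             x = x)
}

# brute-force maximally selected log-rank scan using survival::survdiff as
# the independent statistic (sign-free)
maxstat_brute <- function(values, time, event, minprop = 0.1) {
  n <- length(values)
  sv <- sort(unique(values))
  mids <- (sv[-length(sv)] + sv[-1]) / 2
  mins <- ceiling(minprop * n)
  ok <- vapply(mids, function(c0) {
    nl <- sum(values <= c0); nl >= mins && (n - nl) >= mins
  }, logical(1))
  mids <- mids[ok]
  zs <- vapply(mids, function(c0) {
    g <- factor(values > c0)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    sqrt(sd$chisq)
  }, numeric(1))
  best <- which.max(zs)
  list(cutoff = mids[best], statistic = zs[best])
}
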
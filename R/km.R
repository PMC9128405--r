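#' Kaplan-Meier estimation with Greenwood confidence intervals
#'
#' Product-limit estimator S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i), with Greenwood's variance
#' Var(S) = S^2 * sum d_i / (n_i (n_i - d_i)) and, by default, 95%
#' intervals on the log(-log S) scale (bounded inside [0, 1]).
#'
#' @name kaplan-meier
NULL

# core product-limit computation on one sample
.km_curve <- function(time, event, conf_type = "log-log", conf_level = 0.95) {
  stopifnot(length(time) == length(event), length(time) >= 1,
            all(time > 0), all(event %in% c(0, 1, FALSE, TRUE)))
  event <- as.integer(event)
  ut <- sort(unique(time[event == 1]))
  n <- length(time)
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))  # Inf if S hits 0
  var_s <- surv^2 * gw
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (conf_type == "log-log") {
    ok <- surv > 0 & surv < 1
    se_ll <- rep(0, length(surv))
    se_ll[ok] <- sqrt(gw[ok]) / abs(log(surv[ok]))
    lower <- upper <- surv
    lower[ok] <- surv[ok]^exp(z * se_ll[ok])
    upper[ok] <- surv[ok]^exp(-z * se_ll[ok])
    lower[surv == 0] <- 0; upper[surv == 0] <- 0
  } else {
    se <- sqrt(var_s)
    lower <- pmax(surv - z * se, 0)
    upper <- pmin(surv + z * se, 1)
  }
  list(time = ut, n_risk = n_risk, n_event = n_event, surv = surv,
       var = var_s, lower = lower, upper = upper,
       n = n, n_events = sum(event), max_time = max(time),
       conf_type = conf_type, conf_level = conf_level)
}

#' Fit Kaplan-Meier curves
#'
#' @param formula `survival::Surv(time, event) ~ 1` for a single curve or
#'   `~ group` for one curve per stratum.
#' @param data data.frame holding the variables.
#' @param conf_type `"log-log"` (default, the conventional bounded
#'   transform) or `"plain"` (linear scale).
#' @param conf_level confidence level; default 0.95.
#' @return object of class `km_fit`: list of per-stratum curves, each with
#'   event times, at-risk and event counts, the survival step function,
#'   Greenwood variance and confidence bounds.
#' @examples
#' d <- data.frame(t = c(1, 2, 3), e = c(1, 1, 1))
#' fit <- km_fit(survival::Surv(t, e) ~ 1, d)
#' survival_at(fit, 2)   # 1/3
#' @export
km_fit <- function(formula, data, conf_type = c("log-log", "plain"),
                   conf_level = 0.95) {
  conf_type <- match.arg(conf_type)
  if (nrow(data) == 0L) stop("empty input: no observations")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) stop("left-hand side must be a survival::Surv object")
  if (nrow(y) == 0L) stop("empty input: no observations")
  time <- y[, "time"]; event <- y[, "status"]
  groups <- if (ncol(mf) > 1L) interaction(mf[, -1L, drop = FALSE], drop = TRUE)
            else factor(rep("all", length(time)))
  strata <- lapply(split(seq_along(time), groups), function(idx)
    .km_curve(time[idx], event[idx], conf_type, conf_level))
  structure(list(strata = strata, formula = formula,
                 conf_type = conf_type, conf_level = conf_level),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step evaluation: S(t) is the post-jump value at event
#' times. Times beyond the last observed time carry the last value
#' forward, flagged in the `truncated` column.
#'
#' @param fit a `km_fit` (all strata are evaluated) or a single stratum.
#' @param t vector of times (>= 0).
#' @return data.frame: `stratum`, `time`, `surv`, `lower`, `upper`,
#'   `truncated`.
#' @export
survival_at <- function(fit, t) {
  stopifnot(all(t >= 0))
  eval1 <- function(curve, nm) {
    idx <- findInterval(t, curve$time)      # 0 before first event time
    pick <- function(v, default) ifelse(idx == 0, default, v[pmax(idx, 1)])
    data.frame(stratum = nm, time = t,
               surv = pick(curve$surv, 1),
               lower = pick(curve$lower, 1),
               upper = pick(curve$upper, 1),
               truncated = t > curve$max_time)
  }
  if (inherits(fit, "km_fit")) {
    out <- do.call(rbind, Map(eval1, fit$strata, names(fit$strata)))
    rownames(out) <- NULL
    out
  } else eval1(fit, "all")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier estimate\n")
  for (nm in names(x$strata)) {
    s <- x$strata[[nm]]
    cat(sprintf("  %s: n = %d, events = %d, final S = %.3f\n",
                nm, s$n, s$n_events,
                if (length(s$surv)) s$surv[length(s$surv)] else 1))
  }
  invisible(x)
}

#' @export
summary.km_fit <- function(object, times = NULL, ...) {
  if (!is.null(times)) return(survival_at(object, times))
  do.call(rbind, lapply(names(object$strata), function(nm) {
    s <- object$strata[[nm]]
    if (length(s$time) == 0L)
      return(data.frame(stratum = character(0), time = numeric(0),
                        n_risk = numeric(0), n_event = numeric(0),
                        surv = numeric(0), lower = numeric(0),
                        upper = numeric(0)))
    data.frame(stratum = nm, time = s$time, n_risk = s$n_risk,
               n_event = s$n_event, surv = s$surv,
               lower = s$lower, upper = s$upper)
  }))
}

#' Plot Kaplan-Meier curves
#'
#' Step curves per stratum with optional confidence bands.
#'
#' @param x a `km_fit`.
#' @param conf draw confidence bands (dashed); default TRUE for a single
#'   stratum.
#' @param col colours recycled over strata.
#' @param xlab,ylab,... passed to [graphics::plot()].
#' @export
plot.km_fit <- function(x, conf = length(x$strata) == 1L,
                        col = seq_along(x$strata),
                        xlab = "Months", ylab = "Survival probability", ...) {
  xmax <- max(vapply(x$strata, function(s) s$max_time, numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(x$strata)) {
    s <- x$strata[[i]]
    tt <- c(0, s$time); ss <- c(1, s$surv)
    graphics::lines(stats::stepfun(s$time, ss), do.points = FALSE,
                    col = col[i], lwd = 2, xval = c(tt, xmax))
    if (conf && length(s$time)) {
      graphics::lines(stats::stepfun(s$time, c(1, s$lower)),
                      do.points = FALSE, col = col[i], lty = 2)
      graphics::lines(stats::stepfun(s$time, c(1, s$upper)),
                      do.points = FALSE, col = col[i], lty = 2)
    }
  }
  if (length(x$strata) > 1L)
    graphics::legend("bottomleft", legend = names(x$strata),
                     col = col, lwd = 2, bty = "n")
  invisible(x)
}
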
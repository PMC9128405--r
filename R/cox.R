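#' Cox proportional hazards regression
#'
#' Newton-Raphson maximisation of the Cox partial likelihood with Efron
#' (default) or Breslow handling of tied event times. Convergence is
#' declared when the largest score component falls below 1e-9 or the
#' log partial likelihood changes by less than 1e-10. Standard errors are
#' Wald, from the inverse observed information; factors are dummy-coded
#' against their first (reference) level.
#'
#' @name cox
NULL

# log partial likelihood, score and observed information at beta.
# x is the (centred) design matrix, sorted jointly with time/event.
.cox_eval <- function(beta, time, event, x, ties) {
  n <- nrow(x); p <- ncol(x)
  lp <- drop(x %*% beta)
  w <- exp(lp)
  ord <- order(time, decreasing = TRUE)     # grow the risk set backwards
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    t0 <- time[ord[i]]
    j <- i
    while (j <= n && time[ord[j]] == t0) j <- j + 1L
    idx <- ord[i:(j - 1L)]
    xb <- x[idx, , drop = FALSE]; wb <- w[idx]
    S0 <- S0 + sum(wb)
    S1 <- S1 + colSums(wb * xb)
    S2 <- S2 + crossprod(xb, wb * xb)
    dead <- idx[event[idx] == 1L]
    d <- length(dead)
    if (d > 0L) {
      xd <- x[dead, , drop = FALSE]
      ll <- ll + sum(lp[dead])
      U <- U + colSums(xd)
      if (ties == "breslow" || d == 1L) {
        ll <- ll - d * log(S0)
        U <- U - d * (S1 / S0)
        I <- I + d * (S2 / S0 - tcrossprod(S1) / S0^2)
      } else {                               # efron
        s0d <- sum(w[dead])
        s1d <- colSums(w[dead] * xd)
        s2d <- crossprod(xd, w[dead] * xd)
        for (l in 0:(d - 1L)) {
          f <- l / d
          den <- S0 - f * s0d
          a <- S1 - f * s1d
          b <- S2 - f * s2d
          ll <- ll - log(den)
          U <- U - a / den
          I <- I + b / den - tcrossprod(a) / den^2
        }
      }
    }
    i <- j
  }
  list(ll = ll, U = U, I = I)
}

#' Fit a Cox proportional hazards model
#'
#' @param formula `survival::Surv(time, event) ~ terms`; factors are
#'   dummy-coded against their first level (set reference levels with
#'   [stats::relevel()] or factor level order).
#' @param data data.frame with the model variables.
#' @param ties `"efron"` (default) or `"breslow"` tie correction.
#' @param max_iter Newton-Raphson iteration cap; default 25, with step
#'   halving when a step decreases the partial likelihood.
#' @return object of class `cox_fit` with coefficients, Wald standard
#'   errors, variance matrix, log partial likelihood (null and fitted),
#'   event count and per-term bookkeeping. `summary()` prints hazard
#'   ratios with 95% confidence intervals and Wald p-values.
#' @details A covariate with zero variance raises a design error. A
#'   monotone partial likelihood (perfect separation) is reported as a
#'   non-convergence error naming the runaway term.
#' @examples
#' d <- data.frame(t = c(4, 3, 1, 1, 2, 2, 3), e = c(1, 1, 1, 0, 1, 1, 0),
#'                 x = c(0, 2, 1, 1, 1, 0, 0))
#' coef(cox_fit(survival::Surv(t, e) ~ x, d))
#' @export
cox_fit <- function(formula, data, ties = c("efron", "breslow"),
                    max_iter = 25L) {
  ties <- match.arg(ties)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) stop("left-hand side must be a survival::Surv object")
  time <- y[, "time"]; event <- as.integer(y[, "status"])
  if (sum(event) == 0L) stop("degenerate outcome: no events")
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  assign <- attr(X, "assign")
  int <- which(assign == 0L)
  if (length(int)) { X <- X[, -int, drop = FALSE]; assign <- assign[-int] }
  if (ncol(X) == 0L) stop("no covariates in the model")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("design error: zero-variance term ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  means <- colMeans(X)
  Xc <- sweep(X, 2, means)

  p <- ncol(Xc)
  beta <- numeric(p)
  ev <- .cox_eval(beta, time, event, Xc, ties)
  ll0 <- ev$ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(ev$I, ev$U), error = function(e)
      stop("non-convergence: singular information matrix"))
    new_beta <- beta + step
    new_ev <- .cox_eval(new_beta, time, event, Xc, ties)
    halve <- 0L
    while (new_ev$ll < ev$ll && halve < 10L) {   # step halving
      step <- step / 2
      new_beta <- beta + step
      new_ev <- .cox_eval(new_beta, time, event, Xc, ties)
      halve <- halve + 1L
    }
    dll <- new_ev$ll - ev$ll
    beta <- new_beta; ev <- new_ev
    if (max(abs(ev$U)) < 1e-9 || abs(dll) < 1e-10) { converged <- TRUE; break }
  }
  if (!converged || any(abs(beta) > 15)) {
    worst <- colnames(X)[which.max(abs(beta))]
    stop("non-convergence (monotone likelihood?) for term: ", worst)
  }
  vcov <- solve(ev$I)
  se <- sqrt(diag(vcov))
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))

  term_labels <- attr(mt, "term.labels")
  structure(list(
    coefficients = beta, se = stats::setNames(se, colnames(X)),
    vcov = vcov, loglik = c(null = ll0, fitted = ev$ll),
    n = length(time), nevent = sum(event),
    ties = ties, iter = it, formula = formula,
    assign = assign, term_labels = term_labels,
    xlevels = stats::.getXlevels(mt, mf), means = means,
    terms = mt
  ), class = "cox_fit")
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$vcov

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik[["fitted"]], df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.cox_fit <- function(object, newdata = NULL,
                            type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) stop("newdata is required")
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  X <- X[, names(object$coefficients), drop = FALSE]
  lp <- drop(sweep(X, 2, object$means) %*% object$coefficients)
  if (type == "lp") lp else exp(lp)
}

#' Block Wald test for a whole model term
#'
#' Tests all dummy columns of a term jointly (chi-square on as many df as
#' the term has columns) - the unit at which categorical factors enter or
#' leave backward selection.
#'
#' @param fit a `cox_fit`.
#' @param term a term label from the model formula; default all terms.
#' @return data.frame: `term`, `df`, `chisq`, `p`.
#' @export
wald_test <- function(fit, term = NULL) {
  labs <- fit$term_labels
  if (is.null(term)) term <- labs
  out <- lapply(term, function(tm) {
    j <- which(fit$assign == match(tm, labs))
    if (length(j) == 0L) stop("unknown term: ", tm)
    b <- fit$coefficients[j]
    chisq <- drop(t(b) %*% solve(fit$vcov[j, j, drop = FALSE], b))
    data.frame(term = tm, df = length(j), chisq = chisq,
               p = stats::pchisq(chisq, length(j), lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$nevent))
  print(round(rbind(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                    se = x$se), 4))
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- object$coefficients; se <- object$se
  tab <- data.frame(
    term = names(b), coef = b, se = se, hr = exp(b),
    hr_lower = exp(b - z * se), hr_upper = exp(b + z * se),
    p = 2 * stats::pnorm(-abs(b / se)), row.names = NULL)
  structure(list(table = tab, blocks = wald_test(object),
                 n = object$n, nevent = object$nevent,
                 loglik = object$loglik, ties = object$ties),
            class = "summary.cox_fit")
}

#' @export
print.summary.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (%s ties): n = %d, events = %d, logPL = %.3f\n",
              x$ties, x$n, x$nevent, x$loglik[["fitted"]]))
  tab <- x$table
  tab$hr <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$hr_lower, tab$hr_upper)
  tab$p <- format.pval(tab$p, digits = 3)
  print(tab[, c("term", "coef", "se", "hr", "p")], row.names = FALSE,
        digits = 3)
  invisible(x)
}
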
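#' Log-rank tests
#'
#' Observed-minus-expected statistics with hypergeometric variance summed
#' over event times; the k-group chi-square drops one group and inverts
#' the (k-1)-dimensional covariance block.
#'
#' @name logrank
NULL

# two-group tally: O, E and hypergeometric variance for group TRUE,
# single O(n log n) pass; `g` is a logical grouping vector
.logrank_2group <- function(time, event, g) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- as.integer(event[ord]); g_s <- as.integer(g[ord])
  n <- length(t_s)
  first <- which(!duplicated(t_s))           # first index of each unique time
  last <- c(first[-1] - 1L, n)
  cs_e <- cumsum(e_s); cs_eg <- cumsum(e_s * g_s)
  rc_g <- rev(cumsum(rev(g_s)))              # group-1 at risk from index i on
  d  <- cs_e[last] - c(0, cs_e[last])[seq_along(last)]
  d1 <- cs_eg[last] - c(0, cs_eg[last])[seq_along(last)]
  n_at <- n - first + 1L
  n1_at <- rc_g[first]
  keep <- d > 0
  d <- d[keep]; d1 <- d1[keep]; n_at <- n_at[keep]; n1_at <- n1_at[keep]
  O <- sum(d1)
  E <- sum(d * n1_at / n_at)
  vterm <- ifelse(n_at > 1,
                  d * (n1_at / n_at) * (1 - n1_at / n_at) *
                    (n_at - d) / (n_at - 1), 0)
  V <- sum(vterm)
  list(O = O, E = E, V = V)
}

# standardized two-group log-rank statistic (signed); NA if variance 0
.logrank_z <- function(time, event, g) {
  tl <- .logrank_2group(time, event, g)
  if (tl$V <= 0) return(NA_real_)
  (tl$O - tl$E) / sqrt(tl$V)
}

#' k-group log-rank test
#'
#' @param time,event follow-up times (> 0) and event indicators (0/1).
#' @param group vector of k >= 2 group labels; every level must be
#'   populated.
#' @return list of class `logrank_test`: `chisq`, `df` (k - 1), `p`,
#'   per-group observed and expected event counts.
#' @examples
#' # two identical groups carry no signal: chisq = 0, p = 1
#' lr <- logrank_test(rep(c(2, 4, 6), 2), rep(1, 6), rep(c("a", "b"), each = 3))
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2L) stop("grouping error: need at least 2 groups")
  if (any(table(group) == 0L)) stop("grouping error: empty group")
  stopifnot(length(time) == length(event), length(time) == length(group))

  lev <- levels(group)
  ord <- order(time)
  t_s <- time[ord]; e_s <- as.integer(event[ord]); g_s <- group[ord]
  n <- length(t_s)
  OmE <- numeric(k); Obs <- numeric(k); Exp <- numeric(k)
  V <- matrix(0, k, k)
  ut <- unique(t_s[e_s == 1L])
  for (t0 in ut) {
    at <- t_s >= t0
    n_at <- sum(at)
    d <- sum(e_s == 1L & t_s == t0)
    ng <- vapply(lev, function(l) sum(at & g_s == l), numeric(1))
    dg <- vapply(lev, function(l) sum(e_s == 1L & t_s == t0 & g_s == l),
                 numeric(1))
    p <- ng / n_at
    Obs <- Obs + dg
    Exp <- Exp + d * p
    if (n_at > 1) {
      c0 <- d * (n_at - d) / (n_at - 1)
      V <- V + c0 * (diag(p, k) - tcrossprod(p))
    }
  }
  omE <- Obs - Exp
  sub <- seq_len(k - 1L)
  vs <- V[sub, sub, drop = FALSE]
  chisq <- tryCatch(
    drop(t(omE[sub]) %*% solve(vs, omE[sub])),
    error = function(e) {
      vi <- .ginv(vs)
      drop(t(omE[sub]) %*% vi %*% omE[sub])
    })
  structure(list(chisq = chisq, df = k - 1L,
                 p = stats::pchisq(chisq, k - 1L, lower.tail = FALSE),
                 observed = stats::setNames(Obs, lev),
                 expected = stats::setNames(Exp, lev),
                 n = n), class = "logrank_test")
}

# Moore-Penrose pseudoinverse via SVD (singular covariance fallback)
.ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.3f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  tab <- data.frame(observed = x$observed, expected = round(x$expected, 2))
  print(tab)
  invisible(x)
}
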
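#' 2x2 contingency table
#'
#' Rows: exposure present/absent (e.g. baseline pulsation); columns:
#' event/no-event (e.g. longitudinal size change / stable).
#'
#' @param a,b,c,d non-negative counts: `a` exposed events, `b` exposed
#'   non-events, `c` unexposed events, `d` unexposed non-events.
#' @return an object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0), all(counts == round(counts)), sum(counts) >= 1)
  structure(as.list(counts), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

.hyper_support <- function(t) {
  m <- t$a + t$b; n <- t$c + t$d; k <- t$a + t$c
  list(m = m, n = n, k = k, x = max(0, k - n):min(k, m))
}

#' Two-sided Fisher exact test (point-probability method)
#'
#' Sums, over all 2x2 tables with the observed margins, the hypergeometric
#' probabilities that do not exceed the probability of the observed table.
#' Tables with an empty margin admit a single configuration and return
#' `p = 1` by convention.
#'
#' @param t a [contingency_2x2()].
#' @return two-sided p-value.
#' @export
fisher_exact_two_sided <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  s <- .hyper_support(t)
  if (length(s$x) == 1) return(1)
  probs <- dhyper(s$x, s$m, s$n, s$k)
  p_obs <- dhyper(t$a, s$m, s$n, s$k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

.noncentral_hyper <- function(s, log_psi) {
  lw <- lchoose(s$m, s$x) + lchoose(s$n, s$k - s$x) + s$x * log_psi
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Conditional-MLE odds ratio with exact confidence interval
#'
#' Point estimate: the odds ratio psi of the noncentral hypergeometric
#' distribution (conditioning on both margins) under which the expected
#' count in cell `a` equals the observed one. Confidence limits invert the
#' one-sided exact conditional tests at `(1 - level)/2` per side. Tables
#' observed at the boundary of the conditional support yield 0 or `Inf`
#' point estimates with one-sided intervals.
#'
#' @param t a [contingency_2x2()].
#' @param level confidence level.
#' @return list with `point`, `ci_low`, `ci_high`, `method`.
#' @export
conditional_or <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_2x2"), level > 0, level < 1)
  s <- .hyper_support(t)
  if (length(s$x) == 1) stop("degenerate margins: conditional support is a single table")
  alpha <- (1 - level) / 2
  expect_a <- function(log_psi) sum(s$x * .noncentral_hyper(s, log_psi))
  p_upper_tail <- function(log_psi) {  # P(X >= a)
    w <- .noncentral_hyper(s, log_psi)
    sum(w[s$x >= t$a])
  }
  p_lower_tail <- function(log_psi) {  # P(X <= a)
    w <- .noncentral_hyper(s, log_psi)
    sum(w[s$x <= t$a])
  }
  solve_log <- function(f, target) {
    g <- function(lp) f(lp) - target
    lo <- -1; hi <- 1
    while (g(lo) * g(hi) > 0 && hi < 745) { lo <- lo * 1.6; hi <- hi * 1.6 }
    uniroot(g, c(lo, hi), tol = 1e-10)$root
  }

  at_min <- t$a == min(s$x); at_max <- t$a == max(s$x)
  point <- if (at_min) 0 else if (at_max) Inf else exp(solve_log(expect_a, t$a))
  ci_low <- if (at_min) 0 else exp(solve_log(p_upper_tail, alpha))
  ci_high <- if (at_max) Inf else exp(solve_log(p_lower_tail, alpha))
  list(point = point, ci_low = ci_low, ci_high = ci_high,
       method = "conditional MLE, exact conditional inversion")
}

.wilson_ci <- function(k, n, z) {
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Risk difference with Newcombe hybrid-score interval
#'
#' Point estimate `a/(a+b) - c/(c+d)`; the confidence interval combines the
#' Wilson score limits of the two proportions (Newcombe's method 10), which
#' behaves sensibly at 0/n and n/n proportions where a Wald interval
#' degenerates.
#'
#' @param t a [contingency_2x2()].
#' @param level confidence level.
#' @return list with `point`, `ci_low`, `ci_high`, `method`.
#' @export
risk_difference <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_2x2"))
  n1 <- t$a + t$b; n2 <- t$c + t$d
  if (n1 < 1 || n2 < 1) stop("both rows need at least one observation")
  z <- qnorm(1 - (1 - level) / 2)
  p1 <- t$a / n1; p2 <- t$c / n2
  w1 <- .wilson_ci(t$a, n1, z); w2 <- .wilson_ci(t$c, n2, z)
  point <- p1 - p2
  list(point = point,
       ci_low = point - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2),
       ci_high = point + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2),
       method = "Newcombe hybrid score")
}

#' Hedges' g standardised mean difference from group summaries
#'
#' Pooled-SD Cohen's d with the small-sample correction
#' `J = 1 - 3 / (4 (n1 + n2 - 2) - 1)`; the normal-approximation confidence
#' interval uses `SE = J * sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2)))`.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @param level confidence level.
#' @return list with `point`, `ci_low`, `ci_high`, `method`.
#' @export
hedges_g <- function(m1, sd1, n1, m2, sd2, n2, level = 0.95) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled SD is zero")
  d <- (m1 - m2) / sp
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  se <- J * sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- qnorm(1 - (1 - level) / 2)
  list(point = g, ci_low = g - z * se, ci_high = g + z * se,
       method = "Hedges' g, normal-approximation CI")
}

#' Spearman rank correlation
#'
#' Average ranks for ties; the p-value is exact (full enumeration of rank
#' permutations) for `n <= 9` and uses the t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `rho`, `p`, `n`, `method`, `status` (`"ok"` or
#'   `"undefined"` for constant input).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "spearman",
                status = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    p <- .spearman_perm_p(rx, ry)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- min(1, 2 * stats::pt(-abs(tstat), n - 2))
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method, status = "ok")
}

#' Mann-Whitney U test
#'
#' `U` counts pairs where an `x` observation exceeds a `y` observation (ties
#' count 1/2). The two-sided p-value is exact, tie-aware, by enumeration of
#' all group assignments for combined `n <= 12`, and uses the tie-corrected
#' normal approximation with continuity correction otherwise.
#'
#' @param x,y numeric samples (both nonempty).
#' @param exact_max maximum combined size for exact enumeration.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  comb <- c(x, y)
  r <- rank(comb)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  U <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  if (N <= exact_max) {
    sets <- combn(N, n1)
    us <- apply(sets, 2, u_of)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(comb)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    z <- (abs(U - mu) - 0.5) / sigma
    p <- min(1, 2 * pnorm(-max(0, z)))
    method <- "normal approximation, tie-corrected"
  }
  list(U = U, p = p, method = method)
}
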
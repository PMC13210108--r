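swp_table <- contingency_2x2(6, 3, 0, 2)
gvp_table <- contingency_2x2(4, 4, 2, 1)

test_that("two-sided Fisher p-values match enumeration and base R", {
  expect_equal(fisher_exact_two_sided(swp_table), 84 / 462, tolerance = 1e-12)
  expect_equal(round(fisher_exact_two_sided(swp_table), 2), 0.18)
  expect_equal(fisher_exact_two_sided(gvp_table), 1, tolerance = 1e-12)

  # both extreme tables with unit margins have probability 1/2
  expect_equal(fisher_exact_two_sided(contingency_2x2(1, 0, 0, 1)), 1)

  # empty-margin convention
  expect_equal(fisher_exact_two_sided(contingency_2x2(0, 0, 3, 2)), 1)

  set.seed(5)
  for (i in 1:200) {
    n <- sample(1:20, 1)
    cell <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
    t <- contingency_2x2(cell[1], cell[2], cell[3], cell[4])
    p <- fisher_exact_two_sided(t)
    expect_gte(p, 0); expect_lte(p, 1)
    ref <- stats::fisher.test(matrix(c(cell[1], cell[3], cell[2], cell[4]), 2))
    expect_equal(p, ref$p.value, tolerance = 1e-9)
    # transpose invariance (swapping rows with columns)
    expect_equal(p, fisher_exact_two_sided(
      contingency_2x2(cell[1], cell[3], cell[2], cell[4])), tolerance = 1e-12)
  }
})

test_that("conditional odds ratio matches exact conditional inference", {
  or_gvp <- conditional_or(gvp_table)
  expect_equal(round(or_gvp$point, 2), 0.53)
  ref <- stats::fisher.test(matrix(c(4, 2, 4, 1), 2))
  expect_equal(or_gvp$point, unname(ref$estimate), tolerance = 1e-4)
  expect_equal(or_gvp$ci_low, as.numeric(ref$conf.int[1]), tolerance = 5e-3)
  expect_equal(or_gvp$ci_high, as.numeric(ref$conf.int[2]), tolerance = 5e-3)

  or_swp <- conditional_or(swp_table)
  expect_identical(or_swp$point, Inf)
  expect_identical(or_swp$ci_high, Inf)
  expect_equal(round(or_swp$ci_low, 2), 0.24)

  expect_equal(conditional_or(contingency_2x2(2, 2, 2, 2))$point, 1,
               tolerance = 1e-9)

  # direction: point < 1 iff observed a is below its null expectation
  set.seed(11)
  for (i in 1:50) {
    cell <- as.vector(stats::rmultinom(1, sample(6:25, 1), rep(0.25, 4))) + 1
    t <- contingency_2x2(cell[1], cell[2], cell[3], cell[4])
    est <- conditional_or(t)$point
    m <- cell[1] + cell[2]; n2 <- cell[3] + cell[4]; k <- cell[1] + cell[3]
    e_null <- k * m / (m + n2)
    if (abs(cell[1] - e_null) > 1e-9) {
      expect_equal(est < 1, cell[1] < e_null)
    }
  }

  expect_error(conditional_or(contingency_2x2(2, 0, 3, 0)), "degenerate")
})

test_that("risk differences use the Newcombe hybrid-score interval", {
  rd_swp <- risk_difference(swp_table)
  expect_equal(round(rd_swp$point, 2), 0.67)
  expect_equal(round(rd_swp$ci_low, 2), -0.06)
  expect_equal(round(rd_swp$ci_high, 2), 0.88)

  rd_gvp <- risk_difference(gvp_table)
  expect_equal(round(rd_gvp$point, 2), -0.17)

  eq <- risk_difference(contingency_2x2(3, 3, 2, 2))
  expect_equal(eq$point, 0)

  set.seed(3)
  for (i in 1:100) {
    cell <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    if (cell[1] + cell[2] == 0 || cell[3] + cell[4] == 0) next
    rd <- risk_difference(contingency_2x2(cell[1], cell[2], cell[3], cell[4]))
    expect_lte(rd$ci_low, rd$point + 1e-12)
    expect_gte(rd$ci_high, rd$point - 1e-12)
    expect_gte(rd$ci_low, -1); expect_lte(rd$ci_high, 1)
  }
})

test_that("Hedges' g reproduces the hand-evaluated formulas", {
  g <- hedges_g(19.1, 11.6, 6, 16.8, 5.6, 5)
  expect_equal(round(g$point, 2), 0.22)
  expect_equal(round(g$ci_low, 2), -0.87)
  expect_equal(round(g$ci_high, 2), 1.31)

  # J for 9 degrees of freedom and g = J * d by direct evaluation
  sp <- sqrt((5 * 11.6^2 + 4 * 5.6^2) / 9)
  J <- 1 - 3 / 35
  expect_equal(J, 0.9142857, tolerance = 1e-6)
  expect_equal(g$point, J * (19.1 - 16.8) / sp, tolerance = 1e-12)

  expect_equal(hedges_g(5, 2, 8, 5, 3, 9)$point, 0)

  swapped <- hedges_g(16.8, 5.6, 5, 19.1, 11.6, 6)
  expect_equal(swapped$point, -g$point, tolerance = 1e-12)
  expect_equal(swapped$ci_low, -g$ci_high, tolerance = 1e-12)
  expect_equal(swapped$ci_high, -g$ci_low, tolerance = 1e-12)

  expect_error(hedges_g(1, 0, 5, 1, 0, 5), "pooled SD")
})

test_that("Spearman correlation is exact for small n", {
  expect_equal(spearman_rho(1:6, c(2, 4, 5, 7, 9, 20))$rho, 1)
  expect_equal(spearman_rho(1:6, rev(c(2, 4, 5, 7, 9, 20)))$rho, -1)

  # full enumeration oracle at n = 5
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  x <- c(3, 1, 4, 1.5, 9); y <- c(2, 7, 1, 8, 2.8)
  res <- spearman_rho(x, y)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  all_p <- vapply(perms(ry), function(p) abs(cor(rx, p)), 0)
  expect_equal(res$p, mean(all_p >= obs - 1e-12), tolerance = 1e-12)
  expect_equal(res$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(res$p,
               suppressWarnings(cor.test(x, y, method = "spearman")$p.value),
               tolerance = 1e-9)

  expect_identical(spearman_rho(rep(1, 5), 1:5)$status, "undefined")

  # large-n branch agrees with the t approximation in cor.test
  set.seed(8)
  x2 <- rnorm(25); y2 <- x2 + rnorm(25)
  r2 <- spearman_rho(x2, y2)
  ref <- suppressWarnings(cor.test(x2, y2, method = "spearman"))
  expect_equal(r2$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("Mann-Whitney U is exact and tie-aware for small samples", {
  sep <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1, tolerance = 1e-12)    # 2 / C(6,3)

  same <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$U, 4.5)                       # at its null mean
  expect_equal(same$p, 1)

  set.seed(13)
  for (i in 1:30) {
    x <- sample(1:6, 5, replace = TRUE)
    y <- sample(1:6, 6, replace = TRUE)
    mine <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(unname(mine$U), unname(ref$statistic), tolerance = 1e-12)
  }

  # without ties the exact p matches wilcox.test exactly
  for (i in 1:20) {
    x <- sample(1:100, 5); y <- sample(101:200, 6) - sample(1:150, 6)
    mine <- mann_whitney_u(x, y)
    if (!any(duplicated(c(x, y)))) {
      ref <- wilcox.test(x, y, exact = TRUE)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  }

  # continuity-corrected normal approximation tracks the exact answer at
  # n = 6 vs 6 (worst case ~0.016 across random draws)
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    exact <- mann_whitney_u(x, y)$p
    approx <- mann_whitney_u(x, y, exact_max = 0)$p
    expect_lt(abs(exact - approx), 0.02)
  }
})
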
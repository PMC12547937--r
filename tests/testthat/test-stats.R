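test_that("one-sample Wilcoxon vs 1 behaves at its analytic extremes", {
  # symmetric around 1 -> no evidence
  sym <- 1 + c(-0.3, -0.2, -0.1, 0.1, 0.2, 0.3)
  r <- one_sample_wilcoxon_vs_1(sym)
  expect_gt(r$p, 0.9)
  expect_equal(r$median, 1)

  # all above 1, n = 10, tie-free: minimal attainable exact p = 2/2^10
  set.seed(5)
  up <- 1 + sort(runif(10, 0.1, 1))
  r2 <- one_sample_wilcoxon_vs_1(up)
  expect_equal(r2$p, 2 / 2^10)
  expect_equal(r2$n_dropped, 0)

  # ties at exactly 1 are dropped and counted
  r3 <- one_sample_wilcoxon_vs_1(c(rep(1, 3), up))
  expect_equal(r3$n_dropped, 3)
  expect_error(one_sample_wilcoxon_vs_1(c(1, 1, 1, 1.1, 1.2, 1)),
               ">= 5")
})

test_that("median CI from order statistics covers the true median", {
  set.seed(6)
  hits <- 0
  for (i in 1:200) {
    x <- exp(rnorm(25, 0, 0.4))    # true median 1
    ci <- one_sample_wilcoxon_vs_1(x)$ci
    if (ci[1] <= 1 && 1 <= ci[2]) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.9)       # nominal 95%, conservative
})

test_that("Friedman statistic is null on identical columns and detects shifts", {
  m <- matrix(rep(c(1, 2, 3, 4, 5), 3), ncol = 3)
  colnames(m) <- c("a", "b", "c")
  # identical columns tie within every block: statistic 0
  r <- friedman_dunn(m)
  expect_equal(r$friedman_chisq, 0)
  expect_gt(r$friedman_p, 0.99)

  set.seed(7)
  m2 <- matrix(rnorm(30), ncol = 3)
  m2[, 3] <- m2[, 3] + 10
  colnames(m2) <- c("ctrl", "x", "far")
  r2 <- friedman_dunn(m2, control = "ctrl")
  expect_lt(r2$friedman_p, 0.001)
  far_row <- r2$pairwise[grepl("far", r2$pairwise$comparison), ]
  expect_lt(far_row$p_adj, 0.05)
})

test_that("Dunn mean ranks equal a brute-force rank computation", {
  set.seed(8)
  m <- matrix(rnorm(24), ncol = 3)
  m[, 2] <- m[, 2] + 1
  colnames(m) <- c("ctrl", "gi", "wash")
  r <- friedman_dunn(m, control = "ctrl")
  # direct rank oracle
  rk <- t(apply(m, 1, rank))
  expect_equal(unname(r$mean_ranks), unname(colMeans(rk)))
  n <- nrow(m); k <- ncol(m)
  z_expected <- (colMeans(rk)[1] - colMeans(rk)[2]) /
    sqrt(k * (k + 1) / (6 * n))
  expect_equal(r$pairwise$z[1], unname(z_expected))
  expect_equal(nrow(r$pairwise), 2)     # control-vs-treatment family only
})

test_that("group comparisons dispatch to the right designs", {
  set.seed(9)
  a <- rnorm(12)
  # a vs itself is all ties; the normal approximation is expected here
  expect_gt(suppressWarnings(group_compare(a, a,
                                           design = "mann_whitney"))$p,
            0.9)
  expect_gt(group_compare(a, a + rnorm(12, 0, 1e-8),
                          design = "paired_t")$p, 0.05)

  b <- a + 0.8                           # constant positive difference
  expect_lt(group_compare(b, a, design = "paired_t")$p, 0.001)
  expect_error(group_compare(a, a[1:3], design = "paired_t"),
               "equal lengths")
})

test_that("Dunnett decisions agree with a permutation oracle", {
  set.seed(10)
  g <- rep(c("ctrl", "t1", "t2"), each = 8)
  y <- rnorm(24)
  y[g == "t2"] <- y[g == "t2"] + 2.5
  r <- group_compare(design = "anova_dunnett", values = y, groups = g,
                     control = "ctrl")
  expect_equal(nrow(r), 2)
  p_t1 <- r$p[grepl("t1", r$comparison)]
  p_t2 <- r$p[grepl("t2", r$comparison)]
  expect_lt(p_t2, 0.01)
  expect_gt(p_t1, 0.1)

  # permutation oracle on the mean difference, per comparison
  perm_p <- function(target) {
    obs <- mean(y[g == target]) - mean(y[g == "ctrl"])
    sel <- g %in% c("ctrl", target)
    yy <- y[sel]; gg <- g[sel]
    stat <- replicate(2000, {
      sh <- sample(gg)
      mean(yy[sh == target]) - mean(yy[sh == "ctrl"])
    })
    mean(abs(stat) >= abs(obs))
  }
  expect_lt(perm_p("t2"), 0.01)
  expect_gt(perm_p("t1"), 0.1)
})

test_that("tests are invariant to input ordering and p-values are in [0,1]", {
  set.seed(11)
  x <- exp(rnorm(12, 0.3, 0.4))
  p1 <- one_sample_wilcoxon_vs_1(x)$p
  p2 <- one_sample_wilcoxon_vs_1(rev(x))$p
  expect_equal(p1, p2)
  expect_true(p1 >= 0 && p1 <= 1)
  a <- rnorm(10); b <- rnorm(10, 1)
  expect_equal(group_compare(a, b, design = "mann_whitney")$p,
               group_compare(sample(a), sample(b),
                             design = "mann_whitney")$p)
})
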
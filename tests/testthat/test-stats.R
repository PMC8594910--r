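test_that("Spearman correlation handles perfect association and ties", {
  x <- 1:6
  expect_equal(spearman_cor(x, x * 2)$estimate[["r_s"]], 1)
  expect_equal(spearman_cor(x, -x)$estimate[["r_s"]], -1)
  expect_equal(spearman_cor(x, -x, sided = "less")$p,
               1 / factorial(6), tolerance = 1e-12)
  xt <- c(1, 2, 2, 3, 4); yt <- c(5, 3, 3, 2, 1)
  expect_equal(spearman_cor(xt, yt)$estimate[["r_s"]],
               cor(xt, yt, method = "spearman"))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("small-sample Spearman p matches tie-free exact theory and an
           independent permutation oracle with ties", {
  x <- c(1, 2, 3, 4, 5, 6, 7); y <- c(2, 1, 4, 3, 6, 5, 7)
  ours <- spearman_cor(x, y, sided = "greater")
  ref <- suppressWarnings(
    cor.test(x, y, method = "spearman", alternative = "greater"))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  ## reference-table case: 7 pairs with average-rank ties in the medians
  fx <- load_fixtures()
  med <- fx$table2$median_pt_uA
  oc <- fx$table2$oc_right
  ours2 <- spearman_cor(oc, med, sided = "greater")
  ## independent oracle: lexicographic enumeration of all 7! pairings
  rx <- rank(oc); ry <- rank(med)
  P <- all_permutations_lex(7)
  allr <- apply(P, 1, function(p) cor(rx, ry[p]))
  expect_equal(ours2$p, mean(allr >= ours2$estimate[["r_s"]] - 1e-12),
               tolerance = 1e-12)
  expect_equal(ours2$estimate[["r_s"]], cor(oc, med, method = "spearman"))
})

test_that("Pearson regression matches the normal-equations oracle", {
  set.seed(6)
  for (k in 1:5) {
    x <- rnorm(8); y <- 2 * x + rnorm(8)
    pr <- pearson_regression(x, y)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(pr$estimate[["intercept"]], beta[1], tolerance = 1e-10)
    expect_equal(pr$estimate[["slope"]], beta[2], tolerance = 1e-10)
    expect_equal(pr$estimate[["r2"]], summary(lm(y ~ x))$r.squared,
                 tolerance = 1e-10)
  }
  x <- 1:5
  expect_equal(pearson_regression(x, 3 * x + 2)$estimate[["r2"]], 1)
  expect_error(pearson_regression(rep(2, 5), 1:5), "variance")
})

test_that("Friedman ANOVA matches manual ranks and friedman.test", {
  X <- matrix(c(10, 20, 30,
                12, 25, 31,
                14, 22, 33), 3, 3, byrow = TRUE)
  ## hand ranks: every row ranks 1,2,3 -> column sums 3,6,9
  fr <- friedman_anova(X, exact = FALSE)
  expect_equal(fr$statistic, 12 / (3 * 3 * 4) * sum((c(3, 6, 9) - 6)^2))
  expect_equal(fr$statistic, unname(friedman.test(X)$statistic))
  expect_equal(friedman_anova(matrix(rep(1:4, 3), 4, 3),
                              exact = FALSE)$statistic, 0)
  expect_error(friedman_anova(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("Friedman exact p matches within-row permutation enumeration", {
  set.seed(12)
  X <- matrix(rnorm(12), 4, 3)
  ours <- friedman_anova(X)     # enumerates (3!)^4 internally
  expect_true(ours$exact)
  ## independent oracle: expand.grid over lexicographic row permutations
  P <- all_permutations_lex(3)
  R <- t(apply(X, 1, rank))
  grid <- expand.grid(1:6, 1:6, 1:6, 1:6)
  stat <- function(Rp) {
    Rj <- colSums(Rp)
    S <- sum((Rj - 4 * 2)^2)
    S / (4 * 3 * 4 / 12)
  }
  obs <- stat(R)
  vals <- apply(grid, 1, function(g) {
    Rp <- R
    for (i in 1:4) Rp[i, ] <- R[i, P[g[i], ]]
    stat(Rp)
  })
  expect_equal(ours$p, mean(vals >= obs - 1e-12), tolerance = 1e-12)
})

test_that("signed-rank exact p matches full sign enumeration", {
  set.seed(13)
  x <- round(rnorm(10, 100, 20))
  y <- x + 25
  ours <- wilcoxon_signed_rank(x, y, sided = "less")
  ## independent oracle: all 2^10 sign assignments of the |d| ranks
  d <- x - y
  r <- rank(abs(d))
  n <- length(d)
  Vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, 0)
  V <- sum(r[d > 0])
  expect_equal(ours$p, mean(Vs <= V), tolerance = 1e-12)
  expect_equal(ours$statistic, V)
  ## y = x + 25 shifts every pair: V = 0, one-sided p = 2^-10
  expect_equal(ours$p, 1 / 1024, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(x, x), "degenerate")
})

test_that("signed-rank test agrees with wilcox.test when ties are absent", {
  set.seed(14)
  x <- rnorm(12); y <- x + rnorm(12, 0.3, 0.7)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("pairwise Wilcoxon applies the Bonferroni correction", {
  set.seed(15)
  X <- matrix(rnorm(30, 100, 10), 10, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  X[, 3] <- X[, 3] + 20
  out <- wilcoxon_pairwise(X)
  expect_equal(nrow(out), 3)
  expect_equal(out$p_bonferroni, pmin(1, 3 * out$p))
  out2 <- wilcoxon_pairwise(X, pairs = list(c("A", "C")), m = 21)
  expect_equal(out2$p_bonferroni, pmin(1, 21 * out2$p))
})

test_that("Mann-Whitney U matches enumeration and hand examples", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$statistic, 0)
  ## mirrored samples: U = n1 n2 / 2
  a <- c(-2, -1, 1, 2)
  expect_equal(mann_whitney(a, -a)$statistic, length(a)^2 / 2)
  set.seed(16)
  g1 <- rnorm(4); g2 <- rnorm(4, 1)
  ours <- mann_whitney(g1, g2, sided = "less")
  ## independent oracle: bitmask enumeration of the 70 labelings
  pool <- c(g1, g2); r <- rank(pool)
  labels <- which(vapply(0:255, function(m) sum(bitwAnd(bitwShiftR(m, 0:7), 1L)) == 4L, TRUE))
  Us <- vapply(labels - 1L, function(m) {
    id <- which(bitwAnd(bitwShiftR(m, 0:7), 1L) == 1L)
    sum(r[id]) - 4 * 5 / 2
  }, 0)
  U <- sum(r[1:4]) - 10
  expect_equal(ours$p, mean(Us <= U + 1e-9), tolerance = 1e-12)
  ref <- wilcox.test(g1, g2, alternative = "less", exact = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(17)
  x <- runif(9, 1, 5); y <- runif(9, 1, 5)
  expect_equal(spearman_cor(x, y)$p, spearman_cor(exp(x), y^3)$p)
  g1 <- runif(5); g2 <- runif(6)
  expect_equal(mann_whitney(g1, g2)$p, mann_whitney(log(g1), log(g2))$p)
})

test_that("distance analysis excludes So-rS and validates its input", {
  d <- data.frame(montage = c("Fp2-So", "F7-F8", "So-rS", "Cz-F8",
                              "Fp2-Cz", "Fp2-O2", "Fp2-rS"),
                  eye_cm = c(2.7, 5.5, 13.0, 7.1, 8.0, 8.6, 8.3),
                  oc_cm = c(15.1, 11.0, 16.0, 9.8, 9.0, 9.4, 14.0))
  pt <- setNames(c(75, 100, 125, 125, 175, 200, 175), d$montage)
  res <- distance_analysis(d, pt)
  expect_equal(res$eye$n, 6)              # So-rS dropped
  expect_s3_class(res$eye, "stats_result")
  dd <- d; dd$eye_cm <- 5
  expect_error(distance_analysis(dd, pt), "variance")
  expect_error(distance_analysis(d[1:3, ], pt), "fewer than 3")
})
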
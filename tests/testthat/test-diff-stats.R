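test_that("Welch statistic matches t.test and the hand formula", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  w <- welch_statistic(x, y)
  tt <- t.test(x, y)
  expect_equal(w$t, unname(tt$statistic))
  expect_equal(w$df, unname(tt$parameter))
  expect_equal(w$p, tt$p.value)
  # direct formula
  se <- sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(w$t, (mean(x) - mean(y)) / se)

  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 2))
    w <- welch_statistic(a, b); tt <- t.test(a, b)
    expect_equal(w$t, unname(tt$statistic))
    expect_equal(w$p, tt$p.value)
  }

  # identical groups: t = 0, p = 1
  w0 <- welch_statistic(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  expect_error(welch_statistic(1, c(1, 2)), "2 finite")
})

test_that("S0 statistic damps the standard error and collapses correctly", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_equal(s0_statistic(x, y, 0), welch_statistic(x, y)$t)
  # hand case: diff 2, se 0.5, s0 2 -> 0.8
  x2 <- c(2.5, 3, 3.5)   # mean 3, var 0.25 -> var/n = 1/12
  y2 <- c(0.5, 1, 1.5)   # same spread
  se <- sqrt(2 / 12)
  expect_equal(s0_statistic(x2, y2, 2), 2 / (se + 2))
  expect_equal(s0_statistic(c(10, 12), c(2, 3), 1e9), 0, tolerance = 1e-7)
  expect_error(s0_statistic(x, y, -1))
})

test_that("permutation FDR is reproducible, downward-closed, and finds planted effects", {
  set.seed(31)
  mat <- matrix(rnorm(400 * 10, 0, 0.2), 400, 10,
                dimnames = list(paste0("f", 1:400), NULL))
  mat[1:4, 6:10] <- mat[1:4, 6:10] + 3
  g <- factor(rep(c("AO", "UT"), c(5, 5)), levels = c("AO", "UT"))
  # note column order: first five are group AO here
  r1 <- permutation_fdr(mat, rep(c("UT", "AO"), each = 5) |>
                          factor(levels = c("AO", "UT")),
                        s0 = 2, fdr_level = 0.01, n_permutations = 100, seed = 5)
  r2 <- permutation_fdr(mat, rep(c("UT", "AO"), each = 5) |>
                          factor(levels = c("AO", "UT")),
                        s0 = 2, fdr_level = 0.01, n_permutations = 100, seed = 5)
  expect_identical(tidy(r1), tidy(r2))

  res <- tidy(r1)
  expect_true(all(res$significant[1:4]))
  expect_true(all(res$direction[1:4] == "up"))
  expect_equal(res$log2fc[1:4], rowMeans(mat[1:4, 6:10]) - rowMeans(mat[1:4, 1:5]))

  # downward closure in |d|: every feature at least as extreme as a
  # significant one is itself significant
  thr <- min(abs(res$d[res$significant]))
  expect_true(all(res$significant[abs(res$d) >= thr]))
  # q matches significance at the level
  expect_identical(res$significant, res$q <= 0.01)
})

test_that("permutation FDR handles identical groups and enumeration", {
  mat <- matrix(rep(1:6, each = 4) + 0.1 * (1:4), 4, 6,
                dimnames = list(paste0("f", 1:4), NULL))
  # identical data in both groups: nothing can be significant
  m2 <- cbind(mat[, 1:3], mat[, 1:3])
  r <- permutation_fdr(m2, rep(c("a", "b"), each = 3), s0 = 0.5,
                       fdr_level = 0.05, n_permutations = 250, seed = 2)
  expect_equal(sum(tidy(r)$significant), 0)
  # 3v3 has choose(6,3)=20 distinct assignments <= 250: enumerated
  expect_true(r$enumerated)
  expect_equal(r$n_permutations, 20)
  expect_error(permutation_fdr(mat[, 1:4], c("a", "a", "b", "b"), s0 = 1,
                               fdr_level = 0.5, n_permutations = 0, seed = 1))
})

test_that("permutation FDR is calibrated on pure-null data", {
  calls <- vapply(1:8, function(s) {
    set.seed(s)
    mat <- matrix(rnorm(500 * 10, 0, 0.2), 500, 10,
                  dimnames = list(paste0("f", 1:500), NULL))
    r <- permutation_fdr(mat, rep(c("A", "B"), each = 5), s0 = 2,
                         fdr_level = 0.01, n_permutations = 250, seed = s)
    sum(tidy(r)$significant)
  }, numeric(1))
  # realized FDP is 1 whenever anything is called on null data
  expect_lte(mean(calls > 0), 0.125)
})

test_that("moderated t agrees with the closed-form posterior update", {
  set.seed(12)
  mat <- matrix(rnorm(200 * 8, 0, 0.3), 200, 8,
                dimnames = list(paste0("f", 1:200), NULL))
  mat[1:5, 5:8] <- mat[1:5, 5:8] + 1.5
  g <- factor(rep(c("AO", "UT"), each = 4), levels = c("AO", "UT"))
  out <- moderated_t(mat, g)
  d0 <- attr(out, "d0"); s0_sq <- attr(out, "s0_sq")

  # independent evaluation: pooled residual variance per feature, shrunk
  # toward the prior, moderated t = effect / (u * s_tilde)
  m1 <- rowMeans(mat[, 1:4]); m2 <- rowMeans(mat[, 5:8])
  resid <- cbind(mat[, 1:4] - m1, mat[, 5:8] - m2)
  dg <- 8 - 2
  sg2 <- rowSums(resid^2) / dg
  s_post <- (d0 * s0_sq + dg * sg2) / (d0 + dg)
  u <- sqrt(1 / 4 + 1 / 4)
  expect_equal(out$log2fc, unname(m1 - m2))
  expect_equal(out$t, unname((m1 - m2) / (u * sqrt(s_post))), tolerance = 1e-9)
  expect_equal(out$df, rep(d0 + dg, 200))
  expect_equal(out$p, unname(2 * pt(-abs(out$t), d0 + dg)), tolerance = 1e-9)
  expect_true(all(out$p_adj >= out$p))
  # planted features surface at the top
  expect_true(all(rank(out$p_adj)[1:5] <= 8))

  # identical per-feature variances: moderated t equals ordinary t
  flat <- matrix(rep(c(0, 1), each = 4), 50, 8, byrow = TRUE) +
    matrix(rep(rnorm(8, 0, 1e-12), each = 50), 50, 8)
  # construct exactly equal variances via permuted identical residuals
  base <- rnorm(8, 0, 0.5)
  flat <- t(vapply(1:50, function(i) base + i, numeric(8)))
  rownames(flat) <- paste0("f", 1:50)
  outf <- moderated_t(flat, g)
  ordinary <- apply(flat, 1, function(r) {
    d <- mean(r[1:4]) - mean(r[5:8])
    sg <- sqrt(sum((r[1:4] - mean(r[1:4]))^2 + (r[5:8] - mean(r[5:8]))^2) / 6)
    d / (sg * sqrt(1 / 2))
  })
  expect_equal(outf$t, unname(ordinary), tolerance = 1e-6)
})

test_that("Benjamini-Hochberg matches the hand step-up computation", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  # monotone in rank order
  set.seed(7)
  p <- runif(50)
  adj <- benjamini_hochberg(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj <= 1))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})
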
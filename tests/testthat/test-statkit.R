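test_that("ICC worked examples match the mean-squares arithmetic", {
  ident <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2)
  expect_equal(as.numeric(iccConsistency(ident)), 1)
  expect_equal(as.numeric(iccAgreement(ident)), 1)

  offset <- matrix(c(1, 2, 3, 2, 3, 4), ncol = 2)
  expect_equal(as.numeric(iccConsistency(offset)), 1)  # MSE = 0
  expect_equal(as.numeric(iccAgreement(offset)), 2 / 3)
  ms <- aovMeanSquares(offset)
  expect_equal(ms$msr, 2)  # guard the oracle itself
  expect_equal(ms$msc, 1.5)
  expect_equal(ms$mse, 0)

  expect_error(iccConsistency(matrix(1:4, 2, 2)), "at least 3")
  expect_error(iccConsistency(matrix(c(1, NA, 2, 4, 5, 6), 3, 2)), "complete")
})

test_that("both ICC forms agree with the aov oracle on an exhaustive grid", {
  # every 3 x 2 matrix with entries in {0, 1, 2}
  grid <- expand.grid(rep(list(0:2), 6))
  checked <- 0L
  for (i in seq_len(nrow(grid))) {
    mat <- matrix(as.numeric(grid[i, ]), 3, 2)
    ms <- aovMeanSquares(mat)
    den_c <- ms$msr + (ms$k - 1) * ms$mse
    den_a <- den_c + ms$k * (ms$msc - ms$mse) / ms$n
    if (den_c == 0 || den_a == 0) next  # degenerate constant matrices
    expect_equal(as.numeric(iccConsistency(mat)),
                 (ms$msr - ms$mse) / den_c, tolerance = 1e-12)
    expect_equal(as.numeric(iccAgreement(mat)),
                 (ms$msr - ms$mse) / den_a, tolerance = 1e-12)
    checked <- checked + 1L
  }
  expect_gt(checked, 600L)

  # and on larger random matrices up to 6 x 4
  set.seed(88)
  for (rep in 1:25) {
    n <- sample(3:6, 1L); k <- sample(2:4, 1L)
    mat <- matrix(sample(0:3, n * k, replace = TRUE), n, k)
    ms <- aovMeanSquares(mat)
    den_c <- ms$msr + (ms$k - 1) * ms$mse
    den_a <- den_c + ms$k * (ms$msc - ms$mse) / ms$n
    if (den_c == 0 || den_a == 0) next
    expect_equal(as.numeric(iccConsistency(mat)),
                 (ms$msr - ms$mse) / den_c, tolerance = 1e-12)
    expect_equal(as.numeric(iccAgreement(mat)),
                 (ms$msr - ms$mse) / den_a, tolerance = 1e-12)
  }

  # agreement never exceeds consistency under a fixed offset
  set.seed(3)
  for (rep in 1:20) {
    base <- rnorm(8)
    mat <- cbind(base, base + runif(1, 0.5, 3))
    expect_lte(as.numeric(iccAgreement(mat)),
               as.numeric(iccConsistency(mat)) + 1e-12)
  }
})

test_that("ICC of independently shuffled columns is near zero", {
  set.seed(21)
  vals <- matrix(rnorm(400), 200, 2)
  icc <- iccConsistency(cbind(vals[sample(200), 1], vals[sample(200), 2]))
  expect_lt(abs(as.numeric(icc)), 0.2)
})

test_that("ICC agreement categories follow the published cut points", {
  expect_equal(classifyIcc(0.49), "poor")
  expect_equal(classifyIcc(0.5), "moderate")
  expect_equal(classifyIcc(0.75), "good")
  expect_equal(classifyIcc(0.9), "excellent")
  expect_equal(classifyIcc(0.95), "excellent")
  expect_equal(classifyIcc(0.95, pValue = 0.2), "ns")
  expect_error(classifyIcc(1.2), "exceed")
})

test_that("paired difference statistics use the pair-mean percent scale", {
  same <- pairedDifferenceStats(c(3, 4, 5), c(3, 4, 5))
  expect_equal(unlist(same[1, 1:4]),
               c(mean_abs_diff = 0, sd_abs_diff = 0,
                 mean_pct_diff = 0, sd_pct_diff = 0))
  st <- pairedDifferenceStats(c(100, 200), c(110, 190))
  expect_equal(st$mean_abs_diff, 10)
  expect_equal(st$sd_abs_diff, 0)
  expect_equal(st$mean_pct_diff, (100 * 10 / 105 + 100 * 10 / 195) / 2,
               tolerance = 1e-12)
  expect_equal(st$mean_pct_diff, 7.326, tolerance = 1e-3)
  # symmetric in its arguments
  st2 <- pairedDifferenceStats(c(110, 190), c(100, 200))
  expect_equal(st, st2)
  expect_warning(pairedDifferenceStats(c(1, -1), c(2, 1)), "zero pair mean")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  res <- oneWayAnova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 1.5)
  expect_equal(c(res$df_between, res$df_within), c(1, 4))
  flat <- oneWayAnova(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(flat$F, 0)
  expect_equal(flat$p_value, 1)
  expect_error(oneWayAnova(c(1, 2, 3), c("a", "a", "b")), "at least 2")

  # permutation null: p-values roughly uniform
  set.seed(15)
  y <- rnorm(12)
  ps <- vapply(1:200, function(i)
    oneWayAnova(y, sample(rep(c("a", "b", "c"), each = 4)))$p_value,
    numeric(1L))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.5), 0.65)
})

test_that("repeated-measures ANOVA reduces to the paired t-test at k = 2", {
  set.seed(42)
  n <- 12
  d <- data.frame(subj = rep(seq_len(n), 2),
                  cond = rep(c("A", "B"), each = n),
                  y = c(rnorm(n), rnorm(n, 0.6)))
  res <- rmAnova(d, "y", "subj", "cond")
  tt <- t.test(d$y[d$cond == "A"], d$y[d$cond == "B"], paired = TRUE)
  expect_equal(res$F[res$effect == "cond"], unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_equal(res$p_value[res$effect == "cond"], tt$p.value,
               tolerance = 1e-9)

  # identical conditions per subject: no within-subject effect
  d0 <- data.frame(subj = rep(1:6, 3), cond = rep(c("A", "B", "C"), each = 6),
                   y = rep(rnorm(6), 3))
  res0 <- rmAnova(d0, "y", "subj", "cond")
  expect_equal(res0$F[res0$effect == "cond"], 0)

  # configured channel offset of 2 SD is detected at n = 20
  set.seed(7)
  n <- 20
  base <- rnorm(n)
  d2 <- data.frame(subj = rep(seq_len(n), 4),
                   chan = rep(c("765/NIR", "532/LSC", "473/LSC", "473/SSC"),
                              each = n),
                   y = c(base, base, base, base) + rnorm(4 * n, sd = 1) +
                     rep(c(0, 0, 0, 2), each = n))
  res2 <- rmAnova(d2, "y", "subj", "chan")
  expect_lt(res2$p_value[res2$effect == "chan"], 0.05)

  # incomplete subjects are dropped with a message
  d3 <- rbind(d, data.frame(subj = 99, cond = "A", y = 1))
  expect_message(rmAnova(d3, "y", "subj", "cond"), "dropped")
})

test_that("pooled-variance t statistic matches the textbook formula", {
  res <- tTestUnpaired(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_equal(res$t, (2 - 3) / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-12)
})

test_that("Holm step-down matches p.adjust and dominates Bonferroni", {
  # 6 pairwise comparisons: the smallest p faces alpha / 6
  hb <- holmBonferroni(c(0.005, 0.04, 0.2, 0.6, 0.8, 0.9))
  expect_equal(hb$thresholds[1L], 0.05 / 6)
  expect_equal(round(hb$thresholds[1L], 3), 0.008)
  expect_true(hb$reject[1L])

  expect_error(holmBonferroni(numeric(0)), "empty")
  one <- holmBonferroni(0.03)
  expect_true(one$reject)
  expect_equal(one$adjusted_p, 0.03)

  set.seed(19)
  for (rep in 1:50) {
    m <- sample(1:10, 1L)
    p <- runif(m)^sample(1:3, 1L)
    hb <- holmBonferroni(p)
    expect_equal(hb$adjusted_p, p.adjust(p, "holm"), tolerance = 1e-12)
    # every Bonferroni rejection is a Holm rejection
    bonf <- p <= 0.05 / m
    expect_true(all(hb$reject[bonf]))
    # adjusted p-values are monotone in raw-p order
    expect_true(all(diff(hb$adjusted_p[order(p)]) >= -1e-12))
    # rejection iff adjusted p below alpha
    expect_equal(hb$reject, hb$adjusted_p <= 0.05 + 1e-15)
  }
})

test_that("two-group sample sizes follow the z formula", {
  expect_equal(sampleSizeTwoGroup(1, 1), 16L)
  expect_equal(sampleSizeTwoGroup(0.5, 1), 63L)  # halving delta ~ quadruples
  expect_equal(sampleSizeTwoGroup(0.013, 0.005), 3L)
  expect_equal(sampleSizeTwoGroup(0.013, 0.019, sided = 1L), 27L)
  expect_error(sampleSizeTwoGroup(0, 1), "non-zero")
  expect_error(sampleSizeTwoGroup(1, -1), "positive")
})

test_that("linear trends reproduce the covariance closed form", {
  tr <- linearTrend(1:10, 2 * (1:10) + 1)
  expect_equal(unlist(tr), c(slope = 2, intercept = 1, r = 1))
  expect_equal(linearTrend(1:5, rep(3, 5))$slope, 0)
  set.seed(33)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(linearTrend(x, y)$slope, cov(x, y) / var(x), tolerance = 1e-12)
  expect_error(linearTrend(rep(1, 5), 1:5), "distinct")
})

test_that("repeatability reports carry ICC class and difference statistics", {
  set.seed(55)
  truth <- rnorm(40, 300, 40)
  a <- data.frame(label = 1:40, tau_m_ps = truth + rnorm(40, sd = 5),
                  g = 0.8 + rnorm(40, sd = 0.002))
  b <- data.frame(label = 1:40, tau_m_ps = truth + rnorm(40, sd = 5),
                  g = 0.8 + rnorm(40, sd = 0.002))
  rep_tab <- repeatabilityReport(a, b, parameters = c("tau_m_ps", "g"))
  expect_equal(rep_tab$parameter, c("tau_m_ps", "g"))
  expect_equal(rep_tab$icc_class[1L], "excellent")
  expect_true(all(rep_tab$mean_pct_diff >= 0))
  expect_equal(rep_tab$n_units, c(40L, 40L))
})
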
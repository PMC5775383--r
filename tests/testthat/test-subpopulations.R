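# exhaustive-permutation Mann-Whitney oracle for small tie-free samples:
# returns the U statistic of (a vs b) and its exact two-sided p value
bruteWilcoxon <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  Us <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
  list(U = U, p = p)
}

test_that("bias-adjusted skewness matches hand and library oracles", {
  expect_equal(sampleSkewness(c(-1, 0, 1)), 0)
  expect_equal(sampleSkewness(c(0, 0, 0, 10)), 2, tolerance = 1e-12)
  expect_error(sampleSkewness(c(1, 2)), "at least 3")

  skip_if_not_installed("e1071")
  set.seed(8)
  for (i in 1:10) {
    x <- rlnorm(sample(5:60, 1))
    expect_equal(sampleSkewness(x), e1071::skewness(x, type = 2),
                 tolerance = 1e-12)
  }
})

test_that("skewness series needs 3+ traces and tracks the tail", {
  tg <- c(0, 2)
  small <- cellTraceSet(matrix(0, 2, 2), matrix(0, 2, 2), tg,
                        data.frame(trackId = 1:2))
  expect_error(skewnessSeries(small), "at least 3")

  # a right tail at the final time produces positive final skewness
  ic <- rbind(c(100, 110), c(100, 112), c(100, 108), c(100, 200))
  tr <- cellTraceSet(ic, matrix(100, 4, 2), tg, data.frame(trackId = 1:4))
  ss <- skewnessSeries(tr)
  expect_equal(ss$time, tg)
  expect_gt(ss$skewness[2], 1)
})

test_that("asymmetry threshold on a pure Gaussian sample", {
  set.seed(12)
  x <- rnorm(1000, mean = 10, sd = 2)
  thr <- computeThreshold(x)
  expect_equal(thr$threshold, 10 + 3 * 2, tolerance = 0.1)
  expect_lte(mean(x > thr$threshold), 0.005)

  expect_error(computeThreshold(rep(5, 50)), "degenerate")
  expect_error(computeThreshold(rnorm(10)), "at least 30")
})

test_that("threshold is translation-equivariant", {
  set.seed(13)
  x <- c(rnorm(400, 50, 5), rnorm(40, 120, 10))
  t0 <- computeThreshold(x)$threshold
  for (c0 in c(-100, 17.3, 1e4))
    expect_equal(computeThreshold(x + c0)$threshold, t0 + c0,
                 tolerance = 1e-6)
})

test_that("threshold separates a well-separated mixture", {
  set.seed(14)
  n <- 1000
  isHp <- runif(n) < 0.1
  x <- rnorm(n, 100, 10)
  x[isHp] <- rnorm(sum(isHp), 100 + 6 * 10, 10)
  thr <- computeThreshold(x)$threshold
  called <- x > thr
  expect_gte(sum(called & isHp) / sum(isHp), 0.9)       # recall
  expect_gte(sum(called & isHp) / sum(called), 0.9)     # precision
})

test_that("HP classification: labels, sentinel, and truth recovery", {
  tg <- seq(0, 62, 2)
  # all cells below an explicit threshold: 0% HP, sentinel HP curve
  ic <- matrix(100, 5, length(tg)) + outer(1:5, tg / 62)
  tr <- cellTraceSet(ic, matrix(100, 5, length(tg)), tg,
                     data.frame(trackId = 1:5))
  cls <- classifyHP(tr, threshold = 50)
  expect_equal(hpPercentage(cls), 0)
  expect_true(all(is.na(cls@hpMeanDeltaI)))
  expect_false(any(hpLabels(cls)$isHp))

  # estimated threshold recovers the preset prevalence (binomial 95% CI)
  lay <- smallLayout(16, 16)
  truth <- generatePopulation(lay, conditionPreset("R5"), seed = 81)
  traces <- simulateTraceSet(truth, seed = 81, viableOnly = TRUE)
  cls2 <- classifyHP(traces)
  p <- 0.1527
  n <- nCells(traces)
  expect_lt(abs(hpPercentage(cls2) / 100 - p),
            1.96 * sqrt(p * (1 - p) / n))
  # labels agree with the generator truth
  expect_gte(mean(hpLabels(cls2)$isHp == cellData(traces)$isHp), 0.95)
})

test_that("morphology comparison reflects the diameter multiplier", {
  areas <- rep(c(100, 120, 140), 20)
  same <- compareMorphology(rep(c(TRUE, FALSE), 30), areas)
  expect_equal(unname(same@effect["areaRatio"]), 1, tolerance = 1e-9)
  expect_gt(same@pValue, 0.8)
  expect_error(compareMorphology(rep(TRUE, 10), rnorm(10)), "non-empty")

  # area ratio ~ multiplier^2 on generated populations
  lay <- chipLayout(40, 40, pitch = 70, anchorRadius = 30)
  for (mult in c(1, 1.15)) {
    truth <- generatePopulation(
      lay, conditionPreset("R5", hpDiameterMultiplier = mult), seed = 91)
    area <- pi * (truth$diameter / 2)^2
    cmp <- compareMorphology(truth$isHp, area)
    expect_equal(unname(cmp@effect["areaRatio"]), mult^2,
                 tolerance = 0.05)
  }
})

test_that("rank tests match oracles and handle identical groups", {
  g <- list(a = c(5, 6, 7, 8), b = c(5, 6, 7, 8), c = c(5, 6, 7, 8))
  kw <- kruskalWallis(g)
  expect_lt(unname(kw@statistic), 1e-9)
  expect_gt(kw@pValue, 0.99)
  expect_error(kruskalWallis(list(a = 1, b = 2)), "at least 2")

  cases <- list(
    list(a = c(1, 2, 3), b = c(10, 20, 30)),
    list(a = c(3, 9, 1, 7), b = c(2, 8)),
    list(a = c(0.5, 4.4, 2.2), b = c(1.1, 3.3, 5.5)))
  for (cs in cases) {
    w <- wilcoxonRankSum(cs$a, cs$b)
    oracle <- bruteWilcoxon(cs$a, cs$b)
    expect_equal(unname(w@statistic), oracle$U)
    expect_equal(w@pValue, oracle$p, tolerance = 1e-9)
  }
})

test_that("mean deviation and Anderson-Darling behave", {
  expect_equal(meanDeviation(c(0, 10)), 5)
  expect_equal(meanDeviation(rep(3, 7)), 0)

  set.seed(15)
  expect_true(andersonDarlingNormal(rnorm(200))$normal)
  expect_false(andersonDarlingNormal(rexp(200))$normal)
  expect_error(andersonDarlingNormal(rnorm(5)), "n >= 8")
})

test_that("type-I control: few false HPs when no subpopulation exists", {
  lay <- smallLayout(16, 16)
  rates <- vapply(1:20, function(s) {
    truth <- generatePopulation(lay, conditionPreset("null", viability = 1),
                                seed = 200 + s)
    traces <- simulateTraceSet(truth, seed = 300 + s)
    mean(hpLabels(classifyHP(traces))$isHp)
  }, 0)
  expect_lte(mean(rates), 0.02)
})

test_that("null populations show no skewness trend and |g1| stays small", {
  lay <- smallLayout(16, 16)
  slopes <- numeric(10)
  finalG1 <- numeric(10)
  for (s in 1:10) {
    truth <- generatePopulation(lay, conditionPreset("null", viability = 1),
                                seed = 400 + s)
    traces <- simulateTraceSet(truth, seed = 500 + s)
    ss <- skewnessSeries(traces)
    ss <- ss[ss$time > 0, ]  # g1 undefined at t = 0 where delta-I is 0
    slopes[s] <- fitLinear(ss$time, ss$skewness)$slope
    finalG1[s] <- ss$skewness[nrow(ss)]
  }
  # mean final-time |g1| well below 0.3, and no increasing trend
  expect_lt(mean(abs(finalG1)), 0.3)
  tt <- t.test(slopes, alternative = "greater")
  expect_gte(tt$p.value, 0.05)
})

test_that("HP recall is monotone in the slope multiplier", {
  lay <- smallLayout(16, 16)
  recall <- vapply(c(2, 4, 8), function(mult) {
    hits <- vapply(1:5, function(s) {
      truth <- generatePopulation(
        lay, conditionPreset("R5", hpSlopeMultiplier = mult, viability = 1),
        seed = 600 + s)
      traces <- simulateTraceSet(truth, seed = 700 + s)
      labs <- hpLabels(classifyHP(traces))
      hp <- cellData(traces)$isHp
      if (!any(hp)) return(NA_real_)
      mean(labs$isHp[hp])
    }, 0)
    mean(hits, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(recall) >= -1e-9))
  expect_gte(recall[2], 0.9)  # default effect size
})

test_that("skewness grows from 12 h to 62 h when HPs are present", {
  lay <- smallLayout(16, 16)
  grew <- vapply(1:20, function(s) {
    truth <- generatePopulation(lay, conditionPreset("R5", viability = 1),
                                seed = 800 + s)
    traces <- simulateTraceSet(truth, seed = 900 + s)
    ss <- skewnessSeries(traces)
    ss$skewness[ss$time == 62] > ss$skewness[ss$time == 12]
  }, NA)
  expect_gte(mean(grew), 0.95)
})
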
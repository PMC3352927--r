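test_that("coefficient of variation follows the SD*100/mean definition", {
  expect_equal(coefficientOfVariation(c(5, 5, 5)), 0)
  expect_equal(coefficientOfVariation(c(1, 3)), 70.71068, tolerance = 1e-6)
  ## scale invariance
  set.seed(2)
  x <- rlnorm(20)
  expect_equal(coefficientOfVariation(3.7 * x), coefficientOfVariation(x))
  expect_error(coefficientOfVariation(c(-1, 1)), "zero mean")
  expect_error(coefficientOfVariation(5))
})

test_that("Mann-Whitney exact p matches full enumeration for all n <= 6", {
  mw <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(testStatistic(mw), 0)
  expect_equal(pValue(mw), 0.1)
  set.seed(31)
  for (n1 in 2:6) {
    for (n2 in n1:6) {
      a <- rnorm(n1)
      b <- rnorm(n2, 0.8)
      got <- mannWhitney(a, b)
      oracle <- mwEnumerate(a, b)
      expect_equal(testStatistic(got), oracle$u,
                   info = sprintf("U for n=(%d,%d)", n1, n2))
      expect_equal(pValue(got), oracle$p,
                   info = sprintf("p for n=(%d,%d)", n1, n2))
    }
  }
  ## identical multisets cannot separate
  expect_gte(pValue(mannWhitney(c(1, 2, 3), c(1, 2, 3))), 0.99)
  expect_error(mannWhitney(numeric(0), 1:3), "empty")
})

test_that("normal approximation agrees with the exact test at n = 8", {
  ## exhaustive over every achievable U at n1 = n2 = 8: the enumerated
  ## worst-case discrepancy of the corrected normal approximation is 0.0109
  ## (close to, but slightly above, a round 0.01)
  b <- as.numeric(1:8)
  for (u in 0:64) {
    k <- u %/% 8                     # a-values above every b
    r <- u %% 8                      # one a-value above exactly r b-values
    a2 <- c(100 + seq_len(k),
            if (r > 0) r + 0.5,
            seq_len(8 - k - (r > 0)) / 10 - 2)
    got <- suppressWarnings(stats::wilcox.test(a2, b, exact = TRUE))
    stopifnot(unname(got$statistic) == u)
    approx <- suppressWarnings(
      stats::wilcox.test(a2, b, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(got$p.value - approx), 0.011)
  }
})

test_that("Welch t matches the hand formula and its degenerate cases", {
  x <- c(1, 2, 3, 4)
  same <- welchT(x, x)
  expect_equal(testStatistic(same), 0)
  expect_equal(pValue(same), 1)
  got <- welchT(c(1, 2, 3, 4), c(3, 4, 5, 6))
  oracle <- welchOracle(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(testStatistic(got), oracle$t, tolerance = 1e-12)
  expect_equal(attr(got, "df"), oracle$df, tolerance = 1e-12)
  expect_equal(pValue(got), oracle$p, tolerance = 1e-12)
  ## Satterthwaite df below the pooled df under variance imbalance
  set.seed(33)
  a <- rnorm(10, sd = 5)
  b <- rnorm(10, sd = 0.5)
  expect_lt(attr(welchT(a, b), "df"), 18)
  ## zero variance in both groups
  expect_equal(pValue(welchT(c(2, 2), c(2, 2))), 1)
  expect_equal(pValue(welchT(c(2, 2), c(3, 3))), 0)
})

test_that("Dunnett with one treated group reduces to the pooled t test", {
  set.seed(34)
  for (rep in 1:3) {
    a <- rnorm(10)
    b <- rnorm(12, 0.4)
    res <- anovaDunnett(list(control = a, treated = b), controlIndex = 1)
    tp <- stats::t.test(b, a, var.equal = TRUE)$p.value
    expect_lt(abs(adjustedP(res$comparisons[["treated"]]) - tp), 0.005)
  }
  expect_error(anovaDunnett(list(rnorm(5), rnorm(5)), controlIndex = 7),
               "control index")
})

test_that("Dunnett detects a strongly shifted group", {
  set.seed(35)
  groups <- list(control = rnorm(10), t1 = rnorm(10), t2 = rnorm(10, 3))
  res <- anovaDunnett(groups, controlIndex = 1)
  expect_lt(adjustedP(res$comparisons[["t2"]]), 0.01)
  expect_gt(adjustedP(res$comparisons[["t1"]]), 0.05)
  expect_lt(res$omnibusP, 0.01)
  ## adjusted p never undercuts the unadjusted p
  for (cmp in res$comparisons)
    expect_gte(adjustedP(cmp), pValue(cmp) - 1e-12)
})

test_that("4PL fitting recovers noiseless parameters and flags flat data", {
  d <- makeDoseResponse(ic50 = 2.6, hill = 1.5, top = 100, bottom = 0)
  fit <- fit4PL(d$dose, d$response)
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 2.6) / 2.6, 1e-3)
  expect_equal(fit$hill, 1.5, tolerance = 1e-3)
  expect_equal(fit$top, 100, tolerance = 1e-2)
  ## flat response is unidentifiable
  flat <- fit4PL(10^seq(-2, 2, length.out = 8), rep(5, 8))
  expect_false(flat$converged)
  expect_true(is.na(flat$ic50))
  expect_error(fit4PL(c(1, 2, 3), c(1, 2, 3)), "5 dose levels")
})

test_that("noisy 4PL fits keep the median IC50 error under 10%", {
  errs <- vapply(1:100, function(s) {
    d <- makeDoseResponse(ic50 = 2.6, hill = 1.5, top = 100, bottom = 0,
                          doses = 10^seq(-1.5, 2, length.out = 10),
                          nPerDose = 10, noiseSd = 5, seed = 1000 + s)
    fit <- fit4PL(d$dose, d$response)
    if (!fit$converged) return(Inf)
    abs(fit$ic50 - 2.6) / 2.6
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("ROC threshold selection matches the exhaustive sweep", {
  ## perfectly separated samples
  perfect <- rocThreshold(controlRates = c(40, 42, 44),
                          treatedRates = c(20, 22, 24))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  ## identical distributions give no discrimination
  set.seed(36)
  x <- rnorm(200, 40, 5)
  flatJ <- rocThreshold(x, x)$youdenJ
  expect_lt(abs(flatJ), 0.05)
  ## bradycardia-like separation, oracle-checked
  set.seed(37)
  ctl <- rnorm(100, 45, 4)
  trt <- rnorm(100, 33, 6)
  got <- rocThreshold(ctl, trt)
  oracle <- rocSweepOracle(ctl, trt)
  expect_equal(got$threshold, oracle$threshold)
  expect_equal(got$sensitivity, 100 * oracle$sens)
  expect_equal(got$specificity, 100 * oracle$spec)
  expect_gt(got$threshold, mean(trt))
  expect_lt(got$threshold, mean(ctl))
  expect_error(rocThreshold(numeric(0), 1:3), "non-empty")
})
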
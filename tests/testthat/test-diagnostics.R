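test_that("PSRF detects agreement and divergence", {
  set.seed(1)
  n <- 2000
  same <- cbind(rnorm(n), rnorm(n), rnorm(n))
  expect_lt(psrf(same), 1.05)
  ident <- cbind(1:100, 1:100)           # B = 0
  expect_equal(psrf(ident), sqrt(99 / 100))
  far <- cbind(rnorm(n, 0, 0.1), rnorm(n, 10, 0.1))
  expect_gt(psrf(far), 10)
  ## affine invariance
  expect_equal(psrf(3 * same + 5), psrf(same), tolerance = 1e-12)
})

test_that("PSRF agrees with the coda oracle on i.i.d. chains", {
  library(coda)
  set.seed(2)
  ch <- cbind(rnorm(5000), rnorm(5000))
  ours <- psrf(ch)
  ref <- gelman.diag(mcmc.list(mcmc(ch[, 1]), mcmc(ch[, 2])),
                     autoburnin = FALSE)$psrf[1]
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("Geweke flags trends, passes stationary chains, is affine-invariant", {
  set.seed(3)
  ch <- rnorm(5000)
  expect_lt(abs(gewekeZ(ch)), 3)
  trend <- rnorm(5000) + seq(0, 5, length.out = 5000)
  expect_gt(abs(gewekeZ(trend)), 5)
  expect_equal(gewekeZ(rep(2, 1000)), 0)
  expect_equal(gewekeZ(4 * ch + 1), gewekeZ(ch), tolerance = 1e-10)
  ## agreement with coda (different spectral estimators, so compare the
  ## two z-scores across many chains rather than on one realization)
  library(coda)
  set.seed(30)
  d <- replicate(25, {
    x <- rnorm(5000)
    c(gewekeZ(x), unname(geweke.diag(mcmc(x))$z))
  })
  expect_lt(mean(abs(d[1, ] - d[2, ])), 0.4)
  expect_gt(cor(d[1, ], d[2, ]), 0.8)
})

test_that("Geweke calibration: nominal coverage on i.i.d. chains", {
  set.seed(4)
  z <- vapply(1:100, function(i) gewekeZ(rnorm(10000)), numeric(1))
  cover <- mean(abs(z) <= 1.96)
  ## 99% binomial band around 0.95 for 100 draws
  expect_gte(cover, qbinom(0.005, 100, 0.95) / 100)
})

test_that("Heidelberger-Welch stationarity and half-width behave", {
  set.seed(5)
  good <- rnorm(4000, mean = 10)
  h <- heidelbergerWelch(good)
  expect_true(h$stationary)
  expect_true(isTRUE(h$halfwidthOk))
  expect_equal(h$nDiscarded, 0L)
  ## a big early offset needs discards (or fails outright)
  shifted <- c(rnorm(2000, 30), rnorm(2000, 0))
  h2 <- heidelbergerWelch(shifted)
  expect_true(!h2$stationary || h2$nDiscarded > 0)
  ## near-zero mean: half-width indeterminate, not failed
  h3 <- heidelbergerWelch(rnorm(4000, 0))
  expect_true(is.na(h3$halfwidthOk))
  ## agreement with coda on the clean chain's verdicts
  library(coda)
  ref <- heidel.diag(mcmc(good))
  expect_equal(h$stationary, ref[1, "stest"] == 1)
  expect_equal(isTRUE(h$halfwidthOk), ref[1, "htest"] == 1)
})

test_that("Raftery-Lewis hits the i.i.d. floor and penalizes dependence", {
  phi <- qnorm(0.975)
  nMin <- ceiling(phi^2 * 0.025 * 0.975 / 0.005^2)
  expect_equal(nMin, 3746)
  set.seed(6)
  r <- rafteryLewis(rnorm(20000))
  expect_equal(r$nMin, 3746L)
  expect_lt(abs(r$requiredN - 3746) / 3746, 0.5)
  ## strongly autocorrelated AR(1): much longer run needed
  ar <- as.numeric(arima.sim(list(ar = 0.98), 20000))
  r2 <- rafteryLewis(ar)
  expect_gt(r2$requiredN, 3 * r2$nMin)
  expect_error(rafteryLewis(rnorm(100)), "insufficient pilot length")
  ## coda cross-check: same order of magnitude on the i.i.d. chain
  library(coda)
  set.seed(7)
  ch <- rnorm(20000)
  ref <- raftery.diag(mcmc(ch))$resmatrix[1, "N"]
  expect_lt(abs(rafteryLewis(ch)$requiredN - ref) / ref, 0.5)
})

test_that("diagnostics report aggregates verdicts per the rule", {
  reg <- generateRegion(syntheticScenario(nAreas = 20, seed = 15))
  obs <- caseCounts(reg, "high")
  e <- expectedCounts(populations(reg), obs)
  adj <- spatialWeights(reg, scheme = "binary")
  fit <- runBYM(obs, e, adj, nChains = 3, nIterations = 6000,
                burnIn = 2000, thin = 4, seed = 3)
  rep <- diagnosticsReport(fit)
  expect_setequal(rep$parameter, c("c", "tau_u", "tau_v"))
  expect_true(all(rep$verdict %in% c("pass", "warn", "fail")))
  expect_true(all(rep$psrf >= sqrt(0.5), na.rm = TRUE))
})
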
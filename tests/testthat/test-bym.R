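smallFit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      reg <- generateRegion(syntheticScenario(nAreas = 30, seed = 2))
      obs <- caseCounts(reg, "high")
      e <- expectedCounts(populations(reg), obs)
      adj <- spatialWeights(reg, scheme = "binary")
      memo <<- list(reg = reg, obs = obs, e = e, adj = adj,
                    fit = runBYM(obs, e, adj, nChains = 3,
                                 nIterations = 6000, burnIn = 2000,
                                 thin = 4, seed = 4))
    }
    memo
  }
})

test_that("log posterior matches hand-written densities", {
  ## single-area model reduces to Poisson-lognormal
  xy <- cbind(c(0, 500), c(0, 0))       # two isolated areas
  W <- binaryAdjacency(inverseDistanceWeights(
    distanceBandNeighbors(xy, 120), xy))
  st <- list(c = 0.3, u = c(0, 0), v = c(0.2, -0.1), tauU = 2, tauV = 3)
  lp <- logPosterior(st, W, observed = c(4, 6), expected = c(5, 5))
  mu <- 5 * exp(0.3 + st$v)
  byHand <- sum(dpois(c(4, 6), mu, log = TRUE)) +
    sum(dnorm(st$v, 0, 1 / sqrt(3), log = TRUE)) +
    dgamma(2, 0.5, rate = 5e-4, log = TRUE) +
    dgamma(3, 0.5, rate = 5e-4, log = TRUE)
  ## isolated areas: no pairwise term and zero CAR rank
  expect_equal(lp, byHand, tolerance = 1e-12)
})

test_that("iCAR pairwise term is linear in tau and zero at constant u", {
  xy <- cbind(c(0, 50, 100), c(0, 0, 0))
  W <- binaryAdjacency(inverseDistanceWeights(
    distanceBandNeighbors(xy, 60), xy))
  base <- list(c = 0, u = c(0, 0, 0), v = c(0, 0, 0), tauU = 1, tauV = 1)
  stU <- modifyList(base, list(u = c(0.3, -0.1, -0.2)))
  obs <- c(2, 3, 4); e <- c(3, 3, 3)
  ## doubling tau doubles the pairwise penalty exactly
  ss <- (0.3 - (-0.1))^2 + ((-0.1) - (-0.2))^2
  d1 <- logPosterior(stU, W, obs, e) -
        logPosterior(modifyList(stU, list(u = c(0, 0, 0))), W, obs, e)
  st2 <- modifyList(stU, list(tauU = 2))
  d2 <- logPosterior(st2, W, obs, e) -
        logPosterior(modifyList(st2, list(u = c(0, 0, 0))), W, obs, e)
  llDiff <- sum(dpois(obs, e * exp(stU$u), log = TRUE)) -
            sum(dpois(obs, e, log = TRUE))
  expect_equal(d1 - llDiff, -0.5 * ss, tolerance = 1e-12)
  expect_equal(d2 - llDiff, -1.0 * ss, tolerance = 1e-12)
  expect_error(logPosterior(modifyList(base, list(c = NaN)), W, obs, e),
               "non-finite")
})

test_that("precision full conditionals match the symbolic Gamma form", {
  ## p(tauU | rest) ~ Gamma(shape + rank/2, rate + ss/2): check via
  ## log-posterior differences at two tau values
  xy <- cbind(c(0, 50, 100, 150), c(0, 0, 0, 0))
  W <- binaryAdjacency(inverseDistanceWeights(
    distanceBandNeighbors(xy, 60), xy))
  u <- c(0.4, -0.2, 0.1, -0.3)
  st <- list(c = 0, u = u, v = c(0.1, 0, -0.1, 0.05), tauU = 1.3, tauV = 2.1)
  obs <- c(2, 5, 3, 4); e <- rep(3.5, 4)
  ss <- sum(diff(u)^2)                     # chain graph: 3 pairs, rank 3
  for (t2 in c(0.7, 4.2)) {
    lhs <- logPosterior(modifyList(st, list(tauU = t2)), W, obs, e) -
           logPosterior(st, W, obs, e)
    rhs <- dgamma(t2, 0.5 + 3 / 2, rate = 5e-4 + ss / 2, log = TRUE) -
           dgamma(st$tauU, 0.5 + 3 / 2, rate = 5e-4 + ss / 2, log = TRUE)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  ssV <- sum(st$v^2)
  for (t2 in c(0.9, 3.3)) {
    lhs <- logPosterior(modifyList(st, list(tauV = t2)), W, obs, e) -
           logPosterior(st, W, obs, e)
    rhs <- dgamma(t2, 0.5 + 4 / 2, rate = 5e-4 + ssV / 2, log = TRUE) -
           dgamma(st$tauV, 0.5 + 4 / 2, rate = 5e-4 + ssV / 2, log = TRUE)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("retained draws satisfy the sum-to-zero constraint", {
  f <- smallFit()
  sums <- apply(f$fit@u, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-9)
  expect_true(all(f$fit@tauU > 0) && all(f$fit@tauV > 0))
})

test_that("null data give smoothed SIRs near parity", {
  reg <- generateRegion(syntheticScenario(nAreas = 30, sdU = 0, sdV = 0,
                                          seed = 77))
  e <- populations(reg) * 0.003
  obs <- round(e)
  adj <- spatialWeights(reg, scheme = "binary")
  fit <- runBYM(obs, e, adj, nChains = 3, nIterations = 10000,
                burnIn = 3000, thin = 5, seed = 9)
  sm <- smoothedSIR(fit)
  expect_true(all(sm > 0.8 & sm < 1.2))
})

test_that("smoothing shrinks and keeps zero-count areas positive", {
  f <- smallFit()
  sm <- smoothedSIR(f$fit)
  crude <- crudeSIR(f$obs, f$e)
  expect_true(all(sm > 0))
  expect_lte(max(sm), max(crude))
  expect_gte(min(sm), min(crude))
})

test_that("two seeds differ in draws but agree in summaries", {
  f <- smallFit()
  fit2 <- runBYM(f$obs, f$e, f$adj, nChains = 3, nIterations = 6000,
                 burnIn = 2000, thin = 4, seed = 5)
  expect_false(identical(f$fit@c, fit2@c))
  expect_equal(mean(f$fit@c), mean(fit2@c), tolerance = 0.05)
  expect_equal(smoothedSIR(f$fit), smoothedSIR(fit2), tolerance = 0.05)
  ## same seed reproduces exactly
  fit3 <- runBYM(f$obs, f$e, f$adj, nChains = 3, nIterations = 6000,
                 burnIn = 2000, thin = 4, seed = 4)
  expect_identical(f$fit@c, fit3@c)
})

test_that("empty adjacency reduces to the exchangeable model (rjags oracle)", {
  reg <- generateRegion(syntheticScenario(nAreas = 12, spacingKm = 500,
                                          jitterKm = 5, sdV = 0.3,
                                          sdU = 0, seed = 31))
  obs <- caseCounts(reg, "intermediate")
  e <- expectedCounts(populations(reg), obs)
  adj <- spatialWeights(reg, scheme = "binary")  # all isolated at 120 km
  expect_true(all(lengths(adj@neighbors) == 0))
  fit <- runBYM(obs, e, adj, nChains = 3, nIterations = 20000,
                burnIn = 5000, thin = 5, seed = 8)
  library(rjags)
  model <- "model {
    for (i in 1:n) {
      O[i] ~ dpois(E[i] * exp(c + v[i]))
      v[i] ~ dnorm(0, tauV)
    }
    c ~ dunif(-100, 100)
    tauV ~ dgamma(0.5, 0.0005)
  }"
  jm <- jags.model(textConnection(model),
                   data = list(O = as.integer(obs), E = e, n = length(obs)),
                   n.chains = 2, quiet = TRUE,
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 99))
  update(jm, 4000, progress.bar = "none")
  sm <- jags.samples(jm, c("c", "v"), 20000, progress.bar = "none")
  cDraws <- as.numeric(sm$c)                       # iter*chain
  vDraws <- matrix(sm$v, nrow = dim(sm$v)[1])      # n x (iter*chain)
  thetaJags <- rowMeans(exp(sweep(vDraws, 2, cDraws, `+`)))
  expect_equal(unname(smoothedSIR(fit)), thetaJags, tolerance = 0.05)
  expect_equal(mean(fit@c), mean(cDraws), tolerance = 0.05)
})

test_that("IRR summary and percent change follow the definitions", {
  f <- smallFit()
  fit <- runBYM(f$obs, f$e, f$adj, covariate = physicianDensity(f$reg),
                covariateName = "phys_density", nChains = 2,
                nIterations = 4000, burnIn = 1000, thin = 4, seed = 6)
  ir <- irrSummary(fit)
  expect_equal(ir$irr, exp(mean(fit@beta)), tolerance = 1e-12)
  expect_equal(ir$cri, exp(unname(quantile(fit@beta, c(0.025, 0.975)))),
               tolerance = 1e-12)
  expect_equal(ir$significant, ir$cri[1] > 1 || ir$cri[2] < 1)
  expect_error(irrSummary(f$fit), "null model")
  expect_equal(percentChange(0), 0)
  expect_equal(round(percentChange(-0.067), 1), 6.5)
})

test_that("generator surface density agrees with the fitted model's prior", {
  ## round trip: a simulated CAR field has sum-zero components and its
  ## pairwise-difference energy equals u' L u from the Laplacian
  reg <- generateRegion(syntheticScenario(nAreas = 25, seed = 13))
  adj <- spatialWeights(reg, scheme = "binary")
  th <- simulateRiskSurface(reg, adj, c = 0.1, sdU = 0.5, sdV = 0, seed = 21)
  u <- attr(th, "u")
  expect_lt(abs(sum(u)), 1e-9)
  A <- as.matrix(adj)
  L <- diag(rowSums(A)) - A
  ssPair <- 0
  for (i in seq_along(u)) for (j in adj@neighbors[[i]]) if (j > i)
    ssPair <- ssPair + (u[i] - u[j])^2
  expect_equal(ssPair, drop(t(u) %*% L %*% u), tolerance = 1e-10)
  expect_equal(as.numeric(th), exp(0.1 + u + attr(th, "v")), tolerance = 1e-12)
})
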
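test_that("window enumeration respects the population cap", {
  xy <- cbind(c(0, 100, 200), 0)
  pop <- c(10, 10, 10)
  z <- enumerateWindows(xy, pop, 0.34)
  expect_equal(lengths(lapply(z, `[[`, "members")), rep(1L, 3))
  ## at the 0.5 cap a pair (2/3 of the population) still exceeds the limit
  z2 <- enumerateWindows(xy, pop, 0.5)
  sizes <- sort(vapply(z2, function(w) length(w$members), integer(1)))
  expect_equal(sizes, c(1L, 1L, 1L))
  expect_error(enumerateWindows(xy, pop, 0.6), "maxPopFraction")
  expect_error(enumerateWindows(xy, pop, 0))
})

test_that("zone sets equal brute-force enumeration over (center, radius)", {
  set.seed(31)
  xy <- cbind(runif(10, 0, 300), runif(10, 0, 300))
  pop <- sample(100:1000, 10)
  frac <- 0.45
  z <- enumerateWindows(xy, pop, frac)
  keys <- sort(vapply(z, function(w) paste(w$members, collapse = ","), ""))
  ## oracle: every distinct within-cap member set over all center/radius pairs
  d <- bfDist(xy)
  bf <- character()
  for (i in 1:10) for (j in 1:10) {
    members <- sort(which(d[i, ] <= d[i, j]))
    if (sum(pop[members]) <= frac * sum(pop))
      bf <- c(bf, paste(members, collapse = ","))
  }
  expect_equal(keys, sort(unique(bf)))
})

test_that("Poisson LLR matches its closed form and monotonicity", {
  expect_equal(poissonLLR(10, 5, 100)$llr, 10 * log(2) + 90 * log(90 / 95),
               tolerance = 1e-12)
  expect_equal(poissonLLR(10, 5, 100)$llr, 2.0654, tolerance = 1e-3)
  r <- poissonLLR(0, 5, 100)
  expect_equal(r$llr, 100 * log(100 / 95), tolerance = 1e-12)
  expect_equal(r$direction, "low")
  expect_equal(poissonLLR(7, 7, 100)$llr, 0)
  ## strictly increasing above the expectation
  llrs <- poissonLLR(6:20, 5, 100)$llr
  expect_true(all(diff(llrs) > 0))
})

test_that("most-likely cluster equals exhaustive search on small regions", {
  set.seed(41)
  for (k in 1:5) {
    n <- sample(6:10, 1)
    xy <- cbind(runif(n, 0, 300), runif(n, 0, 300))
    pop <- sample(200:2000, n)
    obs <- rpois(n, 4)
    if (sum(obs) == 0) obs[1] <- 3
    expd <- expectedCounts(pop, obs)
    win <- enumerateWindows(xy, pop, 0.5)
    cl <- scanClusters(obs, expd, win, directions = "high")
    bf <- bfBestZone(xy, pop, obs, expd, 0.5, "high")
    if (bf$llr <= 0) {
      expect_length(cl, 0)
    } else {
      expect_equal(cl[[1]]$llr, bf$llr, tolerance = 1e-10)
      expect_equal(cl[[1]]$zone$members, bf$members)
    }
  }
})

test_that("llr is invariant to relabeling areas outside the zone", {
  set.seed(51)
  xy <- cbind(runif(8, 0, 200), runif(8, 0, 200))
  pop <- rep(500, 8)
  obs <- c(12, 10, 2, 3, 1, 4, 2, 2)
  expd <- expectedCounts(pop, obs)
  win <- enumerateWindows(xy, pop, 0.4)
  top <- scanClusters(obs, expd, win, "high")[[1]]
  outside <- setdiff(seq_len(8), top$zone$members)
  obs2 <- obs
  obs2[outside] <- obs[sample(outside)]
  top2 <- scanClusters(obs2, expectedCounts(pop, obs2), win, "high")[[1]]
  expect_equal(top2$llr, top$llr, tolerance = 1e-12)
})

test_that("single-area region returns its only zone", {
  z <- enumerateWindows(cbind(0, 0), 100, 0.25)
  expect_length(z, 1)
  expect_equal(z[[1]]$members, 1L)
})

test_that("Monte-Carlo p has the 1/(nReps+1) floor and is seed-stable", {
  reg <- generateRegion(syntheticScenario(nAreas = 25, sdU = 0, sdV = 0,
                                          seed = 5,
    clusters = list(list(center = 13L, radius_km = 90, multiplier = 3))))
  obs <- caseCounts(reg, "high")
  expd <- expectedCounts(populations(reg), obs)
  win <- enumerateWindows(centroids(reg), populations(reg), 0.35,
                          ids = areaIds(reg))
  a <- kulldorffScan(obs, expd, win, nReps = 9, seed = 2)
  b <- kulldorffScan(obs, expd, win, nReps = 9, seed = 2)
  expect_identical(a@clusters$p_value, b@clusters$p_value)
  ## a 3x planted blob should beat all 9 replicates: p = 0.1
  expect_equal(a@clusters$p_value[1], 0.1)
  expect_equal(a@clusters$direction[1], "high")
})

test_that("planted clusters are recovered across seeds", {
  hits <- 0L
  nSeeds <- 10L
  for (s in seq_len(nSeeds)) {
    reg <- generateRegion(syntheticScenario(nAreas = 36, sdU = 0, sdV = 0,
                                            seed = 600 + s,
      clusters = list(list(center = 15L, radius_km = 80, multiplier = 2.5))))
    xy <- centroids(reg)
    planted <- which(sqrt((xy[, 1] - xy[15, 1])^2 +
                          (xy[, 2] - xy[15, 2])^2) <= 80)
    obs <- caseCounts(reg, "high")
    expd <- expectedCounts(populations(reg), obs)
    win <- enumerateWindows(xy, populations(reg), 0.35, ids = areaIds(reg))
    cl <- scanClusters(obs, expd, win, "high")
    if (length(cl) &&
        length(intersect(cl[[1]]$zone$members, planted)) >=
          ceiling(length(planted) / 2))
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
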
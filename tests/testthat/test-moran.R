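test_that("global Moran's I matches hand cases and the brute-force oracle", {
  W <- toySquareW()
  expect_equal(globalMoran(c(1, -1, -1, 1), W), -1)
  expect_error(globalMoran(rep(2, 4), W), "zero variance")
  ## random regions vs dense double-sum
  set.seed(21)
  for (k in 1:10) {
    n <- sample(5:12, 1)
    xy <- cbind(runif(n, 0, 300), runif(n, 0, 300))
    W <- spatialWeights(xy, radiusKm = 160)
    v <- rnorm(n)
    expect_equal(globalMoran(v, W), bfGlobalMoran(v, as.matrix(W)),
                 tolerance = 1e-10)
    expect_equal(localMoran(v, W), bfLocalMoran(v, as.matrix(W)),
                 tolerance = 1e-10)
    ## affine invariance
    expect_equal(globalMoran(3 * v + 7, W), globalMoran(v, W),
                 tolerance = 1e-10)
    expect_equal(localMoran(3 * v + 7, W), localMoran(v, W),
                 tolerance = 1e-10)
  }
})

test_that("permutation distribution has the -1/(n-1) null expectation", {
  set.seed(4)
  xy <- cbind(runif(9, 0, 200), runif(9, 0, 200))
  W <- spatialWeights(xy, radiusKm = 120)
  res <- globalMoranTest(rnorm(9), W, nPerm = 4999, seed = 10)
  expect_lt(abs(mean(res@permI) - (-1 / 8)), 0.01)
  expect_gte(res@pseudoP, 1 / 5000)
})

test_that("sampled pseudo-p agrees with the complete permutation set", {
  set.seed(6)
  xy <- cbind(runif(6, 0, 150), runif(6, 0, 150))
  W <- spatialWeights(xy, radiusKm = 120)
  v <- rnorm(6)
  obsI <- globalMoran(v, W)
  ## exhaustive relabelings (6! = 720)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ]
  allI <- apply(perms, 1, function(p) globalMoran(v[p], W))
  exactP <- if (obsI >= -1 / 5) mean(allI >= obsI - 1e-12)
            else mean(allI <= obsI + 1e-12)
  res <- globalMoranTest(v, W, nPerm = 999, seed = 2)
  se <- sqrt(exactP * (1 - exactP) / 999)
  expect_lt(abs(res@pseudoP - exactP), 4 * se + 2e-3)
})

test_that("local Moran handles isolated areas and sign logic", {
  xy <- cbind(c(0, 80, 500), c(0, 0, 0))
  W <- spatialWeights(xy, radiusKm = 120)
  v <- c(5, 4, 1)
  li <- localMoran(v, W)
  expect_equal(li[3], 0)            # isolated: empty neighbour sum
  expect_true(all(li[1:2] > 0))     # mutual high pair
})

test_that("LISA labels planted structure and respects the alpha guard", {
  ## 6x6 grid with a high blob in one corner
  xy <- cbind(rep(0:5, 6) * 50, rep(0:5, each = 6) * 50)
  W <- spatialWeights(xy, radiusKm = 75)
  set.seed(9)
  v <- rnorm(36, 0, 0.1)
  blob <- c(1, 2, 7, 8)             # adjacent corner cells
  v[blob] <- v[blob] + 3
  lisa <- lisaClassify(v, W, nPerm = 499, alpha = 0.05, seed = 3)
  expect_true(all(as.character(lisa@table$cluster[blob]) %in%
                  c("High-High", "High-Low")))
  expect_true(sum(lisa@table$cluster[blob] == "High-High") >= 2)
  ## significant only when p <= alpha; sign pairs consistent
  tab <- lisa@table
  z <- v - mean(v)
  sig <- tab$cluster != "Not Significant"
  expect_true(all(tab$pseudoP[sig] <= 0.05))
  expect_true(all(z[tab$cluster %in% c("High-High", "High-Low")] > 0))
  expect_true(all(z[tab$cluster %in% c("Low-Low", "Low-High")] <= 0))
  ## alpha = 0: everything Not Significant
  lisa0 <- lisaClassify(v, W, nPerm = 99, alpha = 0, seed = 3)
  expect_true(all(lisa0@table$cluster == "Not Significant"))
})

test_that("LISA results are reproducible from the master seed", {
  set.seed(14)
  xy <- cbind(runif(15, 0, 250), runif(15, 0, 250))
  W <- spatialWeights(xy, radiusKm = 120)
  v <- rnorm(15)
  a <- lisaClassify(v, W, nPerm = 199, seed = 8)
  b <- lisaClassify(v, W, nPerm = 199, seed = 8)
  expect_identical(a@table$pseudoP, b@table$pseudoP)
})
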
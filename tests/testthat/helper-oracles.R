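# Independent brute-force oracles and small fixtures built in code.
# The oracles deliberately re-derive each statistic from its definition
# (dense double loops, exhaustive enumeration) and never call the package
# functions they are checking.

# dense all-pairs Euclidean distances
bfDist <- function(xy) {
  n <- nrow(xy)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((xy[i, ] - xy[j, ])^2))
  d
}

# Moran's I by the literal double sum over a dense weight matrix
bfGlobalMoran <- function(values, Wm) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + Wm[i, j] * z[i] * z[j]
  (n / sum(Wm)) * num / sum(z^2)
}

bfLocalMoran <- function(values, Wm) {
  n <- length(values)
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- z[i] * sum(Wm[i, ] * z) / m2
  out
}

# Kulldorff LLR written out from the likelihood-ratio definition
bfLLR <- function(O, E, total) {
  t1 <- if (O > 0) O * log(O / E) else 0
  t2 <- if (total - O > 0) (total - O) * log((total - O) / (total - E)) else 0
  if (O == E) 0 else t1 + t2
}

# exhaustive best zone over all (center, radius) pairs under a population cap
bfBestZone <- function(xy, pop, obs, expd, frac, direction = "high") {
  n <- nrow(xy)
  d <- bfDist(xy)
  total <- sum(obs)
  best <- list(llr = -1, members = integer())
  for (i in seq_len(n)) for (j in seq_len(n)) {
    members <- which(d[i, ] <= d[i, j])
    if (sum(pop[members]) > frac * sum(pop)) next
    O <- sum(obs[members]); E <- sum(expd[members])
    if (E <= 0 || E >= sum(expd)) next
    dir <- if (O > E) "high" else if (O < E) "low" else "none"
    if (dir != direction) next
    llr <- bfLLR(O, E, total)
    if (llr > best$llr + 1e-12) best <- list(llr = llr, members = sort(members))
  }
  best
}

# small deterministic study region built from explicit tables
toyRegion <- function(n = 10, seed = 42) {
  set.seed(seed)
  areas <- data.frame(
    area_id = sprintf("T%02d", 1:n),
    x_km = runif(n, 0, 300), y_km = runif(n, 0, 300),
    population = sample(500:5000, n), phys_density = runif(n, 0.3, 3),
    remoteness = runif(n))
  counts <- matrix(rpois(4 * n, 10), n, 4,
                   dimnames = list(NULL, riskLevels()))
  StudyRegion(areas, counts)
}

# rook-adjacency unit square, row-standardized: the 4-area toy band
toySquareW <- function() {
  xy <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  spatialWeights(xy, radiusKm = 1)
}

fixturePath <- function(name) system.file("extdata", name, package = "sirbym")
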
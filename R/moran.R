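## sparse (dgCMatrix) view of a WeightMatrix, used by the permutation code
#' @importFrom Matrix sparseMatrix
.asSparse <- function(W) {
  n <- length(W@ids)
  i <- rep.int(seq_len(n), lengths(W@neighbors))
  j <- unlist(W@neighbors, use.names = FALSE)
  x <- unlist(W@weights, use.names = FALSE)
  if (!length(i)) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                              x = numeric(), dims = c(n, n)))
  Matrix::sparseMatrix(i = i, j = as.integer(j), x = x, dims = c(n, n))
}

.moranPrep <- function(values, W) {
  n <- length(W@ids)
  stopifnot(length(values) == n)
  if (any(!is.finite(values))) stop("values must be finite")
  z <- values - mean(values)
  if (all(z == 0)) stop("zero variance: constant value vector")
  S0 <- sum(unlist(W@weights, use.names = FALSE))
  if (S0 <= 0) stop("weight matrix has no links (S0 = 0)")
  list(n = n, z = z, S0 = S0, Wm = .asSparse(W))
}

#' Global Moran's I
#'
#' \eqn{I = (n/S_0)\, \sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2} with
#' \eqn{z_i} the deviations from the mean and \eqn{S_0 = \sum_{ij} w_{ij}}.
#' Under random relabelling \eqn{E[I] = -1/(n-1)}.
#'
#' @param values Numeric vector (e.g. crude SIRs), one per area of \code{W}.
#' @param W A [WeightMatrix-class].
#' @return Moran's I (numeric scalar).
#' @examples
#' xy <- cbind(rep(1:3, 3) * 50, rep(1:3, each = 3) * 50)
#' W <- spatialWeights(xy, radiusKm = 60)
#' globalMoran(as.numeric(xy[, 1] > 100), W)
#' @export
globalMoran <- function(values, W) {
  p <- .moranPrep(values, W)
  lag <- as.numeric(p$Wm %*% p$z)
  (p$n / p$S0) * sum(p$z * lag) / sum(p$z^2)
}

#' Permutation test for Global Moran's I
#'
#' Permutes the values uniformly over the areas \code{nPerm} times and
#' reports the one-sided pseudo p-value toward the observed tail:
#' \eqn{p = (1 + \#\{I^{perm} \ge I\})/(n_{perm}+1)} when the observed I
#' exceeds its null expectation \eqn{-1/(n-1)}, mirrored otherwise.
#'
#' @inheritParams globalMoran
#' @param nPerm Number of permutations (default 999).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A [GlobalMoranResult-class].
#' @examples
#' xy <- cbind(rep(1:4, 4) * 50, rep(1:4, each = 4) * 50)
#' W <- spatialWeights(xy, radiusKm = 60)
#' globalMoranTest(as.numeric(xy[, 1] > 100), W, nPerm = 99, seed = 1)
#' @export
globalMoranTest <- function(values, W, nPerm = 999, seed = 1L) {
  p <- .moranPrep(values, W)
  obsI <- (p$n / p$S0) * sum(p$z * as.numeric(p$Wm %*% p$z)) / sum(p$z^2)
  expI <- -1 / (p$n - 1)
  set.seed(seed)
  Zp <- vapply(seq_len(nPerm), function(b) p$z[sample.int(p$n)],
               numeric(p$n))
  lag <- as.matrix(p$Wm %*% Zp)
  permI <- (p$n / p$S0) * colSums(Zp * lag) / sum(p$z^2)
  extreme <- if (obsI >= expI) sum(permI >= obsI) else sum(permI <= obsI)
  new("GlobalMoranResult", I = obsI, expectedI = expI,
      pseudoP = (1 + extreme) / (nPerm + 1),
      nPerm = as.integer(nPerm), seed = as.integer(seed), permI = permI)
}

#' Local Moran's I
#'
#' \eqn{I_i = z_i \sum_j w_{ij} z_j / m_2} with \eqn{m_2 = \sum_k z_k^2 / n}
#' (n-denominator variance). Isolated areas (empty neighbour rows) get
#' \eqn{I_i = 0}.
#'
#' @inheritParams globalMoran
#' @return Numeric vector of local statistics \eqn{I_i}.
#' @export
localMoran <- function(values, W) {
  p <- .moranPrep(values, W)
  m2 <- sum(p$z^2) / p$n
  p$z * as.numeric(p$Wm %*% p$z) / m2
}

.LISA_LABELS <- c("High-High", "Low-Low", "Low-High", "High-Low",
                  "Not Significant")

#' LISA classification from Local Moran's I
#'
#' Conditional-permutation inference per area: \eqn{z_i} is held fixed and
#' the remaining values are permuted among the other areas; the pseudo
#' p-value is one-sided toward the observed tail. Areas significant at
#' \code{alpha} are labelled by the signs of \eqn{(z_i, \sum_j w_{ij} z_j)}:
#' (+,+) High-High, (-,-) Low-Low, (-,+) Low-High, (+,-) High-Low; all
#' others "Not Significant". One master seed derives a deterministic
#' per-area substream so results do not depend on iteration order.
#'
#' @inheritParams globalMoranTest
#' @param alpha Significance level for labelling (default 0.05).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   before labelling; default \code{"none"} (raw per-area tests).
#' @return A [LisaResult-class].
#' @examples
#' xy <- cbind(rep(1:4, 4) * 50, rep(1:4, each = 4) * 50)
#' W <- spatialWeights(xy, radiusKm = 60)
#' lisaClassify(rnorm(16), W, nPerm = 99, seed = 1)
#' @export
lisaClassify <- function(values, W, nPerm = 999, alpha = 0.05, seed = 1L,
                         adjust = "none") {
  p <- .moranPrep(values, W)
  n <- p$n
  m2 <- sum(p$z^2) / n
  lag <- as.numeric(p$Wm %*% p$z)
  Ii <- p$z * lag / m2
  set.seed(seed)
  areaSeeds <- sample.int(.Machine$integer.max, n)
  pseudo <- rep(1, n)
  for (i in seq_len(n)) {
    nb <- W@neighbors[[i]]
    if (!length(nb)) next            # isolated: I_i = 0, never significant
    wi <- W@weights[[i]]
    others <- p$z[-i]
    set.seed(areaSeeds[i])
    k <- length(nb)
    permIi <- vapply(seq_len(nPerm), function(b)
      p$z[i] * sum(wi * others[sample.int(n - 1L, k)]) / m2, numeric(1))
    extreme <- if (Ii[i] >= mean(permIi)) sum(permIi >= Ii[i])
               else sum(permIi <= Ii[i])
    pseudo[i] <- (1 + extreme) / (nPerm + 1)
  }
  padj <- stats::p.adjust(pseudo, method = adjust)
  sig <- padj <= alpha & lengths(W@neighbors) > 0
  cl <- rep(.LISA_LABELS[5], n)
  cl[sig & p$z > 0 & lag > 0]  <- .LISA_LABELS[1]
  cl[sig & p$z <= 0 & lag <= 0] <- .LISA_LABELS[2]
  cl[sig & p$z <= 0 & lag > 0] <- .LISA_LABELS[3]
  cl[sig & p$z > 0 & lag <= 0] <- .LISA_LABELS[4]
  tab <- DataFrame(area_id = W@ids, Ii = Ii, pseudoP = pseudo,
                   cluster = factor(cl, levels = .LISA_LABELS))
  new("LisaResult", table = tab, alpha = alpha,
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Write a LISA table (with global summary) to CSV
#'
#' @param lisa A [LisaResult-class].
#' @param global Optional [GlobalMoranResult-class]; appended as a summary
#'   row with area_id \code{"_global"}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeLisaTable <- function(lisa, file, global = NULL) {
  df <- as.data.frame(lisa@table)
  if (!is.null(global))
    df <- rbind(df, data.frame(area_id = "_global", Ii = global@I,
                               pseudoP = global@pseudoP,
                               cluster = sprintf("E[I]=%.4f", global@expectedI)))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
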
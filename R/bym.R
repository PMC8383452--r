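#' @useDynLib sirbym, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.adjParts <- function(adjacency) {
  if (!is(adjacency, "WeightMatrix")) stop("adjacency must be a WeightMatrix")
  if (adjacency@scheme != "binary") adjacency <- binaryAdjacency(adjacency)
  nb <- adjacency@neighbors
  iso <- lengths(nb) == 0L
  comp <- .components(nb)
  ## components among non-isolated areas only (isolated u_i are fixed at 0)
  nComp <- length(unique(comp[!iso]))
  ## relabel non-isolated components 1..nComp; isolated get 0
  compId <- integer(length(nb))
  compId[!iso] <- as.integer(factor(comp[!iso]))
  list(W = adjacency, nb = nb, iso = iso, compId = compId, nComp = nComp,
       rankU = sum(!iso) - nComp)
}

#' Log posterior density of the BYM model
#'
#' Pure-R evaluation (up to an additive constant) of the joint log density:
#' Poisson likelihood with mean \eqn{E_i \theta_i},
#' \eqn{\log\theta_i = c + \beta x_i + u_i + v_i}; intrinsic CAR prior for
#' \eqn{u} in pairwise-difference form
#' \eqn{\frac{rank}{2}\log\tau_u - \frac{\tau_u}{2}\sum_{i\sim j}(u_i-u_j)^2}
#' with rank = (non-isolated areas) - (connected components);
#' \eqn{v_i \sim N(0, 1/\tau_v)}; Gamma(shape, rate) priors on both
#' precisions; flat priors on \eqn{c} and \eqn{\beta}. Kept independent of
#' the compiled sampler as a cross-check path.
#'
#' @param state List with elements \code{c}, \code{u}, \code{v},
#'   \code{tauU}, \code{tauV} and optionally \code{beta}.
#' @param adjacency Binary [WeightMatrix-class].
#' @param observed,expected Per-area counts, \code{expected > 0}.
#' @param covariate Optional covariate vector (required when
#'   \code{state$beta} is present).
#' @param hyperShape,hyperRate Gamma hyper-prior, default (0.5, 0.0005).
#' @return Log density (numeric scalar, up to a constant).
#' @export
logPosterior <- function(state, adjacency, observed, expected,
                         covariate = NULL, hyperShape = 0.5,
                         hyperRate = 5e-4) {
  a <- .adjParts(adjacency)
  n <- length(observed)
  stopifnot(length(state$u) == n, length(state$v) == n, all(expected > 0))
  vals <- unlist(state[c("c", "u", "v", "tauU", "tauV", "beta")],
                 use.names = FALSE)
  if (any(!is.finite(vals))) stop("non-finite state")
  eta <- state$c + state$u + state$v
  if (!is.null(state$beta)) {
    stopifnot(!is.null(covariate))
    eta <- eta + state$beta * covariate
  }
  ll <- sum(stats::dpois(observed, expected * exp(eta), log = TRUE))
  ssPair <- 0
  for (i in seq_len(n)) for (j in a$nb[[i]]) if (j > i)
    ssPair <- ssPair + (state$u[i] - state$u[j])^2
  lpU <- 0.5 * a$rankU * log(state$tauU) - 0.5 * state$tauU * ssPair
  lpV <- sum(stats::dnorm(state$v, 0, 1 / sqrt(state$tauV), log = TRUE))
  lpTau <- stats::dgamma(state$tauU, hyperShape, rate = hyperRate, log = TRUE) +
           stats::dgamma(state$tauV, hyperShape, rate = hyperRate, log = TRUE)
  ll + lpU + lpV + lpTau
}

#' Fit the BYM model by MCMC
#'
#' Metropolis-within-Gibbs for the Besag-York-Mollie model: random-walk
#' Metropolis updates for the intercept, the optional covariate
#' coefficient and each \eqn{u_i}, \eqn{v_i}; conjugate Gamma draws for
#' both precisions (\eqn{\tau_u} shape uses the CAR rank
#' \eqn{n_{free} - \#components}); the structured effect is recentred to
#' sum to zero within each graph component after every sweep. Step sizes
#' adapt toward 30-45% acceptance during burn-in only, preserving detailed
#' balance afterwards. Chains start from overdispersed intercepts and
#' distinct precisions.
#'
#' The default schedule (3 chains x 30,000 iterations, burn-in 10,000,
#' thinning 10) is a desk-scale working default; any schedule can be
#' requested.
#'
#' @param observed,expected Per-area counts; all \code{expected} must be
#'   positive (drop zero-population areas first).
#' @param adjacency Binary [WeightMatrix-class] (any scheme is coerced).
#' @param covariate Optional ecological covariate \eqn{x_i}, used
#'   unstandardized (one covariate per run — "unconditional" models).
#' @param covariateName Label stored with the fit.
#' @param nChains,nIterations,burnIn,thin MCMC schedule.
#' @param seed Master seed; per-chain seeds are derived from it.
#' @param hyperShape,hyperRate Gamma hyper-prior on both precisions,
#'   default (0.5, 0.0005) (shape-rate convention).
#' @return A [BYMPosterior-class].
#' @examples
#' reg <- generateRegion(syntheticScenario(nAreas = 20, seed = 3))
#' obs <- caseCounts(reg, "high")
#' e <- expectedCounts(populations(reg), obs)
#' adj <- spatialWeights(reg, scheme = "binary")
#' fit <- runBYM(obs, e, adj, nChains = 2, nIterations = 2000,
#'               burnIn = 500, thin = 5, seed = 1)
#' head(smoothedSIR(fit))
#' @export
runBYM <- function(observed, expected, adjacency, covariate = NULL,
                   covariateName = if (is.null(covariate)) character() else "x",
                   nChains = 3, nIterations = 30000, burnIn = 10000,
                   thin = 10, seed = 1L, hyperShape = 0.5, hyperRate = 5e-4) {
  stopifnot(nChains >= 2, burnIn < nIterations, thin >= 1)
  n <- length(observed)
  stopifnot(length(expected) == n, all(expected > 0), all(observed >= 0))
  a <- .adjParts(adjacency)
  stopifnot(length(a$nb) == n)
  useBeta <- !is.null(covariate)
  if (useBeta) stopifnot(length(covariate) == n)
  x <- if (useBeta) as.numeric(covariate) else numeric(n)

  set.seed(seed)
  chainSeeds <- sample.int(.Machine$integer.max, nChains)
  cBase <- log(sum(observed) / sum(expected) + 1e-12)
  nKeep <- (nIterations - burnIn) %/% thin
  cD <- matrix(0, nKeep, nChains)
  bD <- matrix(0, nKeep, if (useBeta) nChains else 0)
  uD <- array(0, c(nKeep, n, nChains))
  vD <- array(0, c(nKeep, n, nChains))
  tU <- matrix(0, nKeep, nChains)
  tV <- matrix(0, nKeep, nChains)
  acc <- NULL
  for (ch in seq_len(nChains)) {
    set.seed(chainSeeds[ch])
    off <- 0.5 * (ch - (nChains + 1) / 2)
    res <- .bymChain(as.integer(observed), as.numeric(expected), x,
                     useBeta, lapply(a$nb, as.integer),
                     as.integer(a$iso), as.integer(a$rankU),
                     as.integer(nIterations), as.integer(burnIn),
                     as.integer(thin), hyperShape, hyperRate,
                     as.integer(a$compId), as.integer(a$nComp),
                     cBase + off, if (useBeta) 0.05 * off else 0,
                     2^(ch - 2), 2^(ch - 2))
    cD[, ch] <- res$c
    if (useBeta) bD[, ch] <- res$beta
    uD[, , ch] <- res$u
    vD[, , ch] <- res$v
    tU[, ch] <- res$tauU
    tV[, ch] <- res$tauV
    acc <- rbind(acc, res$accept)
  }
  accMean <- colMeans(acc, na.rm = TRUE)
  if (any(stats::na.omit(c(acc)) < 0.05 | stats::na.omit(c(acc)) > 0.95))
    warning("Metropolis acceptance rate outside [0.05, 0.95] after adaptation")
  theta <- array(0, c(nKeep, n, nChains))
  for (ch in seq_len(nChains)) {
    eta <- uD[, , ch] + vD[, , ch] + cD[, ch]
    if (useBeta) eta <- eta + outer(bD[, ch], x)
    theta[, , ch] <- exp(eta)
  }
  ids <- adjacency@ids
  if (!length(ids)) ids <- as.character(seq_len(n))
  new("BYMPosterior", c = cD, beta = bD, u = uD, v = vD, tauU = tU,
      tauV = tV, theta = theta, areaIds = ids,
      covariateName = covariateName, acceptance = accMean,
      config = list(nChains = nChains, nIterations = nIterations,
                    burnIn = burnIn, thin = thin, seed = seed,
                    hyperShape = hyperShape, hyperRate = hyperRate,
                    chainSeeds = chainSeeds))
}

#' Smoothed SIRs from a BYM fit
#'
#' Posterior mean of \eqn{\theta_i} per area — the BYM-smoothed SIR, which
#' shrinks unstable small-area crude SIRs toward their neighbourhood and
#' the regional level (strictly positive even where \eqn{O_i = 0}).
#'
#' @param posterior A [BYMPosterior-class].
#' @return Named numeric vector, one smoothed SIR per area.
#' @export
smoothedSIR <- function(posterior) {
  out <- apply(posterior@theta, 2, mean)
  names(out) <- posterior@areaIds
  out
}

#' Incidence rate ratio for the ecological covariate
#'
#' Point estimate \eqn{IRR = \exp(\bar\beta)} (exp of the posterior mean)
#' with 95% credible interval \eqn{\exp} of beta's 2.5% and 97.5%
#' quantiles; the association is "significant" when the CrI excludes 1.
#'
#' @param posterior A [BYMPosterior-class] fitted with a covariate.
#' @return List: \code{irr}, \code{cri} (length 2), \code{significant},
#'   \code{betaMean}, \code{betaCri}.
#' @export
irrSummary <- function(posterior) {
  if (!ncol(posterior@beta)) stop("null model: no covariate coefficient")
  b <- as.numeric(posterior@beta)
  betaCri <- unname(stats::quantile(b, c(0.025, 0.975)))
  list(irr = exp(mean(b)), cri = exp(betaCri),
       significant = betaCri[1] > 0 || betaCri[2] < 0,
       betaMean = mean(b), betaCri = betaCri)
}

#' Percent change in SIR per unit covariate
#'
#' For a negative coefficient, the average percent decrease in SIR per
#' one-unit covariate increase: \eqn{100\,(1 - e^{\bar\beta})}.
#'
#' @param betaMean Posterior mean of the log-linear coefficient.
#' @return Percent change (positive = decrease for negative \code{betaMean}).
#' @examples
#' percentChange(-0.067)  # ~6.5
#' @export
percentChange <- function(betaMean) 100 * (1 - exp(betaMean))

#' Posterior summary table
#'
#' @param object A [BYMPosterior-class].
#' @param ... Ignored.
#' @return \code{DataFrame} with mean and the 95% CrI bounds for the
#'   intercept, coefficient (if present), both precisions and every
#'   \eqn{\theta_i}.
#' @export
setMethod("summary", "BYMPosterior", function(object, ...) {
  q <- function(x) stats::quantile(x, c(0.025, 0.975))
  rows <- list(
    DataFrame(parameter = "c", mean = mean(object@c),
              lower = q(object@c)[1], upper = q(object@c)[2]))
  if (ncol(object@beta))
    rows <- c(rows, list(DataFrame(parameter = "beta",
                                   mean = mean(object@beta),
                                   lower = q(object@beta)[1],
                                   upper = q(object@beta)[2])))
  rows <- c(rows, list(
    DataFrame(parameter = "tau_u", mean = mean(object@tauU),
              lower = q(object@tauU)[1], upper = q(object@tauU)[2]),
    DataFrame(parameter = "tau_v", mean = mean(object@tauV),
              lower = q(object@tauV)[1], upper = q(object@tauV)[2])))
  th <- lapply(seq_along(object@areaIds), function(i) {
    x <- object@theta[, i, ]
    DataFrame(parameter = paste0("theta[", object@areaIds[i], "]"),
              mean = mean(x), lower = q(x)[1], upper = q(x)[2])
  })
  out <- do.call(rbind, c(rows, th))
  rownames(out) <- NULL
  out
})

## scalar chains for the diagnostics module: draw x chain matrices
.monitoredChains <- function(posterior) {
  out <- list(c = posterior@c, tau_u = posterior@tauU,
              tau_v = posterior@tauV)
  if (ncol(posterior@beta)) out$beta <- posterior@beta
  out
}
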
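#' SyntheticScenario: parameters of the areal-data generator
#'
#' Describes a synthetic study region with the statistical structure the
#' analysis chain assumes: a jittered-grid geography whose 120-km
#' distance band is connected at the default spacing, log-normal
#' populations, a physician-density-like covariate, and per-risk-level
#' Poisson counts around indirectly standardized expectations with a
#' CAR-structured log-relative-risk surface
#' \eqn{\log\theta_i = c + \beta x_i + u_i + v_i}.
#'
#' @slot nAreas number of areas (default 82, the study-region size).
#' @slot spacingKm grid spacing in km (default 60; the 120-km band then
#'   links each area to its grid neighbourhood).
#' @slot jitterKm uniform centroid jitter, km.
#' @slot popMedian,popSdlog log-normal population model (median men 35+
#'   per area and log-sd).
#' @slot intercept,beta,sdU,sdV true surface parameters: intercept
#'   \eqn{c}, covariate effect \eqn{\beta} (per 1 physician/1000), and the
#'   standard deviations of the structured (CAR) and unstructured effects.
#' @slot covariateModel \code{"lognormal"} (i.i.d.) or \code{"smooth"}
#'   (spatially correlated); both have median ~1 physician per 1000.
#' @slot covSdlog log-scale spread of the covariate.
#' @slot overallRate named per-level 5-year case rate among men 35+
#'   (drives the expected counts).
#' @slot clusters list of planted circular clusters, each
#'   \code{list(center=<area index>, radius_km=<km>, multiplier=<rr>)},
#'   applied to \eqn{\theta} before sampling.
#' @slot seed integer seed; generation is fully reproducible.
#' @export
setClass("SyntheticScenario",
  representation(nAreas = "integer", spacingKm = "numeric",
                 jitterKm = "numeric", popMedian = "numeric",
                 popSdlog = "numeric", intercept = "numeric",
                 beta = "numeric", sdU = "numeric", sdV = "numeric",
                 covariateModel = "character", covSdlog = "numeric",
                 overallRate = "numeric", clusters = "list",
                 seed = "integer"))

#' Build a synthetic scenario
#'
#' Defaults emulate the study conditions: 82 areas on a ~540 x 480 km
#' jittered grid, log-normal populations (median 2500 men 35+, log-sd 1,
#' total ~3.3e5), per-level rates sized so the four risk levels total
#' roughly 400/1100/1050/450 cases, a log-normal physician-density
#' covariate with median 1 per 1000, and a moderately autocorrelated risk
#' surface (sdU = 0.3, sdV = 0.1). Set \code{sdU = sdV = 0} (and
#' \code{beta = 0}) for the flat null surface \eqn{\theta \equiv e^c}.
#'
#' @param nAreas,spacingKm,jitterKm,popMedian,popSdlog,intercept,beta,sdU,sdV,covariateModel,covSdlog,overallRate,clusters,seed
#'   See [SyntheticScenario-class].
#' @return A [SyntheticScenario-class].
#' @examples
#' syntheticScenario(seed = 1)
#' @export
syntheticScenario <- function(nAreas = 82, spacingKm = 60, jitterKm = 10,
                              popMedian = 2500, popSdlog = 1,
                              intercept = 0, beta = 0, sdU = 0.3,
                              sdV = 0.1,
                              covariateModel = c("lognormal", "smooth"),
                              covSdlog = 0.6,
                              overallRate = c(metastatic = 0.00135,
                                              high = 0.0036,
                                              intermediate = 0.0035,
                                              low = 0.0015),
                              clusters = list(), seed = 1L) {
  covariateModel <- match.arg(covariateModel)
  if (length(overallRate) == 1L)
    overallRate <- stats::setNames(rep(overallRate, 4), riskLevels())
  stopifnot(all(riskLevels() %in% names(overallRate)),
            all(overallRate >= 0), nAreas >= 1)
  new("SyntheticScenario", nAreas = as.integer(nAreas),
      spacingKm = spacingKm, jitterKm = jitterKm, popMedian = popMedian,
      popSdlog = popSdlog, intercept = intercept, beta = beta, sdU = sdU,
      sdV = sdV, covariateModel = covariateModel, covSdlog = covSdlog,
      overallRate = overallRate[riskLevels()], clusters = clusters,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf("SyntheticScenario: %d areas, %g-km grid (jitter %g km), seed %d\n",
              object@nAreas, object@spacingKm, object@jitterKm, object@seed))
  cat(sprintf("  surface: c=%g beta=%g sdU=%g sdV=%g; covariate: %s\n",
              object@intercept, object@beta, object@sdU, object@sdV,
              object@covariateModel))
  if (length(object@clusters))
    cat("  planted clusters:", length(object@clusters), "\n")
})

## zero-mean draw from the intrinsic CAR prior N(0, sd^2 * L^+), centered
## within each connected component; isolated areas get 0
.rICAR <- function(neighbors, sd) {
  n <- length(neighbors)
  if (sd == 0) return(numeric(n))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, neighbors[[i]]] <- 1
  L <- diag(rowSums(A)) - A
  e <- eigen(L, symmetric = TRUE)
  pos <- e$values > max(e$values, 1) * 1e-10
  if (!any(pos)) return(numeric(n))
  z <- stats::rnorm(sum(pos))
  as.numeric(e$vectors[, pos, drop = FALSE] %*% (z / sqrt(e$values[pos]))) * sd
}

#' Simulate a CAR-structured relative-risk surface
#'
#' Draws \eqn{u} from the intrinsic CAR distribution (a centered
#' multivariate normal on the graph Laplacian's pseudo-inverse, scaled by
#' \code{sdU}; sum-to-zero per component, isolated areas 0), i.i.d.
#' \eqn{v_i \sim N(0, sdV^2)}, and returns
#' \eqn{\theta_i = \exp(c + \beta x_i + u_i + v_i)}. The same model
#' density the BYM sampler assumes, written as an independent code path.
#'
#' @param region A [StudyRegion-class] (supplies the covariate default).
#' @param adjacency A [WeightMatrix-class] over the same areas.
#' @param c,beta,sdU,sdV Surface parameters.
#' @param covariate Covariate vector (default physician density).
#' @param seed Integer seed.
#' @return Numeric \eqn{\theta} vector with attributes \code{"u"} and
#'   \code{"v"}.
#' @export
simulateRiskSurface <- function(region, adjacency, c = 0, beta = 0,
                                sdU = 0.3, sdV = 0.1,
                                covariate = physicianDensity(region),
                                seed = 1L) {
  set.seed(seed)
  n <- nrow(region)
  stopifnot(length(adjacency@neighbors) == n)
  u <- .rICAR(adjacency@neighbors, sdU)
  v <- stats::rnorm(n, 0, sdV)
  theta <- exp(c + beta * covariate + u + v)
  attr(theta, "u") <- u
  attr(theta, "v") <- v
  theta
}

#' Simulate observed case counts
#'
#' Baseline expectations \eqn{E_i = n_i \cdot rate}; any planted clusters
#' multiply \eqn{\theta} inside their circles; counts are drawn
#' \eqn{O_i \sim Poisson(E_i \theta_i)}.
#'
#' @param region A [StudyRegion-class].
#' @param theta Relative-risk vector.
#' @param overallRate Scalar case rate among men 35+.
#' @param seed Integer seed.
#' @param clusters Planted clusters (see [SyntheticScenario-class]).
#' @return Integer count vector.
#' @export
simulateCases <- function(region, theta, overallRate, seed = 1L,
                          clusters = list()) {
  set.seed(seed)
  stopifnot(overallRate >= 0)
  n <- nrow(region)
  E <- populations(region) * overallRate
  th <- as.numeric(theta)
  if (length(clusters)) {
    xy <- centroids(region)
    for (cl in clusters) {
      ctr <- xy[cl$center, ]
      d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
      th[d <= cl$radius_km] <- th[d <= cl$radius_km] * cl$multiplier
    }
  }
  stats::rpois(n, E * th)
}

#' Generate a synthetic study region
#'
#' Builds the geography (jittered grid spanning a domain whose default
#' spacing keeps the 120-km band connected), draws populations and the
#' covariate, simulates an independent risk surface and case counts per
#' risk level, and returns a [StudyRegion-class]. The true surfaces are
#' stored in \code{metadata(region)$truth}. Byte-identical on re-run for a
#' fixed scenario.
#'
#' @param scenario A [SyntheticScenario-class].
#' @return A [StudyRegion-class].
#' @examples
#' reg <- generateRegion(syntheticScenario(nAreas = 20, seed = 1))
#' reg
#' @export
generateRegion <- function(scenario) {
  stopifnot(is(scenario, "SyntheticScenario"))
  n <- scenario@nAreas
  set.seed(scenario@seed)
  subSeeds <- sample.int(.Machine$integer.max, 2L + 2L * length(riskLevels()))
  ## geography: first n cells of a near-square grid, row-major
  set.seed(subSeeds[1])
  ncols <- ceiling(sqrt(n))
  ix <- (seq_len(n) - 1L) %% ncols
  iy <- (seq_len(n) - 1L) %/% ncols
  x <- ix * scenario@spacingKm +
       stats::runif(n, -scenario@jitterKm, scenario@jitterKm)
  y <- iy * scenario@spacingKm +
       stats::runif(n, -scenario@jitterKm, scenario@jitterKm)
  pop <- pmax(1, round(stats::rlnorm(n, log(scenario@popMedian),
                                     scenario@popSdlog)))
  ids <- sprintf("GA%02d", seq_len(n))
  ## covariate and remoteness
  set.seed(subSeeds[2])
  adjNb <- if (n >= 2) {
    distanceBandNeighbors(cbind(x, y), 120, ids = ids)
  } else {
    structure(list(integer()), ids = ids)
  }
  phys <- if (scenario@covariateModel == "lognormal") {
    stats::rlnorm(n, 0, scenario@covSdlog)
  } else {
    exp(.rICAR(adjNb, 0.8 * scenario@covSdlog) +
        stats::rnorm(n, 0, 0.5 * scenario@covSdlog))
  }
  remote <- if (n > 1 && max(y) > min(y))
    (y - min(y)) / (max(y) - min(y)) + stats::rnorm(n, 0, 0.05)
  else stats::rnorm(n, 0, 0.05)
  width <- max(x) - min(x); height <- max(y) - min(y)
  ctrA <- c(min(x) + 0.3 * width, min(y) + 0.25 * height)
  ctrB <- c(min(x) + 0.7 * width, min(y) + 0.25 * height)
  centre <- nearestCentre(cbind(x, y), ctrA, ctrB)
  areas <- data.frame(area_id = ids, x_km = x, y_km = y,
                      population = as.integer(pop),
                      phys_density = phys, remoteness = remote,
                      nearest_centre = centre)
  ## per-level surfaces and counts
  adjW <- if (n >= 2) inverseDistanceWeights(adjNb, cbind(x, y)) else NULL
  adjB <- if (n >= 2) binaryAdjacency(adjW) else NULL
  counts <- matrix(0L, n, length(riskLevels()),
                   dimnames = list(ids, riskLevels()))
  truth <- list(scenario = scenario, theta = list(), u = list(), v = list())
  regTmp <- StudyRegion(areas, counts)
  for (k in seq_along(riskLevels())) {
    lv <- riskLevels()[k]
    theta <- if (n >= 2) {
      simulateRiskSurface(regTmp, adjB, c = scenario@intercept,
                          beta = scenario@beta, sdU = scenario@sdU,
                          sdV = scenario@sdV, covariate = phys,
                          seed = subSeeds[1L + 2L * k])
    } else structure(rep(exp(scenario@intercept), n), u = 0, v = 0)
    counts[, lv] <- simulateCases(regTmp, theta,
                                  scenario@overallRate[[lv]],
                                  seed = subSeeds[2L + 2L * k],
                                  clusters = scenario@clusters)
    truth$theta[[lv]] <- as.numeric(theta)
    truth$u[[lv]] <- attr(theta, "u")
    truth$v[[lv]] <- attr(theta, "v")
  }
  StudyRegion(areas, counts, metadata = list(truth = truth))
}
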
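.pairDist <- function(centroids) {
  as.matrix(stats::dist(centroids))
}

#' Distance-band neighbours
#'
#' Areas within \code{radiusKm} (inclusive) of an area's centroid are its
#' neighbours; the relation is symmetric and areas outside every band are
#' left isolated. Distances are planar Euclidean in km — coordinates must
#' already be projected.
#'
#' @param centroids Two-column matrix of planar coordinates (km).
#' @param radiusKm Band radius, default 120.
#' @param ids Optional area ids (default \code{"1"..."n"} or rownames).
#' @return List of integer neighbour vectors, one per area, with the ids as
#'   a \code{"ids"} attribute.
#' @examples
#' distanceBandNeighbors(cbind(c(0, 100, 300), 0), 120)
#' @export
distanceBandNeighbors <- function(centroids, radiusKm = 120, ids = NULL) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  stopifnot(n >= 2, radiusKm > 0)
  if (is.null(ids)) ids <- rownames(centroids)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- .pairDist(centroids)
  dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup))
    stop(sprintf("duplicate centroids: areas '%s' and '%s' coincide",
                 ids[dup[1, 1]], ids[dup[1, 2]]))
  nb <- lapply(seq_len(n), function(i)
    as.integer(which(d[i, ] > 0 & d[i, ] <= radiusKm)))
  attr(nb, "ids") <- ids
  attr(nb, "centroids") <- centroids
  nb
}

#' Inverse-distance weights on a neighbour structure
#'
#' \eqn{w_{ij} = 1 / d_{ij}} (km) for every neighbour pair; symmetric by
#' construction before any row standardization.
#'
#' @param neighbors Neighbour lists from [distanceBandNeighbors()].
#' @param centroids Coordinates (defaults to those stored on
#'   \code{neighbors}).
#' @return A [WeightMatrix-class] with scheme \code{"inverse_distance"}.
#' @examples
#' nb <- distanceBandNeighbors(cbind(c(0, 100, 300), 0), 120)
#' inverseDistanceWeights(nb)
#' @export
inverseDistanceWeights <- function(neighbors, centroids = attr(neighbors, "centroids")) {
  ids <- attr(neighbors, "ids")
  if (is.null(ids)) ids <- as.character(seq_along(neighbors))
  centroids <- as.matrix(centroids)
  d <- .pairDist(centroids)
  w <- lapply(seq_along(neighbors), function(i) {
    nb <- neighbors[[i]]
    if (length(nb)) unname(1 / d[i, nb]) else numeric()
  })
  new("WeightMatrix", ids = ids,
      neighbors = lapply(neighbors, as.integer), weights = w,
      scheme = "inverse_distance", rowStandardized = FALSE)
}

#' Row-standardize a weight matrix
#'
#' Scales each non-empty row to sum to one (the GeoDa convention for Moran
#' statistics); empty rows are left empty. Idempotent.
#'
#' @param W A [WeightMatrix-class].
#' @return The row-standardized \code{WeightMatrix}.
#' @export
rowStandardize <- function(W) {
  w <- lapply(W@weights, function(wi) if (length(wi)) wi / sum(wi) else wi)
  methods::initialize(W, weights = w, rowStandardized = TRUE)
}

#' Binary adjacency from any weight matrix
#'
#' Keeps the neighbour relation, sets all weights to 1 — the form the
#' intrinsic CAR prior consumes.
#'
#' @param W A [WeightMatrix-class].
#' @return A binary \code{WeightMatrix}.
#' @export
binaryAdjacency <- function(W) {
  w <- lapply(W@weights, function(wi) rep(1, length(wi)))
  methods::initialize(W, weights = w, scheme = "binary",
                      rowStandardized = FALSE)
}

#' Convenience builder: distance-band spatial weights
#'
#' @param region A [StudyRegion-class] (or a two-column centroid matrix).
#' @param radiusKm Band radius in km (default 120).
#' @param scheme \code{"inverse_distance"} or \code{"binary"}.
#' @param standardize Row-standardize (default TRUE for inverse-distance,
#'   ignored for binary).
#' @param excludeZeroPop Drop zero-population areas before banding (they are
#'   excluded from all SIR/clustering vectors); default TRUE for regions.
#' @return A [WeightMatrix-class].
#' @examples
#' reg <- generateRegion(syntheticScenario(nAreas = 20, seed = 1))
#' spatialWeights(reg)
#' @export
spatialWeights <- function(region, radiusKm = 120,
                           scheme = c("inverse_distance", "binary"),
                           standardize = TRUE, excludeZeroPop = TRUE) {
  scheme <- match.arg(scheme)
  if (is(region, "StudyRegion")) {
    xy <- centroids(region)
    rownames(xy) <- areaIds(region)
    if (excludeZeroPop) xy <- xy[populations(region) > 0, , drop = FALSE]
  } else xy <- as.matrix(region)
  nb <- distanceBandNeighbors(xy, radiusKm)
  W <- inverseDistanceWeights(nb, xy)
  if (scheme == "binary") return(binaryAdjacency(W))
  if (standardize) W <- rowStandardize(W)
  W
}

#' Assign each area its nearest assessment centre
#'
#' Labels each area \code{"A"} or \code{"B"} by the shorter planar
#' Euclidean distance from its centroid to the two centre points; exact
#' ties go to \code{"A"} with a warning.
#'
#' @param centroids Two-column coordinate matrix (km).
#' @param centreA,centreB Length-2 numeric points (km).
#' @return Character vector of \code{"A"}/\code{"B"} labels.
#' @examples
#' nearestCentre(cbind(0, 0), c(10, 0), c(100, 0))
#' @export
nearestCentre <- function(centroids, centreA, centreB) {
  centroids <- as.matrix(centroids)
  dA <- sqrt((centroids[, 1] - centreA[1])^2 + (centroids[, 2] - centreA[2])^2)
  dB <- sqrt((centroids[, 1] - centreB[1])^2 + (centroids[, 2] - centreB[2])^2)
  ties <- which(dA == dB)
  if (length(ties))
    warning(sprintf("%d area(s) equidistant from both centres; assigned to centre A",
                    length(ties)))
  ifelse(dA <= dB, "A", "B")
}

#' Export weights as an adjacency list
#'
#' One line per directed link: \code{area_id,neighbor_id,weight} — a plain
#' format cross-checkable against external tools.
#'
#' @param W A [WeightMatrix-class].
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeWeights <- function(W, file) {
  rows <- lapply(seq_along(W@ids), function(i) {
    nb <- W@neighbors[[i]]
    if (!length(nb)) return(NULL)
    data.frame(area_id = W@ids[i], neighbor_id = W@ids[nb],
               weight = W@weights[[i]])
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

## connected components of the neighbour graph (isolated areas are their
## own singleton components); used by the CAR rank correction and the
## synthetic CAR draw
.components <- function(neighbors) {
  n <- length(neighbors)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      i <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[i]) next
      comp[i] <- cur
      stack <- c(stack, neighbors[[i]][comp[neighbors[[i]]] == 0L])
    }
  }
  comp
}
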
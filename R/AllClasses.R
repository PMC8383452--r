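#' @importFrom methods new validObject is as setClass setGeneric setMethod setValidity show slot
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

## Canonical risk-level ordering used throughout (GUROC levels plus a
## "metastatic" level for cases presenting with metastases).
.RISK_LEVELS <- c("metastatic", "high", "intermediate", "low")

#' Risk levels recognised by the package
#'
#' The four prostate-cancer risk levels every case count is attributed to:
#' the three GUROC clinical levels (high, intermediate, low) plus
#' "metastatic". The ordering is canonical and shared by all matrices
#' derived from a [StudyRegion].
#'
#' @return Character vector of the four level labels, in canonical order.
#' @examples
#' riskLevels()
#' @export
riskLevels <- function() .RISK_LEVELS

#' StudyRegion: areal case-count data for small-area disease mapping
#'
#' A \code{StudyRegion} extends
#' \linkS4class{SummarizedExperiment}: rows are geographic areas (GAs),
#' columns are the four risk levels, and the single assay
#' \code{"counts"} holds the observed case counts \eqn{O_i}. Area-level
#' attributes (planar centroid coordinates in km, male population aged
#' 35+, family-physician density per 1000 population, remoteness index,
#' and optionally the nearest assessment centre) live in \code{rowData}.
#'
#' The row (area) ordering is fixed at construction and shared by every
#' vector and matrix derived downstream (weights, SIRs, random effects).
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @seealso [StudyRegion()] for construction, [sirTable()] for SIRs.
#' @export
setClass("StudyRegion", contains = "SummarizedExperiment")

setValidity("StudyRegion", function(object) {
  msg <- character()
  rd <- rowData(object)
  need <- c("x_km", "y_km", "population", "phys_density", "remoteness")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData is missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "area ids (rownames) must be present and unique")
  if (!identical(colnames(object), .RISK_LEVELS))
    msg <- c(msg, paste0("columns must be exactly the risk levels: ",
                         paste(.RISK_LEVELS, collapse = ", ")))
  if (!"counts" %in% assayNames(object)) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    cnt <- assay(object, "counts")
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be finite non-negative integers")
  }
  if (!length(msg)) {
    if (any(!is.finite(rd$population)) || any(rd$population < 0) ||
        any(rd$population != round(rd$population)))
      msg <- c(msg, "population must be non-negative integers")
    if (any(!is.finite(rd$phys_density)) || any(rd$phys_density < 0))
      msg <- c(msg, "phys_density must be non-negative")
    if (any(!is.finite(rd$x_km)) || any(!is.finite(rd$y_km)))
      msg <- c(msg, "centroid coordinates must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StudyRegion
#'
#' @param areas A \code{data.frame} (or \code{DataFrame}) with one row per
#'   geographic area and columns \code{area_id}, \code{x_km}, \code{y_km}
#'   (planar centroid coordinates in km), \code{population} (men aged 35+),
#'   \code{phys_density} (family physicians per 1000 population) and
#'   \code{remoteness}; an optional \code{nearest_centre} column
#'   (\code{"A"}/\code{"B"}) is carried through.
#' @param counts Matrix or data.frame of observed case counts, one row per
#'   area (same order as \code{areas}) and one column per risk level; column
#'   names must cover \code{riskLevels()} (reordered canonically).
#' @param metadata Optional named list stored in \code{metadata()} (the
#'   synthetic generator records the true risk surface here).
#'
#' @return A [StudyRegion-class] object.
#' @examples
#' areas <- data.frame(area_id = c("a", "b"), x_km = c(0, 50), y_km = c(0, 0),
#'                     population = c(1000L, 2000L), phys_density = c(1, 2),
#'                     remoteness = c(0.2, 0.4))
#' cnt <- matrix(1L, 2, 4, dimnames = list(NULL, riskLevels()))
#' StudyRegion(areas, cnt)
#' @export
StudyRegion <- function(areas, counts, metadata = list()) {
  areas <- as.data.frame(areas)
  req <- c("area_id", "x_km", "y_km", "population")
  miss <- setdiff(req, colnames(areas))
  if (length(miss))
    stop("areas is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(areas$phys_density)) areas$phys_density <- 0
  if (is.null(areas$remoteness))   areas$remoteness <- 0
  counts <- as.matrix(as.data.frame(counts))
  miss <- setdiff(.RISK_LEVELS, colnames(counts))
  if (length(miss))
    stop("counts is missing risk level(s): ", paste(miss, collapse = ", "))
  counts <- counts[, .RISK_LEVELS, drop = FALSE]
  storage.mode(counts) <- "integer"
  if (nrow(counts) != nrow(areas))
    stop("areas and counts must have the same number of rows")
  rd <- areas[, setdiff(colnames(areas), "area_id"), drop = FALSE]
  se <- SummarizedExperiment(
    assays  = SimpleList(counts = counts),
    rowData = DataFrame(rd),
    metadata = metadata)
  rownames(se) <- as.character(areas$area_id)
  colnames(se) <- .RISK_LEVELS
  new("StudyRegion", se)
}

setMethod("show", "StudyRegion", function(object) {
  cnt <- assay(object, "counts")
  cat("StudyRegion with", nrow(object), "geographic areas\n")
  cat("  total population (men 35+):",
      format(sum(rowData(object)$population), big.mark = ","), "\n")
  tot <- colSums(cnt)
  cat("  observed cases:",
      paste(sprintf("%s=%d", names(tot), tot), collapse = ", "),
      sprintf("(total %d)\n", sum(tot)))
  iso <- sum(rowData(object)$population == 0)
  if (iso) cat("  areas with zero population:", iso, "\n")
})

#' WeightMatrix: spatial neighbourhood structure
#'
#' Sparse neighbour lists plus aligned pairwise weights for a fixed area
#' ordering, under one of two schemes: \code{"inverse_distance"}
#' (\eqn{w_{ij} = 1/d_{ij}}, used by the Moran statistics) or
#' \code{"binary"} (adjacency for the intrinsic CAR prior). The neighbour
#' relation is symmetric and free of self-neighbours; isolated areas have
#' empty rows.
#'
#' @slot ids character, area ids in the shared ordering.
#' @slot neighbors list of integer vectors, 1-based neighbour indices.
#' @slot weights list of numeric vectors aligned with \code{neighbors}.
#' @slot scheme \code{"inverse_distance"} or \code{"binary"}.
#' @slot rowStandardized logical; if TRUE every non-empty row sums to 1.
#' @seealso [distanceBandNeighbors()], [inverseDistanceWeights()],
#'   [rowStandardize()], [binaryAdjacency()]
#' @export
setClass("WeightMatrix",
  representation(ids = "character", neighbors = "list", weights = "list",
                 scheme = "character", rowStandardized = "logical"))

setValidity("WeightMatrix", function(object) {
  n <- length(object@ids)
  msg <- character()
  if (length(object@neighbors) != n || length(object@weights) != n)
    return("neighbors and weights must have one entry per area")
  if (anyDuplicated(object@ids)) msg <- c(msg, "area ids must be unique")
  if (!object@scheme %in% c("inverse_distance", "binary"))
    msg <- c(msg, "scheme must be 'inverse_distance' or 'binary'")
  for (i in seq_len(n)) {
    nb <- object@neighbors[[i]]
    w  <- object@weights[[i]]
    if (length(nb) != length(w))
      return(sprintf("row %d: neighbors and weights lengths differ", i))
    if (length(nb)) {
      if (any(nb < 1L | nb > n)) return(sprintf("row %d: index out of range", i))
      if (any(nb == i)) msg <- c(msg, sprintf("row %d: self-neighbor", i))
      if (anyDuplicated(nb)) msg <- c(msg, sprintf("row %d: duplicated neighbor", i))
      if (any(w <= 0)) msg <- c(msg, sprintf("row %d: non-positive weight", i))
      ## symmetry of the relation
      for (j in nb) if (!(i %in% object@neighbors[[j]]))
        return(sprintf("asymmetric relation: %d in N(%d) but not vice versa", j, i))
    }
  }
  if (length(msg)) msg[1] else TRUE
})

setMethod("show", "WeightMatrix", function(object) {
  deg <- lengths(object@neighbors)
  cat(sprintf("WeightMatrix (%s%s) for %d areas\n", object@scheme,
              if (object@rowStandardized) ", row-standardized" else "",
              length(object@ids)))
  cat(sprintf("  links: %d, mean degree %.1f, isolated areas: %d\n",
              sum(deg) / 2, mean(deg), sum(deg == 0)))
})

#' Dense matrix form of a WeightMatrix (zero off-neighbourhood).
#' @param x A \code{WeightMatrix}.
#' @param ... ignored.
#' @return Dense numeric n x n matrix.
#' @export
as.matrix.WeightMatrix <- function(x, ...) {
  n <- length(x@ids)
  m <- matrix(0, n, n, dimnames = list(x@ids, x@ids))
  for (i in seq_len(n))
    m[i, x@neighbors[[i]]] <- x@weights[[i]]
  m
}

#' @describeIn WeightMatrix-class dense matrix form.
#' @param x A \code{WeightMatrix}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "WeightMatrix", as.matrix.WeightMatrix)

#' GlobalMoranResult: permutation test for Global Moran's I
#'
#' @slot I observed Moran's I.
#' @slot expectedI null expectation \eqn{-1/(n-1)}.
#' @slot pseudoP one-sided permutation pseudo p-value,
#'   \eqn{(1 + \#\{I^{perm} \ge I\})/(n_{perm}+1)} toward the observed tail.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used.
#' @slot permI the permuted statistics (for diagnostics/plots).
#' @export
setClass("GlobalMoranResult",
  representation(I = "numeric", expectedI = "numeric", pseudoP = "numeric",
                 nPerm = "integer", seed = "integer", permI = "numeric"))

setMethod("show", "GlobalMoranResult", function(object) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f)\n",
              object@I, object@expectedI))
  cat(sprintf("  pseudo p = %.4f (%d permutations)\n",
              object@pseudoP, object@nPerm))
})

#' LisaResult: Local Moran's I with LISA cluster classification
#'
#' @slot table a \code{DataFrame} with per-area columns \code{area_id},
#'   \code{Ii}, \code{pseudoP}, \code{cluster} (one of \code{"High-High"},
#'   \code{"Low-Low"}, \code{"Low-High"}, \code{"High-Low"},
#'   \code{"Not Significant"}).
#' @slot alpha significance level used for classification.
#' @slot nPerm conditional permutations per area.
#' @slot seed master seed.
#' @export
setClass("LisaResult",
  representation(table = "DataFrame", alpha = "numeric",
                 nPerm = "integer", seed = "integer"))

setMethod("show", "LisaResult", function(object) {
  cat(sprintf("Local Moran's I (LISA), %d areas, alpha = %g, %d permutations\n",
              nrow(object@table), object@alpha, object@nPerm))
  print(table(object@table$cluster))
})

#' ScanResult: Kulldorff spatial scan clusters
#'
#' Ranked non-overlapping clusters from the purely spatial Poisson scan.
#'
#' @slot clusters \code{DataFrame} with columns \code{rank},
#'   \code{direction}, \code{center_area}, \code{radius_km},
#'   \code{members} (semicolon-separated area ids), \code{observed},
#'   \code{expected}, \code{rr} (relative risk inside vs outside),
#'   \code{llr}, \code{p_value}.
#' @slot nReps Monte-Carlo replicates used for the p-values.
#' @slot seed RNG seed.
#' @export
setClass("ScanResult",
  representation(clusters = "DataFrame", nReps = "integer", seed = "integer"))

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("Kulldorff spatial scan: %d non-overlapping cluster(s), %d replicates\n",
              nrow(object@clusters), object@nReps))
  if (nrow(object@clusters))
    print(as.data.frame(object@clusters[, c("rank", "direction", "center_area",
                                            "observed", "expected", "llr",
                                            "p_value")]))
})

#' BYMPosterior: MCMC draws from the Besag-York-Mollie model
#'
#' Retained (post burn-in, thinned) draws from \code{nChains} chains of the
#' Metropolis-within-Gibbs sampler for the BYM model
#' \eqn{O_i \sim Poisson(E_i \theta_i)},
#' \eqn{\log\theta_i = c + \beta x_i + u_i + v_i} with an intrinsic CAR
#' prior on \eqn{u} (sum-to-zero constrained) and i.i.d. normal \eqn{v}.
#'
#' @slot c matrix (draw x chain) of intercept draws.
#' @slot beta matrix of covariate-coefficient draws, or 0-column matrix for
#'   the null model.
#' @slot u array (draw x area x chain) of structured effects.
#' @slot v array of unstructured effects.
#' @slot tauU,tauV matrices of precision draws.
#' @slot theta array (draw x area x chain) of relative risks
#'   \eqn{\theta_i = \exp(c + \beta x_i + u_i + v_i)}.
#' @slot areaIds character.
#' @slot covariateName character (length 0 for the null model).
#' @slot acceptance named numeric, mean Metropolis acceptance rates.
#' @slot config list: nChains, nIterations, burnIn, thin, seed, hyper prior.
#' @export
setClass("BYMPosterior",
  representation(c = "matrix", beta = "matrix", u = "array", v = "array",
                 tauU = "matrix", tauV = "matrix", theta = "array",
                 areaIds = "character", covariateName = "character",
                 acceptance = "numeric", config = "list"))

setMethod("show", "BYMPosterior", function(object) {
  nd <- nrow(object@c)
  cat(sprintf("BYMPosterior: %d areas, %d chains x %d retained draws%s\n",
              length(object@areaIds), ncol(object@c), nd,
              if (length(object@covariateName))
                paste0(", covariate '", object@covariateName, "'") else " (null model)"))
  cat(sprintf("  intercept mean %.3f; tau_u mean %.2f; tau_v mean %.2f\n",
              mean(object@c), mean(object@tauU), mean(object@tauV)))
  if (length(object@covariateName)) {
    ir <- irrSummary(object)
    cat(sprintf("  beta mean %.4f, IRR %.3f (95%% CrI %.3f to %.3f)%s\n",
                mean(object@beta), ir$irr, ir$cri[1], ir$cri[2],
                if (ir$significant) "" else "  [not significant]"))
  }
})
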
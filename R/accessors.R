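#' Accessors for StudyRegion
#'
#' @param x A [StudyRegion-class].
#' @param level Risk level label(s); default all four.
#' @return \code{areaIds}: character vector; \code{centroids}: two-column
#'   numeric matrix (km); \code{populations}, \code{physicianDensity},
#'   \code{remotenessIndex}: numeric vectors; \code{caseCounts}: integer
#'   matrix (areas x requested levels) or vector if one level requested.
#' @name StudyRegion-accessors
#' @examples
#' reg <- generateRegion(syntheticScenario(nAreas = 10, seed = 1))
#' head(centroids(reg))
#' caseCounts(reg, "metastatic")[1:5]
NULL

#' @rdname StudyRegion-accessors
#' @export
areaIds <- function(x) rownames(x)

#' @rdname StudyRegion-accessors
#' @export
centroids <- function(x) {
  rd <- rowData(x)
  cbind(x_km = rd$x_km, y_km = rd$y_km)
}

#' @rdname StudyRegion-accessors
#' @export
populations <- function(x) as.numeric(rowData(x)$population)

#' @rdname StudyRegion-accessors
#' @export
physicianDensity <- function(x) as.numeric(rowData(x)$phys_density)

#' @rdname StudyRegion-accessors
#' @export
remotenessIndex <- function(x) as.numeric(rowData(x)$remoteness)

#' @rdname StudyRegion-accessors
#' @export
caseCounts <- function(x, level = riskLevels()) {
  level <- match.arg(level, riskLevels(), several.ok = TRUE)
  m <- assay(x, "counts")[, level, drop = length(level) > 1]
  m
}
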
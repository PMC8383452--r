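#' Read an area-attribute CSV into a StudyRegion
#'
#' Expected header: \code{area_id,x_km,y_km,population,phys_density,
#' remoteness} plus one integer count column per risk level
#' (\code{metastatic,high,intermediate,low}); an optional
#' \code{nearest_centre} column is carried through. Validation failures
#' name the offending field.
#'
#' @param file Path to the CSV.
#' @return A [StudyRegion-class].
#' @export
readRegionCSV <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("area_id", "x_km", "y_km", "population", "phys_density",
            "remoteness", riskLevels())
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("input is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$area_id))
    stop("duplicate area ids: ",
         paste(unique(df$area_id[duplicated(df$area_id)]), collapse = ", "))
  for (lv in riskLevels())
    if (any(df[[lv]] != round(df[[lv]])))
      stop("non-integer counts in column '", lv, "'")
  StudyRegion(df[, setdiff(colnames(df), riskLevels())],
              df[, riskLevels()])
}

#' Write a StudyRegion to the area-attribute CSV dialect
#'
#' Inverse of [readRegionCSV()]; numeric columns are written with full
#' precision so a fixed-seed region round-trips byte-identically.
#'
#' @param region A [StudyRegion-class].
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeRegionCSV <- function(region, file) {
  rd <- as.data.frame(rowData(region))
  df <- cbind(data.frame(area_id = areaIds(region)), rd,
              as.data.frame(assay(region, "counts")))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

.geojsonFeature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry,
       properties = as.list(properties))
}

#' Write area centroids (with attributes) as GeoJSON points
#'
#' @param region A [StudyRegion-class].
#' @param file Output path.
#' @param properties Optional data.frame of extra per-area properties
#'   (e.g. crude/smoothed SIRs, LISA classes), matched by position.
#' @return \code{file}, invisibly.
#' @export
writeCentroidsGeoJSON <- function(region, file, properties = NULL) {
  xy <- centroids(region)
  rd <- as.data.frame(rowData(region))
  feats <- lapply(seq_len(nrow(region)), function(i) {
    pr <- c(list(area_id = areaIds(region)[i]), as.list(rd[i, ]))
    if (!is.null(properties)) pr <- c(pr, as.list(properties[i, , drop = FALSE]))
    .geojsonFeature(list(type = "Point",
                         coordinates = as.numeric(xy[i, ])), pr)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write scan-cluster circles as GeoJSON polygons
#'
#' Each reported cluster becomes a 64-vertex polygon approximating its
#' circle, carrying the cluster's statistics as properties.
#'
#' @param scan A [ScanResult-class].
#' @param region The [StudyRegion-class] the scan ran on.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeClusterCirclesGeoJSON <- function(scan, region, file) {
  xy <- centroids(region)
  ids <- areaIds(region)
  tab <- scan@clusters
  feats <- lapply(seq_len(nrow(tab)), function(k) {
    ctr <- xy[match(tab$center_area[k], ids), ]
    r <- max(tab$radius_km[k], 1)
    ang <- seq(0, 2 * pi, length.out = 65)
    ring <- cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
    .geojsonFeature(
      list(type = "Polygon", coordinates = list(apply(ring, 1, as.numeric,
                                                      simplify = FALSE))),
      as.data.frame(tab[k, c("rank", "direction", "center_area",
                             "observed", "expected", "llr", "p_value")]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Attach per-area properties to supplied GeoJSON geometries
#'
#' Reads a FeatureCollection whose features carry an \code{area_id}
#' property, joins the supplied per-area table on \code{area_id}, and
#' writes the result — a choropleth-ready layer.
#'
#' @param geojsonIn Path to the input FeatureCollection.
#' @param table data.frame with an \code{area_id} column.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeChoroplethGeoJSON <- function(geojsonIn, table, file) {
  gj <- jsonlite::read_json(geojsonIn)
  table <- as.data.frame(table)
  for (k in seq_along(gj$features)) {
    aid <- gj$features[[k]]$properties$area_id
    row <- match(aid, table$area_id)
    if (!is.na(row))
      gj$features[[k]]$properties <-
        c(gj$features[[k]]$properties,
          as.list(table[row, setdiff(colnames(table), "area_id")]))
  }
  jsonlite::write_json(gj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
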
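#' Enumerate circular scan windows
#'
#' Candidate zones for the purely spatial scan: for every centre area,
#' zones grow by adding areas in increasing centroid distance, and a zone
#' is retained while its population does not exceed
#' \code{maxPopFraction} of the total. Duplicate member sets (reachable
#' from several centres) are kept once. A single-area region yields its
#' one singleton zone.
#'
#' @param centroids Two-column planar coordinate matrix (km).
#' @param populations Non-negative population vector, same ordering.
#' @param maxPopFraction Maximum zone population as a fraction of the total,
#'   in (0, 0.5]; default 0.25.
#' @param ids Optional area ids.
#' @return List of zones; each zone is a list with \code{center} (index),
#'   \code{center_id}, \code{radius_km}, \code{members} (sorted indices) and
#'   \code{pop}. Area ids are attached as attribute \code{"ids"}.
#' @examples
#' z <- enumerateWindows(cbind(c(0, 100, 200), 0), c(10, 10, 10), 0.34)
#' length(z)   # three singleton zones
#' @export
enumerateWindows <- function(centroids, populations, maxPopFraction = 0.25,
                             ids = NULL) {
  if (maxPopFraction <= 0 || maxPopFraction > 0.5)
    stop("maxPopFraction must be in (0, 0.5]")
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  stopifnot(length(populations) == n)
  if (is.null(ids)) ids <- rownames(centroids)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1L) {
    z <- list(list(center = 1L, center_id = ids[1], radius_km = 0,
                   members = 1L, pop = populations[1]))
    attr(z, "ids") <- ids
    return(z)
  }
  d <- .pairDist(centroids)
  cap <- maxPopFraction * sum(populations)
  zones <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))     # self first; distance ties by index
    cum <- cumsum(populations[ord])
    kmax <- which(cum <= cap)
    if (!length(kmax)) next
    for (k in seq_len(max(kmax))) {
      if (cum[k] > cap) next
      members <- sort(ord[seq_len(k)])
      key <- paste(members, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      zones[[length(zones) + 1L]] <-
        list(center = i, center_id = ids[i], radius_km = d[i, ord[k]],
             members = members, pop = cum[k])
    }
  }
  attr(zones, "ids") <- ids
  zones
}

#' Poisson scan log-likelihood ratio
#'
#' Kulldorff's LLR for a candidate zone under the conditional Poisson
#' model: with \eqn{O} cases inside, expectation \eqn{E} inside and
#' \eqn{T} total cases,
#' \eqn{LLR = O \log(O/E) + (T-O)\log((T-O)/(T-E))}, terms with a zero
#' count evaluated as 0. The direction is \code{"high"} when \eqn{O > E}.
#'
#' @param obsIn Observed cases inside the zone (vectorized).
#' @param expIn Expected cases inside, \eqn{0 < E < T}.
#' @param obsTotal Total observed cases \eqn{T}.
#' @return List with numeric \code{llr} (\eqn{\ge 0}) and character
#'   \code{direction} (\code{"high"}/\code{"low"}; \code{"none"} at
#'   \eqn{O = E}).
#' @examples
#' poissonLLR(10, 5, 100)   # llr ~ 2.065
#' poissonLLR(0, 5, 100)    # llr ~ 5.129, direction "low"
#' @export
poissonLLR <- function(obsIn, expIn, obsTotal) {
  stopifnot(all(expIn > 0), all(expIn < obsTotal), all(obsIn >= 0),
            all(obsIn <= obsTotal))
  t1 <- ifelse(obsIn > 0, obsIn * log(obsIn / expIn), 0)
  rem <- obsTotal - obsIn
  t2 <- ifelse(rem > 0, rem * log(rem / (obsTotal - expIn)), 0)
  llr <- t1 + t2
  llr[obsIn == expIn] <- 0
  list(llr = llr,
       direction = ifelse(obsIn > expIn, "high",
                          ifelse(obsIn < expIn, "low", "none")))
}

## LLR over a zones x replicates count matrix (shared expected-in vector)
.llrMatrix <- function(Oin, Ein, total) {
  t1 <- Oin * log(Oin / Ein)
  t1[Oin == 0] <- 0
  rem <- total - Oin
  t2 <- rem * log(rem / (total - Ein))
  t2[rem == 0] <- 0
  t1 + t2
}

## score all zones, order by (-llr, pop, center_id), greedy non-overlap
.rankZones <- function(observed, expected, windows,
                       directions = c("high", "low")) {
  if (!length(windows)) return(list())
  total <- sum(observed)
  Oin <- vapply(windows, function(z) sum(observed[z$members]), numeric(1))
  Ein <- vapply(windows, function(z) sum(expected[z$members]), numeric(1))
  ok <- Ein > 0 & Ein < sum(expected)
  sc <- poissonLLR(pmin(Oin[ok], total), Ein[ok], total)
  cand <- which(ok)[sc$direction %in% directions & sc$llr > 0]
  llr <- sc$llr[match(cand, which(ok))]
  dirs <- sc$direction[match(cand, which(ok))]
  pops <- vapply(windows[cand], `[[`, numeric(1), "pop")
  cids <- vapply(windows[cand], `[[`, character(1), "center_id")
  ord <- order(-llr, pops, cids)
  chosen <- list()
  used <- logical(length(observed))
  for (k in ord) {
    z <- windows[[cand[k]]]
    if (any(used[z$members])) next
    used[z$members] <- TRUE
    chosen[[length(chosen) + 1L]] <-
      list(zone = z, llr = llr[k], direction = dirs[k],
           observed = Oin[cand[k]], expected = Ein[cand[k]])
  }
  chosen
}

#' Rank spatial scan clusters (no inference)
#'
#' Scores every candidate zone by the Poisson LLR, reports the most-likely
#' cluster per direction and secondary clusters greedily in LLR order,
#' skipping any zone sharing a member area with an already-reported
#' cluster. LLR ties break toward the smaller population, then the
#' lexicographically smaller centre id.
#'
#' @param observed,expected Per-area counts (indirectly standardized, so
#'   \eqn{\sum E = \sum O}).
#' @param windows Zones from [enumerateWindows()].
#' @param directions Subset of \code{c("high", "low")}.
#' @return List of cluster records (zone, llr, direction, observed,
#'   expected), in reporting order.
#' @export
scanClusters <- function(observed, expected, windows,
                         directions = c("high", "low")) {
  stopifnot(abs(sum(observed) - sum(expected)) < 1e-6 * max(1, sum(observed)))
  .rankZones(observed, expected, windows, directions)
}

#' Monte-Carlo reference distribution for the scan statistic
#'
#' Conditional on the observed total, each replicate redistributes the
#' cases multinomially with probabilities \eqn{E_i / \sum E} and records
#' the replicate-wide maximum LLR per direction — the reference
#' distribution the cluster p-values are measured against.
#'
#' @param obsTotal Total case count.
#' @param expected Per-area expected counts.
#' @param windows Zones from [enumerateWindows()].
#' @param nReps Replicates (default 999).
#' @param seed Integer seed.
#' @return List with numeric vectors \code{high} and \code{low}: replicate
#'   maxima of the LLR in each direction.
#' @export
monteCarloP <- function(obsTotal, expected, windows, nReps = 999, seed = 1L) {
  members <- lapply(windows, `[[`, "members")
  Ein <- vapply(members, function(m) sum(expected[m]), numeric(1))
  keep <- Ein > 0 & Ein < sum(expected)
  members <- members[keep]
  set.seed(seed)
  counts <- stats::rmultinom(nReps, obsTotal, expected / sum(expected))
  .scanRefMax(counts,
              as.integer(c(0L, cumsum(lengths(members)))),
              as.integer(unlist(members, use.names = FALSE) - 1L),
              Ein[keep], as.double(obsTotal))
}

#' Kulldorff's purely spatial Poisson scan
#'
#' Full scan: zone enumeration must be done beforehand
#' ([enumerateWindows()]); this ranks clusters ([scanClusters()]), runs the
#' conditional Monte-Carlo inference ([monteCarloP()]) and attaches the
#' pseudo p-value \eqn{(1 + \#\{max\ LLR^{rep} \ge LLR\})/(n_{reps}+1)}
#' per reported cluster, using the replicate maxima of the matching
#' direction.
#'
#' @inheritParams scanClusters
#' @inheritParams monteCarloP
#' @param ids Area ids (default from \code{windows}).
#' @return A [ScanResult-class].
#' @examples
#' reg <- generateRegion(syntheticScenario(nAreas = 15, seed = 7))
#' obs <- caseCounts(reg, "high")
#' e <- expectedCounts(populations(reg), obs)
#' w <- enumerateWindows(centroids(reg), populations(reg), 0.3)
#' kulldorffScan(obs, e, w, nReps = 99, seed = 1)
#' @export
kulldorffScan <- function(observed, expected, windows,
                          directions = c("high", "low"),
                          nReps = 999, seed = 1L, ids = attr(windows, "ids")) {
  clusters <- scanClusters(observed, expected, windows, directions)
  ref <- monteCarloP(sum(observed), expected, windows, nReps, seed)
  if (is.null(ids)) ids <- as.character(seq_along(observed))
  totO <- sum(observed); totE <- sum(expected)
  g <- function(f, mode) vapply(clusters, f, mode)
  Oin <- g(function(cl) cl$observed, numeric(1))
  Ein <- g(function(cl) cl$expected, numeric(1))
  llr <- g(function(cl) cl$llr, numeric(1))
  dirs <- g(function(cl) cl$direction, character(1))
  pv <- vapply(seq_along(clusters), function(k)
    (1 + sum(ref[[dirs[k]]] >= llr[k])) / (nReps + 1), numeric(1))
  rrOut <- (totO - Oin) / (totE - Ein)
  tab <- DataFrame(
    rank = seq_along(clusters), direction = dirs,
    center_area = g(function(cl) cl$zone$center_id, character(1)),
    radius_km = g(function(cl) cl$zone$radius_km, numeric(1)),
    members = g(function(cl) paste(ids[cl$zone$members], collapse = ";"),
                character(1)),
    observed = as.integer(Oin), expected = Ein,
    rr = ifelse(rrOut > 0, (Oin / Ein) / rrOut, Inf),
    llr = llr, p_value = pv)
  new("ScanResult", clusters = tab, nReps = as.integer(nReps),
      seed = as.integer(seed))
}

#' Write scan clusters to CSV
#'
#' @param x A [ScanResult-class].
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeScanTable <- function(x, file) {
  utils::write.csv(as.data.frame(x@clusters), file, row.names = FALSE)
  invisible(file)
}
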
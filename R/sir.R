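#' Indirectly standardized expected counts
#'
#' Applies the region-wide rate to each area's population:
#' \eqn{E_i = n_i \, (\sum_i O_i / \sum_i n_i)}. By construction
#' \eqn{\sum_i E_i = \sum_i O_i} (indirect standardization), so SIRs are
#' interpretable as departures from regional parity.
#'
#' @param population Non-negative integer vector \eqn{n_i} (men aged 35+).
#' @param observed Non-negative integer vector \eqn{O_i}, same length.
#' @return Numeric vector of expected counts \eqn{E_i}.
#' @examples
#' expectedCounts(c(50, 150, 300), c(1, 3, 6))  # rate 0.02 applied per area
#' @export
expectedCounts <- function(population, observed) {
  stopifnot(length(population) == length(observed), length(population) >= 1)
  if (any(population < 0) || any(observed < 0))
    stop("population and observed counts must be non-negative")
  tot <- sum(population)
  if (tot <= 0) stop("degenerate region: zero total population")
  population * (sum(observed) / tot)
}

#' Crude standardized incidence ratio
#'
#' \eqn{SIR_i = O_i / E_i} where \eqn{E_i > 0}; areas with zero expected
#' count (zero population) get \code{NA} rather than a ratio.
#'
#' @param observed Non-negative counts.
#' @param expected Expected counts from [expectedCounts()].
#' @return Numeric vector; \code{NA} where \code{expected == 0}.
#' @examples
#' crudeSIR(c(0, 6), c(3, 3))
#' @export
crudeSIR <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (any(observed < 0) || any(expected < 0))
    stop("observed and expected must be non-negative")
  ifelse(expected > 0, observed / expected, NA_real_)
}

.SIR_BIN_LABELS <- c("> 50% less than expected",
                     "10 to 50% less than expected",
                     "Within 10% expected",
                     "10 to 50% more than expected",
                     "50 to 100% more than expected",
                     "> 100% more than expected")

#' Classify SIRs into descriptive bins
#'
#' Six bins partition \eqn{[0, \infty)}: \eqn{[0, 0.5)}, \eqn{[0.5, 0.9)},
#' \eqn{[0.9, 1.1]} (the closed "within 10%" central bin), \eqn{(1.1, 1.5]},
#' \eqn{(1.5, 2.0]} and \eqn{(2.0, \infty)}. The central bin is closed on
#' both sides so that exact 10-percent departures still count as "within";
#' the outward bins are half-open to keep the partition exact.
#' Undefined SIRs (no expected cases) get \code{"no-expected-cases"}.
#'
#' @param sir Numeric vector of crude SIRs (\code{NA} allowed).
#' @return Factor with the six bin labels (plus \code{"no-expected-cases"}).
#' @examples
#' classifySIRBins(c(0.49999, 1.0, 3.474))
#' @export
classifySIRBins <- function(sir) {
  if (any(sir[!is.na(sir)] < 0)) stop("SIRs must be non-negative")
  lab <- character(length(sir))
  lab[is.na(sir)] <- "no-expected-cases"
  ok <- !is.na(sir)
  s <- sir[ok]
  lab[ok] <- ifelse(s < 0.5, .SIR_BIN_LABELS[1],
             ifelse(s < 0.9, .SIR_BIN_LABELS[2],
             ifelse(s <= 1.1, .SIR_BIN_LABELS[3],
             ifelse(s <= 1.5, .SIR_BIN_LABELS[4],
             ifelse(s <= 2.0, .SIR_BIN_LABELS[5], .SIR_BIN_LABELS[6])))))
  factor(lab, levels = c(.SIR_BIN_LABELS, "no-expected-cases"))
}

#' Coefficient of variation of annual counts
#'
#' Relative variability of incidence across years, as a percentage:
#' \eqn{100 \cdot s / \bar{x}} with the sample (n-1 denominator) standard
#' deviation.
#'
#' @param yearlyCounts Integer vector of per-year case totals, length >= 2.
#' @return Percent CV (not rounded).
#' @examples
#' annualCV(c(564, 640, 659, 565, 563))  # ~7.9
#' @export
annualCV <- function(yearlyCounts) {
  stopifnot(length(yearlyCounts) >= 2)
  m <- mean(yearlyCounts)
  if (m == 0) stop("zero mean annual count")
  100 * stats::sd(yearlyCounts) / m
}

#' Risk-level proportions
#'
#' Percentage of cases in each risk level, rounded to one decimal place.
#'
#' @param counts Named integer vector (or list) of case counts per level.
#' @return Named numeric vector of percentages (1 d.p.).
#' @examples
#' riskLevelProportions(c(metastatic = 402, high = 1089,
#'                        intermediate = 1056, low = 444))
#' @export
riskLevelProportions <- function(counts) {
  counts <- unlist(counts)
  tot <- sum(counts)
  if (tot <= 0) stop("total count must be positive")
  round(100 * counts / tot, 1)
}

#' Per-area SIR table for a StudyRegion
#'
#' Computes, for each requested risk level, the indirectly standardized
#' expected counts, crude SIRs and bin labels. Areas with zero population
#' are retained in the table (with \code{NA} SIR and the
#' \code{"no-expected-cases"} bin) but are excluded from downstream
#' SIR/clustering vectors.
#'
#' @param region A [StudyRegion-class].
#' @param level Risk level(s); default all four.
#' @return A \code{DataFrame} with columns \code{area_id},
#'   \code{risk_level}, \code{observed}, \code{expected}, \code{crude_sir},
#'   \code{bin}.
#' @examples
#' reg <- generateRegion(syntheticScenario(nAreas = 20, seed = 1))
#' head(sirTable(reg, "metastatic"))
#' @export
sirTable <- function(region, level = riskLevels()) {
  level <- match.arg(level, riskLevels(), several.ok = TRUE)
  pop <- populations(region)
  out <- lapply(level, function(lv) {
    obs <- as.numeric(assay(region, "counts")[, lv])
    expd <- expectedCounts(pop, obs)
    sir <- crudeSIR(obs, expd)
    DataFrame(area_id = areaIds(region), risk_level = lv,
              observed = as.integer(obs), expected = expd,
              crude_sir = sir, bin = classifySIRBins(sir))
  })
  do.call(rbind, out)
}

#' Write an SIR table to CSV
#'
#' @param x Result of [sirTable()].
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeSIRTable <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}
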
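## spectral variance of the mean at frequency zero via non-overlapping
## batch means; floor(sqrt(n)) batches of ~floor(sqrt(n)) draws (the
## standard batch-size choice, keeping enough batches that the implied
## variance estimate has adequate degrees of freedom)
.batchVarMean <- function(chain) {
  n <- length(chain)
  nb <- max(2L, floor(sqrt(n)))
  bs <- floor(n / nb)
  if (bs < 1) return(NA_real_)
  m <- colMeans(matrix(chain[seq_len(nb * bs)], nrow = bs))
  stats::var(m) / nb
}

#' Gelman-Rubin potential scale reduction factor
#'
#' \eqn{\hat R = \sqrt{((n-1)/n \cdot W + B/n) / W}} with \eqn{B} the
#' between-chain and \eqn{W} the within-chain variance of \code{m >= 2}
#' equal-length scalar chains. Values near 1 indicate the chains have
#' mixed over the same distribution.
#'
#' @param chains Matrix with one column per chain (or list of equal-length
#'   numeric vectors).
#' @return \eqn{\hat R} (numeric scalar).
#' @examples
#' psrf(cbind(rnorm(500), rnorm(500)))
#' @export
psrf <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  stopifnot(ncol(chains) >= 2)
  n <- nrow(chains)
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W <= 0) return(if (B > 0) Inf else NaN)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Geweke Z-score for equality of means
#'
#' Compares the mean of the first \code{fracFirst} of the chain with the
#' mean of the last \code{fracLast}:
#' \eqn{z = (\bar x_A - \bar x_B)/\sqrt{se_A^2 + se_B^2}}, standard errors
#' from batch-means estimates of the spectral density at frequency zero.
#' For a stationary chain \eqn{z} is approximately standard normal.
#'
#' @param chain Numeric vector of draws.
#' @param fracFirst,fracLast Window fractions (defaults 0.1 and 0.5).
#' @return The Z-score; 0 by convention for a constant chain.
#' @export
gewekeZ <- function(chain, fracFirst = 0.1, fracLast = 0.5) {
  n <- length(chain)
  stopifnot(fracFirst + fracLast <= 1, n >= 20)
  a <- chain[seq_len(floor(fracFirst * n))]
  b <- chain[seq.int(n - floor(fracLast * n) + 1L, n)]
  se2 <- .batchVarMean(a) + .batchVarMean(b)
  num <- mean(a) - mean(b)
  if (!is.finite(se2) || se2 <= 0) return(0)
  num / sqrt(se2)
}

## asymptotic distribution function of the Cramer-von-Mises statistic
## (series expansion with Bessel-K terms, truncated at four terms)
.pcramer <- function(q, eps = 1e-5) {
  logEps <- log(eps)
  y <- vapply(0:3, function(k) {
    z <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(k + 1) * pi^1.5 * sqrt(q))
    u <- (4 * k + 1)^2 / (16 * q)
    ifelse(u > -logEps, 0, z * exp(-u) * besselK(u, 0.25))
  }, numeric(length(q)))
  if (is.null(dim(y))) sum(y) else rowSums(y)
}

#' Heidelberger-Welch stationarity and half-width tests
#'
#' Stationarity: a Cramer-von-Mises test on the standardized cumulative-sum
#' process of the chain, iteratively discarding the first 10% (up to 50%)
#' until the null of stationarity is not rejected at \code{alpha}.
#' Half-width: on the retained segment, passes when
#' \eqn{1.96\,se(\bar x) \le precision \cdot |\bar x|}; when the mean is
#' essentially zero relative to the chain's spread, the relative-precision
#' criterion is meaningless and the half-width verdict is \code{NA}
#' (indeterminate) rather than failed.
#'
#' @param chain Numeric vector of draws.
#' @param precision Target relative half-width (default 0.1).
#' @param alpha Level of the stationarity test (default 0.05).
#' @return List: \code{stationary}, \code{halfwidthOk} (logical or NA),
#'   \code{nDiscarded}, \code{mean}, \code{halfwidth}.
#' @export
heidelbergerWelch <- function(chain, precision = 0.1, alpha = 0.05) {
  n <- length(chain)
  stopifnot(n >= 20)
  stationary <- FALSE
  nDisc <- 0L
  seg <- chain
  for (frac in seq(0, 0.5, by = 0.1)) {
    nDisc <- floor(frac * n)
    seg <- chain[(nDisc + 1L):n]
    s2 <- .batchVarMean(seg) * length(seg)   # spectral density estimate
    if (!is.finite(s2) || s2 <= 0) { stationary <- TRUE; break }
    m <- length(seg)
    S <- cumsum(seg)
    k <- seq_len(m)
    B <- (S - k * mean(seg)) / sqrt(m * s2)
    cvm <- sum(B^2) / m
    p <- 1 - .pcramer(cvm)
    if (p > alpha) { stationary <- TRUE; break }
  }
  mu <- mean(seg)
  se <- sqrt(.batchVarMean(seg))
  hw <- 1.96 * se
  sdSeg <- stats::sd(seg)
  ## a mean within sampling noise of zero makes the relative-precision
  ## criterion meaningless: report indeterminate, not failed
  halfOk <- if (!is.finite(se)) NA
            else if (sdSeg == 0) TRUE
            else if (abs(mu) <= 5 * se) NA
            else hw <= precision * abs(mu)
  list(stationary = stationary, halfwidthOk = halfOk,
       nDiscarded = nDisc, mean = mu, halfwidth = hw)
}

#' Raftery-Lewis run-length control
#'
#' Two-state Markov-chain method on the indicator of lying below the
#' \code{q}-quantile: the indicator is thinned until first-order Markov
#' dependence is preferred (BIC), transition probabilities are estimated,
#' and the minimum chain length to estimate the \code{q}-quantile within
#' \eqn{\pm r} with probability \code{s} is returned. For an i.i.d. chain
#' this approaches the theoretical floor
#' \eqn{n_{min} = \Phi^{-1}((s+1)/2)^2\, q(1-q)/r^2} (about 3746 at the
#' defaults).
#'
#' @param chain Numeric vector of draws.
#' @param q Quantile of interest (default 0.025).
#' @param r Target precision (default 0.005).
#' @param s Coverage probability (default 0.95).
#' @return List: \code{requiredN} (integer), \code{burnIn},
#'   \code{thinUsed}, \code{nMin} (i.i.d. floor), \code{dependenceFactor}.
#' @export
rafteryLewis <- function(chain, q = 0.025, r = 0.005, s = 0.95) {
  phi <- stats::qnorm(0.5 * (1 + s))
  nMin <- as.integer(ceiling(phi^2 * q * (1 - q) / r^2))
  n <- length(chain)
  if (n < nMin)
    stop(sprintf("insufficient pilot length: %d draws < minimum %d", n, nMin))
  z <- as.integer(chain <= stats::quantile(chain, q))
  ## find thinning at which a first-order chain is preferred over second
  kThin <- 1L
  bic <- 1
  while (bic >= 0) {
    zt <- z[seq(1L, n, by = kThin)]
    if (length(zt) < 50) break
    ## second- vs first-order Markov via G2 with BIC penalty
    trip <- cbind(zt[-c(length(zt) - 1L, length(zt))],
                  zt[-c(1L, length(zt))], zt[-c(1L, 2L)])
    tab <- table(factor(trip[, 1], 0:1), factor(trip[, 2], 0:1),
                 factor(trip[, 3], 0:1))
    g2 <- 0
    for (i1 in 1:2) for (i2 in 1:2) for (i3 in 1:2) {
      o <- tab[i1, i2, i3]
      if (o == 0) next
      e <- sum(tab[i1, i2, ]) * sum(tab[, i2, i3]) / sum(tab[, i2, ])
      g2 <- g2 + 2 * o * log(o / e)
    }
    bic <- g2 - log(sum(tab)) * 2
    if (bic >= 0) kThin <- kThin + 1L
  }
  zt <- z[seq(1L, n, by = kThin)]
  m <- length(zt)
  from <- zt[-m]; to <- zt[-1]
  n01 <- sum(from == 0 & to == 1); n0 <- sum(from == 0)
  n10 <- sum(from == 1 & to == 0); n1 <- sum(from == 1)
  alpha <- if (n0 > 0) n01 / n0 else 0.5
  beta  <- if (n1 > 0) n10 / n1 else 0.5
  alpha <- min(max(alpha, 1e-6), 1 - 1e-6)
  beta  <- min(max(beta, 1e-6), 1 - 1e-6)
  lam <- 1 - alpha - beta
  burn <- if (abs(lam) < 1e-12) 1
          else ceiling(log(0.001 * (alpha + beta) / max(alpha, beta)) /
                       log(abs(lam))) * kThin
  reqN <- ceiling((2 - alpha - beta) * alpha * beta / (alpha + beta)^3 *
                  (phi / r)^2) * kThin
  list(requiredN = as.integer(reqN), burnIn = as.integer(max(burn, 0)),
       thinUsed = kThin, nMin = nMin,
       dependenceFactor = (reqN + max(burn, 0)) / nMin)
}

#' Convergence diagnostics report for a BYM fit
#'
#' Runs the four checks on every monitored scalar parameter (intercept,
#' coefficient if present, both precisions): PSRF across chains, Geweke
#' Z-score, Heidelberger-Welch stationarity/half-width and Raftery-Lewis
#' run length (each per chain; the worst chain is reported). Verdict per
#' parameter: \code{pass} when \eqn{\hat R \le 1.1}, \eqn{|z| \le 1.96},
#' both HW flags hold and the retained draws meet the Raftery-Lewis
#' requirement; one failed check gives \code{warn}, two or more
#' \code{fail}.
#'
#' @param posterior A [BYMPosterior-class].
#' @param rlQ,rlR,rlS Raftery-Lewis settings (see [rafteryLewis()]); the
#'   check is skipped (treated as met) when the retained chain is shorter
#'   than the Raftery-Lewis pilot minimum.
#' @return \code{DataFrame}: parameter, psrf, geweke_z, hw_stationary,
#'   hw_halfwidth_ok, rl_required_n, verdict.
#' @export
diagnosticsReport <- function(posterior, rlQ = 0.025, rlR = 0.005,
                              rlS = 0.95) {
  chains <- .monitoredChains(posterior)
  totalDraws <- nrow(posterior@c) * ncol(posterior@c)
  rows <- lapply(names(chains), function(pn) {
    m <- chains[[pn]]
    R <- psrf(m)
    z <- max(abs(apply(m, 2, gewekeZ)))
    hw <- apply(m, 2, heidelbergerWelch)
    stat <- all(vapply(hw, `[[`, logical(1), "stationary"))
    half <- vapply(hw, `[[`, c(NA), "halfwidthOk")
    halfOk <- if (all(is.na(half))) NA else all(half[!is.na(half)])
    rl <- tryCatch(
      max(vapply(seq_len(ncol(m)), function(ch)
        rafteryLewis(m[, ch], rlQ, rlR, rlS)$requiredN, integer(1))),
      error = function(e) NA_integer_)
    checks <- c(is.finite(R) && R <= 1.1,
                z <= 1.96,
                stat && (is.na(halfOk) || halfOk),
                is.na(rl) || totalDraws >= rl)
    nf <- sum(!checks)
    DataFrame(parameter = pn, psrf = R, geweke_z = z,
              hw_stationary = stat, hw_halfwidth_ok = halfOk,
              rl_required_n = rl,
              verdict = c("pass", "warn", "fail")[min(nf + 1L, 3L)])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a diagnostics report to CSV
#'
#' @param report Result of [diagnosticsReport()].
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeDiagnostics <- function(report, file) {
  utils::write.csv(as.data.frame(report), file, row.names = FALSE)
  invisible(file)
}
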
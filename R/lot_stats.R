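# Distribution statistics of the leaf open times. Both families use the
# pooled nonzero cells of the sinogram: closed leaves are structural (they
# describe field geometry, which has its own metric family), so including
# their zeros would let field size swamp every distributional statistic.

# Population (biased) moment conventions, matching the usual engineering
# defaults: skewness m3/m2^1.5, kurtosis m4/m2^2 (non-excess: normal -> 3).
# Degenerate (zero-variance) samples give NA for both.
pop_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^3) / m2^1.5
}

pop_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^4) / m2^2
}

# Mode of a continuous sample: midpoint of the fullest of 100 equal-width
# bins over [min, max]; ties take the lowest bin. Deterministic, documented;
# a point mass (min == max) is its own mode.
sample_mode <- function(x, bins = 100L) {
  lo <- min(x)
  hi <- max(x)
  if (lo == hi) return(lo)
  edges <- seq(lo, hi, length.out = bins + 1L)
  idx <- pmin(findInterval(x, edges, rightmost.closed = TRUE), bins)
  counts <- tabulate(idx, nbins = bins)
  k <- which.max(counts) # which.max takes the first (lowest) maximum
  (edges[k] + edges[k + 1L]) / 2
}

#' Absolute leaf-open-time statistics
#'
#' Summarizes the distribution of absolute leaf open times
#' (`LOT = S * PT`, ms) over the nonzero sinogram cells: mean, standard
#' deviation (sample, n - 1 denominator), median, mode, minimum, maximum, kurtosis
#' (non-excess) and skewness, plus two cumulative families:
#' \itemize{
#'   \item `CLNS_n`: fraction of LOTs strictly smaller than `n` ms — small
#'     open times challenge the binary MLC's open/close latency;
#'   \item `CLNS_pt,n`: fraction of LOTs within `n` ms of the projection
#'     time (`LOT > PT - n`) — leaves that are effectively always open.
#' }
#'
#' @param plan an [ht_plan] or [ht_sinogram] with at least one open cell.
#' @param clns_thresholds thresholds `n` in ms for `CLNS_n`.
#' @param clns_pt_margins margins `n` in ms for `CLNS_pt,n`.
#' @return Named list with the scalar statistics (`mLOT`, `sdLOT`, `mdLOT`,
#'   `moLOT`, `minLOT`, `maxLOT`, `kLOT`, `sLOT`) and named vectors `CLNS`
#'   and `CLNS_pt`.
#' @examples
#' sg <- ht_sinogram(rbind(c(0.1, 0.2, 0.3, 0.4)), PT = 200)
#' absolute_lot_stats(sg, clns_thresholds = 50)$CLNS # 0.5
#' @export
absolute_lot_stats <- function(plan, clns_thresholds = c(20, 30, 50, 100),
                               clns_pt_margins = 20) {
  sg <- as_sinogram(plan)
  lot <- nonzero_flots(sg) * sg$PT
  CLNS <- vapply(clns_thresholds, function(n) mean(lot < n), numeric(1))
  names(CLNS) <- paste0("CLNS", format(clns_thresholds, trim = TRUE))
  CLNS_pt <- vapply(clns_pt_margins, function(n) mean(lot > sg$PT - n),
                    numeric(1))
  names(CLNS_pt) <- paste0("CLNSpt", format(clns_pt_margins, trim = TRUE))
  list(
    mLOT = mean(lot),
    sdLOT = stats::sd(lot),
    mdLOT = stats::median(lot),
    moLOT = sample_mode(lot),
    minLOT = min(lot),
    maxLOT = max(lot),
    kLOT = pop_kurtosis(lot),
    sLOT = pop_skewness(lot),
    CLNS = CLNS,
    CLNS_pt = CLNS_pt
  )
}

#' Fractional leaf-open-time statistics
#'
#' The same estimators as [absolute_lot_stats()], applied to the fractional
#' open times (the LOT distribution normalized by the projection time), so
#' plans with very different projection times become directly comparable.
#' `CFNS_{n x 100}` is the fraction of nonzero FLOTs strictly smaller than
#' `n`, `n` in `[0, 1]`. Every statistic here equals its absolute
#' counterpart divided by PT, exactly.
#'
#' @param plan an [ht_plan] or [ht_sinogram] with at least one open cell.
#' @param cfns_thresholds thresholds `n` in `[0, 1]`; reported under names
#'   `CFNS{100 n}`.
#' @return Named list: `mFLOT`, `sdFLOT`, `mdFLOT`, `moFLOT`, `minFLOT`,
#'   `maxFLOT`, and vector `CFNS`.
#' @export
relative_lot_stats <- function(plan,
                               cfns_thresholds = c(0.05, 0.10, 0.50, 0.75,
                                                   0.90)) {
  flot <- nonzero_flots(plan)
  CFNS <- vapply(cfns_thresholds, function(n) mean(flot < n), numeric(1))
  names(CFNS) <- paste0("CFNS", format(round(100 * cfns_thresholds),
                                       trim = TRUE))
  list(
    mFLOT = mean(flot),
    sdFLOT = stats::sd(flot),
    mdFLOT = stats::median(flot),
    moFLOT = sample_mode(flot),
    minFLOT = min(flot),
    maxFLOT = max(flot),
    CFNS = CFNS
  )
}
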
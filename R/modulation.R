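# Modulation metrics: temporal/lateral variability of the fractional open
# times across the sinogram.

#' Extended leaf open-time variability
#'
#' For each leaf `j`, the mean absolute FLOT change between projections
#' `Delta_p` apart, normalized by the leaf's maximum opening:
#' `sum_i |S[i, j] - S[i + Delta_p, j]| / ((N - Delta_p) * max_i S[i, j])`.
#' Since every `S[i, j]` lies in `[0, max_i S[i, j]]`, the per-leaf term
#' lies in `[0, 1]`; leaves that never open contribute 0 by definition. The
#' plan value is the mean over all L leaves, so it also lies in `[0, 1]` and
#' is 0 exactly when every leaf keeps the same opening at all projections.
#'
#' @param plan an [ht_plan] or [ht_sinogram].
#' @param delta_p projection step, `1 <= delta_p <= N - 1`.
#' @return Single value in `[0, 1]`.
#' @examples
#' elotv(ht_sinogram(matrix(0.5, 50, 64), PT = 200), 1) # 0
#' @export
elotv <- function(plan, delta_p = 1L) {
  sg <- as_sinogram(plan)
  mean(elotv_leaf_terms(sg$S, delta_p))
}

elotv_leaf_terms <- function(S, delta_p) {
  N <- nrow(S)
  delta_p <- as.integer(delta_p)
  if (delta_p < 1L || delta_p >= N) {
    stop("`delta_p` must satisfy 1 <= delta_p <= N - 1", call. = FALSE)
  }
  col_max <- apply(S, 2L, max)
  d <- abs(S[seq_len(N - delta_p), , drop = FALSE] -
             S[seq_len(N - delta_p) + delta_p, , drop = FALSE])
  terms <- colSums(d) / ((N - delta_p) * col_max)
  terms[col_max == 0] <- 0
  terms
}

#' Leaf open-time variability
#'
#' The classic per-leaf variability score: the complement of the mean
#' absolute adjacent-projection FLOT change, leaf-wise normalized by the
#' leaf's maximum opening and averaged over leaves (never-opening leaves
#' contribute 1, i.e. no variability). By construction
#' `LOTV = 1 - elotv(plan, 1)` for every plan.
#'
#' @param plan an [ht_plan] or [ht_sinogram].
#' @return Single value in `[0, 1]`.
#' @export
lotv <- function(plan) {
  sg <- as_sinogram(plan)
  mean(1 - elotv_leaf_terms(sg$S, 1L))
}

#' Extended plan sinogram time variation
#'
#' Sum of absolute FLOT differences at projection step `delta_p` and leaf
#' step `delta_l`, normalized by the number of projection pairs:
#' `EPSTV = 1/(N - delta_p) * sum_{i=1}^{N-delta_p} sum_{j=1}^{L-delta_l}
#'   (|S[i+delta_p, j] - S[i, j]| + |S[i, j+delta_l] - S[i, j]|)`.
#' With `delta_p = 0` the projection-difference term vanishes and the
#' normalization is `1/N` (leaf-direction variation only); with
#' `delta_l = 0` the leaf-difference term vanishes and `j` runs over all L
#' leaves (projection-direction variation only). `delta_p = delta_l = 0` is
#' degenerate (identically 0) and rejected.
#'
#' @param plan an [ht_plan] or [ht_sinogram].
#' @param delta_p projection step (`0 <= delta_p < N`).
#' @param delta_l leaf step (`0 <= delta_l < L`).
#' @return Single nonnegative value.
#' @export
epstv <- function(plan, delta_p = 1L, delta_l = 1L) {
  sg <- as_sinogram(plan)
  S <- sg$S
  N <- nrow(S)
  L <- ncol(S)
  delta_p <- as.integer(delta_p)
  delta_l <- as.integer(delta_l)
  if (delta_p == 0L && delta_l == 0L) {
    stop("`delta_p` and `delta_l` cannot both be 0 (degenerate)",
         call. = FALSE)
  }
  if (delta_p < 0L || delta_p >= N) stop("`delta_p` must be in [0, N)",
                                         call. = FALSE)
  if (delta_l < 0L || delta_l >= L) stop("`delta_l` must be in [0, L)",
                                         call. = FALSE)
  ii <- seq_len(N - delta_p)
  jj <- seq_len(L - delta_l)
  total <- 0
  if (delta_p > 0L) {
    total <- total + sum(abs(S[ii + delta_p, jj, drop = FALSE] -
                               S[ii, jj, drop = FALSE]))
  }
  if (delta_l > 0L) {
    total <- total + sum(abs(S[ii, jj + delta_l, drop = FALSE] -
                               S[ii, jj, drop = FALSE]))
  }
  total / (N - delta_p)
}

#' Plan sinogram time variation
#'
#' The adjacent-cell special case `pstv(plan) == epstv(plan, 1, 1)`.
#'
#' @param plan an [ht_plan] or [ht_sinogram].
#' @return Single nonnegative value.
#' @export
pstv <- function(plan) epstv(plan, 1L, 1L)

#' Leaf opening/closing events
#'
#' Counts how often each leaf opens and closes over the treatment under the
#' centered-opening timing model: within a projection, an opening of
#' fraction `s` is centered on the projection, so a partial opening
#' (`0 < s < 1`) both opens and closes inside its own projection. Adjacent
#' open cells therefore merge into one continuous opening only when the
#' boundary between them is covered, which requires a fully-open cell on at
#' least one side. Each merged opening contributes one open event and one
#' close event (2 events); in particular an isolated partial cell is its own
#' open/close pair, and a run of `S = 1` cells with partial caps at its two
#' ends is a single pair.
#'
#' `noc_events()` returns the raw plan-wide event count;
#' `noc()` is the plan metric: events averaged per leaf and normalized by
#' the number of projections, `total events / (L * N)`. In a plan with no
#' fully-open cell every open cell is its own pair, which yields the exact
#' relation `CLS = 1 - 0.5 * nOC`; fully-open runs merge events and can only
#' reduce the count, making the relation `CLS <= 1 - 0.5 * nOC`.
#'
#' @param plan an [ht_plan] or [ht_sinogram].
#' @return `noc_events()`: integer event count; `noc()`: events per leaf
#'   per projection. An all-closed plan has 0 events.
#' @examples
#' S <- matrix(0, 5, 64); S[3, 10] <- 0.4
#' noc_events(ht_sinogram(S, PT = 200)) # 2
#' @export
noc_events <- function(plan) {
  S <- as_sinogram(plan)$S
  N <- nrow(S)
  events <- 0L
  for (j in seq_len(ncol(S))) {
    col <- S[, j]
    open <- col > 0
    if (!any(open)) next
    # count open/close pairs: a new pair starts at every open cell that is
    # not merged with the previous cell (merge iff either side is fully open)
    prev_open <- c(FALSE, open[-N])
    prev_full <- c(FALSE, col[-N] == 1)
    merged <- open & prev_open & (prev_full | col == 1)
    events <- events + 2L * sum(open & !merged)
  }
  events
}

#' @rdname noc_events
#' @export
noc <- function(plan) {
  sg <- as_sinogram(plan)
  noc_events(sg) / (sg$N * sg$L)
}

#' Leaf projected sinogram, asymmetry and intensity metrics
#'
#' The leaf projected sinogram is the per-leaf mean fractional open time,
#' `LPS_j = sum_i S[i, j] / N` (closed leaves contribute 0). From it:
#' \describe{
#'   \item{MSA}{mean sinogram asymmetry, the LPS-weighted average leaf
#'     position `sum_j P_j LPS_j / sum_j LPS_j` in number-of-leaves units —
#'     the lateral displacement of the delivered intensity from the MLC
#'     center. Undefined (error) for an all-closed plan.}
#'   \item{mSI, mdSI, sdSI}{mean, median and standard deviation of the LPS
#'     values over all L leaves.}
#' }
#'
#' @param plan an [ht_plan] or [ht_sinogram].
#' @return List with `LPS` (length-L vector), `MSA`, `mSI`, `mdSI`, `sdSI`.
#' @export
lps_metrics <- function(plan) {
  sg <- as_sinogram(plan)
  LPS <- colSums(sg$S) / sg$N
  if (sum(LPS) == 0) {
    stop("all leaves closed: MSA undefined (zero total intensity)",
         call. = FALSE)
  }
  P <- leaf_positions(sg$L)
  list(
    LPS = LPS,
    MSA = sum(P * LPS) / sum(LPS),
    mSI = mean(LPS),
    mdSI = stats::median(LPS),
    sdSI = stats::sd(LPS)
  )
}

#' Modulation index
#'
#' A scalar summary of how aggressively the sinogram is modulated along the
#' projection direction. The package's default definition is a
#' sigma-threshold scan: with `d` the adjacent-projection FLOT changes
#' (`|S[i+1, j] - S[i, j]|` over all leaves) and `sigma` their plan standard
#' deviation of the sinogram values, `z(f)` is the fraction of changes
#' exceeding `f * sigma`, and `MI = integral_0^F z(f) df` evaluated on a
#' grid `f = delta_f, 2 delta_f, ..., F`. A constant sinogram has no
#' changes and `MI = 0`, the definition's minimum; more, or larger, changes
#' raise `z` and therefore MI.
#'
#' The definition is isolated behind the `method` argument so an alternative
#' index can be plugged in when cross-validating against other libraries;
#' the adopted definition is recorded in the result's
#' `attr(, "definition")`.
#'
#' @param plan an [ht_plan] or [ht_sinogram].
#' @param f_max upper integration limit `F` (in sigma units).
#' @param delta_f grid step.
#' @param method `"sigma_scan"` (default) or a function `(S) -> value`.
#' @return Single nonnegative value with attribute `definition`.
#' @export
modulation_index <- function(plan, f_max = 2, delta_f = 0.01,
                             method = "sigma_scan") {
  sg <- as_sinogram(plan)
  if (is.function(method)) {
    out <- method(sg$S)
    attr(out, "definition") <- "user"
    return(out)
  }
  method <- match.arg(method, "sigma_scan")
  S <- sg$S
  N <- nrow(S)
  if (N < 2L) {
    out <- 0
    attr(out, "definition") <- "sigma_scan"
    return(out)
  }
  d <- abs(S[-1L, , drop = FALSE] - S[-N, , drop = FALSE])
  sigma <- stats::sd(S)
  if (!is.finite(sigma) || sigma == 0 || all(d == 0)) {
    out <- 0
  } else {
    f <- seq(delta_f, f_max, by = delta_f)
    z <- vapply(f, function(fi) mean(d > fi * sigma), numeric(1))
    out <- sum(z) * delta_f
  }
  attr(out, "definition") <- "sigma_scan"
  out
}
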
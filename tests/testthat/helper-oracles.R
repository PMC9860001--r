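# Independent oracles and random-case generators shared across the suite.

# Random sinogram with controllable density; values in (0, 1), optionally
# with exact-1 cells injected.
random_sinogram <- function(N = 20, L = 16, density = 0.5, PT = 200,
                            with_ones = FALSE) {
  S <- matrix(0, N, L)
  open <- matrix(runif(N * L) < density, N, L)
  S[open] <- runif(sum(open), 0.01, 0.99)
  if (with_ones) {
    k <- which(open)
    if (length(k)) {
      pick <- sample(k, max(1L, length(k) %/% 5L))
      S[pick] <- 1
    }
  }
  ht_sinogram(S, PT = PT)
}

random_plan <- function(...) ht_plan(random_sinogram(...))

# Brute-force 1-D flood fill: per-row connected components by explicit
# neighbor walking (independent of the rle-based implementation).
flood_fill_components <- function(row) {
  visited <- rep(FALSE, length(row))
  comps <- list()
  for (start in seq_along(row)) {
    if (row[start] == 1L && !visited[start]) {
      stack <- start
      cells <- integer(0)
      while (length(stack)) {
        c0 <- stack[[1L]]
        stack <- stack[-1L]
        if (c0 < 1L || c0 > length(row) || visited[c0] || row[c0] != 1L) next
        visited[c0] <- TRUE
        cells <- c(cells, c0)
        stack <- c(stack, c0 - 1L, c0 + 1L)
      }
      comps[[length(comps) + 1L]] <- range(cells)
    }
  }
  comps
}

# Oracle geometry summary from flood fill, for cross-checking nCC,
# lengthCC and fDISC.
oracle_cc_metrics <- function(mask) {
  per_proj <- apply(mask, 1L, flood_fill_components)
  ncc_i <- lengths(per_proj)
  lens <- unlist(lapply(per_proj, function(comps) {
    vapply(comps, function(b) b[2L] - b[1L] + 1L, numeric(1))
  }))
  list(
    nCC = mean(ncc_i[ncc_i > 0L]),
    lengthCC = sum(lens) / sum(ncc_i),
    fDISC = mean(ncc_i > 1L)
  )
}

# Spearman via explicit average ranks + textbook Pearson formula (no call
# to cor()).
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(rx)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Direct recomputation of LOT statistics over the flattened nonzero list.
oracle_lot_stats <- function(sg) {
  lot <- sg$S[sg$S > 0] * sg$PT
  list(mean = sum(lot) / length(lot),
       sd = sqrt(sum((lot - mean(lot))^2) / (length(lot) - 1)),
       min = min(lot), max = max(lot),
       median = stats::median(lot))
}
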
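# Field-geometry metrics. Everything here reads the binary open/closed mask
# only, so LOT magnitudes never enter: these scores quantify the shape of
# the binary-MLC aperture per projection (span, splitting into disjoint
# subfields, in-field closed leaves, open-edge structure).

#' Per-projection field geometry
#'
#' Decomposes each projection of the mask into maximal runs of consecutive
#' open leaves (the connected components of the 1-D aperture), recording the
#' outermost open-leaf indexes, the per-projection treatment area
#' `TA_i = R_i - L_i + 1` (leaves), and each component's bounds and length.
#' Projections with no open leaf are legal and recorded with zero
#' components and undefined bounds.
#'
#' @param mask binary matrix from [leaf_mask()] (or an [ht_plan] /
#'   [ht_sinogram], masked at `eps = 0`).
#' @return A list of class `ht_projection_geometry`: `left`, `right`, `TA_i`
#'   (per-projection vectors, `NA` where empty), `nCC_i` (component counts),
#'   and `components` (per projection, a 2-column matrix of bounds).
#' @examples
#' m <- matrix(0L, 1, 20); m[1, c(10:11, 14)] <- 1L
#' g <- projection_geometry(m)
#' g$nCC_i # 2
#' @export
projection_geometry <- function(mask) {
  if (inherits(mask, "ht_plan") || inherits(mask, "ht_sinogram")) {
    mask <- leaf_mask(mask)
  }
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L))) {
    stop("`mask` must be a binary 0/1 matrix", call. = FALSE)
  }
  N <- nrow(mask)
  left <- right <- TA_i <- rep(NA_real_, N)
  nCC_i <- integer(N)
  components <- vector("list", N)
  for (i in seq_len(N)) {
    r <- rle(mask[i, ] == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    open <- which(r$values)
    if (length(open)) {
      comp <- cbind(start = starts[open], end = ends[open])
      components[[i]] <- comp
      nCC_i[i] <- nrow(comp)
      left[i] <- comp[1L, 1L]
      right[i] <- comp[nrow(comp), 2L]
      TA_i[i] <- right[i] - left[i] + 1
    } else {
      components[[i]] <- cbind(start = integer(0), end = integer(0))
    }
  }
  structure(
    list(left = left, right = right, TA_i = TA_i, nCC_i = nCC_i,
         components = components, N = N, L = ncol(mask)),
    class = "ht_projection_geometry"
  )
}

#' Field-geometry metric family
#'
#' Plan-level geometry scores computed from the open/closed mask:
#' \describe{
#'   \item{TA}{mean treatment area: average span between the outermost open
#'     leaves, in leaves. Averaged over projections with at least one open
#'     leaf (the bounds do not exist for empty projections).}
#'   \item{centroid}{mean of the average open-leaf position per projection,
#'     in leaf-position units ([leaf_positions()]); signed, 0 for a field
#'     symmetric about the MLC center.}
#'   \item{nCC}{mean number of connected open-leaf components per
#'     projection (averaged over non-empty projections).}
#'   \item{lengthCC}{total component length over total component count —
#'     the average length of a disjoint subfield, in leaves.}
#'   \item{fDISC}{fraction of all N projections with two or more
#'     components, i.e. with at least one closed leaf inside the span.}
#'   \item{CLS}{mean fraction of closed leaves per projection (over all N
#'     and all L leaves).}
#'   \item{CLSin}{mean over all N of (in-span closed leaves) / L.}
#'   \item{CLSin_area}{as CLSin but normalized per projection by `TA_i`
#'     instead of L (empty projections contribute 0).}
#'   \item{CLSin_disc, CLSin_area_disc}{the same two scores restricted to
#'     discontinuous projections (`nCC_i > 1`) only; 0 when no projection is
#'     discontinuous, with attribute `no_discontinuous = TRUE` as the flag.}
#'   \item{L0NS, L1NS, L2NS}{fraction of open cells (pooled over the plan)
#'     with 0, 1 or 2 open lateral neighbors; out-of-range neighbors count
#'     as closed. They partition the open cells, so they sum to 1.}
#' }
#'
#' @param plan an [ht_plan] or [ht_sinogram].
#' @param geom optional precomputed [projection_geometry()].
#' @param eps open/closed threshold passed to [leaf_mask()].
#' @return Named numeric vector with the 13 scores listed above. For a plan
#'   with zero open cells every score is `NA`.
#' @export
geometry_metrics <- function(plan, geom = NULL, eps = 0) {
  mask <- leaf_mask(plan, eps = eps)
  if (is.null(geom)) geom <- projection_geometry(mask)
  N <- geom$N
  L <- geom$L
  active <- geom$nCC_i > 0L
  nms <- c("TA", "centroid", "nCC", "lengthCC", "fDISC", "CLS", "CLSin",
           "CLSin_area", "CLSin_disc", "CLSin_area_disc",
           "L0NS", "L1NS", "L2NS")
  if (!any(active)) {
    out <- rep(NA_real_, length(nms))
    names(out) <- nms
    return(out)
  }
  P <- leaf_positions(L)

  open_per_proj <- rowSums(mask)
  TA <- mean(geom$TA_i[active])
  centroid <- mean(vapply(which(active), function(i) {
    open <- mask[i, ] == 1L
    sum(P[open]) / sum(open)
  }, numeric(1)))
  nCC <- mean(geom$nCC_i[active])
  total_len <- sum(vapply(geom$components[active], function(cmp) {
    sum(cmp[, "end"] - cmp[, "start"] + 1L)
  }, numeric(1)))
  lengthCC <- total_len / sum(geom$nCC_i[active])
  fDISC <- mean(geom$nCC_i > 1L)

  CLS <- 1 - mean(open_per_proj) / L
  in_field_closed <- ifelse(active, geom$TA_i - open_per_proj, 0)
  CLSin <- mean(in_field_closed / L)
  CLSin_area <- mean(ifelse(active, in_field_closed / geom$TA_i, 0))
  disc <- geom$nCC_i > 1L
  if (any(disc)) {
    CLSin_disc <- mean(in_field_closed[disc] / L)
    CLSin_area_disc <- mean(in_field_closed[disc] / geom$TA_i[disc])
    no_disc <- FALSE
  } else {
    CLSin_disc <- 0
    CLSin_area_disc <- 0
    no_disc <- TRUE
  }

  # open lateral neighbor counts, pooled over all open cells of the plan
  left_nb <- cbind(0L, mask[, -L, drop = FALSE])
  right_nb <- cbind(mask[, -1L, drop = FALSE], 0L)
  nb <- left_nb + right_nb
  nb_open <- nb[mask == 1L]
  LnNS <- tabulate(nb_open + 1L, nbins = 3L) / length(nb_open)

  out <- c(TA, centroid, nCC, lengthCC, fDISC, CLS, CLSin, CLSin_area,
           CLSin_disc, CLSin_area_disc, LnNS)
  names(out) <- nms
  if (no_disc) attr(out, "no_discontinuous") <- TRUE
  out
}
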
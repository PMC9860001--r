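#' Fractional leaf-open-time sinogram
#'
#' The central object of the package: an `N x L` matrix `S` of fractional
#' leaf open times (FLOTs), one row per gantry projection and one column per
#' binary-MLC leaf, together with the projection time. Every entry lies in
#' `[0, 1]`; the absolute leaf open time (LOT) of cell `(i, j)` is
#' `S[i, j] * PT` milliseconds. A leaf is closed at a projection when its
#' FLOT is exactly zero.
#'
#' Values exceeding 1 by at most `1e-9` are clipped to 1 with a warning
#' (floating-point slack from upstream systems); larger violations, or
#' negative entries, are integrity errors naming the offending cell.
#'
#' @param S numeric matrix of fractional open times, projections in rows,
#'   leaves in columns.
#' @param PT projection time in milliseconds (single positive number).
#' @return An object of class `ht_sinogram`: a list with elements `S`, `PT`,
#'   `N` (number of projections) and `L` (number of leaves).
#' @examples
#' sg <- ht_sinogram(matrix(0.5, 3, 64), PT = 200)
#' sg$N
#' @export
ht_sinogram <- function(S, PT) {
  if (!is.matrix(S) || !is.numeric(S)) {
    stop("`S` must be a numeric matrix (projections x leaves)", call. = FALSE)
  }
  if (nrow(S) < 1L || ncol(S) < 2L) {
    stop("sinogram needs N >= 1 projections and L >= 2 leaves", call. = FALSE)
  }
  if (!is.numeric(PT) || length(PT) != 1L || is.na(PT) || PT <= 0) {
    stop("`PT` must be a single positive projection time in ms", call. = FALSE)
  }
  if (anyNA(S)) stop("sinogram contains NA cells", call. = FALSE)
  bad <- which(S < 0 | S > 1 + 1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "sinogram integrity error: S[%d, %d] = %.12g outside [0, 1]",
      bad[1L, 1L], bad[1L, 2L], S[bad[1L, 1L], bad[1L, 2L]]
    ), call. = FALSE)
  }
  over <- S > 1
  if (any(over)) {
    warning(sprintf("clipped %d sinogram cell(s) exceeding 1 by <= 1e-9",
                    sum(over)), call. = FALSE)
    S[over] <- 1
  }
  dimnames(S) <- NULL
  structure(
    list(S = S, PT = as.numeric(PT), N = nrow(S), L = ncol(S)),
    class = "ht_sinogram"
  )
}

#' @export
print.ht_sinogram <- function(x, ...) {
  cat(sprintf("<ht_sinogram> %d projections x %d leaves, PT = %g ms\n",
              x$N, x$L, x$PT))
  nz <- x$S[x$S > 0]
  if (length(nz)) {
    cat(sprintf("  open cells: %d (%.1f%%), FLOT range [%.3g, %.3g]\n",
                length(nz), 100 * length(nz) / length(x$S),
                min(nz), max(nz)))
  } else {
    cat("  all leaves closed\n")
  }
  invisible(x)
}

#' Helical tomotherapy plan document
#'
#' Bundles a sinogram with the delivery metadata needed by the delivery
#' metric family. All metadata besides the sinogram are optional: a missing
#' field is stored as `NA` and every metric that needs it reports
#' not-available instead of a silent zero.
#'
#' @param sinogram an [ht_sinogram].
#' @param plan_id plan identifier (single string).
#' @param tps_dialect one of `"precision"`, `"raystation"`, `"native"`.
#' @param FW jaw field width in cm.
#' @param GP gantry period in s. When both `GP` and the sinogram projection
#'   time are present they must agree (`PT = GP / projections_per_rotation`);
#'   on disagreement beyond 1e-3 relative the sinogram-derived value wins and
#'   a warning is raised.
#' @param TL target length in cm (pass-through metadata).
#' @param CT couch translation over the treatment in cm.
#' @param dose_per_fraction prescription dose per fraction in Gy.
#' @param projections_per_rotation projections per gantry rotation
#'   (51 for standard HT geometry).
#' @return An object of class `ht_plan`.
#' @export
ht_plan <- function(sinogram, plan_id = "plan",
                    tps_dialect = c("native", "precision", "raystation"),
                    FW = NA_real_, GP = NA_real_, TL = NA_real_,
                    CT = NA_real_, dose_per_fraction = NA_real_,
                    projections_per_rotation = 51L) {
  if (!inherits(sinogram, "ht_sinogram")) {
    stop("`sinogram` must be an ht_sinogram", call. = FALSE)
  }
  tps_dialect <- match.arg(tps_dialect)
  num1 <- function(x, nm, positive = TRUE) {
    if (length(x) != 1L || (!is.na(x) && (!is.numeric(x) || (positive && x <= 0)))) {
      stop(sprintf("`%s` must be a single positive number or NA", nm),
           call. = FALSE)
    }
    as.numeric(x)
  }
  ppr <- as.numeric(projections_per_rotation)
  if (length(ppr) != 1L || is.na(ppr) || ppr < 1) {
    stop("`projections_per_rotation` must be a single count >= 1",
         call. = FALSE)
  }
  GP <- num1(GP, "GP")
  if (!is.na(GP)) {
    gp_from_pt <- sinogram$PT * ppr / 1000
    if (abs(GP - gp_from_pt) / gp_from_pt > 1e-3) {
      warning(sprintf(
        "stored GP (%g s) disagrees with PT x %g = %g s; using sinogram-derived value",
        GP, ppr, gp_from_pt), call. = FALSE)
      GP <- gp_from_pt
    }
  }
  structure(
    list(
      sinogram = sinogram,
      plan_id = as.character(plan_id)[1L],
      tps_dialect = tps_dialect,
      FW = num1(FW, "FW"),
      GP = GP,
      TL = num1(TL, "TL"),
      CT = num1(CT, "CT", positive = FALSE),
      dose_per_fraction = num1(dose_per_fraction, "dose_per_fraction"),
      projections_per_rotation = ppr
    ),
    class = "ht_plan"
  )
}

#' @export
print.ht_plan <- function(x, ...) {
  cat(sprintf("<ht_plan> '%s' (%s dialect)\n", x$plan_id, x$tps_dialect))
  print(x$sinogram)
  meta <- c(FW = x$FW, GP = x$GP, TL = x$TL, CT = x$CT,
            dose_per_fraction = x$dose_per_fraction,
            projections_per_rotation = x$projections_per_rotation)
  avail <- !is.na(meta)
  cat("  metadata:",
      if (any(avail)) paste(names(meta)[avail], signif(meta[avail], 6),
                            sep = "=", collapse = ", ")
      else "none", "\n")
  if (any(!avail)) {
    cat("  missing:", paste(names(meta)[!avail], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Leaf position array
#'
#' Dimensionless leaf indexes measured from the geometrical center of the
#' MLC. For an even number of leaves `L` the array is
#' `(-L/2, ..., -1, +1, ..., +L/2)`: antisymmetric, with no zero entry
#' because the center falls between the two central leaves. Centroid and
#' mean sinogram asymmetry are reported in these number-of-leaves units.
#'
#' @param L number of leaves (even).
#' @return Numeric vector of length `L`.
#' @examples
#' leaf_positions(4) # -2 -1  1  2
#' @export
leaf_positions <- function(L) {
  L <- as.integer(L)
  if (is.na(L) || L < 2L || L %% 2L != 0L) {
    stop("`L` must be an even leaf count >= 2", call. = FALSE)
  }
  c(seq.int(-L %/% 2L, -1L), seq.int(1L, L %/% 2L))
}

#' Binary open/closed mask of a sinogram
#'
#' The mask sinogram `O` has `O[i, j] = 1` where the leaf is open
#' (`S[i, j] > eps`) and 0 elsewhere. All field-geometry metrics are
#' computed from this mask, so LOT magnitudes do not enter them.
#'
#' @param x an [ht_sinogram] or [ht_plan].
#' @param eps open/closed threshold; a leaf counts as open when its FLOT
#'   strictly exceeds `eps`. The default 0 matches the convention that a
#'   leaf is closed only when its open time is exactly zero.
#' @return Integer 0/1 matrix with the sinogram's dimensions.
#' @export
leaf_mask <- function(x, eps = 0) {
  S <- as_sinogram(x)$S
  (S > eps) + 0L
}

# Coerce plan-or-sinogram arguments; every metric entry point accepts both.
as_sinogram <- function(x) {
  if (inherits(x, "ht_plan")) return(x$sinogram)
  if (inherits(x, "ht_sinogram")) return(x)
  stop("expected an ht_plan or ht_sinogram", call. = FALSE)
}

as_plan <- function(x) {
  if (inherits(x, "ht_plan")) return(x)
  if (inherits(x, "ht_sinogram")) return(ht_plan(x))
  stop("expected an ht_plan or ht_sinogram", call. = FALSE)
}

# Nonzero fractional open times, flattened; errors on all-closed plans
# because every LOT-distribution statistic is undefined there.
nonzero_flots <- function(x) {
  S <- as_sinogram(x)$S
  v <- S[S > 0]
  if (!length(v)) {
    stop("all leaves closed: LOT distribution undefined", call. = FALSE)
  }
  v
}
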
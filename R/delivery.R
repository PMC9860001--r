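#' Delivery parameter metrics
#'
#' Computes the 12-metric Delivery subcategory from a plan's metadata and
#' sinogram: pitch, field width (FW, cm), projection time (PT, ms), gantry
#' period (GP, s), treatment time (TT, s), target length (TL, cm), couch
#' speed (CS, cm/s), couch translation (CT, cm), number of projections
#' (Nproj), number of rotations (Nrot, fractional), modulation factor (MF)
#' and treatment time per fraction dose (TTDF, s/Gy).
#'
#' Definitions used:
#' \itemize{
#'   \item `TT = Nproj * PT` (converted to seconds); ramp-up and dead time
#'     are excluded, so cross-center comparisons with latency models must
#'     adjust.
#'   \item `MF = max(LOT) / mean(LOT)` over the *nonzero* leaf open times:
#'     the actual modulation factor. Including structurally closed leaves
#'     would make MF grow with field size rather than with modulation.
#'   \item `CS = CT / TT`, `pitch = (CS * GP) / FW` (couch travel per
#'     rotation over field width), `Nrot = Nproj / projections_per_rotation`,
#'     `TTDF = TT / dose_per_fraction`.
#' }
#' Any metric whose metadata inputs are missing is reported `NA` (explicit
#' not-available), never silently zero.
#'
#' @param plan an [ht_plan].
#' @return Named numeric vector with elements `pitch`, `FW`, `PT`, `GP`,
#'   `TT`, `TL`, `CS`, `CT`, `Nproj`, `Nrot`, `MF`, `TTDF`.
#' @examples
#' pl <- generate_plan(ht_profile(seed = 1))
#' compute_delivery(pl)
#' @param allow_na_mf report `MF = NA` instead of erroring on an all-closed
#'   sinogram (used by the batch engine for per-cell failure isolation).
#' @export
compute_delivery <- function(plan, allow_na_mf = FALSE) {
  plan <- as_plan(plan)
  sg <- plan$sinogram
  PT <- sg$PT
  ppr <- plan$projections_per_rotation
  if (is.na(ppr)) ppr <- 51

  nz <- sg$S[sg$S > 0]
  if (!length(nz) && !allow_na_mf) {
    stop("all leaves closed: modulation factor undefined", call. = FALSE)
  }
  MF <- if (length(nz)) max(nz) / mean(nz) else NA_real_

  N_proj <- sg$N
  N_rot <- N_proj / ppr
  TT <- N_proj * PT / 1000
  GP <- PT * ppr / 1000
  CS <- if (!is.na(plan$CT)) plan$CT / TT else NA_real_
  pitch <- if (!is.na(CS) && !is.na(plan$FW)) (CS * GP) / plan$FW else NA_real_
  TTDF <- if (!is.na(plan$dose_per_fraction)) TT / plan$dose_per_fraction
          else NA_real_

  c(pitch = pitch, FW = plan$FW, PT = PT, GP = GP, TT = TT, TL = plan$TL,
    CS = CS, CT = plan$CT, Nproj = N_proj, Nrot = N_rot, MF = MF,
    TTDF = TTDF)
}
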
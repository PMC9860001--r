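#' Synthetic plan generator profile
#'
#' Describes the statistical structure of a generated plan: how many
#' projections and leaves, the shape of the nonzero fractional open-time
#' (FLOT) distribution, how much of the MLC opens per projection, how
#' discontinuous the open field is, and how far the field center sits from
#' the MLC center. Two of the shapes emulate the FLOT histograms that
#' separate delivery-efficiency classes in clinical HT cohorts: a bimodal
#' distribution (modes near 0.5 and near the maximum FLOT, characteristic of
#' heavily time-modulated, less efficient plans) and a flat distribution
#' with a marked peak in the last bin (characteristic of efficient plans
#' that modulate by splitting the field geometrically).
#'
#' @param n_projections projections per plan.
#' @param n_leaves leaves (even; 64 for the standard HT binary MLC).
#' @param flot_shape `"constant"`, `"uniform_flat"`, `"bimodal"` or
#'   `"flat_with_end_peak"`.
#' @param open_fraction fraction of the MLC forming the open span per
#'   projection, in `(0, 1]`.
#' @param discontinuity expected number of closed gaps strictly inside the
#'   open span per projection (Poisson mean, >= 0).
#' @param asymmetry_shift lateral offset of the field center in leaves
#'   (signed).
#' @param allow_full_open if `TRUE`, FLOTs sampled above 0.98 are snapped to
#'   exactly 1, producing fully-open runs; if `FALSE` every nonzero FLOT is
#'   strictly below 1 (the regime in which `CLS = 1 - 0.5 * nOC` is exact).
#' @param flot_value the FLOT used by the `"constant"` shape.
#' @param PT projection time in ms.
#' @param seed integer seed; generation is reproducible given the profile.
#' @return An object of class `ht_profile`.
#' @export
ht_profile <- function(n_projections = 100L, n_leaves = 64L,
                       flot_shape = c("uniform_flat", "constant", "bimodal",
                                      "flat_with_end_peak"),
                       open_fraction = 0.4, discontinuity = 0.5,
                       asymmetry_shift = 0, allow_full_open = FALSE,
                       flot_value = 0.5, PT = 200, seed = 1L) {
  flot_shape <- match.arg(flot_shape)
  if (open_fraction <= 0 || open_fraction > 1) {
    stop("`open_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (round(open_fraction * n_leaves) < 1) {
    stop("infeasible profile: open_fraction x n_leaves < 1", call. = FALSE)
  }
  if (discontinuity < 0) stop("`discontinuity` must be >= 0", call. = FALSE)
  structure(
    list(n_projections = as.integer(n_projections),
         n_leaves = as.integer(n_leaves),
         flot_shape = flot_shape,
         open_fraction = open_fraction,
         discontinuity = discontinuity,
         asymmetry_shift = asymmetry_shift,
         allow_full_open = isTRUE(allow_full_open),
         flot_value = flot_value,
         PT = PT,
         seed = as.integer(seed)),
    class = "ht_profile"
  )
}

#' @export
print.ht_profile <- function(x, ...) {
  cat(sprintf(
    "<ht_profile> %d x %d, shape=%s, open_fraction=%g, discontinuity=%g,\n",
    x$n_projections, x$n_leaves, x$flot_shape, x$open_fraction,
    x$discontinuity))
  cat(sprintf("  shift=%g leaves, full_open=%s, PT=%g ms, seed=%d\n",
              x$asymmetry_shift, x$allow_full_open, x$PT, x$seed))
  invisible(x)
}

# Draw n nonzero FLOTs for a profile. Shapes are qualitative emulations of
# the two clinically observed histogram families; no quantitative reference
# parameters exist, so the mixture weights and mode locations are fixed
# package choices (see the methods vignette).
sample_flots <- function(profile, n) {
  cap <- if (profile$allow_full_open) 1 else 0.995
  clamp <- function(v) pmin(pmax(v, 0.01), cap)
  v <- switch(profile$flot_shape,
    constant = rep(profile$flot_value, n),
    uniform_flat = stats::runif(n, 0.02, 0.98),
    bimodal = {
      pick <- stats::runif(n) < 0.5
      ifelse(pick,
             stats::rnorm(n, 0.50, 0.05),
             stats::rnorm(n, 0.93, 0.03))
    },
    flat_with_end_peak = {
      pick <- stats::runif(n) < 0.45
      ifelse(pick,
             stats::rnorm(n, 0.97, 0.015),
             stats::runif(n, 0.05, 0.98))
    })
  v <- clamp(v)
  if (profile$allow_full_open) v[v > 0.98] <- 1
  v
}

#' Generate one synthetic plan
#'
#' Builds an [ht_plan] whose sinogram follows the profile: each projection
#' opens a contiguous span of `round(open_fraction * L)` leaves centered at
#' `L/2 + asymmetry_shift`, a Poisson-distributed number of closed gaps is
#' punched strictly inside the span (never at its ends, so the span bounds
#' remain the outermost open leaves), and the open cells receive FLOTs drawn
#' from the profile's shape. Identical profiles (including seed) give
#' identical plans.
#'
#' @param profile an [ht_profile].
#' @param plan_id identifier stored in the plan.
#' @return An [ht_plan].
#' @export
generate_plan <- function(profile, plan_id = sprintf("synth-%06d",
                                                     profile$seed)) {
  stopifnot(inherits(profile, "ht_profile"))
  N <- profile$n_projections
  L <- profile$n_leaves
  width <- max(1L, round(profile$open_fraction * L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(profile$seed)

  S <- matrix(0, N, L)
  center <- L / 2 + 0.5 + profile$asymmetry_shift
  left <- floor(center - width / 2 + 0.5)
  left <- min(max(left, 1L), L - width + 1L)
  span <- left:(left + width - 1L)
  for (i in seq_len(N)) {
    open <- span
    if (profile$discontinuity > 0 && width > 2L) {
      n_gaps <- stats::rpois(1L, profile$discontinuity)
      n_gaps <- min(n_gaps, width - 2L)
      if (n_gaps > 0L) {
        interior <- span[-c(1L, width)]
        gaps <- sample(interior, n_gaps)
        open <- setdiff(open, gaps)
      }
    }
    S[i, open] <- sample_flots(profile, length(open))
  }
  pl <- ht_plan(
    sinogram = ht_sinogram(S, PT = profile$PT),
    plan_id = plan_id,
    tps_dialect = "native",
    FW = 2.5,
    GP = profile$PT * 51 / 1000,
    TL = 10,
    CT = 10,
    dose_per_fraction = 2,
    projections_per_rotation = 51L
  )
  pl
}

#' Generate a cohort of synthetic plans
#'
#' Draws `n_plans` plans from a weighted mixture of profiles. The per-plan
#' seed is `master_seed + plan index` (a stated, deterministic splitting
#' rule), so cohorts are reproducible element-wise: plan `k` of a cohort is
#' the same object no matter how many plans are requested.
#'
#' @param n_plans number of plans (0 gives an empty list).
#' @param profiles list of [ht_profile]s.
#' @param weights positive mixture weights, recycled to `length(profiles)`.
#' @param master_seed integer master seed.
#' @return A list of [ht_plan]s. The drawn profile index of each plan is
#'   attached as attribute `"profile_index"` (and on each plan as
#'   `attr(plan, "profile_index")`), so labeled-cohort tests can recover the
#'   mixture component.
#' @export
generate_cohort <- function(n_plans, profiles, weights = 1,
                            master_seed = 1L) {
  if (inherits(profiles, "ht_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("empty profile mixture", call. = FALSE)
  if (!all(vapply(profiles, inherits, logical(1), "ht_profile"))) {
    stop("`profiles` must be a list of ht_profile objects", call. = FALSE)
  }
  weights <- rep_len(weights, length(profiles))
  if (any(weights <= 0)) stop("mixture weights must be positive",
                              call. = FALSE)
  n_plans <- as.integer(n_plans)
  if (n_plans == 0L) return(structure(list(), profile_index = integer(0)))

  # component choice for plan k depends only on (master_seed, k)
  idx <- vapply(seq_len(n_plans), function(k) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(master_seed * 1000003L %% 2147483647L + k)
    sample.int(length(profiles), 1L, prob = weights)
  }, integer(1))

  plans <- vector("list", n_plans)
  for (k in seq_len(n_plans)) {
    p <- profiles[[idx[k]]]
    p$seed <- (master_seed + k) %% 2147483647L
    plans[[k]] <- generate_plan(p, plan_id = sprintf("synth-%04d", k))
    attr(plans[[k]], "profile_index") <- idx[k]
  }
  attr(plans, "profile_index") <- idx
  plans
}

# Save/restore the global RNG state so generation with an explicit seed does
# not disturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
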
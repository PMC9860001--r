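#' Default metric registry
#'
#' The registry is an ordered table of metric descriptors driving
#' [extract_metrics()]. The default holds exactly 65 metrics in five
#' subcategories — Delivery (12), AbsoluteLOT (13), RelativeLOT (11),
#' Geometry (13), Modulation (16) — split into the 29 metrics with prior
#' literature definitions (`group = "old"`) and the 36 newly introduced
#' ones (`group = "new"`). Parameter choices baked into the default:
#' `CLNS` thresholds 20/30/50/100 ms, `CLNS_pt` margin 20 ms, `CFNS`
#' thresholds 0.05/0.10/0.50/0.75/0.90, `ELOTV` projection steps 1..5,
#' `EPSTV` steps (1,1), (1,0), (0,1).
#'
#' Thresholds and steps are user-extensible: pass a configuration list to
#' grow or shrink the cumulative families and variability steps.
#'
#' @param config optional list with any of `clns_thresholds`,
#'   `clns_pt_margins`, `cfns_thresholds`, `elotv_steps`, `epstv_steps`
#'   (2-column matrix of (delta_p, delta_l) rows), `eps` (mask threshold).
#' @return A data.frame of class `ht_metric_registry` with columns `name`,
#'   `category`, `group` and a `config` attribute.
#' @examples
#' nrow(default_registry()) # 65
#' table(default_registry()$group)
#' @export
default_registry <- function(config = list()) {
  cfg <- utils::modifyList(list(
    clns_thresholds = c(20, 30, 50, 100),
    clns_pt_margins = 20,
    cfns_thresholds = c(0.05, 0.10, 0.50, 0.75, 0.90),
    elotv_steps = 1:5,
    epstv_steps = rbind(c(1, 1), c(1, 0), c(0, 1)),
    eps = 0
  ), config)

  row <- function(name, category, group) {
    data.frame(name = name, category = category, group = group,
               stringsAsFactors = FALSE)
  }
  delivery <- row(c("pitch", "FW", "PT", "GP", "TT", "TL", "CS", "CT",
                    "Nproj", "Nrot", "MF", "TTDF"), "Delivery", "old")
  # thresholds with prior literature definitions keep group "old";
  # user-added thresholds are new by construction
  clns <- row(paste0("CLNS", format(cfg$clns_thresholds, trim = TRUE)),
              "AbsoluteLOT",
              ifelse(cfg$clns_thresholds %in% c(30, 50, 100), "old", "new"))
  clns_pt <- row(paste0("CLNSpt", format(cfg$clns_pt_margins, trim = TRUE)),
                 "AbsoluteLOT",
                 ifelse(cfg$clns_pt_margins == 20, "old", "new"))
  abs_scalar <- rbind(
    row(c("mLOT", "sdLOT", "mdLOT", "moLOT", "minLOT", "maxLOT"),
        "AbsoluteLOT", "old"),
    row(c("kLOT", "sLOT"), "AbsoluteLOT", "new"))
  rel_new <- row(c("mFLOT", "sdFLOT", "moFLOT", "mdFLOT", "minFLOT",
                   "maxFLOT",
                   paste0("CFNS", round(100 * cfg$cfns_thresholds))),
                 "RelativeLOT", "new")
  geo_old <- row(c("L0NS", "L1NS", "CLS", "CLSin"), "Geometry", "old")
  geo_new <- row(c("L2NS", "nCC", "lengthCC", "TA", "fDISC", "CLSin_area",
                   "CLSin_disc", "CLSin_area_disc", "centroid"),
                 "Geometry", "new")
  mod_old <- row(c("PSTV", "LOTV", "MI"), "Modulation", "old")
  mod_new <- row(c("nOC",
                   paste0("EPSTV", apply(cfg$epstv_steps, 1L, paste,
                                         collapse = "")),
                   paste0("ELOTV", cfg$elotv_steps),
                   "mSI", "mdSI", "sdSI", "MSA"),
                 "Modulation", "new")
  reg <- rbind(delivery,
               abs_scalar[1:6, ], clns[order(-cfg$clns_thresholds), ],
               clns_pt, abs_scalar[7:8, ],
               rel_new, geo_old, geo_new, mod_old, mod_new)
  if (anyDuplicated(reg$name)) {
    stop("registry names must be unique", call. = FALSE)
  }
  attr(reg, "config") <- cfg
  class(reg) <- c("ht_metric_registry", "data.frame")
  reg
}

#' @export
print.ht_metric_registry <- function(x, ...) {
  cat(sprintf("<ht_metric_registry> %d metrics (%d old, %d new)\n",
              nrow(x), sum(x$group == "old"), sum(x$group == "new")))
  print(table(category = x$category, group = x$group))
  invisible(x)
}
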
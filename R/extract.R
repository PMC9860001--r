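# Extraction engine: evaluate a metric registry over a batch of plans.
# Metric values are computed block-wise (one block per subcategory, sharing
# intermediates such as the mask decomposition), but failures are isolated
# per cell: a block that errors marks only its own metrics not-available,
# with the reason logged, and never aborts the batch.

evaluate_plan_metrics <- function(plan, registry) {
  cfg <- attr(registry, "config")
  values <- stats::setNames(rep(NA_real_, nrow(registry)), registry$name)
  failures <- list()
  fail <- function(metrics, err) {
    present <- intersect(metrics, names(values))
    for (m in present) {
      failures[[m]] <<- conditionMessage(err)
    }
  }
  put <- function(v) {
    common <- intersect(names(v), names(values))
    values[common] <<- v[common]
  }

  tryCatch({
    d <- compute_delivery(plan, allow_na_mf = TRUE)
    if (is.na(d[["MF"]])) {
      fail("MF", simpleError("all leaves closed: modulation factor undefined"))
    }
    put(d)
  }, error = function(e) fail(c("pitch", "FW", "PT", "GP", "TT", "TL",
                                "CS", "CT", "Nproj", "Nrot", "MF",
                                "TTDF"), e))

  tryCatch({
    st <- absolute_lot_stats(plan, cfg$clns_thresholds, cfg$clns_pt_margins)
    put(c(unlist(st[c("mLOT", "sdLOT", "mdLOT", "moLOT", "minLOT", "maxLOT",
                      "kLOT", "sLOT")]),
          st$CLNS, st$CLNS_pt))
  }, error = function(e) fail(c("mLOT", "sdLOT", "mdLOT", "moLOT", "minLOT",
                                "maxLOT", "kLOT", "sLOT",
                                grep("^CLNS", names(values), value = TRUE)),
                              e))

  tryCatch({
    st <- relative_lot_stats(plan, cfg$cfns_thresholds)
    put(c(unlist(st[c("mFLOT", "sdFLOT", "mdFLOT", "moFLOT", "minFLOT",
                      "maxFLOT")]),
          st$CFNS))
  }, error = function(e) fail(c("mFLOT", "sdFLOT", "mdFLOT", "moFLOT",
                                "minFLOT", "maxFLOT",
                                grep("^CFNS", names(values), value = TRUE)),
                              e))

  tryCatch(put(geometry_metrics(plan, eps = cfg$eps)),
           error = function(e) fail(c("TA", "centroid", "nCC", "lengthCC",
                                      "fDISC", "CLS", "CLSin", "CLSin_area",
                                      "CLSin_disc", "CLSin_area_disc",
                                      "L0NS", "L1NS", "L2NS"), e))

  for (dp in cfg$elotv_steps) {
    nm <- paste0("ELOTV", dp)
    if (nm %in% names(values)) {
      tryCatch(values[nm] <- elotv(plan, dp),
               error = function(e) fail(nm, e))
    }
  }
  if ("LOTV" %in% names(values)) {
    tryCatch(values["LOTV"] <- lotv(plan),
             error = function(e) fail("LOTV", e))
  }
  for (k in seq_len(nrow(cfg$epstv_steps))) {
    dp <- cfg$epstv_steps[k, 1L]
    dl <- cfg$epstv_steps[k, 2L]
    nm <- paste0("EPSTV", dp, dl)
    if (nm %in% names(values)) {
      tryCatch(values[nm] <- epstv(plan, dp, dl),
               error = function(e) fail(nm, e))
    }
  }
  if ("PSTV" %in% names(values)) {
    tryCatch(values["PSTV"] <- pstv(plan),
             error = function(e) fail("PSTV", e))
  }
  if ("nOC" %in% names(values)) {
    tryCatch(values["nOC"] <- noc(plan), error = function(e) fail("nOC", e))
  }
  tryCatch({
    lm <- lps_metrics(plan)
    put(c(MSA = lm$MSA, mSI = lm$mSI, mdSI = lm$mdSI, sdSI = lm$sdSI))
  }, error = function(e) fail(c("MSA", "mSI", "mdSI", "sdSI"), e))
  if ("MI" %in% names(values)) {
    tryCatch(values["MI"] <- as.numeric(modulation_index(plan)),
             error = function(e) fail("MI", e))
  }

  list(values = values, failures = failures)
}

#' Extract a metric table from a batch of plans
#'
#' Evaluates every metric of the registry on every plan, producing a
#' rectangular plan-by-metric table (plan ids in the first column, one
#' column per registry metric, in registry order). A metric that cannot be
#' computed for a plan — missing metadata, an all-closed sinogram — is
#' reported `NA` and the reason is collected in the table's `failures`
#' attribute; a bad plan never aborts the batch. Extraction is
#' deterministic and order-independent: permuting the input plans permutes
#' the rows only.
#'
#' @param plans a list of [ht_plan]s (or a single plan).
#' @param registry an `ht_metric_registry`; defaults to the 65-metric
#'   [default_registry()].
#' @return A `data.frame` of class `ht_metric_table` with attributes
#'   `registry` and `failures` (named by `plan_id`, only for plans with at
#'   least one failed cell).
#' @examples
#' plans <- generate_cohort(3, ht_profile(), master_seed = 1)
#' mt <- extract_metrics(plans)
#' dim(mt) # 3 plans x (1 + 65) columns
#' @export
extract_metrics <- function(plans, registry = default_registry()) {
  if (inherits(plans, "ht_plan")) plans <- list(plans)
  if (!inherits(registry, "ht_metric_registry")) {
    stop("`registry` must be an ht_metric_registry", call. = FALSE)
  }
  if (!length(plans)) {
    out <- as.data.frame(c(list(plan_id = character(0)),
                           stats::setNames(rep(list(numeric(0)),
                                               nrow(registry)),
                                           registry$name)))
    return(structure(out, registry = registry, failures = list(),
                     class = c("ht_metric_table", "data.frame")))
  }
  rows <- lapply(plans, evaluate_plan_metrics, registry = registry)
  values <- do.call(rbind, lapply(rows, function(r) r$values))
  out <- data.frame(plan_id = vapply(plans, function(p) p$plan_id,
                                     character(1)),
                    values, check.names = FALSE, stringsAsFactors = FALSE)
  failures <- lapply(rows, function(r) r$failures)
  names(failures) <- out$plan_id
  failures <- failures[lengths(failures) > 0L]
  rownames(out) <- NULL
  structure(out, registry = registry, failures = failures,
            class = c("ht_metric_table", "data.frame"))
}

#' @export
print.ht_metric_table <- function(x, ...) {
  cat(sprintf("<ht_metric_table> %d plan(s) x %d metric(s)\n",
              nrow(x), ncol(x) - 1L))
  fails <- attr(x, "failures")
  if (length(fails)) {
    cat(sprintf("  %d plan(s) with not-available cells\n", length(fails)))
  }
  NextMethod()
}

#' Write / read a metric table as CSV
#'
#' UTF-8 CSV with a header row, `plan_id` first. A provenance comment block
#' (`# key: value`) records the registry size and conventions so a table
#' can be audited without the session that produced it;
#' `read_metric_table()` skips it.
#'
#' @param table an `ht_metric_table` (or plain data.frame with `plan_id`).
#' @param path output / input CSV path.
#' @return `write_metric_table()`: `path` invisibly;
#'   `read_metric_table()`: a data.frame.
#' @export
write_metric_table <- function(table, path) {
  reg <- attr(table, "registry")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  cfg <- if (!is.null(reg)) attr(reg, "config") else NULL
  writeLines(c(
    "# htcomplexity metric table",
    sprintf("# metrics: %d", ncol(table) - 1L),
    if (!is.null(cfg)) sprintf("# mask_eps: %g", cfg$eps),
    "# conventions: nonzero-LOT statistics; strict CLNS/CFNS inequalities"
  ), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
}
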
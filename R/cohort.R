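# Cohort-level statistics: metric-metric correlation structure, screening
# of metrics against patient-specific QA passing rates, and stratification
# of a cohort by delivery efficiency (CFNS75 quartiles).

CORRELATION_CLASSES <- c("very weak", "weak", "moderate", "strong",
                         "very strong")

#' Grade a correlation magnitude
#'
#' Fixed, conventional class boundaries on `|rho|`: very weak `[0, 0.2)`,
#' weak `[0.2, 0.4)`, moderate `[0.4, 0.6)`, strong `[0.6, 0.8)`,
#' very strong `[0.8, 1]`.
#'
#' @param rho correlation value(s).
#' @return Factor with the five class levels (`NA` stays `NA`).
#' @export
correlation_class <- function(rho) {
  idx <- findInterval(abs(rho), c(0, 0.2, 0.4, 0.6, 0.8))
  factor(CORRELATION_CLASSES[idx], levels = CORRELATION_CLASSES)
}

# Spearman rho and two-sided p-value on complete pairs. Ties get average
# ranks; p-values use the large-sample t approximation
# t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
spearman_pair <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) return(c(rho = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  c(rho = rho, p = p, n = n)
}

metric_columns <- function(table) {
  df <- as.data.frame(table)
  nm <- setdiff(names(df), "plan_id")
  df[nm]
}

#' Metric-metric Spearman correlation map
#'
#' Pairwise Spearman rank correlations over all metric columns of a metric
#' table, with two-sided p-values, five-class magnitude grades and a
#' significance mask at level `alpha`. Constant columns (no rank
#' variability) and pairs with fewer than 3 complete observations are
#' flagged not-available.
#'
#' @param table an `ht_metric_table` (or data.frame with a `plan_id`
#'   column).
#' @param alpha significance level for the mask.
#' @return Object of class `ht_correlation_map`: list with matrices `rho`,
#'   `p`, `class` (character), `significant` (logical), plus `alpha` and
#'   `constant` (names of constant columns).
#' @export
correlation_map <- function(table, alpha = 0.05) {
  X <- metric_columns(table)
  if (nrow(X) < 3L) stop("need at least 3 plans", call. = FALSE)
  m <- ncol(X)
  nms <- names(X)
  rho <- p <- matrix(NA_real_, m, m, dimnames = list(nms, nms))
  for (a in seq_len(m)) {
    rho[a, a] <- 1
    p[a, a] <- 0
    for (b in seq_len(a - 1L)) {
      sp <- spearman_pair(X[[a]], X[[b]])
      rho[a, b] <- rho[b, a] <- sp[["rho"]]
      p[a, b] <- p[b, a] <- sp[["p"]]
    }
  }
  cls <- matrix(as.character(correlation_class(rho)), m, m,
                dimnames = list(nms, nms))
  constant <- nms[vapply(X, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0L && stats::sd(v) == 0
  }, logical(1))]
  structure(
    list(rho = rho, p = p, class = cls, significant = !is.na(p) & p < alpha,
         alpha = alpha, constant = constant),
    class = "ht_correlation_map"
  )
}

#' @export
print.ht_correlation_map <- function(x, ...) {
  m <- nrow(x$rho)
  off <- x$rho[lower.tri(x$rho)]
  cat(sprintf("<ht_correlation_map> %d metrics, alpha = %g\n", m, x$alpha))
  cat(sprintf("  off-diagonal |rho|: median %.2f, max %.2f; %d%% significant\n",
              stats::median(abs(off), na.rm = TRUE),
              max(abs(off), na.rm = TRUE),
              round(100 * mean(x$significant[lower.tri(x$rho)],
                               na.rm = TRUE))))
  if (length(x$constant)) {
    cat("  constant columns:", paste(x$constant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Screen metrics against patient-specific QA results
#'
#' Two-step selection of the complexity metrics related to a gamma passing
#' rate endpoint:
#' \enumerate{
#'   \item keep the metrics whose Spearman correlation with the endpoint is
#'     significant (`p < alpha`);
#'   \item walk the kept metrics in decreasing `|rho|` (ties broken by
#'     metric name) and drop any metric that is strongly correlated
#'     (`|rho| >= redundancy_threshold`, Spearman, between metric columns)
#'     with an already-kept one — of a redundant pair, the member with the
#'     smaller endpoint correlation is the one removed.
#' }
#' An empty selection is a valid outcome (no metric passes the screen).
#'
#' @param table metric table (rows matched to `psqa` by `plan_id`).
#' @param psqa data.frame with `plan_id` and one or more passing-rate
#'   columns in percent (e.g. `PR_3G2`, `PR_2L2`), values in `[0, 100]`.
#' @param endpoint name of the passing-rate column to screen against.
#' @param alpha significance level of step 1.
#' @param redundancy_threshold `|rho|` at or above which two metrics count
#'   as redundant; the default 0.6 is the lower edge of the "strong" class.
#' @return Object of class `ht_metric_selection`: data.frame with columns
#'   `metric`, `rho`, `p`, plus attributes `dropped` (redundancy victims)
#'   and `endpoint`.
#' @export
select_metrics <- function(table, psqa, endpoint, alpha = 0.05,
                           redundancy_threshold = 0.6) {
  df <- as.data.frame(table)
  if (!endpoint %in% names(psqa)) {
    stop(sprintf("endpoint column '%s' not in PSQA table", endpoint),
         call. = FALSE)
  }
  pr <- psqa[[endpoint]]
  if (any(!is.na(pr) & (pr < 0 | pr > 100))) {
    stop("passing rates must lie in [0, 100] percent", call. = FALSE)
  }
  merged <- merge(df, psqa[c("plan_id", endpoint)], by = "plan_id")
  if (!nrow(merged)) stop("no plan_id overlap with PSQA table",
                          call. = FALSE)
  y <- merged[[endpoint]]
  metrics <- setdiff(names(df), c("plan_id", endpoint))

  sc <- t(vapply(metrics, function(m) spearman_pair(merged[[m]], y),
                 numeric(3)))
  keep <- !is.na(sc[, "p"]) & sc[, "p"] < alpha
  cand <- data.frame(metric = metrics[keep],
                     rho = sc[keep, "rho"],
                     p = sc[keep, "p"],
                     stringsAsFactors = FALSE)
  cand <- cand[order(-abs(cand$rho), cand$metric), , drop = FALSE]

  kept <- character(0)
  dropped <- character(0)
  for (m in cand$metric) {
    redundant <- FALSE
    for (k in kept) {
      r <- spearman_pair(merged[[m]], merged[[k]])[["rho"]]
      if (!is.na(r) && abs(r) >= redundancy_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (redundant) dropped <- c(dropped, m) else kept <- c(kept, m)
  }
  out <- cand[cand$metric %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, dropped = dropped, endpoint = endpoint, alpha = alpha,
            redundancy_threshold = redundancy_threshold,
            class = c("ht_metric_selection", "data.frame"))
}

#' @export
print.ht_metric_selection <- function(x, ...) {
  cat(sprintf("<ht_metric_selection> endpoint %s: %d metric(s) kept, %d dropped as redundant\n",
              attr(x, "endpoint"), nrow(x), length(attr(x, "dropped"))))
  NextMethod()
}

#' Read a patient-specific QA results table
#'
#' CSV with a `plan_id` column and one or more gamma passing-rate columns
#' in percent (conventionally `PR_3G2` for the 3%-global/2 mm criterion and
#' `PR_2L2` for 2%-local/2 mm). Values must lie in `[0, 100]`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_psqa_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"plan_id" %in% names(df)) {
    stop("PSQA table must have a plan_id column", call. = FALSE)
  }
  rates <- setdiff(names(df), "plan_id")
  for (r in rates) {
    v <- df[[r]]
    if (!is.numeric(v) || any(!is.na(v) & (v < 0 | v > 100))) {
      stop(sprintf("PSQA column '%s' must be percentages in [0, 100]", r),
           call. = FALSE)
    }
  }
  df
}

#' Stratify a cohort by delivery efficiency
#'
#' Splits a cohort on its `CFNS75` values (fraction of nonzero FLOTs below
#' 0.75): plans strictly below the 25th percentile form the most efficient
#' group, plans strictly above the 75th percentile the least efficient
#' (percentiles by linear interpolation; plans at a percentile belong to
#' neither group). Every other metric is then compared between the groups
#' with a two-sample t-test (Student's equal-variance by default, Welch via
#' `var_equal = FALSE`), flagged at the 0.05 and 0.01 levels. The two
#' groups' fractional open-time distributions are summarized as pooled
#' histograms: each plan's nonzero FLOTs are binned on `[0, 1]` and
#' normalized to unit sum before pooling, and each group reports the
#' per-bin mean with a 95% Gaussian confidence interval.
#'
#' @param table metric table containing a `CFNS75` column.
#' @param plans the cohort's [ht_plan]s, in table row order (needed for the
#'   histograms; may be `NULL` to skip them).
#' @param bins number of FLOT histogram bins on `[0, 1]`.
#' @param var_equal use Student's (TRUE, default) or Welch's t-test.
#' @return Object of class `ht_efficiency_split`: list with `groups`
#'   (per-plan label: `"efficient"`, `"inefficient"` or `NA`), `cutoffs`,
#'   `comparison` (per-metric data.frame: group means/sds, t, p, flags) and
#'   `histograms` (per group: bin mids, mean, lo, hi).
#' @export
efficiency_split <- function(table, plans = NULL, bins = 20L,
                             var_equal = TRUE) {
  df <- as.data.frame(table)
  if (!"CFNS75" %in% names(df)) stop("metric table lacks a CFNS75 column",
                                     call. = FALSE)
  if (nrow(df) < 8L) stop("need at least 8 plans to stratify",
                          call. = FALSE)
  v <- df$CFNS75
  q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  eff <- !is.na(v) & v < q[1L]
  ineff <- !is.na(v) & v > q[2L]
  if (!any(eff) || !any(ineff)) {
    stop(sprintf(
      "degenerate CFNS75 percentiles (q25 = %g, q75 = %g): a strict split leaves an empty group",
      q[1L], q[2L]), call. = FALSE)
  }
  groups <- rep(NA_character_, nrow(df))
  groups[eff] <- "efficient"
  groups[ineff] <- "inefficient"

  metrics <- setdiff(names(df), "plan_id")
  comparison <- do.call(rbind, lapply(metrics, function(m) {
    a <- df[[m]][eff]
    b <- df[[m]][ineff]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    p <- tval <- NA_real_
    if (length(a) >= 2L && length(b) >= 2L &&
        (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      tt <- stats::t.test(a, b, var.equal = var_equal)
      p <- tt$p.value
      tval <- unname(tt$statistic)
    }
    data.frame(metric = m,
               mean_efficient = mean(a), sd_efficient = stats::sd(a),
               mean_inefficient = mean(b), sd_inefficient = stats::sd(b),
               t = tval, p = p,
               sig_05 = !is.na(p) & p < 0.05,
               sig_01 = !is.na(p) & p < 0.01,
               stringsAsFactors = FALSE)
  }))
  rownames(comparison) <- NULL

  histograms <- NULL
  if (!is.null(plans)) {
    if (length(plans) != nrow(df)) {
      stop("`plans` must match the metric table rows", call. = FALSE)
    }
    breaks <- seq(0, 1, length.out = bins + 1L)
    mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
    plan_hist <- function(p) {
      flot <- nonzero_flots(p)
      h <- graphics::hist(pmin(flot, 1), breaks = breaks, plot = FALSE)
      h$counts / sum(h$counts)
    }
    pool <- function(sel) {
      H <- do.call(rbind, lapply(plans[sel], plan_hist))
      mu <- colMeans(H)
      se <- apply(H, 2L, stats::sd) / sqrt(nrow(H))
      data.frame(mid = mids, mean = mu,
                 lo = mu - 1.96 * se, hi = mu + 1.96 * se)
    }
    histograms <- list(efficient = pool(eff), inefficient = pool(ineff))
  }

  structure(
    list(groups = groups, cutoffs = c(q25 = q[1L], q75 = q[2L]),
         n = c(efficient = sum(eff), inefficient = sum(ineff)),
         comparison = comparison, histograms = histograms,
         var_equal = var_equal),
    class = "ht_efficiency_split"
  )
}

#' @export
print.ht_efficiency_split <- function(x, ...) {
  cat(sprintf(
    "<ht_efficiency_split> %d efficient / %d least efficient (CFNS75 < %.3g / > %.3g)\n",
    x$n[["efficient"]], x$n[["inefficient"]],
    x$cutoffs[["q25"]], x$cutoffs[["q75"]]))
  sig <- x$comparison[x$comparison$sig_05, "metric"]
  cat(sprintf("  %d metric(s) differ at 0.05%s\n", length(sig),
              if (length(sig)) paste0(": ",
                                      paste(utils::head(sig, 12),
                                            collapse = ", "),
                                      if (length(sig) > 12) ", ...") else ""))
  invisible(x)
}

#' Plot the pooled FLOT histograms of an efficiency split
#'
#' Base-graphics rendering of the per-group average fractional open-time
#' histograms with their 95% confidence bands.
#'
#' @param x an `ht_efficiency_split` computed with plans.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ht_efficiency_split <- function(x, ...) {
  if (is.null(x$histograms)) {
    stop("split was computed without plans: no histograms to plot",
         call. = FALSE)
  }
  he <- x$histograms$efficient
  hi <- x$histograms$inefficient
  ylim <- range(0, he$hi, hi$hi)
  graphics::plot(he$mid, he$mean, type = "b", col = "forestgreen", pch = 16,
                 ylim = ylim, xlab = "fractional leaf open time",
                 ylab = "mean normalized counts", ...)
  graphics::arrows(he$mid, he$lo, he$mid, he$hi, angle = 90, code = 3,
                   length = 0.02, col = "forestgreen")
  graphics::lines(hi$mid, hi$mean, type = "b", col = "steelblue", pch = 17)
  graphics::arrows(hi$mid, hi$lo, hi$mid, hi$hi, angle = 90, code = 3,
                   length = 0.02, col = "steelblue")
  graphics::legend("topleft", legend = c("most efficient", "least efficient"),
                   col = c("forestgreen", "steelblue"), pch = c(16, 17),
                   bty = "n")
  invisible(x)
}
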
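make_table <- function(df) {
  # plain data.frame stand-in for a metric table
  cbind(data.frame(plan_id = sprintf("p%02d", seq_len(nrow(df)))), df)
}

test_that("correlation map matches the rank-then-Pearson oracle on small cohorts", {
  set.seed(17)
  for (rep in 1:5) {
    X <- data.frame(a = rnorm(10), b = runif(10),
                    c = sample(5, 10, TRUE), # ties exercise average ranks
                    d = rnorm(10))
    cm <- correlation_map(make_table(X))
    for (i in 1:4) for (j in 1:4) {
      expect_equal(cm$rho[i, j], oracle_spearman(X[[i]], X[[j]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("correlation classes follow the fixed boundaries", {
  expect_identical(as.character(correlation_class(c(0, 0.19, 0.2, 0.45,
                                                    -0.7, 0.8, 1))),
                   c("very weak", "very weak", "weak", "moderate", "strong",
                     "very strong", "very strong"))
  # self-correlation is rho = 1, very strong; monotone copies too
  x <- rnorm(20)
  tab <- make_table(data.frame(x = x, y = exp(x), z = rnorm(20)))
  cm <- correlation_map(tab)
  expect_equal(cm$rho["x", "x"], 1)
  expect_equal(cm$rho["x", "y"], 1) # rank invariance under monotone maps
  expect_identical(cm$class["x", "y"], "very strong")
  expect_true(cm$significant["x", "y"])
})

test_that("constant columns and short overlaps are flagged not-available", {
  tab <- make_table(data.frame(a = 1:6, b = rep(2, 6),
                               c = c(1, 2, NA, NA, NA, NA)))
  cm <- correlation_map(tab)
  expect_identical(cm$constant, "b")
  expect_true(is.na(cm$rho["a", "b"]))
  expect_true(is.na(cm$rho["a", "c"])) # only 2 complete pairs
  expect_error(correlation_map(make_table(data.frame(a = 1:2))), "3 plans")
})

test_that("metric selection keeps significant metrics and prunes redundancy", {
  set.seed(23)
  n <- 40
  x <- rnorm(n)
  tab <- make_table(data.frame(
    strong = x, # correlates with endpoint
    copy = 2 * x + 0.01 * rnorm(n), # redundant, slightly weaker
    noise = rnorm(n)
  ))
  psqa <- data.frame(plan_id = tab$plan_id,
                     PR_3G2 = pmin(100, pmax(0, 90 + 5 * x + rnorm(n))))
  sel <- select_metrics(tab, psqa, endpoint = "PR_3G2")
  expect_identical(sel$metric[1], "strong")
  expect_false("copy" %in% sel$metric) # the smaller |rho| twin is removed
  expect_true("copy" %in% attr(sel, "dropped"))
  expect_false("noise" %in% sel$metric)
  # the kept set never contains a mutually redundant pair
  for (i in seq_len(nrow(sel))) for (j in seq_len(i - 1L)) {
    r <- abs(cor(rank(tab[[sel$metric[i]]]), rank(tab[[sel$metric[j]]])))
    expect_lt(r, 0.6)
  }
  # a single significant metric comes back unchanged
  sel1 <- select_metrics(make_table(data.frame(strong = x)), psqa, "PR_3G2")
  expect_identical(sel1$metric, "strong")
})

test_that("selection returns empty on null endpoints and validates inputs", {
  set.seed(29)
  tab <- make_table(data.frame(m1 = rnorm(30), m2 = rnorm(30)))
  psqa <- data.frame(plan_id = tab$plan_id, PR_2L2 = runif(30, 85, 100))
  sel <- select_metrics(tab, psqa, endpoint = "PR_2L2", alpha = 1e-6)
  expect_identical(nrow(sel), 0L)
  expect_error(select_metrics(tab, psqa, endpoint = "PR_3G2"), "endpoint")
  bad <- psqa
  bad$PR_2L2[1] <- 140
  expect_error(select_metrics(tab, bad, endpoint = "PR_2L2"), "\\[0, 100\\]")
})

test_that("per-metric false-keep rate under a null endpoint is near alpha", {
  set.seed(31)
  n <- 30
  tab <- make_table(as.data.frame(matrix(rnorm(n * 10), n,
                                         dimnames = list(NULL,
                                                         paste0("m", 1:10)))))
  keep_rate <- mean(replicate(200, {
    psqa <- data.frame(plan_id = tab$plan_id, PR = runif(n, 80, 100))
    nrow(select_metrics(tab, psqa, endpoint = "PR",
                        redundancy_threshold = 1.01)) / 10
  }))
  expect_gt(keep_rate, 0.02)
  expect_lt(keep_rate, 0.09)
})

test_that("efficiency split recovers the generator mixture and its histograms", {
  profs <- list(ht_profile(flot_shape = "flat_with_end_peak"),
                ht_profile(flot_shape = "bimodal"))
  plans <- generate_cohort(32, profs, weights = c(1, 1), master_seed = 21)
  labels <- attr(plans, "profile_index")
  mt <- extract_metrics(plans)
  sp <- efficiency_split(mt, plans)
  expect_identical(sum(sp$groups == "efficient", na.rm = TRUE), 8L)
  expect_identical(sum(sp$groups == "inefficient", na.rm = TRUE), 8L)
  # strict-quartile groups never exceed a quarter of the cohort (plus ties)
  expect_lte(sp$n[["efficient"]], ceiling(32 / 4))
  expect_lte(sp$n[["inefficient"]], ceiling(32 / 4))
  # the split recovers the generating family
  expect_true(all(labels[which(sp$groups == "efficient")] == 1L))
  expect_true(all(labels[which(sp$groups == "inefficient")] == 2L))
  # per-plan histograms were normalized before pooling
  for (h in sp$histograms) {
    expect_equal(sum(h$mean), 1, tolerance = 1e-12)
    expect_true(all(h$hi >= h$lo))
  }
  # the bimodal family carries more sub-0.75 FLOT mass by construction
  cmp <- sp$comparison
  cfns <- cmp[cmp$metric == "CFNS75", ]
  expect_lt(cfns$mean_efficient, cfns$mean_inefficient)
  expect_true(cfns$sig_01)
})

test_that("degenerate cohorts cannot be stratified", {
  plans <- rep(list(generate_plan(ht_profile(seed = 1))), 10)
  mt <- extract_metrics(plans)
  expect_error(efficiency_split(mt, plans), "degenerate")
  expect_error(efficiency_split(mt[1:5, ], plans[1:5]), "at least 8")
  expect_error(efficiency_split(data.frame(plan_id = letters[1:10],
                                           TA = 1:10)),
               "CFNS75")
})
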
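test_that("ELOTV hand cases: constant columns, alternating leaf, closed leaf", {
  # constant sinogram: every leaf keeps its opening -> 0 at any step
  const <- ht_sinogram(matrix(0.5, 50, 64), PT = 200)
  expect_equal(elotv(const, 1), 0)
  expect_equal(elotv(const, 5), 0)

  # one leaf alternating 0, m, 0, m, ... others closed: its term is 1
  N <- 10; L <- 8; m <- 0.6
  S <- matrix(0, N, L)
  S[seq(2, N, by = 2), 3] <- m
  sg <- ht_sinogram(S, PT = 100)
  expect_equal(elotv(sg, 1), 1 / L)

  # never-open leaves contribute 0, not NaN
  S2 <- matrix(0, 5, 4)
  S2[, 1] <- c(0.2, 0.8, 0.2, 0.8, 0.2)
  expect_true(is.finite(elotv(ht_sinogram(S2, PT = 100), 1)))
  expect_error(elotv(sg, 10), "delta_p")
  expect_error(elotv(sg, 0), "delta_p")
})

test_that("ELOTV stays in [0, 1] over random plans", {
  set.seed(123)
  for (rep in 1:200) {
    sg <- random_sinogram(N = sample(3:15, 1), L = 8,
                          density = runif(1, 0.1, 1),
                          with_ones = runif(1) < 0.3)
    dp <- sample.int(sg$N - 1L, 1L)
    v <- elotv(sg, dp)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("LOTV is the exact complement of ELOTV at step 1", {
  set.seed(9)
  for (rep in 1:50) {
    sg <- random_sinogram(N = sample(2:20, 1), density = runif(1, 0.05, 1))
    expect_equal(lotv(sg) + elotv(sg, 1), 1)
  }
})

test_that("EPSTV hand cases and directional decoupling", {
  m <- 0.8
  sg <- ht_sinogram(rbind(c(0, m), c(m, 0)), PT = 100)
  expect_equal(epstv(sg, 1, 1), 2 * m)

  # constant sinogram: zero for every step pair
  const <- ht_sinogram(matrix(0.3, 6, 6), PT = 100)
  for (steps in list(c(1, 1), c(1, 0), c(0, 1), c(2, 3))) {
    expect_equal(epstv(const, steps[1], steps[2]), 0)
  }

  # varies across leaves but constant along projections:
  # projection-only variation is 0, leaf-only is not
  S <- matrix(rep(seq(0.1, 0.6, length.out = 6), each = 5), 5, 6)
  sg2 <- ht_sinogram(S, PT = 100)
  expect_equal(epstv(sg2, 1, 0), 0)
  expect_gt(epstv(sg2, 0, 1), 0)
  expect_error(epstv(sg2, 0, 0), "degenerate")
})

test_that("PSTV equals EPSTV at unit steps", {
  set.seed(10)
  for (rep in 1:50) {
    sg <- random_sinogram(N = sample(2:20, 1), density = runif(1, 0.05, 1))
    expect_identical(pstv(sg), epstv(sg, 1, 1))
  }
})

test_that("nOC counts centered open/close events", {
  # one isolated partial cell: one open event + one close event
  S <- matrix(0, 5, 64)
  S[3, 10] <- 0.4
  sg <- ht_sinogram(S, PT = 200)
  expect_identical(noc_events(sg), 2L)
  expect_equal(noc(sg), 2 / (5 * 64))

  # partial caps around a fully-open run merge into a single pair
  S2 <- matrix(0, 4, 8)
  S2[, 2] <- c(0.3, 1, 1, 0.6)
  expect_identical(noc_events(ht_sinogram(S2, PT = 100)), 2L)

  # adjacent partials without a fully-open bridge stay separate pairs
  S3 <- matrix(0, 4, 8)
  S3[1:2, 5] <- c(0.3, 0.6)
  expect_identical(noc_events(ht_sinogram(S3, PT = 100)), 4L)

  # all-closed plan has no events
  expect_identical(noc_events(ht_sinogram(matrix(0, 3, 8), PT = 100)), 0L)
  expect_equal(noc(ht_sinogram(matrix(0, 3, 8), PT = 100)), 0)
})

test_that("CLS relates to nOC exactly without full openings, bounded with them", {
  set.seed(202)
  for (rep in 1:50) {
    sg <- random_sinogram(N = sample(2:15, 1), density = runif(1, 0.1, 1))
    if (!any(sg$S > 0)) next
    cls <- geometry_metrics(sg)[["CLS"]]
    expect_equal(cls, 1 - 0.5 * noc(sg)) # no S = 1 anywhere
  }
  for (rep in 1:25) {
    sg <- random_sinogram(N = sample(2:15, 1), density = runif(1, 0.3, 1),
                          with_ones = TRUE)
    cls <- geometry_metrics(sg)[["CLS"]]
    expect_lte(cls - 1e-12, 1 - 0.5 * noc(sg))
  }
})

test_that("LPS metrics match hand evaluation and symmetry", {
  # single always-open leaf at position +3
  L <- 8
  P <- leaf_positions(L) # -4 -3 -2 -1 1 2 3 4
  j <- which(P == 3)
  S <- matrix(0, 5, L)
  S[, j] <- 1
  lm <- lps_metrics(ht_sinogram(S, PT = 100))
  expect_equal(lm$MSA, 3)
  expect_equal(lm$LPS[j], 1)
  expect_equal(sum(lm$LPS), 1)

  # left-right symmetric sinogram: MSA 0
  S2 <- matrix(0, 4, L)
  S2[, c(3, 6)] <- 0.5 # positions -2 and +2
  expect_equal(lps_metrics(ht_sinogram(S2, PT = 100))$MSA, 0)

  # uniform all-open plan: mSI = c, sdSI = 0
  lm3 <- lps_metrics(ht_sinogram(matrix(0.37, 6, L), PT = 100))
  expect_equal(lm3$mSI, 0.37)
  expect_equal(lm3$sdSI, 0)
  expect_error(lps_metrics(ht_sinogram(matrix(0, 2, 4), PT = 100)),
               "undefined")
})

test_that("LPS definition matches direct column averaging", {
  set.seed(3)
  sg <- random_sinogram(N = 12, L = 16)
  expect_equal(lps_metrics(sg)$LPS, colSums(sg$S) / 12)
})

test_that("the modulation index is zero for constant plans and grows with variation", {
  const <- ht_sinogram(matrix(0.5, 20, 8), PT = 100)
  expect_equal(as.numeric(modulation_index(const)), 0)
  # perturbing a subset of leaves away from constancy cannot lower MI
  S <- matrix(0.5, 20, 8)
  S[seq(1, 19, by = 2), 1:2] <- 0.1
  perturbed <- ht_sinogram(S, PT = 100)
  expect_gt(as.numeric(modulation_index(perturbed)),
            as.numeric(modulation_index(const)))
  # plug-in definitions are honored and recorded
  alt <- modulation_index(const, method = function(S) 42)
  expect_equal(as.numeric(alt), 42)
  expect_identical(attr(alt, "definition"), "user")
})
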
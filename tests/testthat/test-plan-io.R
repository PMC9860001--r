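test_that("sinogram constructor enforces the [0, 1] invariant", {
  expect_error(ht_sinogram(matrix(c(0.5, 1.2), 1, 2), PT = 200),
               "S\\[1, 2\\]")
  expect_error(ht_sinogram(matrix(c(-0.1, 0.5), 1, 2), PT = 200),
               "outside \\[0, 1\\]")
  # tolerance boundary: tiny overshoot is clipped with a warning
  S <- matrix(0.5, 2, 4)
  S[1, 1] <- 1 + 1e-12
  expect_warning(sg <- ht_sinogram(S, PT = 200), "clipped")
  expect_identical(sg$S[1, 1], 1)
  expect_error(ht_sinogram(matrix(0.5, 1, 1), PT = 200), "L >= 2")
  expect_error(ht_sinogram(matrix(0.5, 2, 4), PT = 0), "positive")
})

test_that("native format round-trips generated plans exactly", {
  set.seed(11)
  for (rep in 1:10) {
    pl <- random_plan(N = sample(1:30, 1), L = sample(c(8, 16, 64), 1),
                      density = runif(1, 0.2, 0.9))
    f <- withr::local_tempfile(fileext = ".json")
    write_native_plan(pl, f)
    p2 <- read_native_plan(f)
    expect_identical(p2$sinogram$S, pl$sinogram$S)
    expect_identical(p2$sinogram$PT, pl$sinogram$PT)
    expect_identical(p2$plan_id, pl$plan_id)
  }
  # metadata survives too
  pl <- ht_plan(random_sinogram(), plan_id = "x", FW = 5.02, GP = 200 * 51 / 1000,
                TL = 12.3, CT = 8.1, dose_per_fraction = 2.25)
  f <- withr::local_tempfile()
  write_native_plan(pl, f)
  p2 <- read_native_plan(f)
  for (fld in c("FW", "GP", "TL", "CT", "dose_per_fraction")) {
    expect_identical(p2[[fld]], pl[[fld]])
  }
})

test_that("two writes of the same plan are byte-identical", {
  set.seed(3)
  pl <- random_plan(N = 1) # minimal single-projection plan is valid
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_native_plan(pl, f1)
  write_native_plan(pl, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("native reader rejects schema and integrity violations", {
  f <- withr::local_tempfile()
  writeLines('{"S": [1, 2]}', f)
  expect_error(read_native_plan(f), "header")
  writeLines(paste0('{"header": {"plan_id": "x", "PT_ms": 200,',
                    '"N": 1, "L": 2}, "S": [0.5, 1.2]}'), f)
  expect_error(read_native_plan(f), "integrity")
  writeLines(paste0('{"header": {"plan_id": "x", "PT_ms": 200,',
                    '"N": 2, "L": 2}, "S": [0.5, 0.5]}'), f)
  expect_error(read_native_plan(f), "expected N\\*L")
  writeLines("not json at all {", f)
  expect_error(read_native_plan(f), "format error")
})

test_that("small-leaf-count plans flow through the full extraction", {
  set.seed(21)
  pl <- random_plan(N = 12, L = 32, density = 0.7)
  f <- withr::local_tempfile()
  write_native_plan(pl, f)
  p2 <- read_native_plan(f)
  expect_identical(p2$sinogram$L, 32L)
  mt <- extract_metrics(p2)
  expect_identical(dim(mt), c(1L, 66L))
  # geometry consistently uses L = 32
  g <- geometry_metrics(p2)
  expect_true(g["TA"] <= 32)
})

test_that("DICOM adapters round-trip both dialects with a fixed leaf order", {
  set.seed(5)
  S <- matrix(0, 4, 64)
  S[, 20:40] <- round(runif(4 * 21, 0.05, 0.95), 6)
  for (dialect in c("precision", "raystation")) {
    f <- withr::local_tempfile(fileext = ".dcm")
    write_dicom_fixture(f, S, PT = 300, dialect = dialect)
    pl <- read_dicom_rtplan(f)
    expect_identical(pl$tps_dialect, dialect)
    expect_equal(pl$sinogram$S, S, tolerance = 1e-9)
    expect_identical(pl$sinogram$N, 4L)
    expect_identical(pl$sinogram$L, 64L)
    expect_equal(pl$sinogram$PT, 300)
    expect_equal(pl$FW, 2.5)
    expect_equal(pl$CT, 10)
    # column j maps to the same physical leaf in every dialect
    expect_identical(which(colSums(pl$sinogram$S) > 0), 20:40)
  }
})

test_that("uniform DICOM fixture reproduces the constant sinogram", {
  S <- matrix(0.5, 3, 64)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(f, S, PT = 200)
  pl <- read_dicom_rtplan(f)
  expect_identical(pl$sinogram$N, 3L)
  expect_identical(pl$sinogram$L, 64L)
  expect_true(all(pl$sinogram$S == 0.5))
})

test_that("DICOM reader classifies malformed inputs", {
  f <- withr::local_tempfile()
  writeBin(as.raw(rep(0, 256)), f)
  expect_error(read_dicom_rtplan(f), "not a DICOM")
  expect_error(read_dicom_rtplan(tempfile()), "not found")
  # a DICOM that is not an RT-Plan
  g <- withr::local_tempfile()
  bytes <- c(as.raw(rep(0, 128)), charToRaw("DICM"),
             dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
             dcm_element(0x0008, 0x0060, "CS", "CT"))
  writeBin(bytes, g)
  expect_error(read_dicom_rtplan(g), "Modality")
})

test_that("missing prescription loads but makes TTDF unavailable", {
  S <- matrix(0.4, 3, 64)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(f, S, include_prescription = FALSE)
  pl <- read_dicom_rtplan(f)
  expect_true(is.na(pl$dose_per_fraction))
  d <- compute_delivery(pl)
  expect_true(is.na(d[["TTDF"]]))
  expect_false(anyNA(d[c("MF", "TT", "Nproj")]))
})

test_that("format auto-detection routes native vs DICOM", {
  set.seed(9)
  pl <- random_plan()
  f <- withr::local_tempfile()
  write_native_plan(pl, f)
  expect_identical(read_plan(f)$sinogram$S, pl$sinogram$S)
  g <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(g, matrix(0.5, 2, 64))
  expect_identical(read_plan(g)$tps_dialect, "precision")
})
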
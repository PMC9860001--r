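# Native plan exchange format: one JSON document per plan with a header
# object and the row-major sinogram. Numbers are written as decimal text at
# 17 significant digits so a write/read cycle is bit-exact on doubles.

NATIVE_FORMAT_VERSION <- "1"

fmt_num <- function(x) {
  ifelse(is.na(x), "null", vapply(x, function(v) {
    s <- sprintf("%.17g", v)
    # shortest representation that still round-trips
    for (d in 1:16) {
      cand <- sprintf("%.*g", d, v)
      if (as.numeric(cand) == v) return(cand)
    }
    s
  }, character(1)))
}

#' Write a plan in the native JSON exchange format
#'
#' The format is a single JSON object: a `header` (plan id, projection time
#' in ms, delivery metadata, leaf count) plus the sinogram matrix `S` in
#' row-major order. Matrix values are serialized as decimal text that
#' round-trips doubles exactly, so `read_native_plan(write_native_plan(p))`
#' reproduces `p` bit for bit, and two writes of the same plan are
#' byte-identical.
#'
#' @param plan an [ht_plan].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_native_plan <- function(plan, path) {
  plan <- as_plan(plan)
  sg <- plan$sinogram
  header <- sprintf(paste0(
    '{"format":"htcomplexity-native","version":"%s",',
    '"plan_id":%s,"PT_ms":%s,"FW_cm":%s,"GP_s":%s,"TL_cm":%s,"CT_cm":%s,',
    '"dose_per_fraction_Gy":%s,"projections_per_rotation":%s,',
    '"N":%d,"L":%d}'),
    NATIVE_FORMAT_VERSION,
    jsonlite::toJSON(jsonlite::unbox(plan$plan_id)),
    fmt_num(sg$PT), fmt_num(plan$FW), fmt_num(plan$GP), fmt_num(plan$TL),
    fmt_num(plan$CT), fmt_num(plan$dose_per_fraction),
    fmt_num(plan$projections_per_rotation), sg$N, sg$L)
  s_txt <- fmt_num(as.vector(t(sg$S))) # row-major
  body <- paste0('{"header":', header, ',"S":[',
                 paste(s_txt, collapse = ","), "]}")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(body), con)
  invisible(path)
}

#' Read a plan from the native JSON exchange format
#'
#' @param path path to a file produced by [write_native_plan()] (or any
#'   conforming document).
#' @return An [ht_plan]. Schema violations raise a format error naming the
#'   missing or malformed field; sinogram values outside `[0, 1]` raise the
#'   usual integrity error.
#' @export
read_native_plan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("native plan format error: invalid JSON (",
                         conditionMessage(e), ")", call. = FALSE)
                  })
  h <- doc$header
  if (is.null(h)) stop("native plan format error: missing 'header'",
                       call. = FALSE)
  need <- function(field) {
    v <- h[[field]]
    if (is.null(v)) {
      stop("native plan format error: missing header field '", field, "'",
           call. = FALSE)
    }
    v
  }
  opt <- function(field) {
    v <- h[[field]]
    if (is.null(v) || length(v) != 1L || is.na(v)) NA_real_ else as.numeric(v)
  }
  N <- as.integer(need("N"))
  L <- as.integer(need("L"))
  S_flat <- doc$S
  if (is.null(S_flat)) stop("native plan format error: missing 'S'",
                            call. = FALSE)
  if (length(S_flat) != N * L) {
    stop(sprintf("native plan format error: 'S' has %d values, expected N*L = %d",
                 length(S_flat), N * L), call. = FALSE)
  }
  S <- matrix(as.numeric(S_flat), nrow = N, ncol = L, byrow = TRUE)
  ht_plan(
    sinogram = ht_sinogram(S, PT = as.numeric(need("PT_ms"))),
    plan_id = as.character(need("plan_id")),
    tps_dialect = "native",
    FW = opt("FW_cm"),
    GP = opt("GP_s"),
    TL = opt("TL_cm"),
    CT = opt("CT_cm"),
    dose_per_fraction = opt("dose_per_fraction_Gy"),
    projections_per_rotation = opt("projections_per_rotation")
  )
}

#' Read a plan in any supported format
#'
#' Dispatches on content: files starting with a DICOM preamble or tag go to
#' [read_dicom_rtplan()], JSON documents to [read_native_plan()].
#'
#' @param path input file.
#' @param format `"auto"`, `"dicom"` or `"native"`.
#' @param dialect forwarded to [read_dicom_rtplan()].
#' @return An [ht_plan].
#' @export
read_plan <- function(path, format = c("auto", "dicom", "native"),
                      dialect = "auto") {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readBin(path, "raw", n = 1L)
    format <- if (length(first) && first == charToRaw("{")) "native" else "dicom"
  }
  switch(format,
         native = read_native_plan(path),
         dicom = read_dicom_rtplan(path, dialect = dialect))
}
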
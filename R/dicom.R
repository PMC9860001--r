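# Minimal DICOM reader for RT-Plan files.
#
# Supports the two transfer syntaxes HT planning systems export (explicit and
# implicit VR little endian), including nested sequences with defined or
# undefined lengths. Only the element types the RT-Plan adapters need are
# decoded; everything else is kept as raw bytes and ignored. No installed R
# package parses DICOM, hence this reader.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"

# VRs that use the 4-byte length form (2-byte reserved field) in explicit VR.
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

uint16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

uint32 <- function(bytes, at) {
  as.numeric(bytes[at]) + 256 * as.numeric(bytes[at + 1L]) +
    65536 * as.numeric(bytes[at + 2L]) + 16777216 * as.numeric(bytes[at + 3L])
}

tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

# Parse a run of data elements in bytes[start:end]; returns a named list
# keyed "GGGG,EEEE" -> list(vr, bytes) or, for SQ, list(vr="SQ", items=...).
parse_dicom_elements <- function(bytes, start, end, explicit) {
  out <- list()
  pos <- start
  while (pos + 7 <= end + 1 && pos + 3 <= end) {
    group <- uint16(bytes, pos)
    element <- uint16(bytes, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFE) { # item delimiters never appear at this level
      len <- uint32(bytes, pos)
      pos <- pos + 4L
      if (element == 0xE00D || element == 0xE0DD) break
      pos <- pos + len
      next
    }
    vr <- NULL
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      pos <- pos + 2L
      if (vr %in% LONG_VRS) {
        pos <- pos + 2L # reserved
        len <- uint32(bytes, pos)
        pos <- pos + 4L
      } else {
        len <- uint16(bytes, pos)
        pos <- pos + 2L
      }
    } else {
      len <- uint32(bytes, pos)
      pos <- pos + 4L
      vr <- if (len == 0xFFFFFFFF) "SQ" else "UN"
    }
    key <- tag_key(group, element)
    if (identical(vr, "SQ") || len == 0xFFFFFFFF) {
      parsed <- parse_dicom_sequence(bytes, pos, len, end, explicit)
      out[[key]] <- list(vr = "SQ", items = parsed$items)
      pos <- parsed$pos
    } else {
      val <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
      out[[key]] <- list(vr = vr, bytes = val)
      pos <- pos + len
    }
  }
  out
}

# Parse SQ content starting at pos; len may be a defined byte length or
# 0xFFFFFFFF (undefined, terminated by a sequence delimitation item).
parse_dicom_sequence <- function(bytes, pos, len, end, explicit) {
  items <- list()
  seq_end <- if (len != 0xFFFFFFFF) pos + len - 1 else end
  while (pos + 7 <= seq_end + 1) {
    group <- uint16(bytes, pos)
    element <- uint16(bytes, pos + 2L)
    item_len <- uint32(bytes, pos + 4L)
    pos <- pos + 8L
    if (group != 0xFFFE) stop("malformed DICOM sequence", call. = FALSE)
    if (element == 0xE0DD) break # sequence delimiter
    if (element != 0xE000) stop("malformed DICOM sequence item", call. = FALSE)
    if (item_len != 0xFFFFFFFF) {
      items[[length(items) + 1L]] <-
        parse_dicom_elements(bytes, pos, pos + item_len - 1, explicit)
      pos <- pos + item_len
    } else {
      # undefined-length item: scan to its delimiter at this nesting level
      item_end <- find_item_delimiter(bytes, pos, seq_end)
      items[[length(items) + 1L]] <-
        parse_dicom_elements(bytes, pos, item_end - 1, explicit)
      pos <- item_end + 8L
    }
    if (len != 0xFFFFFFFF && pos > seq_end) break
  }
  list(items = items, pos = pos)
}

find_item_delimiter <- function(bytes, pos, end) {
  depth <- 0L
  while (pos + 7 <= end + 1) {
    group <- uint16(bytes, pos)
    element <- uint16(bytes, pos + 2L)
    len <- uint32(bytes, pos + 4L)
    if (group == 0xFFFE && element == 0xE00D && depth == 0L) return(pos)
    if (group == 0xFFFE && element == 0xE000 && len == 0xFFFFFFFF) {
      depth <- depth + 1L
    }
    if (group == 0xFFFE && element == 0xE00D) depth <- depth - 1L
    pos <- pos + 8L + if (group == 0xFFFE || len == 0xFFFFFFFF) 0 else len
  }
  stop("unterminated DICOM item", call. = FALSE)
}

dicom_string <- function(el) {
  if (is.null(el)) return(NA_character_)
  trimws(rawToChar(el$bytes))
}

dicom_numbers <- function(el) {
  if (is.null(el)) return(numeric(0))
  s <- trimws(strsplit(rawToChar(el$bytes), "\\\\")[[1]])
  as.numeric(s[nzchar(s)])
}

#' @keywords internal
read_dicom_file <- function(path) {
  bytes <- readBin(path, what = "raw", n = file.size(path))
  if (length(bytes) < 140) stop("not a DICOM file: too short", call. = FALSE)
  explicit <- TRUE
  start <- 1L
  if (length(bytes) > 132 && rawToChar(bytes[129:132]) == "DICM") {
    # file meta (group 0002) is always explicit VR little endian
    meta_end <- 133L
    meta <- list()
    pos <- 133L
    repeat {
      if (pos + 7 > length(bytes)) break
      if (uint16(bytes, pos) != 0x0002) break
      el_start <- pos
      parsed <- parse_dicom_elements(bytes, pos, pos + 11, TRUE)
      # re-parse one element at a time to find its extent
      group <- uint16(bytes, pos); element <- uint16(bytes, pos + 2L)
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- uint32(bytes, pos + 8L); hdr <- 12L
      } else {
        len <- uint16(bytes, pos + 6L); hdr <- 8L
      }
      val <- if (len > 0) bytes[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
      meta[[tag_key(group, element)]] <- list(vr = vr, bytes = val)
      pos <- pos + hdr + len
    }
    start <- pos
    ts <- dicom_string(meta[["0002,0010"]])
    if (!is.na(ts)) {
      if (ts == DICOM_IMPLICIT_LE) explicit <- FALSE
      else if (ts != DICOM_EXPLICIT_LE) {
        stop(sprintf("unsupported DICOM transfer syntax '%s'", ts),
             call. = FALSE)
      }
    }
  } else {
    # headerless stream: sniff explicit VR from the first element
    vr <- rawToChar(bytes[5:6])
    explicit <- grepl("^[A-Z]{2}$", vr)
    g0 <- uint16(bytes, 1L)
    if (!g0 %in% c(0x0002, 0x0008, 0x0010, 0x300A)) {
      stop("not a DICOM file (no DICM magic, implausible first tag)",
           call. = FALSE)
    }
  }
  parse_dicom_elements(bytes, start, length(bytes), explicit)
}

# --- RT-Plan adapters --------------------------------------------------------

# Per-dialect sinogram row decoding. Conventions (chosen for this package and
# validated by round-trip checks on generated files; vendors do not document
# them publicly):
#   precision:  MLCX LeafJawPositions holds L fractional open times directly.
#   raystation: MLCX LeafJawPositions holds 2L bank positions; the fractional
#               open time of leaf j is positions[L + j] - positions[j].
decode_mlcx_row <- function(values, dialect) {
  if (dialect == "raystation") {
    if (length(values) %% 2L != 0L) {
      stop("raystation MLCX element does not hold 2L bank positions",
           call. = FALSE)
    }
    L <- length(values) %/% 2L
    values[(L + 1L):(2L * L)] - values[1:L]
  } else {
    values
  }
}

detect_dialect <- function(ds) {
  man <- tolower(dicom_string(ds[["0008,0070"]]))
  if (!is.na(man) && grepl("raysearch", man)) return("raystation")
  if (!is.na(man) && grepl("accuray", man)) return("precision")
  "precision"
}

#' Read a helical tomotherapy DICOM RT-Plan
#'
#' Parses an RT-Plan file, locates the delivery sinogram in the beam
#' control-point sequence, and returns a normalized [ht_plan]. Two TPS
#' dialects are supported: Precision stores the fractional open times
#' directly in the MLCX leaf/jaw positions of each control point, while
#' RayStation stores two leaf banks whose per-leaf difference is the open
#' time. Leaf column `j` maps to the same physical leaf in both dialects.
#'
#' Delivery metadata are taken from standard tags where they exist (field
#' width from the ASYMY jaws, couch translation from the table-top
#' longitudinal positions, prescription from the dose-reference and fraction
#' -group sequences). The projection time, which has no standard tag, is
#' read from a documented private block (group 300D, creator
#' "HTCOMPLEXITY"); absent metadata are flagged `NA`, never defaulted.
#'
#' @param path path to the DICOM file.
#' @param dialect `"auto"` (default; decided from the Manufacturer tag),
#'   `"precision"` or `"raystation"`.
#' @return An [ht_plan].
#' @export
read_dicom_rtplan <- function(path,
                              dialect = c("auto", "precision", "raystation")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ds <- read_dicom_file(path)
  modality <- dicom_string(ds[["0008,0060"]])
  if (is.na(modality) || modality != "RTPLAN") {
    stop("not an RT-Plan DICOM file (Modality != RTPLAN)", call. = FALSE)
  }
  if (dialect == "auto") dialect <- detect_dialect(ds)

  beams <- ds[["300A,00B0"]]
  if (is.null(beams) || !length(beams$items)) {
    stop("unsupported plan: no BeamSequence present", call. = FALSE)
  }
  beam <- beams$items[[1L]]
  cps <- beam[["300A,0111"]]
  if (is.null(cps) || !length(cps$items)) {
    stop("unsupported plan: no control points in beam", call. = FALSE)
  }

  rows <- list()
  FW <- NA_real_
  couch_long <- numeric(0)
  for (cp in cps$items) {
    bldps <- cp[["300A,011A"]]
    if (!is.null(bldps)) {
      for (dev in bldps$items) {
        type <- dicom_string(dev[["300A,00B8"]])
        vals <- dicom_numbers(dev[["300A,011C"]])
        if (identical(type, "MLCX")) {
          rows[[length(rows) + 1L]] <- decode_mlcx_row(vals, dialect)
        } else if (identical(type, "ASYMY") && length(vals) == 2L &&
                   is.na(FW)) {
          FW <- (vals[2L] - vals[1L]) / 10 # mm -> cm
        }
      }
    }
    tl <- dicom_numbers(cp[["300A,0129"]])
    if (length(tl) == 1L) couch_long <- c(couch_long, tl)
  }
  if (!length(rows)) {
    stop("unsupported plan: no tomotherapy sinogram (MLCX positions) found",
         call. = FALSE)
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop("inconsistent leaf counts across projections", call. = FALSE)
  }
  S <- do.call(rbind, rows)

  CT <- if (length(couch_long) >= 2L) {
    abs(couch_long[length(couch_long)] - couch_long[1L]) / 10
  } else NA_real_

  # prescription: per-fraction dose = target dose / planned fractions
  dpf <- NA_real_
  drs <- ds[["300A,0010"]]
  fgs <- ds[["300A,0070"]]
  if (!is.null(drs) && length(drs$items) && !is.null(fgs) &&
      length(fgs$items)) {
    target <- dicom_numbers(drs$items[[1L]][["300A,0026"]])
    nfx <- dicom_numbers(fgs$items[[1L]][["300A,0078"]])
    if (length(target) == 1L && length(nfx) == 1L && nfx > 0) {
      dpf <- target / nfx
    }
  }

  # private block: projection time and friends
  creator <- dicom_string(ds[["300D,0010"]])
  priv <- function(elem) {
    if (is.na(creator) || creator != "HTCOMPLEXITY") return(NA_real_)
    v <- dicom_numbers(ds[[tag_key(0x300D, elem)]])
    if (length(v) == 1L) v else NA_real_
  }
  PT <- priv(0x1001)
  GP <- priv(0x1002)
  TL <- priv(0x1003)
  ppr <- priv(0x1004)
  if (is.na(ppr)) ppr <- 51L
  if (is.na(PT)) {
    if (!is.na(GP)) {
      PT <- GP * 1000 / ppr
    } else {
      stop(paste0(
        "projection time missing: no private HTCOMPLEXITY block and no ",
        "gantry period to derive it from"), call. = FALSE)
    }
  }

  plan_id <- dicom_string(ds[["300A,0002"]])
  if (is.na(plan_id)) plan_id <- basename(path)

  ht_plan(
    sinogram = ht_sinogram(S, PT = PT),
    plan_id = plan_id,
    tps_dialect = dialect,
    FW = FW,
    GP = GP,
    TL = TL,
    CT = CT,
    dose_per_fraction = dpf,
    projections_per_rotation = ppr
  )
}
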
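# Synthetic DICOM RT-Plan fixture writer (explicit VR little endian).
# Builds files in the layout the package's per-dialect adapters expect, so
# reader behavior is validated by round-trip/shape checks on generated
# files. Test-only: the package itself never writes DICOM.

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

pad_even <- function(bytes, pad = charToRaw(" ")) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

dcm_element <- function(group, element, vr, value) {
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  val <- if (is.character(value)) {
    pad_even(charToRaw(value),
             pad = if (vr == "UI") as.raw(0) else charToRaw(" "))
  } else if (is.raw(value)) value else stop("unsupported value")
  hdr <- c(u16le(group), u16le(element), charToRaw(vr))
  if (vr %in% long_vrs) {
    c(hdr, as.raw(c(0, 0)), u32le(length(val)), val)
  } else {
    c(hdr, u16le(length(val)), val)
  }
}

dcm_ds <- function(group, element, values) {
  dcm_element(group, element, "DS",
              paste(sprintf("%.10g", values), collapse = "\\"))
}

dcm_item <- function(content) c(u16le(0xFFFE), u16le(0xE000),
                                u32le(length(content)), content)

dcm_sq <- function(group, element, items) {
  content <- do.call(c, lapply(items, dcm_item))
  dcm_element(group, element, "SQ", content)
}

# Write an RT-Plan carrying the sinogram S (N x L FLOTs) in the given
# dialect. Returns the path.
write_dicom_fixture <- function(path, S, PT = 200, dialect = "precision",
                                FW_cm = 2.5, couch_travel_cm = 10,
                                plan_id = "fixture",
                                target_dose = 60, n_fractions = 30,
                                include_private = TRUE,
                                include_prescription = TRUE) {
  N <- nrow(S)
  L <- ncol(S)
  manufacturer <- if (dialect == "raystation") "RaySearch Laboratories"
                  else "Accuray"
  couch_mm <- seq(0, couch_travel_cm * 10, length.out = max(N, 2L))

  cps <- lapply(seq_len(N), function(i) {
    row <- S[i, ]
    mlcx <- if (dialect == "raystation") {
      bank_a <- seq(-5, 5, length.out = L) # bank offsets; difference = FLOT
      c(bank_a, bank_a + row)
    } else row
    c(
      dcm_sq(0x300A, 0x011A, list(
        c(dcm_element(0x300A, 0x00B8, "CS", "ASYMY"),
          dcm_ds(0x300A, 0x011C, c(-FW_cm * 10 / 2, FW_cm * 10 / 2))),
        c(dcm_element(0x300A, 0x00B8, "CS", "MLCX"),
          dcm_ds(0x300A, 0x011C, mlcx))
      )),
      dcm_ds(0x300A, 0x0129, couch_mm[i])
    )
  })

  body <- c(
    dcm_element(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_element(0x0008, 0x0070, "LO", manufacturer),
    dcm_element(0x300A, 0x0002, "SH", plan_id),
    if (include_prescription) c(
      dcm_sq(0x300A, 0x0010, list(dcm_ds(0x300A, 0x0026, target_dose))),
      dcm_sq(0x300A, 0x0070, list(
        dcm_element(0x300A, 0x0078, "IS", as.character(n_fractions))))
    ),
    dcm_sq(0x300A, 0x00B0, list(dcm_sq(0x300A, 0x0111, cps))),
    if (include_private) c(
      dcm_element(0x300D, 0x0010, "LO", "HTCOMPLEXITY"),
      dcm_ds(0x300D, 0x1001, PT),
      dcm_ds(0x300D, 0x1002, PT * 51 / 1000),
      dcm_ds(0x300D, 0x1003, 10),
      dcm_element(0x300D, 0x1004, "IS", "51")
    )
  )

  meta <- dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  bytes <- c(as.raw(rep(0, 128)), charToRaw("DICM"), meta, body)
  writeBin(bytes, path)
  path
}
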
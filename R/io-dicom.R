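# Minimal DICOM I/O for single-frame uncompressed CT slices.
#
# Scope: little-endian transfer syntaxes (explicit 1.2.840.10008.1.2.1 and
# implicit 1.2.840.10008.1.2), 16-bit monochrome pixel data. Encapsulated
# (compressed) syntaxes are rejected. This is deliberately narrow: enough to
# carry HU rasters, pixel spacing and CTDIvol.

dcm_u16 <- function(raw, i) {
  as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
}
dcm_u32 <- function(raw, i) {
  as.numeric(raw[i]) + 256 * as.numeric(raw[i + 1L]) +
    65536 * as.numeric(raw[i + 2L]) + 16777216 * as.numeric(raw[i + 3L])
}

dcm_tag_key <- function(group, elem) sprintf("%04X%04X", group, elem)

# parse one data element header; returns NULL at end of stream
dcm_read_elem <- function(raw, pos, explicit) {
  if (pos + 7L > length(raw)) return(NULL)
  group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2L)
  vr <- NA_character_
  if (explicit && group != 0xFFFEL) {
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN")) {
      len <- dcm_u32(raw, pos + 8L); hdr <- 12L
    } else {
      len <- dcm_u16(raw, pos + 6L); hdr <- 8L
    }
  } else {
    len <- dcm_u32(raw, pos + 4L); hdr <- 8L
  }
  list(group = group, elem = elem, vr = vr, len = len,
       data_pos = pos + hdr)
}

# skip an undefined-length sequence by scanning for its delimitation item
dcm_skip_undefined <- function(raw, pos) {
  pat <- as.raw(c(0xFE, 0xFF, 0xDD, 0xE0))
  n <- length(raw)
  i <- pos
  while (i + 7L <= n) {
    if (raw[i] == pat[1] && raw[i + 1L] == pat[2] &&
        raw[i + 2L] == pat[3] && raw[i + 3L] == pat[4]) {
      return(i + 8L)
    }
    i <- i + 2L
  }
  stop("unterminated undefined-length sequence in DICOM stream")
}

dcm_string <- function(val) {
  s <- rawToChar(val[val != as.raw(0)])
  trimws(s)
}
dcm_ds <- function(val) {
  as.numeric(strsplit(dcm_string(val), "\\\\")[[1]])
}

#' Read a single-frame CT DICOM slice
#'
#' Supports uncompressed little-endian transfer syntaxes with 16-bit pixel
#' data. Hounsfield units are reconstructed as
#' `stored * RescaleSlope + RescaleIntercept`; pixel spacing comes from
#' PixelSpacing, and CTDIvol from tag (0018,9345) when present. A missing
#' CTDIvol produces a warning and an `NA` dose slot (it can be supplied via
#' `ctdi_vol`, which takes precedence over the tag).
#'
#' @param path Path to the DICOM file.
#' @param ctdi_vol Optional CTDIvol override in mGy.
#' @return A [ct_slice()].
#' @export
load_dicom_slice <- function(path, ctdi_vol = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140) stop("not a DICOM file (too short): ", path)
  pos <- if (rawToChar(raw[129:132]) == "DICM") 133L else 1L

  wanted <- c("00080060", "00100020", "00080018", "00189345", "00280010",
              "00280011", "00280030", "00280100", "00280103", "00281052",
              "00281053", "7FE00010")
  vals <- list()
  explicit <- TRUE
  ts <- NULL
  repeat {
    if (pos + 7L > length(raw)) break
    grp <- dcm_u16(raw, pos)
    # the file-meta group (0002) is always explicit VR
    el <- dcm_read_elem(raw, pos, explicit = explicit || grp == 2L)
    if (is.null(el)) break
    key <- dcm_tag_key(el$group, el$elem)
    if (el$len == 4294967295) {              # undefined length
      pos <- dcm_skip_undefined(raw, el$data_pos)
      next
    }
    end <- el$data_pos + el$len - 1L
    if (end > length(raw)) stop("truncated DICOM element ", key)
    if (key == "00020010") {
      ts <- dcm_string(raw[el$data_pos:end])
      if (ts == "1.2.840.10008.1.2") {
        explicit <- FALSE
      } else if (ts != "1.2.840.10008.1.2.1") {
        stop("unsupported transfer syntax: ", ts)
      }
    } else if (key %in% wanted && el$len > 0) {
      vals[[key]] <- raw[el$data_pos:end]
    }
    pos <- el$data_pos + el$len
  }

  modality <- if (!is.null(vals[["00080060"]])) dcm_string(vals[["00080060"]]) else "CT"
  if (modality != "CT") stop("not a CT slice (Modality = ", modality, ")")
  if (is.null(vals[["00280030"]])) stop("DICOM file lacks PixelSpacing")
  spacing <- dcm_ds(vals[["00280030"]])
  rows <- dcm_u16(vals[["00280010"]], 1L)
  cols <- dcm_u16(vals[["00280011"]], 1L)
  bits <- if (!is.null(vals[["00280100"]])) dcm_u16(vals[["00280100"]], 1L) else 16L
  if (bits != 16L) stop("only 16-bit pixel data is supported")
  signed <- !is.null(vals[["00280103"]]) && dcm_u16(vals[["00280103"]], 1L) == 1L
  slope <- if (!is.null(vals[["00281053"]])) dcm_ds(vals[["00281053"]])[1] else 1
  intercept <- if (!is.null(vals[["00281052"]])) dcm_ds(vals[["00281052"]])[1] else 0
  px <- vals[["7FE00010"]]
  if (is.null(px)) stop("DICOM file lacks PixelData")
  stored <- readBin(px, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  hu <- matrix(stored * slope + intercept, nrow = rows, ncol = cols,
               byrow = TRUE)

  tag_ctdi <- if (!is.null(vals[["00189345"]])) {
    readBin(vals[["00189345"]], "double", 1L, size = 8L, endian = "little")
  } else NA_real_
  dose <- if (!is.null(ctdi_vol)) ctdi_vol else tag_ctdi
  if (!is.finite(dose)) {
    warning("DICOM file carries no CTDIvol (0018,9345); SSDE will not be computed")
  }
  id <- if (!is.null(vals[["00100020"]])) dcm_string(vals[["00100020"]]) else
    basename(path)
  ct_slice(hu, spacing, dose, id)
}

dcm_pad <- function(val, pad = as.raw(0x20)) {
  if (length(val) %% 2L == 1L) c(val, pad) else val
}

dcm_enc_elem <- function(group, elem, vr, val) {
  head <- writeBin(c(as.integer(group), as.integer(elem)), raw(),
                   size = 2L, endian = "little")
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
    len <- writeBin(as.integer(length(val)), raw(), size = 4L,
                    endian = "little")
    hdr <- c(head, charToRaw(vr), as.raw(c(0, 0)), len)
  } else {
    len <- writeBin(as.integer(length(val)), raw(), size = 2L,
                    endian = "little")
    hdr <- c(head, charToRaw(vr), len)
  }
  c(hdr, val)
}

#' Write a slice as a single-frame CT DICOM file
#'
#' Explicit-VR little-endian writer used for fixtures and round-trip tests.
#' HU values are rounded and stored as signed 16-bit integers with rescale
#' slope 1 and intercept 0.
#'
#' @param slice A [ct_slice()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dicom_slice <- function(slice, path) {
  hu <- round(slice$hu_pixels)
  if (any(hu < -32768 | hu > 32767)) stop("HU out of 16-bit range")
  rows <- nrow(hu); cols <- ncol(hu)
  px <- writeBin(as.integer(t(hu)), raw(), size = 2L, endian = "little")
  str_val <- function(s, pad = as.raw(0x20)) dcm_pad(charToRaw(s), pad)
  us_val <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                 endian = "little")
  sop_class <- "1.2.840.10008.5.1.4.1.1.2"
  sop_inst <- paste0("1.2.826.0.1.3680043.8.498.",
                     sum(utf8ToInt(paste0("x", slice$id))) %% 99999L + 1L)

  meta <- c(
    dcm_enc_elem(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_enc_elem(0x0002, 0x0002, "UI", str_val(sop_class, as.raw(0))),
    dcm_enc_elem(0x0002, 0x0003, "UI", str_val(sop_inst, as.raw(0))),
    dcm_enc_elem(0x0002, 0x0010, "UI", str_val("1.2.840.10008.1.2.1", as.raw(0))),
    dcm_enc_elem(0x0002, 0x0012, "UI",
                 str_val("1.2.826.0.1.3680043.8.498.1", as.raw(0)))
  )
  body <- c(
    dcm_enc_elem(0x0008, 0x0016, "UI", str_val(sop_class, as.raw(0))),
    dcm_enc_elem(0x0008, 0x0018, "UI", str_val(sop_inst, as.raw(0))),
    dcm_enc_elem(0x0008, 0x0060, "CS", str_val("CT")),
    dcm_enc_elem(0x0010, 0x0020, "LO",
                 str_val(if (is.na(slice$id)) "anon" else slice$id)),
    if (is.finite(slice$ctdi_vol)) {
      dcm_enc_elem(0x0018, 0x9345, "FD",
                   writeBin(as.numeric(slice$ctdi_vol), raw(), size = 8L,
                            endian = "little"))
    },
    dcm_enc_elem(0x0028, 0x0002, "US", us_val(1L)),
    dcm_enc_elem(0x0028, 0x0004, "CS", str_val("MONOCHROME2")),
    dcm_enc_elem(0x0028, 0x0010, "US", us_val(rows)),
    dcm_enc_elem(0x0028, 0x0011, "US", us_val(cols)),
    dcm_enc_elem(0x0028, 0x0030, "DS",
                 str_val(sprintf("%.8g\\%.8g", slice$pixel_spacing[1],
                                 slice$pixel_spacing[2]))),
    dcm_enc_elem(0x0028, 0x0100, "US", us_val(16L)),
    dcm_enc_elem(0x0028, 0x0101, "US", us_val(16L)),
    dcm_enc_elem(0x0028, 0x0102, "US", us_val(15L)),
    dcm_enc_elem(0x0028, 0x0103, "US", us_val(1L)),
    dcm_enc_elem(0x0028, 0x1052, "DS", str_val("0")),
    dcm_enc_elem(0x0028, 0x1053, "DS", str_val("1")),
    dcm_enc_elem(0x7FE0, 0x0010, "OW", px)
  )
  group_len <- dcm_enc_elem(0x0002, 0x0000, "UL",
                            writeBin(as.integer(length(meta)), raw(),
                                     size = 4L, endian = "little"))
  out <- c(raw(128L), charToRaw("DICM"), group_len, meta, body)
  writeBin(out, path)
  invisible(path)
}
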
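#' CT slice container
#'
#' The pipeline's input unit: a Hounsfield-unit raster with its pixel
#' spacing, the scanner-reported CTDIvol when available, and an identifier.
#'
#' @param hu_pixels Numeric matrix of Hounsfield units.
#' @param pixel_spacing Pixel spacing in mm, `c(row, col)` or scalar.
#' @param ctdi_vol CTDIvol in mGy, or `NA` when not reported.
#' @param id Opaque slice/patient identifier.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(hu_pixels, pixel_spacing, ctdi_vol = NA_real_,
                     id = NA_character_) {
  if (!is.matrix(hu_pixels) || !is.numeric(hu_pixels)) {
    stop("hu_pixels must be a numeric matrix")
  }
  pixel_spacing <- check_spacing(pixel_spacing)
  if (min(hu_pixels) < -1024) {
    message("HU values below -1024 found (floor of the usual CT scale)")
  }
  structure(list(hu_pixels = hu_pixels, pixel_spacing = pixel_spacing,
                 ctdi_vol = as.numeric(ctdi_vol), id = as.character(id)),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("ct_slice [%s]: %d x %d px, spacing %.3g x %.3g mm, CTDIvol %s\n",
              x$id, nrow(x$hu_pixels), ncol(x$hu_pixels),
              x$pixel_spacing[1], x$pixel_spacing[2],
              if (is.finite(x$ctdi_vol)) sprintf("%.2f mGy", x$ctdi_vol)
              else "n/a"))
  invisible(x)
}

#' Write a slice in the portable fixture dialect
#'
#' Two plain-text files: `<stem>.csv` (the HU raster, comma-separated, no
#' header) and `<stem>.json` (pixel spacing in mm, CTDIvol in mGy,
#' identifier, plus any extra metadata).
#'
#' @param slice A [ct_slice()].
#' @param stem Path stem (without extension).
#' @param extra Optional named list merged into the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_fixture <- function(slice, stem, extra = NULL) {
  utils::write.table(slice$hu_pixels, paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(
    format = "ssdect-fixture-v1",
    id = slice$id,
    pixel_spacing_mm = slice$pixel_spacing,
    ctdi_vol_mgy = if (is.finite(slice$ctdi_vol)) slice$ctdi_vol else NULL,
    hu_csv = basename(paste0(stem, ".csv"))
  )
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(stem, ".json"))
}

#' Load a slice from the fixture dialect
#'
#' @param stem Path stem, or the path of either of the two fixture files.
#' @return A [ct_slice()]; identical downstream contract as
#'   [load_dicom_slice()].
#' @export
load_fixture <- function(stem) {
  stem <- sub("\\.(csv|json)$", "", stem)
  sidecar <- paste0(stem, ".json")
  if (!file.exists(sidecar)) stop("fixture sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(c("pixel_spacing_mm", "hu_csv"), names(meta))
  if (length(missing) > 0) {
    stop("fixture sidecar is missing required keys: ",
         paste(missing, collapse = ", "))
  }
  hu <- as.matrix(utils::read.table(file.path(dirname(sidecar), meta$hu_csv),
                                    sep = ",", header = FALSE))
  dimnames(hu) <- NULL
  ctdi <- if (is.null(meta$ctdi_vol_mgy)) NA_real_ else meta$ctdi_vol_mgy
  if (!is.finite(ctdi)) {
    warning("fixture carries no CTDIvol; SSDE will not be computed")
  }
  ct_slice(hu, meta$pixel_spacing_mm, ctdi,
           if (is.null(meta$id)) basename(stem) else meta$id)
}

report_columns <- c("id", "d_w", "d_eff_corr", "f_dw", "f_deff",
                    "ctdi_vol", "ssde_dw", "ssde_deff")

#' Turn dose results into a report table
#'
#' @param results A list of [dose_result()] objects (possibly empty).
#' @return A data.frame with one row per slice and a stable column order.
#' @export
report_table <- function(results) {
  if (length(results) == 0) {
    df <- as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), 7)), report_columns))
    return(df)
  }
  do.call(rbind, lapply(results, function(r) {
    data.frame(id = r$id, d_w = r$d_w, d_eff_corr = r$d_eff_corr,
               f_dw = r$f_dw, f_deff = r$f_deff, ctdi_vol = r$ctdi_vol,
               ssde_dw = r$ssde_dw, ssde_deff = r$ssde_deff,
               stringsAsFactors = FALSE)
  }))
}

#' Write a per-slice dose report
#'
#' CSV reports round numeric values to one decimal (the precision used in
#' clinical dose tables); JSON reports keep full precision. Missing SSDE
#' values (no CTDIvol) are written as empty cells / nulls.
#'
#' @param results A list of [dose_result()] objects, or a data.frame from
#'   [report_table()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- if (is.data.frame(results)) results else report_table(results)
  if (format == "csv") {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = 1)
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path Report path (CSV or JSON, inferred from the extension).
#' @return A data.frame with the report columns.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path)) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(report_columns, names(df))
  if (length(missing) > 0) {
    stop("report is missing columns: ", paste(missing, collapse = ", "))
  }
  df
}
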
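default_header_attrs <- c(
  "SOPInstanceUID", "StudyInstanceUID", "SeriesInstanceUID", "SeriesNumber",
  "InstanceNumber", "SeriesDescription", "Modality", "Rows", "Columns",
  "PixelSpacing", "RepetitionTime", "EchoTime", "InversionTime",
  "TriggerTime", "FlipAngle")

#' Tabulate DICOM headers across images and series
#'
#' Lists the headers of many instances side by side, one row per file, so
#' pulse-sequence parameters (TI, TE, TR, flip angle, matrix) can be compared
#' directly across images or series. Rows are grouped by series UID and
#' ordered by instance number within a series.
#'
#' @param paths DICOM file paths.
#' @param attributes keywords to tabulate; defaults to a standard selection.
#'   Unknown keywords yield an all-`NA` column with a warning.
#' @return a tibble with one row per instance, first column `file`.
#' @export
dump_headers <- function(paths, attributes = default_header_attrs) {
  if (length(paths) == 0) stop("no input files given", call. = FALSE)
  unknown <- setdiff(attributes, .dict$keyword)
  if (length(unknown)) {
    warning("unknown DICOM attribute(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  rows <- lapply(paths, function(p) {
    e <- dicom_read(p)$elements
    vals <- lapply(attributes, function(a) {
      v <- e[[a]]
      if (is.null(v) || length(v) == 0) NA else paste(v, collapse = "\\")
    })
    names(vals) <- attributes
    tibble::as_tibble(c(list(file = p), vals))
  })
  tbl <- do.call(rbind, rows)
  if ("SeriesInstanceUID" %in% names(tbl)) {
    inst <- if ("InstanceNumber" %in% names(tbl)) {
      suppressWarnings(as.numeric(tbl$InstanceNumber))
    } else {
      seq_len(nrow(tbl))
    }
    tbl <- tbl[order(match(tbl$SeriesInstanceUID,
                           unique(tbl$SeriesInstanceUID)), inst), ]
  }
  tbl
}

#' Write a header table to CSV
#'
#' @param table tibble from [dump_headers()].
#' @param path output CSV path.
#' @export
write_header_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a relaxation map as a DICOM image
#'
#' Writes the map as a derived MR image readable by conventional MR analysis
#' software: 16-bit unsigned pixels encoding milliseconds directly
#' (1 LSB = 1 ms, rescale slope 1, intercept 0, nearest-integer rounding).
#' Spatial and study tags are copied from the template source instance; the
#' exported image gets fresh series/instance UIDs and a series description
#' naming the technique. Relaxation-time limits above 65535 ms cannot be
#' stored losslessly and are rejected.
#'
#' @param map a `relaxation_map` from [compute_map()].
#' @param template a [source_image_set()] (its first instance supplies the
#'   template header) or a path to a source DICOM file.
#' @param out_path output file path.
#' @return `out_path`, invisibly.
#' @export
export_map_dicom <- function(map, template, out_path) {
  if (map$config$limit_ms > 65535) {
    stop("relaxation-time limit exceeds 65535 ms; cannot encode 1 ms per ",
         "16-bit unit", call. = FALSE)
  }
  v <- map$values
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("map contains non-finite or negative values", call. = FALSE)
  }
  if (inherits(template, "source_image_set")) {
    tpl <- list(
      StudyInstanceUID = template$identifiers$study_uid[[1]],
      PixelSpacing = template$geometry$pixel_spacing,
      ImagePositionPatient = template$geometry$image_position,
      ImageOrientationPatient = template$geometry$image_orientation)
  } else {
    e <- dicom_read(template)$elements
    tpl <- e[intersect(c("StudyInstanceUID", "PatientName", "PatientID",
                         "StudyDate", "PixelSpacing", "ImagePositionPatient",
                         "ImageOrientationPatient"), names(e))]
  }
  tpl$SOPInstanceUID <- new_uid()
  tpl$SeriesInstanceUID <- new_uid()
  if (is.null(tpl$StudyInstanceUID)) tpl$StudyInstanceUID <- new_uid()
  tpl$SeriesDescription <- paste0("Relaxation map [ms]: ", map$technique)
  tpl$InstanceNumber <- 1L
  tpl$SeriesNumber <- 999L
  dicom_write(out_path, tpl, round(v))
  invisible(out_path)
}

#' Read an exported relaxation map back from DICOM
#'
#' @param path DICOM file written by [export_map_dicom()].
#' @return numeric matrix of milliseconds.
#' @export
read_map_dicom <- function(path) {
  dicom_read(path)$pixel
}

#' Export a relaxation map as a graphics file for illustration
#'
#' Scales `0..limit` ms to the grayscale range and writes PNG (8-bit, or
#' colormapped RGB) or TIFF (16-bit gray). Graphics exports quantize the map
#' and are for illustration only; quantitative post-processing should use
#' [export_map_dicom()].
#'
#' @param map a `relaxation_map`.
#' @param out_path output path; format chosen by extension (`.png`/`.tif`,
#'   `.tiff`).
#' @param colormap optional vector of colors (e.g. `hcl.colors(256)`) for a
#'   colormapped PNG; ignored for TIFF.
#' @return `out_path`, invisibly.
#' @export
export_map_graphic <- function(map, out_path, colormap = NULL) {
  scaled <- pmin(pmax(map$values / map$config$limit_ms, 0), 1)
  ext <- tolower(tools::file_ext(out_path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, out_path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (is.null(colormap)) {
      png::writePNG(scaled, out_path)
    } else {
      idx <- pmin(floor(scaled * length(colormap)) + 1, length(colormap))
      rgb <- grDevices::col2rgb(colormap[idx]) / 255
      img <- array(0, dim = c(nrow(scaled), ncol(scaled), 3))
      img[, , 1] <- matrix(rgb[1, ], nrow(scaled))
      img[, , 2] <- matrix(rgb[2, ], nrow(scaled))
      img[, , 3] <- matrix(rgb[3, ], nrow(scaled))
      png::writePNG(img, out_path)
    }
  } else {
    stop("unsupported graphics format: .", ext, call. = FALSE)
  }
  invisible(out_path)
}
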
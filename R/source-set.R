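#' Source image set
#'
#' Ordered stack of co-registered 2D magnitude images with per-image timing
#' (inversion time or echo time, in ms) and shared geometry. Built either
#' from DICOM files with [read_series()] or in memory by the phantom
#' simulator.
#'
#' @param images list of numeric matrices, identical dimensions.
#' @param times_ms numeric vector, one TI or TE per image (ms).
#' @param time_kind `"TI"` or `"TE"` - which tag the times came from.
#' @param layout `"one_series_multi_image"` (Look-Locker, MOLLI, multi-echo)
#'   or `"multi_series_one_image"` (classic IR, single-echo).
#' @param geometry list with `pixel_spacing`, `image_position`,
#'   `image_orientation` copied from the source headers.
#' @param identifiers data frame with one row per image: `study_uid`,
#'   `series_uid`, `sop_uid`, `instance_number`, `file`.
#' @return an object of class `source_image_set`.
#' @export
source_image_set <- function(images, times_ms,
                             time_kind = c("TI", "TE"),
                             layout = c("one_series_multi_image",
                                        "multi_series_one_image"),
                             geometry = default_geometry(),
                             identifiers = NULL) {
  time_kind <- match.arg(time_kind)
  layout <- match.arg(layout)
  stopifnot(is.list(images), length(images) >= 1,
            length(images) == length(times_ms))
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all images must share the same matrix size (common field-of-view)",
         call. = FALSE)
  }
  if (is.null(identifiers)) {
    series <- if (layout == "one_series_multi_image") {
      rep(new_uid(), length(images))
    } else {
      replicate(length(images), new_uid())
    }
    identifiers <- data.frame(
      study_uid = rep(new_uid(), length(images)),
      series_uid = series,
      sop_uid = replicate(length(images), new_uid()),
      instance_number = seq_along(images),
      file = NA_character_,
      stringsAsFactors = FALSE)
  }
  structure(list(images = images, times_ms = as.numeric(times_ms),
                 time_kind = time_kind, layout = layout,
                 geometry = geometry, identifiers = identifiers),
            class = "source_image_set")
}

default_geometry <- function(pixel_spacing = c(1.5, 1.5)) {
  list(pixel_spacing = pixel_spacing,
       image_position = c(0, 0, 0),
       image_orientation = c(1, 0, 0, 0, 1, 0))
}

#' @export
print.source_image_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<source_image_set> %d images, %dx%d, %s, layout %s\n",
              length(x$images), d[1], d[2], x$time_kind, x$layout))
  cat(sprintf("  %s [ms]: %s\n", x$time_kind,
              paste(format(x$times_ms, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' @export
dim.source_image_set <- function(x) {
  c(dim(x$images[[1]]), length(x$images))
}

# stack the images into rows x cols x n for fast per-pixel extraction
as_array <- function(set) {
  d <- dim(set)
  array(unlist(set$images, use.names = FALSE), dim = d)
}

#' Read a DICOM source series into a source image set
#'
#' Decodes each file, checks for a common field-of-view, and extracts per-image
#' timing: inversion time (0018,0082) when present on every image, falling
#' back to trigger time (0018,1060) with a warning (vendor MOLLI exports store
#' the effective TI there), otherwise echo time (0018,0081). The series layout
#' (one series with many images vs many single-image series) is inferred from
#' the SeriesInstanceUID values.
#'
#' @param paths character vector of DICOM file paths.
#' @return a [source_image_set()].
#' @export
read_series <- function(paths) {
  if (length(paths) == 0) stop("no input files given", call. = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("cannot read file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  objs <- lapply(paths, dicom_read)
  els <- lapply(objs, `[[`, "elements")

  dims <- vapply(objs, function(o) dim(o$pixel), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("images do not share a common field-of-view (matrix sizes differ)",
         call. = FALSE)
  }

  pull <- function(key) vapply(els, function(e) {
    v <- e[[key]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[[1]])
  }, numeric(1))
  ti <- pull("InversionTime")
  trig <- pull("TriggerTime")
  te <- pull("EchoTime")

  if (all(is.finite(ti))) {
    times <- ti; kind <- "TI"
  } else if (all(is.finite(trig))) {
    warning("no InversionTime tag; using TriggerTime as effective TI",
            call. = FALSE)
    times <- trig; kind <- "TI"
  } else if (all(is.finite(te))) {
    times <- te; kind <- "TE"
  } else {
    stop("appropriate timing information (InversionTime/EchoTime) missing ",
         "from one or more DICOM headers", call. = FALSE)
  }

  pull_chr <- function(key) vapply(els, function(e) {
    v <- e[[key]]
    if (is.null(v)) NA_character_ else as.character(v[[1]])
  }, character(1))
  series_uid <- pull_chr("SeriesInstanceUID")
  layout <- if (length(unique(series_uid)) == 1 && length(paths) > 1) {
    "one_series_multi_image"
  } else {
    "multi_series_one_image"
  }

  inst <- pull("InstanceNumber")
  e1 <- els[[1]]
  geometry <- list(
    pixel_spacing = if (is.null(e1$PixelSpacing)) c(1, 1) else e1$PixelSpacing,
    image_position = if (is.null(e1$ImagePositionPatient)) c(0, 0, 0) else e1$ImagePositionPatient,
    image_orientation = if (is.null(e1$ImageOrientationPatient)) c(1, 0, 0, 0, 1, 0) else e1$ImageOrientationPatient)

  source_image_set(
    images = lapply(objs, `[[`, "pixel"),
    times_ms = times, time_kind = kind, layout = layout,
    geometry = geometry,
    identifiers = data.frame(
      study_uid = pull_chr("StudyInstanceUID"),
      series_uid = series_uid,
      sop_uid = pull_chr("SOPInstanceUID"),
      instance_number = ifelse(is.finite(inst), inst, seq_along(paths)),
      file = paths, stringsAsFactors = FALSE))
}

technique_info <- function(technique) {
  tab <- list(
    T1_IR      = list(kind = "TI", min_n = 3, layout = "multi_series_one_image"),
    T1_LL      = list(kind = "TI", min_n = 3, layout = "one_series_multi_image"),
    T1_MOLLI   = list(kind = "TI", min_n = 3, layout = "one_series_multi_image"),
    T2_SE      = list(kind = "TE", min_n = 2, layout = "multi_series_one_image"),
    T2_ME      = list(kind = "TE", min_n = 2, layout = "one_series_multi_image"),
    T2STAR_SE  = list(kind = "TE", min_n = 2, layout = "multi_series_one_image"),
    T2STAR_ME  = list(kind = "TE", min_n = 2, layout = "one_series_multi_image"))
  info <- tab[[technique]]
  if (is.null(info)) {
    stop("unknown technique: ", technique, "; expected one of ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  info
}

#' Validate a source image set for a mapping technique
#'
#' Checks the number of source images (three-parameter techniques need at
#' least three, two-parameter at least two; T2* with offset needs three),
#' the common field-of-view, presence and distinctness of timing values, and
#' that the series layout matches the technique.
#'
#' @param set a [source_image_set()].
#' @param technique one of `T1_IR`, `T1_LL`, `T1_MOLLI`, `T2_SE`, `T2_ME`,
#'   `T2STAR_SE`, `T2STAR_ME`.
#' @param use_offset for T2* techniques, whether the three-parameter offset
#'   model will be fitted.
#' @return character vector of violations; empty means the set is valid.
#' @export
validate_source_set <- function(set, technique, use_offset = TRUE) {
  info <- technique_info(technique)
  v <- character(0)
  min_n <- info$min_n
  if (startsWith(technique, "T2STAR") && use_offset) min_n <- 3
  if (length(set$images) < min_n) {
    v <- c(v, sprintf(
      "wrong number of source images: %d given, technique %s needs at least %d",
      length(set$images), technique, min_n))
  }
  if (set$time_kind != info$kind) {
    v <- c(v, sprintf("timing information mismatch: set carries %s but %s needs %s",
                      set$time_kind, technique, info$kind))
  }
  if (anyNA(set$times_ms) || any(!is.finite(set$times_ms))) {
    v <- c(v, "missing or non-finite timing values")
  } else if (anyDuplicated(set$times_ms)) {
    v <- c(v, sprintf("duplicate %s values", set$time_kind))
  }
  if (set$layout != info$layout) {
    v <- c(v, sprintf("series layout %s does not match technique %s (expected %s)",
                      set$layout, technique, info$layout))
  }
  v
}

#' Sort a source image set by inversion/echo time
#'
#' Mapping requires the stack ordered by ascending TI (inversion recovery
#' family) or TE (decay family); the sort is stable and reorders images,
#' times and identifiers together. Duplicate times are rejected.
#'
#' @param set a [source_image_set()].
#' @return the sorted set.
#' @export
sort_by_time <- function(set) {
  if (anyDuplicated(set$times_ms)) {
    stop(sprintf("duplicate %s values; cannot sort", set$time_kind),
         call. = FALSE)
  }
  o <- order(set$times_ms)
  set$images <- set$images[o]
  set$times_ms <- set$times_ms[o]
  set$identifiers <- set$identifiers[o, , drop = FALSE]
  rownames(set$identifiers) <- NULL
  set
}
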
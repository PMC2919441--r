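# Minimal DICOM Part-10 codec for uncompressed single-frame MR magnitude
# images: explicit VR little endian on write; explicit and implicit VR little
# endian on read. Scope is deliberately narrow -- the tags quantitative
# mapping needs (timing, geometry, UIDs, rescale, 16-bit monochrome pixel
# data) -- not a general DICOM toolkit.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_MR_STORAGE  <- "1.2.840.10008.5.1.4.1.1.4"
UID_IMPL_CLASS  <- "2.25.305186665782951164430853810537142722607"

# tag dictionary: keyword -> group, element, VR
dicom_dict <- function() {
  d <- rbind(
    c("ImageType",                 "0008", "0008", "CS"),
    c("SOPClassUID",               "0008", "0016", "UI"),
    c("SOPInstanceUID",            "0008", "0018", "UI"),
    c("StudyDate",                 "0008", "0020", "DA"),
    c("Modality",                  "0008", "0060", "CS"),
    c("SeriesDescription",         "0008", "103e", "LO"),
    c("PatientName",               "0010", "0010", "PN"),
    c("PatientID",                 "0010", "0020", "LO"),
    c("RepetitionTime",            "0018", "0080", "DS"),
    c("EchoTime",                  "0018", "0081", "DS"),
    c("InversionTime",             "0018", "0082", "DS"),
    c("TriggerTime",               "0018", "1060", "DS"),
    c("FlipAngle",                 "0018", "1314", "DS"),
    c("StudyInstanceUID",          "0020", "000d", "UI"),
    c("SeriesInstanceUID",         "0020", "000e", "UI"),
    c("SeriesNumber",              "0020", "0011", "IS"),
    c("InstanceNumber",            "0020", "0013", "IS"),
    c("ImagePositionPatient",      "0020", "0032", "DS"),
    c("ImageOrientationPatient",   "0020", "0037", "DS"),
    c("SamplesPerPixel",           "0028", "0002", "US"),
    c("PhotometricInterpretation", "0028", "0004", "CS"),
    c("Rows",                      "0028", "0010", "US"),
    c("Columns",                   "0028", "0011", "US"),
    c("PixelSpacing",              "0028", "0030", "DS"),
    c("BitsAllocated",             "0028", "0100", "US"),
    c("BitsStored",                "0028", "0101", "US"),
    c("HighBit",                   "0028", "0102", "US"),
    c("PixelRepresentation",       "0028", "0103", "US"),
    c("RescaleIntercept",          "0028", "1052", "DS"),
    c("RescaleSlope",              "0028", "1053", "DS"),
    c("PixelData",                 "7fe0", "0010", "OW"))
  data.frame(keyword = d[, 1], group = strtoi(d[, 2], 16L),
             element = strtoi(d[, 3], 16L), vr = d[, 4],
             stringsAsFactors = FALSE)
}
.dict <- dicom_dict()

long_form_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

u16_bytes <- function(x) {
  x <- as.integer(round(x))
  as.raw(c(rbind(x %% 256L, x %/% 256L)))
}
u32_bytes <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
str_bytes <- function(s, pad = as.raw(0x20)) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, pad)
  b
}
ds_string <- function(v) paste(vapply(v, function(x)
  formatC(x, digits = 10, format = "g", width = 0), character(1)),
  collapse = "\\")

encode_value <- function(vr, value) {
  switch(vr,
         US = u16_bytes(value),
         UL = u32_bytes(value),
         OW = u16_bytes(value),
         DS = str_bytes(ds_string(value)),
         IS = str_bytes(paste(as.integer(value), collapse = "\\")),
         UI = str_bytes(as.character(value), pad = as.raw(0x00)),
         OB = as.raw(value),
         str_bytes(as.character(value)))  # CS, LO, SH, PN, DA, ...
}

encode_element <- function(group, element, vr, value) {
  body <- encode_value(vr, value)
  hdr <- c(u16_bytes(group), u16_bytes(element), charToRaw(vr))
  if (vr %in% long_form_vrs) {
    c(hdr, as.raw(c(0, 0)), u32_bytes(length(body)), body)
  } else {
    if (length(body) > 65535) stop("value too long for short-form VR")
    c(hdr, u16_bytes(length(body)), body)
  }
}

# elements: named list keyword -> value (dictionary supplies tag + VR).
# Written in ascending tag order as the standard requires.
dicom_write <- function(path, elements, pixel) {
  stopifnot(is.matrix(pixel))
  if (any(pixel < 0) || any(pixel > 65535)) {
    stop("pixel values must fit unsigned 16-bit storage", call. = FALSE)
  }
  defaults <- list(
    ImageType = "DERIVED\\PRIMARY", Modality = "MR",
    SOPClassUID = UID_MR_STORAGE,
    SamplesPerPixel = 1L, PhotometricInterpretation = "MONOCHROME2",
    Rows = nrow(pixel), Columns = ncol(pixel),
    BitsAllocated = 16L, BitsStored = 16L, HighBit = 15L,
    PixelRepresentation = 0L, RescaleIntercept = 0, RescaleSlope = 1)
  for (k in names(defaults)) {
    if (is.null(elements[[k]])) elements[[k]] <- defaults[[k]]
  }
  elements$Rows <- nrow(pixel)
  elements$Columns <- ncol(pixel)

  idx <- match(names(elements), .dict$keyword)
  if (anyNA(idx)) {
    stop("unknown DICOM keyword(s): ",
         paste(names(elements)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ord <- order(.dict$group[idx], .dict$element[idx])
  body <- raw(0)
  for (i in ord) {
    k <- idx[i]
    body <- c(body, encode_element(.dict$group[k], .dict$element[k],
                                   .dict$vr[k], elements[[i]]))
  }
  # pixel data row-major, matching matrix [row, col] layout
  body <- c(body, encode_element(0x7fe0, 0x0010, "OW",
                                 as.vector(t(round(pixel)))))

  meta <- c(
    encode_element(0x0002, 0x0001, "OB", c(0L, 1L)),
    encode_element(0x0002, 0x0002, "UI", elements$SOPClassUID),
    encode_element(0x0002, 0x0003, "UI", elements$SOPInstanceUID),
    encode_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    encode_element(0x0002, 0x0012, "UI", UID_IMPL_CLASS))
  meta <- c(encode_element(0x0002, 0x0000, "UL", length(meta)), meta)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

r_u16 <- function(b, pos) {
  as.integer(b[pos]) + 256L * as.integer(b[pos + 1])
}
r_u32 <- function(b, pos) {
  as.numeric(b[pos]) + 256 * as.numeric(b[pos + 1]) +
    65536 * as.numeric(b[pos + 2]) + 16777216 * as.numeric(b[pos + 3])
}

decode_value <- function(vr, bytes) {
  if (length(bytes) == 0) return(NULL)
  txt <- function() {
    s <- rawToChar(bytes[bytes != as.raw(0x00)])
    trimws(s)
  }
  switch(vr,
         US = {
           n <- length(bytes) / 2
           vapply(seq_len(n), function(i) r_u16(bytes, 2 * i - 1), integer(1))
         },
         UL = r_u32(bytes, 1),
         OW = {
           n <- length(bytes) / 2
           vapply(seq_len(n), function(i) r_u16(bytes, 2 * i - 1), integer(1))
         },
         DS = as.numeric(strsplit(txt(), "\\", fixed = TRUE)[[1]]),
         IS = as.integer(strsplit(txt(), "\\", fixed = TRUE)[[1]]),
         txt())
}

lookup_vr <- function(group, element) {
  hit <- .dict$vr[.dict$group == group & .dict$element == element]
  if (length(hit)) hit[[1]] else "UN"
}

# Returns list(elements = keyword -> value, pixel = matrix of rescaled
# intensities, stored = integer matrix as stored, path).
dicom_read <- function(path) {
  b <- readBin(path, "raw", n = file.info(path)$size)
  if (length(b) < 140 || rawToChar(b[129:132]) != "DICM") {
    stop(sprintf("not a DICOM part-10 file: %s", path), call. = FALSE)
  }
  pos <- 133
  transfer <- UID_EXPLICIT_LE
  elements <- list()
  pixel_raw <- NULL
  explicit <- TRUE

  read_element <- function() {
    group <- r_u16(b, pos); element <- r_u16(b, pos + 2)
    if (explicit || group == 0x0002) {
      vr <- rawToChar(b[(pos + 4):(pos + 5)])
      if (vr %in% long_form_vrs) {
        len <- r_u32(b, pos + 8); start <- pos + 12
      } else {
        len <- r_u16(b, pos + 6); start <- pos + 8
      }
    } else {
      vr <- lookup_vr(group, element)
      len <- r_u32(b, pos + 4); start <- pos + 8
    }
    bytes <- if (len > 0) b[start:(start + len - 1)] else raw(0)
    pos <<- start + len
    list(group = group, element = element, vr = vr, bytes = bytes)
  }

  while (pos + 7 <= length(b)) {
    el <- read_element()
    if (el$group == 0x0002) {
      if (el$element == 0x0010) transfer <- decode_value("UI", el$bytes)
      next
    }
    if (!transfer %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE)) {
      stop(sprintf("unsupported transfer syntax %s in %s", transfer, path),
           call. = FALSE)
    }
    explicit <- transfer == UID_EXPLICIT_LE
    if (el$group == 0x7fe0 && el$element == 0x0010) {
      pixel_raw <- el$bytes
      break
    }
    key <- .dict$keyword[.dict$group == el$group & .dict$element == el$element]
    if (length(key)) elements[[key[[1]]]] <- decode_value(el$vr, el$bytes)
  }

  if (is.null(pixel_raw)) stop(sprintf("no pixel data in %s", path), call. = FALSE)
  rows <- elements$Rows; cols <- elements$Columns
  if (is.null(rows) || is.null(cols)) {
    stop(sprintf("missing Rows/Columns in %s", path), call. = FALSE)
  }
  stored <- matrix(decode_value("OW", pixel_raw), nrow = rows, ncol = cols,
                   byrow = TRUE)
  slope <- if (is.null(elements$RescaleSlope)) 1 else elements$RescaleSlope
  inter <- if (is.null(elements$RescaleIntercept)) 0 else elements$RescaleIntercept
  list(elements = elements, pixel = stored * slope + inter,
       stored = stored, path = path)
}

# DICOM UID under the 2.25 (UUID-derived) root, drawn from the current RNG so
# seeded simulations are reproducible bit-for-bit.
new_uid <- function() {
  paste0("2.25.", paste(c(sample(1:9, 1), sample(0:9, 30, replace = TRUE)),
                        collapse = ""))
}
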
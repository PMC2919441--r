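#' Synthetic multi-compartment gel phantom specification
#'
#' Describes a digital analogue of the gadolinium-doped agarose gel phantoms
#' used to validate relaxation-time mapping: non-overlapping compartments
#' (disks or rectangles) with known per-compartment T1, T2 and
#' proton-density signal scale, surrounded by air (zero signal), imaged as a
#' 128x128 stack of 8 magnitude images with Rician noise.
#'
#' For inversion-recovery simulation each compartment pixel follows
#' \eqn{|A - B\exp(-TI/T1^*)|} with `A = proton density` and
#' `B = inversion_quality * A`. Classic IR uses `T1* = T1`; Look-Locker and
#' MOLLI emulation deflects the apparent time constant phenomenologically,
#' `T1* = t1star_factor * T1`, which forces
#' `inversion_quality = 1/t1star_factor + 1` so that the Look-Locker
#' correction recovers the true T1 exactly (closed-loop consistency); an
#' explicit inconsistent `inversion_quality` is rejected. Decay sets follow
#' \eqn{A\exp(-TE/T2)}; T2* sets add the constant baseline `offset_c` to
#' compartment pixels.
#'
#' @param matrix_size image dimensions, default `c(128, 128)`.
#' @param compartments data frame with columns `shape` (`"disk"` or
#'   `"rect"`), `row`, `col` (center, pixels), `size1` (disk radius or rect
#'   height), `size2` (rect width; ignored for disks), `t1_ms`, `t2_ms`,
#'   `pd` (proton-density intensity scale). Default: the four-compartment
#'   preset of [gel_phantom_compartments()].
#' @param inversion_quality B/A ratio for classic IR simulation (2 = perfect
#'   inversion); `NULL` (default) picks the technique-consistent value.
#' @param t1star_factor apparent-to-true T1 ratio emulating Look-Locker
#'   readout deflection (< 1).
#' @param offset_c constant baseline added to compartment pixels in T2*
#'   simulations (intensity units).
#' @param noise_sigma Rician noise scale, the per-channel standard deviation
#'   of the complex Gaussian noise. The default 20 is 2% of the default
#'   proton density (SNR 50).
#' @param seed RNG seed for reproducible noise and UIDs; `NULL` leaves the
#'   RNG state alone.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = c(128, 128),
                         compartments = gel_phantom_compartments(),
                         inversion_quality = NULL,
                         t1star_factor = 0.8,
                         offset_c = 40,
                         noise_sigma = 20,
                         seed = NULL) {
  stopifnot(length(matrix_size) == 2, all(matrix_size >= 8),
            noise_sigma >= 0, t1star_factor > 0, t1star_factor < 1)
  need <- c("shape", "row", "col", "size1", "size2", "t1_ms", "t2_ms", "pd")
  if (!all(need %in% names(compartments))) {
    stop("compartments must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  spec <- structure(list(matrix_size = as.integer(matrix_size),
                         compartments = as.data.frame(compartments),
                         inversion_quality = inversion_quality,
                         t1star_factor = t1star_factor,
                         offset_c = offset_c, noise_sigma = noise_sigma,
                         seed = seed),
                    class = "phantom_spec")
  truth_maps(spec)  # errors on overlap / out-of-bounds
  spec
}

#' Four-compartment gel phantom preset
#'
#' Four disks of radius 20 centered in the image quadrants with uniform
#' proton density 1000, T1 225/275/325/550 ms and T2 40/60/80/100 ms --
#' the short-T1 range of gadolinium-doped agarose gels. A synthetic layout,
#' not a reproduction of any scanned phantom. The T1 values are chosen so
#' that no compartment's inversion-recovery null crossing (in either the
#' classic-IR or the Look-Locker/MOLLI emulation) falls within several noise
#' standard deviations of a sampled inversion time of the default 100-1400 ms
#' protocol: a magnitude sample near the null is dominated by the Rician
#' noise floor, which makes any ROI-averaged comparison ill-conditioned
#' regardless of the mapping software.
#'
#' @return compartment data frame for [phantom_spec()].
#' @export
gel_phantom_compartments <- function() {
  data.frame(shape = "disk",
             row = c(32, 32, 96, 96), col = c(32, 96, 32, 96),
             size1 = 20, size2 = NA_real_,
             t1_ms = c(225, 275, 325, 550),
             t2_ms = c(40, 60, 80, 100),
             pd = 1000)
}

compartment_mask <- function(spec, i, shrink = 0) {
  d <- spec$matrix_size
  co <- spec$compartments[i, ]
  if (co$shape == "disk") {
    r2 <- (co$size1 - shrink)^2
    outer(seq_len(d[1]), seq_len(d[2]),
          function(r, c) (r - co$row)^2 + (c - co$col)^2 <= r2)
  } else if (co$shape == "rect") {
    h <- co$size1 / 2 - shrink; w <- co$size2 / 2 - shrink
    outer(seq_len(d[1]), seq_len(d[2]),
          function(r, c) abs(r - co$row) <= h & abs(c - co$col) <= w)
  } else {
    stop("unknown compartment shape: ", co$shape, call. = FALSE)
  }
}

#' Region-of-interest mask for one phantom compartment
#'
#' The compartment footprint optionally eroded by `shrink` pixels, the usual
#' ROI practice of staying clear of compartment borders.
#'
#' @param spec a [phantom_spec()].
#' @param compartment compartment index.
#' @param shrink erosion in pixels.
#' @return logical matrix.
#' @export
phantom_roi <- function(spec, compartment, shrink = 3) {
  compartment_mask(spec, compartment, shrink = shrink)
}

#' Ground-truth parameter maps of a phantom
#'
#' @param spec a [phantom_spec()].
#' @return list of matrices `t1`, `t2`, `pd` (air = 0) and `compartment`
#'   (integer labels, 0 = air).
#' @export
truth_maps <- function(spec) {
  d <- spec$matrix_size
  t1 <- t2 <- pd <- matrix(0, d[1], d[2])
  label <- matrix(0L, d[1], d[2])
  for (i in seq_len(nrow(spec$compartments))) {
    m <- compartment_mask(spec, i)
    if (any(label[m] != 0L)) {
      stop("overlapping compartments in phantom specification", call. = FALSE)
    }
    if (!any(m)) stop("compartment ", i, " lies outside the image", call. = FALSE)
    label[m] <- i
    t1[m] <- spec$compartments$t1_ms[i]
    t2[m] <- spec$compartments$t2_ms[i]
    pd[m] <- spec$compartments$pd[i]
  }
  list(t1 = t1, t2 = t2, pd = pd, compartment = label)
}

#' Add Rician noise to a magnitude image
#'
#' Magnitude reconstruction of complex Gaussian noise:
#' `out = sqrt((in + n1)^2 + n2^2)` with `n1, n2 ~ Normal(0, sigma)`.
#' Rayleigh-distributed in air, approximately Gaussian at high SNR, and
#' strictly non-negative -- which is exactly what makes polarity restoration
#' necessary for inversion-recovery data.
#'
#' @param image numeric matrix of (signed or magnitude) intensities.
#' @param sigma per-channel noise standard deviation (>= 0).
#' @return noisy magnitude matrix.
#' @export
add_rician_noise <- function(image, sigma) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(abs(image))
  n <- length(image)
  sqrt((image + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

default_times <- function(technique) {
  if (technique_info(technique)$kind == "TI") {
    seq(100, 1400, length.out = 8)
  } else {
    seq(20, 160, by = 20)
  }
}

ir_quality <- function(spec, technique) {
  if (technique %in% c("T1_LL", "T1_MOLLI")) {
    consistent <- 1 / spec$t1star_factor + 1
    if (!is.null(spec$inversion_quality) &&
        abs(spec$inversion_quality - consistent) > 1e-9) {
      stop(sprintf(
        paste0("inconsistent phantom: Look-Locker/MOLLI emulation with ",
               "t1star_factor %.3g requires inversion_quality = ",
               "1/t1star_factor + 1 = %.6g (got %.6g)"),
        spec$t1star_factor, consistent, spec$inversion_quality), call. = FALSE)
    }
    consistent
  } else {
    if (is.null(spec$inversion_quality)) 2.0 else spec$inversion_quality
  }
}

#' Simulate a source image series from a phantom
#'
#' Evaluates the technique's signal model at every pixel with the
#' compartment's true parameters, takes the magnitude, adds seeded Rician
#' noise, and assembles a [source_image_set()] with the layout the technique
#' implies (one multi-image series for Look-Locker/MOLLI/multi-echo, one
#' single-image series per time point for classic IR/single-echo). With
#' `out_dir` set, each image is also written as a DICOM file with the
#' correct timing tags.
#'
#' @param spec a [phantom_spec()].
#' @param technique mapping technique (see [mapping_config()]).
#' @param times_ms acquisition times in ms, sorted ascending; default 8
#'   points, TI 100-1400 ms for the inversion-recovery family and TE
#'   10-80 ms for the decay family.
#' @param out_dir optional directory for DICOM fixture files (stored pixel
#'   values are rounded to integers; the returned in-memory set keeps full
#'   precision).
#' @return a [source_image_set()]; when files were written, their paths are
#'   in `attr(, "paths")`.
#' @export
simulate_series <- function(spec, technique, times_ms = NULL, out_dir = NULL) {
  info <- technique_info(technique)
  if (is.null(times_ms)) times_ms <- default_times(technique)
  if (is.unsorted(times_ms, strictly = TRUE)) {
    stop("times_ms must be strictly ascending", call. = FALSE)
  }
  if (any(times_ms < 0)) stop("times_ms must be non-negative", call. = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)

  truth <- truth_maps(spec)
  inside <- truth$compartment > 0L
  is_ir <- info$kind == "TI"
  is_t2star <- startsWith(technique, "T2STAR")

  if (is_ir) {
    a <- truth$pd
    b <- ir_quality(spec, technique) * a
    t1star <- if (technique == "T1_IR") truth$t1 else spec$t1star_factor * truth$t1
  }

  images <- lapply(times_ms, function(tt) {
    clean <- matrix(0, spec$matrix_size[1], spec$matrix_size[2])
    if (is_ir) {
      clean[inside] <- abs(a[inside] - b[inside] * exp(-tt / t1star[inside]))
    } else {
      clean[inside] <- truth$pd[inside] * exp(-tt / truth$t2[inside])
      if (is_t2star) clean[inside] <- clean[inside] + spec$offset_c
    }
    add_rician_noise(clean, spec$noise_sigma)
  })

  set <- source_image_set(images, times_ms,
                          time_kind = info$kind, layout = info$layout,
                          geometry = default_geometry())
  if (!is.null(out_dir)) {
    attr(set, "paths") <- write_series_dicom(set, technique, out_dir)
  }
  set
}

write_series_dicom <- function(set, technique, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kind <- set$time_kind
  paths <- character(length(set$images))
  for (i in seq_along(set$images)) {
    els <- list(
      SOPInstanceUID = set$identifiers$sop_uid[i],
      StudyInstanceUID = set$identifiers$study_uid[i],
      SeriesInstanceUID = set$identifiers$series_uid[i],
      SeriesNumber = if (set$layout == "one_series_multi_image") 1L else i,
      InstanceNumber = set$identifiers$instance_number[i],
      SeriesDescription = paste0("synthetic phantom ", technique),
      PatientName = "PHANTOM^SYNTHETIC", PatientID = "PHANTOM",
      StudyDate = "20100730",
      PixelSpacing = set$geometry$pixel_spacing,
      ImagePositionPatient = set$geometry$image_position,
      ImageOrientationPatient = set$geometry$image_orientation,
      RepetitionTime = 2.7, FlipAngle = 35)
    if (kind == "TI") {
      els$InversionTime <- set$times_ms[i]
      els$EchoTime <- 1.1
    } else {
      els$EchoTime <- set$times_ms[i]
    }
    paths[i] <- file.path(out_dir, sprintf("%s_%02d.dcm", tolower(technique), i))
    dicom_write(paths[i], els, pmin(round(set$images[[i]]), 65535))
  }
  paths
}
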
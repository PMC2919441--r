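#' Mapping configuration
#'
#' Bundles the user-controlled computing parameters: technique, relaxation
#' time limit, noise level, optional sub-region and per-image registration
#' shifts.
#'
#' @param technique one of `T1_IR`, `T1_LL`, `T1_MOLLI`, `T2_SE`, `T2_ME`,
#'   `T2STAR_SE`, `T2STAR_ME`.
#' @param limit_ms maximum relaxation time in ms (> 0). Bounds the sign
#'   search for inversion-recovery data (flips run over images with
#'   `TI < 0.67 * limit_ms`) and the exported value range: fitted times above
#'   the limit are clipped to it.
#' @param noise_level intensity threshold (>= 0). A pixel is fitted only if
#'   at least one source image exceeds this intensity there; all other
#'   pixels are 0 in the map.
#' @param region optional `c(row0, col0, n_rows, n_cols)` sub-rectangle
#'   (1-based origin, inclusive extent) to confine mapping; pixels outside
#'   are 0.
#' @param use_offset T2* only: fit the three-parameter constant-offset model.
#' @param shifts optional [shift_spec()] of per-image rigid translations
#'   applied before fitting.
#' @param control a [fit_control()].
#' @return an object of class `mapping_config`.
#' @export
mapping_config <- function(technique, limit_ms, noise_level = 0,
                           region = NULL, use_offset = TRUE, shifts = NULL,
                           control = fit_control()) {
  technique_info(technique)  # validates the name
  stopifnot(limit_ms > 0, noise_level >= 0)
  if (!is.null(region)) {
    stopifnot(length(region) == 4, all(region[3:4] >= 1), all(region[1:2] >= 1))
  }
  structure(list(technique = technique, limit_ms = limit_ms,
                 noise_level = noise_level, region = region,
                 use_offset = use_offset, shifts = shifts,
                 control = control),
            class = "mapping_config")
}

#' Noise gate mask
#'
#' A pixel passes the gate when the signal intensity of any of its source
#' images is above the user-defined noise level; only those pixels are
#' fitted. With `noise_level = 0` every pixel with nonzero signal anywhere in
#' the stack is retained, including air-background noise.
#'
#' @param stack a [source_image_set()].
#' @param noise_level intensity threshold (>= 0).
#' @return logical matrix, `TRUE` where fitting will occur.
#' @export
noise_mask <- function(stack, noise_level) {
  stopifnot(noise_level >= 0)
  m <- Reduce(pmax, stack$images)
  m > noise_level
}

region_mask <- function(dims, region) {
  m <- matrix(FALSE, dims[1], dims[2])
  if (is.null(region)) return(!m)
  r0 <- region[1]; c0 <- region[2]
  r1 <- min(r0 + region[3] - 1, dims[1])
  c1 <- min(c0 + region[4] - 1, dims[2])
  if (r0 > dims[1] || c0 > dims[2]) {
    stop("region lies outside the image", call. = FALSE)
  }
  m[r0:r1, c0:c1] <- TRUE
  m
}

#' Compute a relaxation-time map pixel by pixel
#'
#' The core mapping routine: validates the source set for the chosen
#' technique, applies optional registration shifts, sorts the images by
#' TI/TE, gates background by the noise level, and fits every retained pixel
#' with the technique's signal model. For Look-Locker and MOLLI sets the
#' fitted time constant is the apparent T1*, which is corrected to T1 with
#' [ll_correct()]; pixels whose fit does not converge, whose corrected fit is
#' non-physical (B <= A), or which fall below the noise gate or outside the
#' region are assigned exactly 0. Fitted times above `limit_ms` are clipped
#' to the limit, so every map value lies in `[0, limit_ms]`.
#'
#' @param stack a [source_image_set()].
#' @param config a [mapping_config()].
#' @return an object of class `relaxation_map`: `values` (matrix, ms),
#'   `converged`, `n_flipped` and `chi` matrices, the technique, the config,
#'   and a provenance record.
#' @export
compute_map <- function(stack, config) {
  v <- validate_source_set(stack, config$technique, config$use_offset)
  if (length(v)) {
    stop("source set not valid for ", config$technique, ":\n  - ",
         paste(v, collapse = "\n  - "), call. = FALSE)
  }
  if (!is.null(config$shifts)) stack <- apply_shifts(stack, config$shifts)
  stack <- sort_by_time(stack)
  arr <- as_array(stack)
  d <- dim(arr)

  mask <- noise_mask(stack, config$noise_level) & region_mask(d, config$region)

  values <- matrix(0, d[1], d[2])
  converged <- matrix(FALSE, d[1], d[2])
  nflip <- matrix(0L, d[1], d[2])
  chi <- matrix(NA_real_, d[1], d[2])
  times <- stack$times_ms
  tech <- config$technique
  is_ll <- tech %in% c("T1_LL", "T1_MOLLI")
  is_ir <- tech %in% c("T1_IR", "T1_LL", "T1_MOLLI")
  is_t2star <- startsWith(tech, "T2STAR")

  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; cc <- idx[k, 2]
    sig <- arr[r, cc, ]
    fit <- if (is_ir) {
      fit_ir_pixel(sig, times, config$limit_ms, config$control)
    } else if (is_t2star) {
      fit_t2star_pixel(sig, times, config$use_offset, config$control)
    } else {
      fit_t2_pixel(sig, times, config$control)
    }
    if (!fit$converged) next
    val <- fit$relaxation_time_ms
    if (is_ll) {
      val <- tryCatch(ll_correct(fit$params), error = function(e) NA_real_)
      if (!is.finite(val) || val <= 0) next  # non-physical correction -> 0
    }
    values[r, cc] <- min(val, config$limit_ms)
    converged[r, cc] <- TRUE
    nflip[r, cc] <- fit$n_flipped
    chi[r, cc] <- fit$chi
  }

  structure(list(
    values = values, converged = converged, n_flipped = nflip, chi = chi,
    technique = tech, config = config,
    provenance = list(
      study_uid = unique(stack$identifiers$study_uid),
      series_uid = unique(stack$identifiers$series_uid),
      times_ms = times, time_kind = stack$time_kind,
      n_masked = nrow(idx), n_fitted = sum(converged),
      package_version = as.character(utils::packageVersion("relaxmap")))),
    class = "relaxation_map")
}

#' @export
print.relaxation_map <- function(x, ...) {
  d <- dim(x$values)
  nz <- x$values[x$values > 0]
  cat(sprintf("<relaxation_map> %s, %dx%d, limit %g ms\n",
              x$technique, d[1], d[2], x$config$limit_ms))
  cat(sprintf("  fitted pixels: %d / %d masked; zeroed: %d\n",
              x$provenance$n_fitted, x$provenance$n_masked,
              prod(d) - x$provenance$n_fitted))
  if (length(nz)) {
    q <- stats::quantile(nz, c(0.05, 0.5, 0.95))
    cat(sprintf("  nonzero values [ms]: median %.1f (5-95%%: %.1f-%.1f)\n",
                q[2], q[1], q[3]))
  }
  invisible(x)
}

#' Per-pixel fit report for diagnostics
#'
#' Recomputes the fit of one pixel and returns everything needed to plot it:
#' the raw magnitudes, the sign-restored samples actually fitted, the fitted
#' curve, the parameters and Chi. Parameters match [compute_map()] at that
#' pixel (the same fitting path is run).
#'
#' @param stack a [source_image_set()].
#' @param config a [mapping_config()].
#' @param row,col pixel position (1-based).
#' @return list of class `pixel_report`: `fitted_flag`, `samples` (tibble
#'   with `time_ms`, `raw`, `restored`, `fitted`), `params`, `chi`,
#'   `n_flipped`, `relaxation_time_ms` (post-correction, clipped), `reason`
#'   when not fitted.
#' @export
pixel_curve_report <- function(stack, config, row, col) {
  if (!is.null(config$shifts)) stack <- apply_shifts(stack, config$shifts)
  stack <- sort_by_time(stack)
  d <- dim(stack)
  if (row < 1 || row > d[1] || col < 1 || col > d[2]) {
    stop("pixel out of bounds", call. = FALSE)
  }
  arr <- as_array(stack)
  sig <- arr[row, col, ]
  times <- stack$times_ms

  gated <- noise_mask(stack, config$noise_level)[row, col] &&
    region_mask(d, config$region)[row, col]
  base <- list(row = row, col = col, technique = config$technique,
               samples = tibble::tibble(time_ms = times, raw = sig,
                                        restored = sig, fitted = NA_real_))
  if (!gated) {
    return(structure(c(base, list(fitted_flag = FALSE,
                                  reason = "not fitted: below noise level or outside region",
                                  params = NULL, chi = NA_real_, n_flipped = 0L,
                                  relaxation_time_ms = 0)),
                     class = "pixel_report"))
  }
  tech <- config$technique
  fit <- if (tech %in% c("T1_IR", "T1_LL", "T1_MOLLI")) {
    fit_ir_pixel(sig, times, config$limit_ms, config$control)
  } else if (startsWith(tech, "T2STAR")) {
    fit_t2star_pixel(sig, times, config$use_offset, config$control)
  } else {
    fit_t2_pixel(sig, times, config$control)
  }
  if (!fit$converged) {
    return(structure(c(base, list(fitted_flag = FALSE,
                                  reason = "not fitted: fit did not converge",
                                  params = NULL, chi = NA_real_,
                                  n_flipped = 0L, relaxation_time_ms = 0)),
                     class = "pixel_report"))
  }
  val <- fit$relaxation_time_ms
  reason <- NULL
  if (tech %in% c("T1_LL", "T1_MOLLI")) {
    val <- tryCatch(ll_correct(fit$params), error = function(e) NA_real_)
    if (!is.finite(val) || val <= 0) {
      return(structure(c(base, list(fitted_flag = FALSE,
                                    reason = "not fitted: non-physical Look-Locker correction (B <= A)",
                                    params = fit$params, chi = fit$chi,
                                    n_flipped = fit$n_flipped,
                                    relaxation_time_ms = 0)),
                       class = "pixel_report"))
    }
  }
  base$samples$restored <- fit$signal_used
  base$samples$fitted <- fitted(fit)
  structure(c(base, list(fitted_flag = TRUE, reason = reason,
                         params = fit$params, chi = fit$chi,
                         n_flipped = fit$n_flipped,
                         relaxation_time_ms = min(val, config$limit_ms))),
            class = "pixel_report")
}

#' @export
print.pixel_report <- function(x, ...) {
  cat(sprintf("<pixel_report> (%d, %d), %s\n", x$row, x$col, x$technique))
  if (!x$fitted_flag) {
    cat(" ", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  relaxation time: %.2f ms   chi: %.4g   flipped signs: %d\n",
              x$relaxation_time_ms, x$chi, x$n_flipped))
  cat("  params:", paste(sprintf("%s=%.4g", names(x$params),
                                 unlist(x$params)), collapse = "  "), "\n")
  invisible(x)
}
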
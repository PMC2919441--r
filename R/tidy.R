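#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a relaxation map into a per-pixel tibble
#'
#' @param x a `relaxation_map`.
#' @param drop_zero keep only fitted (nonzero) pixels.
#' @param ... unused.
#' @return tibble with `row`, `col`, `value_ms`, `converged`, `n_flipped`,
#'   `chi`.
#' @method tidy relaxation_map
#' @export
tidy.relaxation_map <- function(x, drop_zero = FALSE, ...) {
  d <- dim(x$values)
  out <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    value_ms = as.vector(x$values),
    converged = as.vector(x$converged),
    n_flipped = as.vector(x$n_flipped),
    chi = as.vector(x$chi))
  if (drop_zero) out <- out[out$converged, , drop = FALSE]
  out
}

#' One-row summary of a relaxation map
#'
#' @param x a `relaxation_map`.
#' @param ... unused.
#' @return tibble with pixel counts, zero fraction and value/chi quantiles.
#' @method glance relaxation_map
#' @export
glance.relaxation_map <- function(x, ...) {
  nz <- x$values[x$converged]
  chi <- x$chi[is.finite(x$chi)]
  q <- function(v, p) if (length(v)) unname(stats::quantile(v, p)) else NA_real_
  tibble::tibble(
    technique = x$technique,
    n_pixels = length(x$values),
    n_fitted = sum(x$converged),
    n_zero = sum(!x$converged),
    limit_ms = x$config$limit_ms,
    noise_level = x$config$noise_level,
    median_ms = q(nz, 0.5),
    q05_ms = q(nz, 0.05),
    q95_ms = q(nz, 0.95),
    chi_median = q(chi, 0.5),
    chi_q95 = q(chi, 0.95))
}

#' Plot a relaxation map
#'
#' Raster display in milliseconds; zero-valued (unfitted) pixels render as
#' the lowest color, reproducing the characteristic signal-dropout look of
#' non-converged regions.
#'
#' @param object a `relaxation_map`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot relaxation_map
#' @export
autoplot.relaxation_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, object$config$limit_ms),
                                  name = "ms") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$technique, "relaxation map"),
                  x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' Plot a single-pixel fit report
#'
#' Raw magnitudes, the sign-restored samples the winning fit used, and the
#' fitted curve.
#'
#' @param object a `pixel_report` from [pixel_curve_report()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pixel_report
#' @export
autoplot.pixel_report <- function(object, ...) {
  s <- object$samples
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw, shape = "raw"),
                        size = 2.5) +
    ggplot2::geom_point(ggplot2::aes(y = .data$restored, shape = "restored"),
                        color = "darkgreen", size = 2.5) +
    ggplot2::scale_shape_manual(values = c(raw = 8, restored = 18),
                                name = NULL) +
    ggplot2::labs(x = "time [ms]", y = "signal intensity",
                  title = sprintf("pixel (%d, %d), %s", object$row,
                                  object$col, object$technique)) +
    ggplot2::theme_minimal()
  if (object$fitted_flag) {
    grid <- seq(min(s$time_ms), max(s$time_ms), length.out = 200)
    curve <- switch(object$technique,
                    T1_IR = , T1_LL = , T1_MOLLI =
                      ir_signal(object$params, grid),
                    T2STAR_SE = , T2STAR_ME =
                      if (!is.null(object$params$C)) {
                        t2star_offset_signal(object$params, grid)
                      } else {
                        object$params$A * exp(-grid / object$params$T2star)
                      },
                    t2_signal(object$params, grid))
    p <- p + ggplot2::geom_line(data = tibble::tibble(time_ms = grid,
                                                      fit = curve),
                                ggplot2::aes(y = .data$fit), color = "red") +
      ggplot2::labs(subtitle = sprintf("%.1f ms, chi %.3g, %d sign(s) flipped",
                                       object$relaxation_time_ms, object$chi,
                                       object$n_flipped))
  } else {
    p <- p + ggplot2::labs(subtitle = object$reason)
  }
  p
}

#' @importFrom rlang .data
NULL
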
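#' Fit control settings
#'
#' @param maxiter maximum Levenberg-Marquardt iterations per candidate fit.
#' @param ptol relative parameter tolerance declaring convergence.
#' @return a list of class `fit_control`.
#' @export
fit_control <- function(maxiter = 200, ptol = 1e-8) {
  stopifnot(maxiter >= 1, ptol > 0)
  structure(list(maxiter = as.integer(maxiter), ptol = ptol),
            class = "fit_control")
}

#' Goodness-of-fit statistic
#'
#' Chi is the unweighted sum of squared residuals of a fit; the polarity
#' search selects the sign pattern with the lowest Chi.
#'
#' @param residuals numeric vector, at least one element.
#' @return non-negative scalar.
#' @export
chi_of <- function(residuals) {
  if (length(residuals) == 0) stop("at least one residual required", call. = FALSE)
  sum(residuals^2)
}

#' Number of sign-flip cycles for the polarity search
#'
#' Magnitude reconstruction discards the sign of inversion-recovery signals.
#' The search negates an increasing number of leading (lowest-TI) images,
#' stopping at the last image with `TI < 0.67 * limit_t1`; this returns that
#' largest flip count.
#'
#' @param tis inversion times in ms, sorted ascending.
#' @param limit_t1 user relaxation-time limit in ms (> 0).
#' @return integer count of leading images eligible for sign flipping.
#' @export
max_flip_count <- function(tis, limit_t1) {
  stopifnot(limit_t1 > 0)
  if (is.unsorted(tis, strictly = FALSE)) {
    stop("`tis` must be sorted ascending", call. = FALSE)
  }
  sum(tis < 0.67 * limit_t1)
}

# One Levenberg-Marquardt fit with analytic Jacobian; returns NULL on any
# optimizer failure or non-finite outcome. `res_fn`/`jac_fn` take the bare
# parameter vector (hot path: called once per iteration per pixel).
lm_fit <- function(par0, res_fn, jac_fn, control) {
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = par0, fn = res_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(maxiter = control$maxiter,
                                           ptol = control$ptol))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  ok <- fit$info %in% 1:4 && all(is.finite(fit$par)) && is.finite(fit$deviance)
  if (!ok) return(NULL)
  list(par = fit$par, chi = fit$deviance)
}

# model-specific residual and Jacobian closures over the bare parameter
# vector; analytic derivatives matching ir_grad/t2_grad/t2star_offset_grad
ir_res_jac <- function(y, t) {
  list(res = function(p) y - p[1] + p[2] * exp(-t / p[3]),
       jac = function(p) {
         e <- exp(-t / p[3])
         cbind(-1, e, p[2] * e * t / p[3]^2)
       })
}
t2_res_jac <- function(y, t) {
  list(res = function(p) y - p[1] * exp(-t / p[2]),
       jac = function(p) {
         e <- exp(-t / p[2])
         cbind(-e, -p[1] * e * t / p[2]^2)
       })
}
t2star_res_jac <- function(y, t) {
  list(res = function(p) y - p[1] * exp(-t / p[2]) - p[3],
       jac = function(p) {
         e <- exp(-t / p[2])
         cbind(-e, -p[1] * e * t / p[2]^2, -1)
       })
}

pixel_fit <- function(params, relaxation_time_ms, chi, converged, n_flipped,
                      model, times_ms, signal_used) {
  structure(list(params = params,
                 relaxation_time_ms = relaxation_time_ms,
                 chi = chi,
                 converged = converged,
                 n_flipped = n_flipped,
                 model = model,
                 times_ms = times_ms,
                 signal_used = signal_used),
            class = "pixel_fit")
}

failed_fit <- function(model, times_ms, signal) {
  pixel_fit(params = NULL, relaxation_time_ms = 0, chi = NA_real_,
            converged = FALSE, n_flipped = 0L, model = model,
            times_ms = times_ms, signal_used = signal)
}

sort_pairs <- function(signal, times) {
  o <- order(times)
  list(signal = signal[o], times = times[o])
}

#' Fit the inversion-recovery model to one pixel with polarity restoration
#'
#' Runs the cyclic sign search: for each candidate count `n` from 0 up to
#' [max_flip_count()], the `n` leading (lowest-TI) magnitudes are negated and
#' the three-parameter model \eqn{A - B\exp(-TI/T1^*)} is fitted by
#' Levenberg-Marquardt; the candidate with the lowest Chi (sum of squared
#' residuals) wins, ties going to the smallest flip count. The returned
#' relaxation time is the fitted \eqn{T1^*}; for Look-Locker/MOLLI data the
#' caller applies [ll_correct()].
#'
#' @param signal magnitude intensities, one per image.
#' @param tis inversion times in ms (paired with `signal`; sorted internally).
#' @param limit_t1 relaxation-time limit in ms, bounds the sign search.
#' @param control a [fit_control()].
#' @return a `pixel_fit` with fields `params` (A, B, T1star), `chi`,
#'   `converged`, `n_flipped`, and a `sign_search` attribute listing every
#'   candidate (n_flipped, chi, parameters, converged).
#' @export
fit_ir_pixel <- function(signal, tis, limit_t1, control = fit_control()) {
  if (length(signal) != length(tis)) {
    stop("`signal` and `tis` must have the same length", call. = FALSE)
  }
  if (length(signal) < 3) {
    stop("at least 3 samples required for the 3-parameter fit", call. = FALSE)
  }
  p <- sort_pairs(signal, tis)
  signal <- p$signal; tis <- p$times

  n_max <- min(max_flip_count(tis, limit_t1), length(signal))
  a0 <- max(abs(signal))
  if (!is.finite(a0) || a0 <= 0) return(failed_fit("ir", tis, signal))
  t1s0 <- min(max(tis[which.min(abs(signal))] / log(2), 1), limit_t1)
  par0 <- c(A = a0, B = 2 * a0, T1star = t1s0)

  cand <- vector("list", n_max + 1)
  for (n in 0:n_max) {
    s <- signal
    if (n > 0) s[seq_len(n)] <- -s[seq_len(n)]
    rj <- ir_res_jac(s, tis)
    fit <- lm_fit(par0, rj$res, rj$jac, control)
    cand[[n + 1]] <- list(n_flipped = n, fit = fit, signal = s)
  }
  chis <- vapply(cand, function(x) {
    if (is.null(x$fit)) Inf else x$fit$chi
  }, numeric(1))
  search <- tibble::tibble(
    n_flipped = 0:n_max,
    chi = ifelse(is.finite(chis), chis, NA_real_),
    converged = is.finite(chis),
    A = vapply(cand, function(x) if (is.null(x$fit)) NA_real_ else x$fit$par[["A"]], numeric(1)),
    B = vapply(cand, function(x) if (is.null(x$fit)) NA_real_ else x$fit$par[["B"]], numeric(1)),
    T1star = vapply(cand, function(x) if (is.null(x$fit)) NA_real_ else x$fit$par[["T1star"]], numeric(1)))

  win <- which.min(chis)  # ties -> smallest n_flipped (first index)
  best <- cand[[win]]
  out <- if (is.null(best$fit) || best$fit$par[["T1star"]] <= 0) {
    failed_fit("ir", tis, signal)
  } else {
    pixel_fit(params = as.list(best$fit$par),
              relaxation_time_ms = best$fit$par[["T1star"]],
              chi = best$fit$chi, converged = TRUE,
              n_flipped = best$n_flipped, model = "ir",
              times_ms = tis, signal_used = best$signal)
  }
  attr(out, "sign_search") <- search
  attr(out, "selected_index") <- win
  out
}

#' Fit the two-parameter mono-exponential decay to one pixel
#'
#' Fits \eqn{A\exp(-TE/T2)}; decay data are non-negative, so no sign search
#' is performed. Initial values come from a log-linear regression on the
#' positive samples.
#'
#' @inheritParams fit_ir_pixel
#' @param tes echo times in ms (paired with `signal`; sorted internally).
#' @return a `pixel_fit` with `params` (A, T2).
#' @export
fit_t2_pixel <- function(signal, tes, control = fit_control()) {
  if (length(signal) != length(tes)) {
    stop("`signal` and `tes` must have the same length", call. = FALSE)
  }
  if (length(signal) < 2) {
    stop("at least 2 samples required for the 2-parameter fit", call. = FALSE)
  }
  p <- sort_pairs(signal, tes)
  signal <- p$signal; tes <- p$times

  par0 <- decay_start(signal, tes)
  if (is.null(par0)) return(failed_fit("t2", tes, signal))
  rj <- t2_res_jac(signal, tes)
  fit <- lm_fit(c(A = par0$A, T2 = par0$decay), rj$res, rj$jac, control)
  if (is.null(fit) || fit$par[["T2"]] <= 0) return(failed_fit("t2", tes, signal))
  pixel_fit(params = as.list(fit$par),
            relaxation_time_ms = fit$par[["T2"]],
            chi = fit$chi, converged = TRUE, n_flipped = 0L,
            model = "t2", times_ms = tes, signal_used = signal)
}

#' Fit the T2* decay to one pixel, optionally with a constant offset
#'
#' With `use_offset = TRUE` fits the three-parameter model
#' \eqn{A\exp(-TE/T2^*) + C}, whose baseline C absorbs the magnitude-image
#' noise floor at long echo times; otherwise falls back to the two-parameter
#' mono-exponential.
#'
#' @inheritParams fit_t2_pixel
#' @param use_offset fit the constant-offset model (needs >= 3 samples).
#' @return a `pixel_fit` with `params` (A, T2star, C) or (A, T2).
#' @export
fit_t2star_pixel <- function(signal, tes, use_offset = TRUE,
                             control = fit_control()) {
  if (!use_offset) {
    out <- fit_t2_pixel(signal, tes, control)
    out$model <- "t2star"
    if (!is.null(out$params)) names(out$params)[names(out$params) == "T2"] <- "T2star"
    return(out)
  }
  if (length(signal) != length(tes)) {
    stop("`signal` and `tes` must have the same length", call. = FALSE)
  }
  if (length(signal) < 3) {
    stop("at least 3 samples required for the 3-parameter fit", call. = FALSE)
  }
  p <- sort_pairs(signal, tes)
  signal <- p$signal; tes <- p$times

  c0 <- min(signal)
  par0 <- decay_start(signal - c0, tes)
  if (is.null(par0)) return(failed_fit("t2star_offset", tes, signal))
  rj <- t2star_res_jac(signal, tes)
  fit <- lm_fit(c(A = par0$A, T2star = par0$decay, C = c0),
                rj$res, rj$jac, control)
  if (is.null(fit) || fit$par[["T2star"]] <= 0) {
    return(failed_fit("t2star_offset", tes, signal))
  }
  pixel_fit(params = as.list(fit$par),
            relaxation_time_ms = fit$par[["T2star"]],
            chi = fit$chi, converged = TRUE, n_flipped = 0L,
            model = "t2star_offset", times_ms = tes, signal_used = signal)
}

# Log-linear start for exponential decay: regress log(signal) on te over the
# positive samples. NULL if fewer than two usable samples or a non-decaying
# slope that cannot seed the optimizer.
decay_start <- function(signal, tes) {
  pos <- which(signal > 0)
  if (length(pos) < 2) return(NULL)
  co <- stats::coef(stats::lm(log(signal[pos]) ~ tes[pos]))
  a0 <- exp(co[[1]])
  slope <- co[[2]]
  decay0 <- if (is.finite(slope) && slope < 0) -1 / slope else max(tes)
  if (!is.finite(a0) || a0 <= 0 || !is.finite(decay0)) return(NULL)
  list(A = a0, decay = min(max(decay0, 1e-3), 1e6))
}

#' @export
print.pixel_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<pixel_fit> not converged (map value 0)\n")
    return(invisible(x))
  }
  cat(sprintf("<pixel_fit> model=%s  relaxation=%.2f ms  chi=%.4g  n_flipped=%d\n",
              x$model, x$relaxation_time_ms, x$chi, x$n_flipped))
  cat("  params:", paste(sprintf("%s=%.4g", names(x$params),
                                 unlist(x$params)), collapse = "  "), "\n")
  invisible(x)
}

#' @export
fitted.pixel_fit <- function(object, ...) {
  if (!object$converged) return(rep(NA_real_, length(object$times_ms)))
  switch(object$model,
         ir = ir_signal(object$params, object$times_ms),
         t2 = t2_signal(object$params, object$times_ms),
         t2star = t2_signal(stats::setNames(object$params, c("A", "T2")),
                            object$times_ms),
         t2star_offset = t2star_offset_signal(object$params, object$times_ms))
}
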
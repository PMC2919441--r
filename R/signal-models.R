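#' Signal models for relaxation-time mapping
#'
#' Closed-form signal equations shared by the per-pixel fitting engine and the
#' synthetic phantom simulator. All times are in milliseconds throughout the
#' package, matching the units of the DICOM InversionTime and EchoTime tags
#' and of the exported maps.
#'
#' Three models are supported:
#' \describe{
#'   \item{inversion recovery}{\eqn{S(TI) = A - B \exp(-TI/T1^*)}, with
#'     \eqn{A} a signal-intensity scale, \eqn{B} the inversion depth
#'     (\eqn{B = 2A} is a perfect inversion), and \eqn{T1^*} the apparent
#'     longitudinal relaxation time. The signal is signed; magnitude
#'     reconstruction discards the sign, which the fitting engine restores.}
#'   \item{mono-exponential decay}{\eqn{S(TE) = A \exp(-TE/T2)}, the
#'     two-parameter model for T2 (and offset-free T2*) decay.}
#'   \item{offset decay}{\eqn{S(TE) = A \exp(-TE/T2^*) + C}, the
#'     three-parameter T2* model with a constant baseline \eqn{C} that absorbs
#'     the noise floor of magnitude images at long echo times.}
#' }
#'
#' For Look-Locker and MOLLI acquisitions the repeated readouts deflect the
#' recovery curve, so the fitted time constant is an apparent \eqn{T1^*};
#' [ll_correct()] maps it to T1 via \eqn{T1 = T1^* (B/A - 1)}, which reduces
#' to the identity at perfect inversion.
#'
#' @param params a named list or vector of model parameters (see each
#'   function).
#' @param ti,te acquisition time in milliseconds, non-negative; vectorized.
#' @return signal intensity (arbitrary units); `ir_signal()` is signed, the
#'   decay models are positive for `A > 0`.
#' @examples
#' ir_signal(list(A = 100, B = 200, T1star = 1000), ti = 1000 * log(2)) # 0
#' t2_signal(list(A = 1000, T2 = 50), te = 50)                          # 1000/e
#' ll_correct(list(A = 100, B = 200, T1star = 800))                     # 800
#' @name signal_models
NULL

check_time <- function(t, what) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)) || any(t < 0)) {
    stop(sprintf("`%s` must be finite, non-negative, and numeric", what),
         call. = FALSE)
  }
  invisible(t)
}

#' @rdname signal_models
#' @export
ir_signal <- function(params, ti) {
  check_time(ti, "ti")
  params$A - params$B * exp(-ti / params$T1star)
}

#' @rdname signal_models
#' @export
t2_signal <- function(params, te) {
  check_time(te, "te")
  params$A * exp(-te / params$T2)
}

#' @rdname signal_models
#' @export
t2star_offset_signal <- function(params, te) {
  check_time(te, "te")
  params$A * exp(-te / params$T2star) + params$C
}

#' Look-Locker correction of an apparent T1
#'
#' Converts the apparent relaxation time fitted from Look-Locker or MOLLI
#' data to the true T1 using the remaining two fit parameters:
#' \eqn{T1 = T1^* (B/A - 1)}. At perfect inversion (\eqn{B = 2A}) the
#' correction is the identity. Fits with \eqn{B \le A} have no physical
#' zero crossing and are rejected; the mapper sends such pixels to the same
#' zero channel as non-converged fits.
#'
#' @param params list with elements `A`, `B`, `T1star` (ms).
#' @return corrected T1 in milliseconds.
#' @export
ll_correct <- function(params) {
  if (!is.finite(params$A) || !is.finite(params$B) || params$A <= 0) {
    stop("non-physical-fit: A must be positive and finite", call. = FALSE)
  }
  ratio <- params$B / params$A - 1
  if (ratio <= 0) {
    stop("non-physical-fit: Look-Locker correction requires B > A",
         call. = FALSE)
  }
  params$T1star * ratio
}

# Analytic Jacobians, one row per time point, one column per parameter in the
# order the fitters use. Supplied to the optimizer instead of finite
# differences.

ir_grad <- function(params, ti) {
  e <- exp(-ti / params$T1star)
  cbind(A = rep(1, length(ti)),
        B = -e,
        T1star = -params$B * e * ti / params$T1star^2)
}

t2_grad <- function(params, te) {
  e <- exp(-te / params$T2)
  cbind(A = e, T2 = params$A * e * te / params$T2^2)
}

t2star_offset_grad <- function(params, te) {
  e <- exp(-te / params$T2star)
  cbind(A = e,
        T2star = params$A * e * te / params$T2star^2,
        C = rep(1, length(te)))
}
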
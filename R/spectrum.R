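#' Self-affine roughness spectrum
#'
#' Describes the isotropic power spectral density of a randomly rough,
#' self-affine surface: a plateau of value `C0` below the roll-off
#' wavenumber `qr`, a power-law decay \eqn{C(q) = C0 (q/q_r)^{-2(1+H)}}
#' between `qr` and the short-wavelength cut-off `qs`, and zero beyond
#' `qs`.  `H` is the Hurst exponent.
#'
#' The absolute scale `C0` is a free convention: generated surfaces are
#' rescaled to a prescribed root-mean-square gradient before use, which
#' removes any dependence on it.
#'
#' @param qr roll-off wavenumber, \eqn{2\pi/\lambda_r} (1/length).
#' @param qs cut-off wavenumber, \eqn{2\pi/\lambda_s} (1/length).
#' @param H Hurst exponent, in (0, 1).
#' @param C0 plateau value \eqn{C(q_r)} (length^4).
#' @return an object of class `"spectrum_spec"`.
#' @seealso [psd_value()], [generate_heightfield()]
#' @examples
#' sp <- spectrum_spec(qr = 2 * pi / 64, qs = 2 * pi / 4, H = 0.8)
#' psd_value(sp, sp$qr / 2) / sp$C0   # plateau branch
#' @export
spectrum_spec <- function(qr, qs, H, C0 = 1) {
  stopifnot(is.numeric(qr), is.numeric(qs), is.numeric(H), is.numeric(C0))
  if (!(qr > 0 && qs > qr)) stop("need 0 < qr < qs")
  if (!(H > 0 && H < 1)) stop("Hurst exponent must lie in (0, 1)")
  if (!(C0 > 0)) stop("C0 must be positive")
  structure(list(qr = qr, qs = qs, H = H, C0 = C0),
            class = "spectrum_spec")
}

#' Evaluate the roughness power spectral density
#'
#' @param spec a [spectrum_spec()].
#' @param q wavenumber(s), must be non-negative (1/length).
#' @return power spectral density values (length^4); vectorised over `q`.
#' @export
psd_value <- function(spec, q) {
  stopifnot(inherits(spec, "spectrum_spec"))
  if (any(q < 0)) stop("wavenumbers must be non-negative")
  out <- numeric(length(q))
  plateau <- q > 0 & q < spec$qr
  band <- q >= spec$qr & q <= spec$qs
  out[plateau] <- spec$C0
  out[band] <- spec$C0 * (q[band] / spec$qr)^(-2 * (1 + spec$H))
  dim(out) <- dim(q)
  out
}

#' @export
print.spectrum_spec <- function(x, ...) {
  cat("Self-affine roughness spectrum\n")
  cat(sprintf("  roll-off  qr = %g  (lambda_r = %g)\n", x$qr, 2 * pi / x$qr))
  cat(sprintf("  cut-off   qs = %g  (lambda_s = %g)\n", x$qs, 2 * pi / x$qs))
  cat(sprintf("  Hurst     H  = %g   (band slope %.3g)\n", x$H, -2 * (1 + x$H)))
  invisible(x)
}
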
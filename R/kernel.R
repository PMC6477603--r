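#' Elastic layer specification
#'
#' A homogeneous elastic sheet of width `w` and contact modulus `Estar`,
#' resting on a fluid foundation (uniform back pressure, no shear
#' coupling).  `w = Inf` selects the elastic half-space limit.
#'
#' @param Estar contact modulus E* (pressure units), > 0.
#' @param w layer width (length), > 0 or `Inf`.
#' @param lambda_s optional short-wavelength cut-off used to report the
#'   dimensionless width `W = w / lambda_s`.
#' @return an object of class `"layer_spec"`.
#' @export
layer_spec <- function(Estar = 1, w = Inf, lambda_s = NULL) {
  stopifnot(Estar > 0, w > 0)
  W <- if (is.null(lambda_s)) NA_real_ else w / lambda_s
  structure(list(Estar = Estar, w = w, W = W, lambda_s = lambda_s),
            class = "layer_spec")
}

#' @export
print.layer_spec <- function(x, ...) {
  if (is.infinite(x$w)) {
    cat(sprintf("Elastic half-space, E* = %g\n", x$Estar))
  } else {
    cat(sprintf("Elastic layer on fluid foundation: w = %g, E* = %g", x$w, x$Estar))
    if (!is.na(x$W)) cat(sprintf(", W = w/lambda_s = %g", x$W))
    cat("\n")
  }
  invisible(x)
}

#' Finite-width correction factor of the layer Green's function
#'
#' For a free-standing sheet of width `w` on a fluid foundation the
#' per-mode compliance is the half-space value multiplied by
#' \deqn{f(t) = \frac{\sinh 2t + 2t}{\cosh 2t - 1 - 2t^2}, \quad t = qw.}
#' `f` decreases monotonically from the thin-plate branch
#' \eqn{6/t^3} at small `t` to 1 in the thick (half-space) limit.
#'
#' Below `t = 0.1` the subtracted denominator loses precision
#' catastrophically, so Taylor-series forms of numerator and denominator
#' are used there (terms through \eqn{t^9} and \eqn{t^{10}}; relative
#' truncation error below 1e-13 at the switch point).  Above `t = 19`
#' the hyperbolic terms overflow while `f` is within 1e-13 of 1, so the
#' asymptotic form \eqn{1 + (4t^2 + 4t + 2) e^{-2t}} is used.
#'
#' @param t dimensionless width `q * w`, > 0; vectorised.
#' @return f(t), dimensionless, >= 1.
#' @export
finite_width_factor <- function(t) {
  if (any(t <= 0)) stop("dimensionless width t must be positive")
  out <- numeric(length(t))
  lo <- t < 0.1
  hi <- t > 19
  mid <- !lo & !hi
  tl <- t[lo]
  out[lo] <- (4 * tl + (4 / 3) * tl^3 + (4 / 15) * tl^5 +
                (8 / 315) * tl^7 + (512 / 362880) * tl^9) /
    ((2 / 3) * tl^4 + (4 / 45) * tl^6 + (2 / 315) * tl^8 +
       (1024 / 3628800) * tl^10)
  tm <- t[mid]
  out[mid] <- (sinh(2 * tm) + 2 * tm) / (cosh(2 * tm) - 1 - 2 * tm^2)
  th <- t[hi]
  out[hi] <- 1 + (4 * th^2 + 4 * th + 2) * exp(-2 * th)
  dim(out) <- dim(t)
  out
}

#' Build the per-mode elastic kernel on a grid
#'
#' The compliance of every nonzero Fourier mode is
#' \deqn{G(q) = \frac{2 f(q w)}{q E^*},}
#' i.e. the half-space compliance `2/(q E*)` enhanced by the
#' finite-width factor.  In the thin limit `qw << 1` the inverse
#' compliance reduces to the thin-plate bending stiffness
#' \eqn{1/G \approx E^* q^4 w^3 / 12}.  The `q = 0` mode has no elastic
#' restoring force (rigid translation of a free sheet); it is flagged
#' and carried by the load balance in the solver, never by `G`.
#'
#' @param layer a [layer_spec()].
#' @param n grid points per side (even).
#' @param a grid spacing.
#' @return an object of class `"elastic_kernel"`: list with
#'   `q_magnitudes` (n x n), `compliance` (n x n, `Inf` at q = 0),
#'   `stiffness` (n x n, `1/G`, 0 at q = 0), `layer`, `n`, `a`.
#' @export
build_kernel <- function(layer, n, a = 1) {
  stopifnot(inherits(layer, "layer_spec"), n %% 2 == 0, n >= 4, a > 0)
  qmag <- wavenumber_magnitude(n, a)
  G <- matrix(Inf, n, n)
  nz <- qmag > 0
  if (is.infinite(layer$w)) {
    G[nz] <- 2 / (qmag[nz] * layer$Estar)
  } else {
    G[nz] <- 2 * finite_width_factor(qmag[nz] * layer$w) /
      (qmag[nz] * layer$Estar)
  }
  invG <- matrix(0, n, n)
  invG[nz] <- 1 / G[nz]
  structure(list(q_magnitudes = qmag, compliance = G, stiffness = invG,
                 layer = layer, n = n, a = a),
            class = "elastic_kernel")
}

#' @export
print.elastic_kernel <- function(x, ...) {
  cat(sprintf("Elastic kernel on %d x %d grid (a = %g)\n", x$n, x$n, x$a))
  print(x$layer)
  nz <- x$q_magnitudes > 0
  cat(sprintf("  compliance range [%.4g, %.4g] (q = 0 mode free)\n",
              min(x$compliance[nz]), max(x$compliance[nz])))
  invisible(x)
}

#' Elastic restoring stress for a displacement field
#'
#' Transforms the displacement, divides each nonzero mode by its
#' compliance `G(q)`, zeroes the `q = 0` mode, and transforms back.  A
#' uniform displacement therefore produces zero stress.
#'
#' @param displacement real n x n displacement grid (length units).
#' @param kernel an [build_kernel()] result.
#' @return real n x n stress grid (pressure units).
#' @export
elastic_stress_field <- function(displacement, kernel) {
  stopifnot(inherits(kernel, "elastic_kernel"),
            all(dim(displacement) == c(kernel$n, kernel$n)))
  ifft_real(stats::fft(displacement) * kernel$stiffness)
}

#' Elastic energy stored in a displacement field
#'
#' Spectral form \eqn{U_{el} = \frac{a^2}{2N} \sum_{q \ne 0}
#' |\tilde z(q)|^2 / G(q)}, normalised so that it equals the real-space
#' work integral \eqn{\frac12 \sum_i \sigma_{el}(r_i) z(r_i) a^2} over
#' the periodic cell (Parseval).
#'
#' @inheritParams elastic_stress_field
#' @return energy (pressure x length x area), >= 0.
#' @export
elastic_energy <- function(displacement, kernel) {
  stopifnot(inherits(kernel, "elastic_kernel"),
            all(dim(displacement) == c(kernel$n, kernel$n)))
  Z <- stats::fft(displacement)
  kernel$a^2 / (2 * length(displacement)) *
    sum(Mod(Z)^2 * kernel$stiffness)
}

#' Persson-theory pressure broadening for a layer kernel
#'
#' In full contact the interfacial pressure inherits the substrate
#' spectrum through the kernel: each mode contributes
#' \eqn{(q E^* / 2 f(qw))^2} times its expected squared height
#' amplitude to the pressure variance.  The expected amplitudes follow
#' the supplied spectrum, normalised so the expected mean-square
#' gradient equals `rms_gradient^2` (matching the surface generator's
#' convention).  For the half-space kernel on a unit-gradient surface
#' this reduces to the closed form \eqn{\Delta\sigma = E^*/2}.
#'
#' @param spec a [spectrum_spec()].
#' @param layer a [layer_spec()].
#' @param n,a grid defining the discrete mode set.
#' @param rms_gradient rms gradient the surface ensemble is normalised
#'   to.
#' @return the pressure-distribution width \eqn{\Delta\sigma}.
#' @export
persson_broadening <- function(spec, layer, n = 256, a = 1,
                               rms_gradient = 1) {
  stopifnot(inherits(spec, "spectrum_spec"), inherits(layer, "layer_spec"))
  qmag <- wavenumber_magnitude(n, a)
  Cq <- psd_value(spec, qmag)
  norm <- sum(qmag^2 * Cq)
  if (norm == 0) return(0)
  s2 <- Cq * (rms_gradient^2 / norm)   # expected |H|^2/N^2 per mode
  nz <- qmag > 0
  fw <- rep(1, sum(nz))
  if (!is.infinite(layer$w)) {
    fw <- finite_width_factor(qmag[nz] * layer$w)
  }
  sqrt(sum((qmag[nz] * layer$Estar / (2 * fw))^2 * s2[nz]))
}

#' Persson's erf area-load relation
#'
#' \eqn{A/A_0 = \mathrm{erf}(\sigma_0 / (\sqrt2 \, \Delta\sigma))}:
#' the relative contact area predicted from the macroscopic pressure
#' and the width of the full-contact pressure distribution.
#'
#' @param sigma0 apparent contact pressure, >= 0.
#' @param delta_sigma pressure-distribution width, > 0.
#' @return area fraction in [0, 1); vectorised.
#' @export
persson_area <- function(sigma0, delta_sigma) {
  if (any(delta_sigma <= 0)) stop("delta_sigma must be positive")
  if (any(sigma0 < 0)) stop("sigma0 must be non-negative")
  x <- sigma0 / (sqrt(2) * delta_sigma)
  2 * stats::pnorm(x * sqrt(2)) - 1   # erf(x)
}
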
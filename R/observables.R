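#' Reduced contact area statistic
#'
#' \eqn{A (A_0 - A) / A_0^2}: vanishes at zero and full contact and
#' peaks at 0.25 for half contact; plotted against load it exposes the
#' low-load linear regime and collapses across layer widths after load
#' rescaling.
#'
#' @param A contact area (or area fraction with `A0 = 1`).
#' @param A0 nominal area.
#' @return dimensionless value in [0, 0.25]; vectorised.
#' @export
reduced_area <- function(A, A0 = 1) {
  if (any(A < 0 | A > A0)) stop("need 0 <= A <= A0")
  A * (A0 - A) / A0^2
}

#' Normalised mean separation
#'
#' \eqn{\tilde s = 1 - \langle u \rangle / u_{max}}: 1 at first touch,
#' 0 at full contact.
#'
#' @param mean_u mean displacement toward the substrate, >= 0.
#' @param u_max full-contact mean displacement, > 0.
#' @return dimensionless separation in [0, 1].
#' @export
normalized_separation <- function(mean_u, u_max) {
  if (any(u_max <= 0)) stop("u_max must be positive (flat substrate is degenerate)")
  if (any(mean_u < 0 | mean_u > u_max + 1e-12)) stop("need 0 <= mean_u <= u_max")
  1 - mean_u / u_max
}

#' Adhesion parameter theta
#'
#' Ratio of stored elastic energy to gained adhesion energy,
#' \eqn{\theta = U_{el} / U_{ad}}; the smaller it is, the more
#' favourable the energy balance of forming contact.  `Uad` is the work
#' of adhesion times the touching area (range-independent in the
#' short-range limit).
#'
#' @param Uel elastic energy, >= 0.
#' @param Uad adhesion energy, > 0.
#' @return dimensionless theta.
#' @export
adhesion_parameter <- function(Uel, Uad) {
  if (any(Uad <= 0)) stop("theta is undefined without adhesion energy (Uad > 0)")
  Uel / Uad
}

#' Assemble an area-load curve
#'
#' @param W dimensionless layer width (`Inf` for the half-space).
#' @param results list of `gfmd_contact` objects, one per load,
#'   ordered or not (rows are sorted by load).
#' @param Estar contact modulus used to nondimensionalise the load.
#' @param rms_grad rms surface gradient entering the dimensionless load
#'   `sigma0 / (Estar * rms_grad)` (1 under the standard
#'   normalisation).
#' @return data frame of class `"area_load_curve"` with columns `W`,
#'   `sigma0`, `area_fraction`, `s_tilde`, `Uel`, `Uad`, `theta`,
#'   `converged`.
#' @export
area_load_curve <- function(W, results, Estar = 1, rms_grad = 1) {
  stopifnot(length(results) >= 1)
  df <- data.frame(
    W = W,
    sigma0 = vapply(results, function(r) r$sigma0 / (Estar * rms_grad),
                    numeric(1)),
    area_fraction = vapply(results, `[[`, numeric(1), "area_fraction"),
    s_tilde = vapply(results, `[[`, numeric(1), "normalized_separation"),
    Uel = vapply(results, `[[`, numeric(1), "Uel"),
    Uad = vapply(results, `[[`, numeric(1), "Uad"),
    theta = vapply(results, `[[`, numeric(1), "theta"),
    converged = vapply(results, `[[`, logical(1), "converged"))
  df <- df[order(df$sigma0), ]
  rownames(df) <- NULL
  class(df) <- c("area_load_curve", "data.frame")
  df
}

#' Fit the erf coefficient of the area-load relation
#'
#' Least-squares fit of `area_fraction = erf(k * sigma0)` to an
#' [area_load_curve()] (loads already dimensionless).  Only points with
#' area fraction inside `window` enter the fit, since the erf form is
#' claimed for low-to-moderate contact.
#'
#' @param curve an `area_load_curve` (or data frame with `sigma0` and
#'   `area_fraction`).
#' @param window admissible range of area fractions.
#' @return list with `k` and `stderr`.
#' @export
fit_erf_k <- function(curve, window = c(0.01, 0.9)) {
  sel <- curve$area_fraction > window[1] & curve$area_fraction < window[2]
  if (sum(sel) < 4) stop("need at least 4 points inside the area window")
  x <- curve$sigma0[sel]
  y <- curve$area_fraction[sel]
  erf <- function(u) 2 * stats::pnorm(u * sqrt(2)) - 1
  k0 <- stats::coef(stats::lm(y ~ x - 1))[[1]] * sqrt(pi) / 2
  sse <- function(k) sum((y - erf(k * x))^2)
  opt <- stats::optimize(sse, interval = c(k0 / 20, k0 * 20),
                         tol = .Machine$double.eps^0.5)
  k <- opt$minimum
  ## Gauss-Newton standard error from the local Jacobian
  J <- (2 / sqrt(pi)) * exp(-(k * x)^2) * x
  dof <- max(length(x) - 1, 1)
  list(k = k, stderr = sqrt(opt$objective / dof / sum(J^2)))
}

#' Load-collapse coefficient between a thin-layer curve and a master
#'
#' Determines the scalar `c` such that replotting the thin-layer curve
#' against the rescaled load `c * sigma0` superposes it onto the
#' (half-space) master curve: thin layers reach a given area at lower
#' load, so `c >= 1` and it grows as the layer thins.  Computed as the
#' geometric mean over overlapping points of the ratio between the
#' master's load (log-log interpolated at equal area fraction) and the
#' curve's load.  Restricted to area fractions below `amax`, where the
#' reduced-area statistic is monotone in load.
#'
#' @param curve an `area_load_curve` for the layer of interest.
#' @param master the reference curve (the master returns `c = 1`).
#' @param amin,amax area-fraction overlap window.
#' @return the collapse coefficient `c`.
#' @export
collapse_coefficient <- function(curve, master, amin = 0.02, amax = 0.5) {
  lo <- max(amin, min(master$area_fraction), min(curve$area_fraction))
  hi <- min(amax, max(master$area_fraction), max(curve$area_fraction))
  sel <- curve$area_fraction >= lo & curve$area_fraction <= hi
  if (!any(sel)) stop("no overlapping area-fraction range between the curves")
  msel <- master$area_fraction > 0 & master$sigma0 > 0
  logload <- stats::approx(log(master$area_fraction[msel]),
                           log(master$sigma0[msel]),
                           xout = log(curve$area_fraction[sel]),
                           rule = 1)$y
  ok <- is.finite(logload)
  if (!any(ok)) stop("no overlapping area-fraction range between the curves")
  exp(mean(logload[ok] - log(curve$sigma0[sel][ok])))
}

#' Power-law fit on log-log axes
#'
#' Ordinary least squares of `log(y)` on `log(x)` inside `window`
#' (on x); the slope is the power-law exponent and the exponentiated
#' intercept the prefactor.
#'
#' @param xs,ys positive numeric vectors.
#' @param window abscissa range included in the fit.
#' @return an object of class `"scaling_fit"`: list with `exponent`,
#'   `prefactor`, `window`, `stderr` and `n`.
#' @export
fit_power_exponent <- function(xs, ys, window = range(xs)) {
  if (any(xs <= 0) || any(ys <= 0)) stop("power-law fit needs positive data")
  sel <- xs >= window[1] & xs <= window[2]
  if (sum(sel) < 3) stop("need at least 3 points inside the window")
  fit <- stats::lm(log(ys[sel]) ~ log(xs[sel]))
  ## exact power laws give a zero-residual fit; the se is then just 0
  se <- if (sum(sel) > 2) {
    suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
  } else NA_real_
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 prefactor = exp(unname(stats::coef(fit)[1])),
                 window = window, stderr = se, n = sum(sel)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: exponent %.4f (se %.3g), prefactor %.4g, %d points in [%.3g, %.3g]\n",
              x$exponent, x$stderr, x$prefactor, x$n,
              x$window[1], x$window[2]))
  invisible(x)
}

#' @export
plot.area_load_curve <- function(x, ..., log = "xy") {
  graphics::plot(x$sigma0, x$area_fraction, log = log, type = "b",
                 xlab = expression(sigma[0] / (E * "*" * sqrt(m2))),
                 ylab = expression(A / A[0]), ...)
  invisible(x)
}
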
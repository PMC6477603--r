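#' Generate a periodic self-affine height field
#'
#' Synthesises a random rough surface from a [spectrum_spec()] by the
#' spectral method: every Fourier mode with \eqn{0 < |q| \le q_s} gets a
#' complex amplitude whose real and imaginary parts are drawn
#' independently from a zero-mean uniform distribution with second
#' moment proportional to \eqn{C(|q|)}.  Uniform rather than Gaussian
#' amplitudes avoid rare outlier modes while leaving the spectrum
#' untouched.  Hermitian symmetry is imposed so the height field is
#' real; self-conjugate modes (zero and Nyquist frequencies) are drawn
#' real, and the mean-height mode is set to zero.
#'
#' The finished surface is normalised to root-mean-square gradient
#' `rms_gradient_target` and then shifted so its highest point sits at
#' zero (in that order: the shift does not affect gradients, whereas
#' normalising after shifting would destroy the zero maximum).
#'
#' @param spec a [spectrum_spec()].
#' @param n grid points per side; must be even and at least 8.
#' @param a grid spacing (length).
#' @param seed integer seed; the same seed and spec give a bit-identical
#'   surface.
#' @param rms_gradient_target target rms gradient after normalisation
#'   (dimensionless).  The default 1 reproduces the usual convention for
#'   contact-mechanics scaling studies.
#' @param finalize if `FALSE`, skip normalisation and shifting and
#'   return the raw synthesised field.
#' @return an object of class `"rough_surface"`: list with `heights`
#'   (n x n matrix, length units), `a`, `n`, `seed`, `spec` and
#'   `rms_gradient`.
#' @examples
#' sp <- spectrum_spec(qr = 2 * pi / 64, qs = 2 * pi / 4, H = 0.8)
#' su <- generate_heightfield(sp, n = 64, a = 1, seed = 1)
#' rms_gradient(su)     # 1 by construction
#' max(su$heights)      # 0 by construction
#' @export
generate_heightfield <- function(spec, n, a = 1, seed = 1L,
                                 rms_gradient_target = 1,
                                 finalize = TRUE) {
  stopifnot(inherits(spec, "spectrum_spec"))
  if (n < 8 || n %% 2 != 0) stop("grid size n must be even and >= 8")
  if (spec$qs > pi / a + 1e-12) {
    stop("cut-off wavenumber qs exceeds the Nyquist limit pi/a")
  }
  set.seed(as.integer(seed))
  qmag <- wavenumber_magnitude(n, a)
  Cq <- psd_value(spec, qmag)

  ## target second moment of |H(q)|^2 is proportional to C(q); the
  ## proportionality constant cancels in the rms-gradient normalisation
  s2 <- Cq
  half <- sqrt(3 * s2 / 2)  # uniform on [-half, half] per component => E|H|^2 = s2
  H <- matrix(complex(real = stats::runif(n * n, -1, 1),
                             imaginary = stats::runif(n * n, -1, 1)),
              n, n) * half

  ## Hermitian symmetry: partner of integer frequency k is (n - k) mod n
  k <- c(0:(n / 2), -(n / 2 - 1):-1)
  KX <- matrix(k, n, n)
  KY <- matrix(k, n, n, byrow = TRUE)
  selfc <- (KX %in% c(0L, n / 2)) & (KY %in% c(0L, n / 2))
  dim(selfc) <- c(n, n)
  canon <- (KY > 0 & KY < n / 2) |
    (KY %in% c(0L, n / 2) & KX > 0 & KX < n / 2)
  rev_idx <- c(1L, n:2)
  Hc <- Conj(H[rev_idx, rev_idx])
  mirror <- !canon & !selfc
  H[mirror] <- Hc[mirror]
  H[selfc] <- stats::runif(sum(selfc), -1, 1) * sqrt(3 * s2[selfc])
  H[1, 1] <- 0 + 0i  # mean height carries no information

  heights <- ifft_real(H)
  surf <- structure(
    list(heights = heights, a = a, n = n, seed = as.integer(seed),
         spec = spec, rms_gradient = NA_real_),
    class = "rough_surface")
  surf$rms_gradient <- rms_gradient(surf)

  if (finalize) {
    if (surf$rms_gradient > 0) {
      surf <- normalize_rms_gradient(surf, target = rms_gradient_target)
    }
    surf <- shift_to_zero_max(surf)
  }
  surf
}

#' Root-mean-square gradient of a surface
#'
#' Computed spectrally as \eqn{\sqrt{\sum_q q^2 |H(q)|^2 / N^2}}, the
#' square root of the spectral mean-square slope.  This agrees with
#' centred finite differences up to discretisation error and is exact
#' for band-limited periodic fields.
#'
#' @param surface a `rough_surface`, or a plain numeric matrix (in which
#'   case `a` supplies the spacing).
#' @param a grid spacing, used only for matrix input.
#' @return the dimensionless rms gradient.
#' @export
rms_gradient <- function(surface, a = NULL) {
  if (inherits(surface, "rough_surface")) {
    h <- surface$heights
    a <- surface$a
  } else {
    h <- surface
    if (is.null(a)) a <- 1
  }
  if (length(h) == 0) stop("empty height grid")
  n <- nrow(h)
  q2 <- fft_wavenumbers(n, a)^2
  qmag2 <- outer(q2, q2, "+")
  H <- stats::fft(h)
  sqrt(sum(qmag2 * Mod(H)^2) / length(h)^2)
}

#' Rescale a surface to a prescribed rms gradient
#'
#' Heights are multiplied by `target / rms_gradient(surface)`; the
#' spectral shape (and hence any fitted Hurst exponent) is unchanged.
#'
#' @param surface a `rough_surface`.
#' @param target desired rms gradient (> 0).
#' @return the rescaled `rough_surface`.
#' @export
normalize_rms_gradient <- function(surface, target = 1) {
  stopifnot(inherits(surface, "rough_surface"), target > 0)
  g <- rms_gradient(surface)
  if (g <= 0) stop("cannot normalise a surface with zero rms gradient")
  surface$heights <- surface$heights * (target / g)
  surface$rms_gradient <- rms_gradient(surface)
  surface
}

#' Shift a surface so its highest point is at zero
#'
#' All heights become non-positive; relative heights are unchanged.
#' Applied after gradient normalisation, never before it.
#'
#' @param surface a `rough_surface`.
#' @return the shifted `rough_surface`.
#' @export
shift_to_zero_max <- function(surface) {
  stopifnot(inherits(surface, "rough_surface"))
  surface$heights <- surface$heights - max(surface$heights)
  surface
}

#' Radially averaged power spectral density
#'
#' Squared Fourier magnitudes `|H(q)|^2 / N^2` are averaged in
#' logarithmically spaced bins of the wavevector magnitude.  With this
#' convention the bin averages are proportional to the generating
#' `psd_value()` curve, so the log-log slope between `qr` and `qs`
#' recovers \eqn{-2(1+H)}.
#'
#' @param surface a `rough_surface`.
#' @param nbins number of logarithmic bins between the smallest nonzero
#'   wavenumber and the Nyquist magnitude.
#' @return data frame with columns `q` (geometric-mean bin wavenumber),
#'   `power` (mean squared amplitude over the bin) and `modes` (bin
#'   count).
#' @export
estimate_psd <- function(surface, nbins = 28) {
  stopifnot(inherits(surface, "rough_surface"))
  h <- surface$heights
  n <- nrow(h)
  qmag <- wavenumber_magnitude(n, surface$a)
  P <- Mod(stats::fft(h))^2 / length(h)^2
  nz <- qmag > 0
  q <- qmag[nz]
  p <- P[nz]
  edges <- exp(seq(log(min(q) * 0.999), log(max(q) * 1.001),
                   length.out = nbins + 1))
  bin <- findInterval(q, edges, rightmost.closed = TRUE)
  keep <- tabulate(bin, nbins) > 0
  out <- data.frame(
    q = exp(tapply(log(q), bin, mean)),
    power = tapply(p, bin, mean),
    modes = tabulate(bin, nbins)[keep],
    row.names = NULL)
  if (!is.null(surface$spec)) {
    inband <- out$q >= surface$spec$qr & out$q <= surface$spec$qs
    if (sum(inband) < 3) {
      stop("fewer than 3 radial bins between qr and qs; grid too small")
    }
  }
  out
}

#' Hurst exponent recovered from a radial PSD table
#'
#' Least-squares slope of log power against log wavenumber over the
#' power-law band, converted through slope = -2(1+H).
#'
#' @param psd data frame from [estimate_psd()] (or with columns `q`,
#'   `power`).
#' @param qr,qs band limits for the fit.
#' @return list with `H`, `slope` and `stderr` (of the slope).
#' @export
fit_hurst <- function(psd, qr, qs) {
  sel <- psd$q >= qr & psd$q <= qs & psd$power > 0
  if (sum(sel) < 3) stop("fewer than 3 PSD bins inside the fit band")
  fit <- stats::lm(log(power) ~ log(q), data = psd[sel, ])
  sl <- unname(stats::coef(fit)[2])
  list(H = -sl / 2 - 1, slope = sl,
       stderr = unname(sqrt(diag(stats::vcov(fit)))[2]))
}

#' @export
print.rough_surface <- function(x, ...) {
  cat(sprintf("Periodic rough surface: %d x %d grid, spacing a = %g\n",
              x$n, x$n, x$a))
  cat(sprintf("  rms gradient %.6g, height range [%.4g, %.4g], seed %d\n",
              x$rms_gradient, min(x$heights), max(x$heights), x$seed))
  if (!is.null(x$spec)) {
    cat(sprintf("  spectrum: H = %g, qr = %.4g, qs = %.4g\n",
                x$spec$H, x$spec$qr, x$spec$qs))
  }
  invisible(x)
}

#' @export
plot.rough_surface <- function(x, ...) {
  graphics::image(seq_len(x$n) * x$a, seq_len(x$n) * x$a, x$heights,
                  xlab = "x", ylab = "y", asp = 1,
                  main = "substrate height", useRaster = TRUE, ...)
  invisible(x)
}

#' Write a surface to a portable plain-text grid file
#'
#' A commented header records the grid and spectrum metadata; the body
#' is the row-major height matrix at full double precision, so
#' [read_surface()] round-trips bit-exactly.
#'
#' @param surface a `rough_surface`.
#' @param path output file path.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "rough_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    "# gfmdlayer surface grid v1",
    sprintf("# n %d", surface$n),
    sprintf("# a %.17g", surface$a),
    sprintf("# seed %d", surface$seed),
    if (!is.null(surface$spec)) {
      sprintf("# spectrum qr %.17g qs %.17g H %.17g C0 %.17g",
              surface$spec$qr, surface$spec$qs,
              surface$spec$H, surface$spec$C0)
    },
    sprintf("# rms_gradient %.17g", surface$rms_gradient))
  writeLines(meta, con)
  utils::write.table(
    format(surface$heights, digits = 17, scientific = TRUE, trim = TRUE),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a surface written by [write_surface()]
#'
#' @param path file path.
#' @return a `rough_surface`.
#' @export
read_surface <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getval <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    if (length(ln) == 0) return(NULL)
    as.numeric(strsplit(ln, " +")[[1]][3])
  }
  n <- as.integer(getval("n"))
  a <- getval("a")
  seed <- as.integer(getval("seed"))
  spec <- NULL
  spln <- hdr[grepl("^# spectrum ", hdr)]
  if (length(spln) == 1) {
    tok <- strsplit(spln, " +")[[1]]
    val <- as.numeric(tok[c(4, 6, 8, 10)])
    spec <- spectrum_spec(qr = val[1], qs = val[2], H = val[3], C0 = val[4])
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  heights <- matrix(scan(text = body, quiet = TRUE), n, n, byrow = TRUE)
  ## write.table emitted rows of the matrix as lines (row-major)
  surf <- structure(
    list(heights = heights, a = a, n = n, seed = seed, spec = spec,
         rms_gradient = NA_real_),
    class = "rough_surface")
  surf$rms_gradient <- rms_gradient(surf)
  surf
}
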
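## Discrete Fourier conventions used throughout the package.
##
## A periodic n x n grid with spacing `a` has positions r_i = (i-1)*a,
## i = 1..n, in each direction.  The forward transform is R's unscaled
## fft(); the inverse carries the 1/N factor (N = n^2):
##
##   H = fft(h);   h = Re(fft(H, inverse = TRUE)) / N
##
## Under this convention Parseval reads sum(h^2) = sum(|H|^2)/N, so the
## spatial mean square height is sum(|H|^2)/N^2 and the mean square
## gradient is sum(q^2 |H|^2)/N^2, with q the wavevector magnitude of
## each mode.

#' Signed wavenumbers of the discrete Fourier grid
#'
#' Returns the signed wavenumbers \eqn{q = 2\pi k / (n a)} in standard
#' FFT storage order (non-negative frequencies first, Nyquist at
#' position `n/2 + 1`, then negative frequencies).
#'
#' @param n grid size (even).
#' @param a grid spacing.
#' @return numeric vector of length `n`.
#' @keywords internal
fft_wavenumbers <- function(n, a = 1) {
  stopifnot(n >= 2, n %% 2 == 0, a > 0)
  k <- c(0:(n / 2), -(n / 2 - 1):-1)
  2 * pi * k / (n * a)
}

## n x n matrix of wavevector magnitudes |q|
wavenumber_magnitude <- function(n, a = 1) {
  q <- fft_wavenumbers(n, a)
  sqrt(outer(q^2, q^2, "+"))
}

## inverse transform back to a real field
ifft_real <- function(H) {
  Re(stats::fft(H, inverse = TRUE)) / length(H)
}
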
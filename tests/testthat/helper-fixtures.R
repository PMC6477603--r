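## fixtures built in code: deterministic substrates with known physics

## single-cosine substrate h = h0 * (cos(q x) - 1): periodic, max = 0
cosine_surface <- function(n, k_index = 4L, h0 = 1, a = 1) {
  q <- 2 * pi * k_index / (n * a)
  x <- (seq_len(n) - 1) * a
  heights <- h0 * (cos(q * x) - 1)
  heights <- matrix(heights, n, n)   # varies along rows (x direction)
  surf <- structure(list(heights = heights, a = a, n = n, seed = 0L,
                         spec = NULL, rms_gradient = NA_real_),
                    class = "rough_surface")
  surf$rms_gradient <- rms_gradient(surf)
  attr(surf, "q") <- q
  attr(surf, "h0") <- h0
  surf
}

flat_surface <- function(n, a = 1, level = 0) {
  surf <- structure(list(heights = matrix(level, n, n), a = a, n = n,
                         seed = 0L, spec = NULL, rms_gradient = 0),
                    class = "rough_surface")
  surf
}

matrix_surface <- function(heights, a = 1) {
  surf <- structure(list(heights = heights, a = a, n = nrow(heights),
                         seed = 0L, spec = NULL, rms_gradient = NA_real_),
                    class = "rough_surface")
  surf$rms_gradient <- rms_gradient(surf)
  surf
}

default_spectrum <- function(a = 1, lambda_s = 4 * a, lambda_r = 16 * lambda_s,
                             H = 0.8) {
  spectrum_spec(qr = 2 * pi / lambda_r, qs = 2 * pi / lambda_s, H = H)
}
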
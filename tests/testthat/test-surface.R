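test_that("generated surfaces are real, periodic-spectrum fields with the contract finalization", {
  sp <- default_spectrum()
  su <- generate_heightfield(sp, n = 128, seed = 7)
  expect_true(is.numeric(su$heights))      # imaginary part dropped after ifft
  expect_equal(max(su$heights), 0)
  expect_equal(rms_gradient(su), 1, tolerance = 1e-12)
  ## determinism: same seed, same spec -> bit-identical field
  su2 <- generate_heightfield(sp, n = 128, seed = 7)
  expect_identical(su$heights, su2$heights)
  ## different seed differs
  su3 <- generate_heightfield(sp, n = 128, seed = 8)
  expect_false(identical(su$heights, su3$heights))
})

test_that("synthesis keeps the imaginary content at round-off level", {
  sp <- default_spectrum()
  set.seed(3)
  ## rebuild the complex spectrum as the generator does and measure Im after ifft
  su <- generate_heightfield(sp, n = 64, seed = 3, finalize = FALSE)
  H <- fft(su$heights)
  back <- fft(H, inverse = TRUE) / length(H)
  expect_lt(max(abs(Im(back))), 1e-10 * stats::sd(su$heights))
})

test_that("rms gradient matches the single-mode closed form and finite differences", {
  n <- 64
  su <- cosine_surface(n, k_index = 5, h0 = 2)
  q <- attr(su, "q")
  expect_equal(su$rms_gradient, 2 * q / sqrt(2), tolerance = 1e-12)
  ## centred finite differences agree to discretization error
  h <- su$heights
  dx <- (h[c(2:n, 1), ] - h[c(n, 1:(n - 1)), ]) / 2
  dy <- (h[, c(2:n, 1)] - h[, c(n, 1:(n - 1))]) / 2
  fd <- sqrt(mean(dx^2 + dy^2))
  expect_equal(fd, su$rms_gradient, tolerance = q^2 / 6)
  expect_equal(rms_gradient(flat_surface(32)$heights), 0)
})

test_that("normalisation and shifting obey their exact contracts", {
  sp <- default_spectrum()
  su <- generate_heightfield(sp, n = 64, seed = 1, finalize = FALSE)
  nrm <- normalize_rms_gradient(su, target = 1)
  expect_equal(nrm$rms_gradient, 1, tolerance = 1e-12)
  ## linear scaling: target 0.5 halves heights relative to target 1
  half <- normalize_rms_gradient(su, target = 0.5)
  expect_equal(half$heights, nrm$heights / 2, tolerance = 1e-12)
  ## idempotence
  expect_equal(normalize_rms_gradient(nrm)$heights, nrm$heights,
               tolerance = 1e-14)
  ## shift: max exactly zero, relative heights unchanged
  sh <- shift_to_zero_max(nrm)
  expect_equal(max(sh$heights), 0)
  expect_equal(sh$heights - min(sh$heights),
               nrm$heights - min(nrm$heights), tolerance = 1e-12)
  expect_equal(shift_to_zero_max(sh)$heights, sh$heights)
  ## degenerate input
  expect_error(normalize_rms_gradient(flat_surface(32)), "zero rms gradient")
})

test_that("radial PSD is flat for white noise and power-law for self-affine fields", {
  ## white noise: slope ~ 0 (averaged over seeds)
  pw <- NULL
  for (s in 1:6) {
    set.seed(s)
    su <- matrix_surface(matrix(rnorm(128^2), 128, 128))
    p <- estimate_psd(su)
    pw <- if (is.null(pw)) p$power else pw + p$power
    qv <- p$q
  }
  sel <- qv > 0.2 & qv < 2
  slope <- unname(coef(lm(log(pw[sel]) ~ log(qv[sel])))[2])
  expect_lt(abs(slope), 0.1)

  ## single cosine: power concentrated in one bin
  su <- cosine_surface(64, k_index = 6)
  p <- estimate_psd(su)
  expect_gt(max(p$power) / sum(p$power), 0.999)

  ## generated H = 0.8 surface: band slope near -3.6
  sp <- default_spectrum()
  su <- generate_heightfield(sp, n = 256, seed = 2)
  fit <- fit_hurst(estimate_psd(su), sp$qr, sp$qs)
  expect_equal(fit$slope, -3.6, tolerance = 0.3)
  expect_equal(fit$H, 0.8, tolerance = 0.15)
})

test_that("a spectrum with no modes on the grid yields a flat surface", {
  ## cut-off below the smallest nonzero grid wavenumber: every mode is
  ## outside the band, normalisation is skipped on the zero-gradient field
  sp <- spectrum_spec(qr = 1e-7, qs = 1e-6, H = 0.5)
  su <- generate_heightfield(sp, n = 32, seed = 1)
  expect_equal(su$heights, matrix(0, 32, 32))
  expect_equal(su$rms_gradient, 0)
})

test_that("generator validates its preconditions", {
  sp <- default_spectrum()
  expect_error(generate_heightfield(sp, n = 63, seed = 1), "even")
  ## qs above the Nyquist limit
  bad <- spectrum_spec(qr = 0.1, qs = 4, H = 0.8)
  expect_error(generate_heightfield(bad, n = 64, a = 1, seed = 1), "Nyquist")
})

test_that("surface files round-trip bit-exactly", {
  sp <- default_spectrum()
  su <- generate_heightfield(sp, n = 32, seed = 5)
  tf <- tempfile(fileext = ".dat")
  on.exit(unlink(tf))
  write_surface(su, tf)
  back <- read_surface(tf)
  expect_identical(back$heights, su$heights)
  expect_equal(back$a, su$a)
  expect_equal(back$spec$H, su$spec$H)
})
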
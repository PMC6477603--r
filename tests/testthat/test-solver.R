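test_that("adhesive stress has the exponential gap dependence", {
  z <- matrix(c(0, log(2) * 0.5, 5), 1, 3)
  h <- matrix(0, 1, 3)
  s <- adhesive_stress(z, h, gamma0 = 2, rho = 0.5)
  expect_equal(s[1, 1], 2 / 0.5)                    # gap 0 -> gamma0/rho
  expect_equal(s[1, 2], 2 / (2 * 0.5))              # gap rho ln 2 -> gamma0/(2 rho)
  expect_equal(adhesive_stress(z, h, 0, 0.5), matrix(0, 1, 3))
  ## work of adhesion recovered: integral of stress over the gap = gamma0
  gaps <- seq(0, 60, by = 1e-3)
  sg <- (2 / 0.5) * exp(-gaps / 0.5)
  trap <- (sum(sg) - 0.5 * (sg[1] + sg[length(sg)])) * 1e-3
  expect_equal(trap, 2, tolerance = 1e-6)
  expect_error(adhesive_stress(matrix(-1), matrix(0), 1, 0.5), "negative gap")
})

test_that("enforce_contact projects exactly the violating subset", {
  su <- cosine_surface(16, k_index = 1, h0 = 1)
  st <- list(z = matrix(0.5, 16, 16), v = matrix(1, 16, 16))
  expect_identical(enforce_contact(st, su)$z, st$z)     # all above: no-op
  st2 <- list(z = matrix(-3, 16, 16), v = matrix(1, 16, 16))
  out2 <- enforce_contact(st2, su)
  expect_identical(out2$z, su$heights)                  # all below: full contact
  expect_true(all(out2$v == 0))
  st3 <- list(z = matrix(-1, 16, 16), v = matrix(1, 16, 16))
  out3 <- enforce_contact(st3, su)
  viol <- st3$z < su$heights
  expect_identical(out3$z[viol], su$heights[viol])
  expect_identical(out3$z[!viol], st3$z[!viol])
  expect_true(all(out3$v[viol] == 0) && all(out3$v[!viol] == 1))
})

test_that("total force combines external, elastic and damping terms correctly", {
  n <- 64
  kern <- build_kernel(layer_spec(1, Inf), n)
  flat <- flat_surface(n, level = -100)
  cfg <- solver_config(sigma0 = 0.2, damping = 0.5)
  ## uniform z: pure external force, no elastic part
  st <- list(z = matrix(-1, n, n), v = matrix(0, n, n))
  F <- total_force(st, flat, kern, cfg)
  expect_equal(F, matrix(-0.2, n, n), tolerance = 1e-12)
  ## single cosine displacement at sigma0 = 0: amplitude E* q h0 a^2/(2 f)
  h0 <- 0.4
  w <- 5
  kw <- build_kernel(layer_spec(1, w), n)
  q <- 2 * pi * 3 / n
  z <- h0 * matrix(cos(q * (0:(n - 1))), n, n)
  cfg0 <- solver_config(sigma0 = 0, damping = 0.5)
  F2 <- total_force(list(z = z, v = matrix(0, n, n)), flat, kw, cfg0)
  expect_equal(max(abs(F2)), q * h0 / (2 * finite_width_factor(q * w)),
               tolerance = 1e-10)
  ## nonzero velocity adds -damping * mass * v
  vst <- list(z = matrix(-1, n, n), v = matrix(2, n, n))
  F3 <- total_force(vst, flat, kern, cfg)
  expect_equal(F3, matrix(-0.2 - 0.5 * 2, n, n), tolerance = 1e-12)
})

test_that("undamped Verlet conserves energy at second order in dt", {
  n <- 32
  kern <- build_kernel(layer_spec(1, Inf), n)
  far <- flat_surface(n, level = -1e6)
  set.seed(4)
  z0 <- elastic_stress_field(matrix(rnorm(n * n), n, n), kern)  # smooth field
  z0 <- z0 / max(abs(z0))
  drift <- function(dt) {
    cfg <- solver_config(sigma0 = 0, damping = 0, dt = dt,
                         accelerator = "fixed")
    st <- list(z = z0, v = matrix(0, n, n), step = 0L)
    E0 <- elastic_energy(z0, kern)
    worst <- 0
    for (i in 1:100) {
      st <- verlet_step(st, far, kern, cfg)
      E <- elastic_energy(st$z, kern) + 0.5 * sum(st$v^2)
      worst <- max(worst, abs(E - E0) / E0)
    }
    worst
  }
  dt0 <- choose_timestep(kern)
  e1 <- drift(dt0)
  e2 <- drift(dt0 / 2)
  expect_lt(e1, 0.1)            # bounded oscillation, no secular drift
  expect_gt(e1 / e2, 2.5)       # error scales ~ dt^2
  expect_lt(e1 / e2, 8)
})

test_that("zero force leaves the state unchanged and stability errors are caught", {
  n <- 16
  kern <- build_kernel(layer_spec(1, Inf), n)
  far <- flat_surface(n, level = -10)
  cfg <- solver_config(sigma0 = 0, damping = 0, accelerator = "fixed")
  st <- initial_state(n)
  out <- verlet_step(st, far, kern, cfg)
  expect_equal(out$z, st$z)
  expect_equal(out$v, st$v)
  expect_equal(out$step, 1L)
  ## grossly unstable dt diverges with a clear message
  cfgbad <- solver_config(sigma0 = 0.5, damping = 0,
                          dt = 1e3 * choose_timestep(kern),
                          accelerator = "fixed", max_steps = 500,
                          check_every = 50)
  su <- cosine_surface(n, h0 = 1)
  expect_error(relax(su, kern, cfgbad), "dt")
})

test_that("flat substrate gives immediate full contact with zero deformation", {
  n <- 32
  kern <- build_kernel(layer_spec(1, Inf), n)
  su <- flat_surface(n, level = 0)
  r <- relax(su, kern, solver_config(sigma0 = 0.3))
  expect_equal(r$area_fraction, 1)
  expect_equal(r$Uel, 0)
  expect_equal(r$mean_displacement, 0)
  expect_true(is.na(r$normalized_separation))
  expect_true(r$converged)
})

test_that("single-cosine full contact reproduces the Westergaard-type pressure field", {
  n <- 64
  su <- cosine_surface(n, k_index = 3, h0 = 0.5)
  q <- attr(su, "q")
  for (w in c(Inf, 5)) {
    fqw <- if (is.infinite(w)) 1 else finite_width_factor(q * w)
    kern <- build_kernel(layer_spec(1, w), n)
    pstar <- q * 0.5 / (2 * fqw)           # full-contact threshold
    r <- relax(su, kern, solver_config(sigma0 = 1.3 * pstar))
    expect_equal(r$area_fraction, 1)
    ## p(r) = sigma0 + E* q h0 cos(qx) / (2 f)
    x <- (0:(n - 1))
    expected <- 1.3 * pstar + q * 0.5 * matrix(cos(q * x), n, n) / (2 * fqw)
    expect_equal(max(abs(r$pressure - expected)) / max(expected), 0,
                 tolerance = 5e-3)
  }
})

test_that("relaxation respects feasibility, load balance and determinism", {
  sp <- default_spectrum()
  su <- generate_heightfield(sp, n = 64, seed = 11)
  kern <- build_kernel(layer_spec(1, 4), n = 64)
  cfg <- solver_config(sigma0 = 0.04)
  r1 <- relax(su, kern, cfg)
  r2 <- relax(su, kern, cfg)
  expect_true(r1$converged)
  ## feasibility is exact
  expect_gte(min(r1$gap), 0)
  ## equilibrium load balance: mean reaction pressure equals sigma0
  expect_lt(abs(mean(r1$pressure) - 0.04) / 0.04, 10 * cfg$force_tol)
  ## determinism
  expect_identical(r1$area_fraction, r2$area_fraction)
  expect_identical(r1$state$z, r2$state$z)
})

test_that("contact area is nondecreasing in load and in compliance", {
  sp <- default_spectrum()
  su <- generate_heightfield(sp, n = 64, seed = 11)
  hs <- build_kernel(layer_spec(1, Inf), 64)
  ## 6-point load ladder, warm-started
  loads <- exp(seq(log(0.02), log(0.4), length.out = 6))
  st <- NULL
  areas <- numeric(0)
  for (s0 in loads) {
    r <- relax(su, hs, solver_config(sigma0 = s0), state = st)
    st <- r$state
    areas <- c(areas, r$area_fraction)
  }
  expect_true(all(diff(areas) >= 0))
  ## at fixed load, thinner layers (W = 0.25 < 1 < Inf) make more contact
  a_by_W <- vapply(c(0.25, 1, Inf), function(W) {
    w <- if (is.infinite(W)) Inf else W * 4
    relax(su, build_kernel(layer_spec(1, w), 64),
          solver_config(sigma0 = 0.05))$area_fraction
  }, numeric(1))
  expect_true(all(diff(a_by_W) <= 0))
})

test_that("adhesion contributes energies and the geometric contact definition", {
  n <- 64
  sp <- default_spectrum()
  su <- generate_heightfield(sp, n = n, seed = 2)
  kern <- build_kernel(layer_spec(1, 4), n)
  cfg <- solver_config(sigma0 = 0.05, gamma0 = 5e-4, rho = 0.4)
  r <- relax(su, kern, cfg)
  expect_true(r$converged)
  ## Uad = gamma0 x touching area (range-independent definition)
  expect_equal(r$Uad, 5e-4 * r$area_fraction * n^2)
  expect_equal(r$theta, r$Uel / r$Uad)
  ## the potential-integral variant exceeds the geometric one (gap tail)
  expect_gt(r$Uad_potential, r$Uad)
  ## load balance with adhesion: mean reaction = sigma0 + mean adhesive pull
  adh <- adhesive_stress(r$z, su$heights, 5e-4, 0.4)
  expect_lt(abs(mean(r$pressure) - 0.05 - mean(adh)) / 0.05, 1e-2)
  ## adhesion enlarges contact at equal load
  r0 <- relax(su, kern, solver_config(sigma0 = 0.05))
  expect_gte(r$area_fraction, r0$area_fraction)
})

test_that("non-convergence is reported, not thrown", {
  sp <- default_spectrum()
  su <- generate_heightfield(sp, n = 64, seed = 3)
  kern <- build_kernel(layer_spec(1, Inf), 64)
  r <- relax(su, kern, solver_config(sigma0 = 0.05, max_steps = 10,
                                     check_every = 5))
  expect_false(r$converged)
  expect_true(is.finite(r$residual))
})

test_that("slowest-mode damping follows the modal criterion", {
  n <- 32
  hs <- build_kernel(layer_spec(1, Inf), n)
  thin <- build_kernel(layer_spec(1, 0.5), n)
  ## thin layer has softer slow modes -> smaller damping rate
  expect_lt(choose_damping(thin), choose_damping(hs))
  ## doubling the mass scales the rate by 1/sqrt(2)
  expect_equal(choose_damping(hs, mass = 2) / choose_damping(hs, mass = 1),
               1 / sqrt(2), tolerance = 1e-12)
  ## rate built from the smallest nonzero modal stiffness
  qmin <- 2 * pi / n
  expect_equal(choose_damping(hs), 0.9 * 2 * sqrt(qmin / 2), tolerance = 1e-12)
})
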
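## Damped-Verlet relaxation of the sheet against a rigid substrate.
##
## Geometry and sign conventions:
##   * substrate heights h(r) <= 0, max(h) = 0;
##   * the undeformed sheet starts at z = 0 and first touches the
##     substrate at its highest point;
##   * the external (fluid) pressure sigma0 pushes z downward, so
##     forces toward the substrate are negative;
##   * the mean displacement is u = -<z> >= 0, full contact corresponds
##     to u_max = -<h>.

#' Solver configuration for GFMD relaxation
#'
#' @param sigma0 external/fluid pressure pressing the sheet onto the
#'   substrate (pressure units), >= 0.
#' @param gamma0 work of adhesion per unit area (pressure x length);
#'   0 disables adhesion.
#' @param rho range of the exponential adhesive attraction (length).
#'   Must be positive when adhesion is active; keep it small against
#'   the shortest roughness wavelength so adhesion is short-ranged.
#' @param mass inertial parameter per grid point (arbitrary units; only
#'   the equilibrium matters, so the default 1 fixes the time scale).
#' @param dt time step; `NULL` selects a quarter of the stability
#'   period of the stiffest mode, `0.5 * sqrt(mass / kappa_max)`.
#' @param damping viscous damping rate; `NULL` selects
#'   [choose_damping()], i.e. the slowest elastic mode slightly
#'   underdamped.
#' @param accelerator `"fire"` (default) adapts the damping and time
#'   step on the fly (velocity quenching when the motion turns uphill),
#'   which reaches the same fixed point as plain damped dynamics in far
#'   fewer steps; `"fixed"` integrates with the constant `dt` and
#'   `damping` above.
#' @param max_steps iteration cap.
#' @param force_tol convergence threshold on the relative force
#'   residual, max |net force| over non-contact points / (sigma0 a^2).
#' @param check_every residual/area check interval (steps).
#' @param contact_tol gap below which a point counts as touching
#'   (length units; projection makes true contacts exact).
#' @param keep_fields store the displacement, gap and contact-pressure
#'   grids in the result.
#' @return an object of class `"solver_config"`.
#' @export
solver_config <- function(sigma0, gamma0 = 0, rho = NULL,
                          mass = 1, dt = NULL, damping = NULL,
                          accelerator = c("fire", "fixed"),
                          max_steps = 50000L, force_tol = 1e-4,
                          check_every = 100L, contact_tol = 1e-10,
                          keep_fields = TRUE) {
  accelerator <- match.arg(accelerator)
  stopifnot(sigma0 >= 0, gamma0 >= 0, mass > 0, max_steps >= 1,
            force_tol > 0)
  adhesion <- gamma0 > 0
  if (adhesion && (is.null(rho) || rho <= 0)) {
    stop("adhesion requires a positive range rho")
  }
  structure(list(sigma0 = sigma0, gamma0 = gamma0, rho = rho,
                 adhesion = adhesion, mass = mass, dt = dt,
                 damping = damping, accelerator = accelerator,
                 max_steps = as.integer(max_steps),
                 force_tol = force_tol,
                 check_every = as.integer(check_every),
                 contact_tol = contact_tol,
                 keep_fields = keep_fields),
            class = "solver_config")
}

#' Short-range adhesive stress
#'
#' Exponential attraction \eqn{\sigma_{adh}(r) = (\gamma_0/\rho)
#' \exp[-(z - h)/\rho]} acting toward the substrate.  Its integral over
#' the gap from 0 to infinity is the work of adhesion \eqn{\gamma_0}.
#'
#' @param z sheet displacement grid.
#' @param h substrate height grid (same shape).
#' @param gamma0 work of adhesion per area.
#' @param rho attraction range, > 0.
#' @return grid of attractive stress magnitudes (pressure units).
#' @export
adhesive_stress <- function(z, h, gamma0, rho) {
  stopifnot(all(dim(z) == dim(h)), rho > 0, gamma0 >= 0)
  gap <- z - h
  if (any(gap < -1e-12)) {
    stop("negative gap: enforce the hard-wall constraint before evaluating adhesion")
  }
  (gamma0 / rho) * exp(-pmax(gap, 0) / rho)
}

## modal stiffness grid kappa(q) = a^2 / G(q); 0 at q = 0
modal_stiffness <- function(kernel) kernel$a^2 * kernel$stiffness

#' Damping rate leaving the slowest elastic mode slightly underdamped
#'
#' Returns `0.9 * 2 * sqrt(kappa_min * mass) / mass`, where `kappa_min`
#' is the smallest nonzero modal stiffness `a^2 / G(q)` on the kernel
#' grid; the factor 0.9 keeps that mode just below critical damping.
#'
#' @param kernel an [build_kernel()] result.
#' @param mass inertial parameter per grid point.
#' @return damping rate (1/time).
#' @export
choose_damping <- function(kernel, mass = 1) {
  kap <- modal_stiffness(kernel)
  kmin <- min(kap[kap > 0])
  0.9 * 2 * sqrt(kmin * mass) / mass
}

#' Stable time step for the stiffest mode
#'
#' A quarter of the Verlet stability limit `2 / omega_max` with
#' `omega_max = sqrt(kappa_max / mass)`.
#'
#' @inheritParams choose_damping
#' @return time step.
#' @export
choose_timestep <- function(kernel, mass = 1) {
  kap <- modal_stiffness(kernel)
  kmax <- max(kap[is.finite(kap)])
  0.25 * 2 / sqrt(kmax / mass)
}

## Net force grid (no damping): external + elastic + adhesion.
## The constraint force is implicit in the projection and not included.
net_force <- function(z, substrate, kernel, config) {
  a2 <- kernel$a^2
  Fq <- -stats::fft(z) * kernel$stiffness * a2
  Fq[1, 1] <- -config$sigma0 * a2 * length(z)
  F <- ifft_real(Fq)
  if (config$adhesion) {
    F <- F - adhesive_stress(z, substrate$heights, config$gamma0,
                             config$rho) * a2
  }
  F
}

#' Total force acting on every grid point
#'
#' Sum of the external pressure force `-sigma0 a^2`, the elastic
#' restoring force, the adhesive pull (when enabled) and the viscous
#' damping force `-damping * mass * v`.  The hard-wall constraint force
#' is applied implicitly by [enforce_contact()] and is not part of this
#' sum.
#'
#' @param state solver state: list with displacement grid `z` and
#'   velocity grid `v`.
#' @param substrate a `rough_surface`.
#' @param kernel an `elastic_kernel`.
#' @param config a [solver_config()].
#' @return n x n force grid (force units; negative = toward substrate).
#' @export
total_force <- function(state, substrate, kernel, config) {
  damping <- if (is.null(config$damping)) choose_damping(kernel, config$mass)
             else config$damping
  net_force(state$z, substrate, kernel, config) -
    damping * config$mass * state$v
}

#' Initial solver state
#'
#' The sheet starts flat at `z = 0` (just touching the substrate
#' maximum) and at rest.
#'
#' @param n grid size.
#' @return list with `z`, `v` (n x n grids) and `step = 0`.
#' @export
initial_state <- function(n) {
  list(z = matrix(0, n, n), v = matrix(0, n, n), step = 0L)
}

#' Project penetrating points back onto the substrate
#'
#' Every point with `z < h` is set exactly onto the substrate and its
#' velocity is removed (maximal dissipation at the wall, which aids
#' convergence); all other points are untouched.
#'
#' @param state solver state (`z`, `v`).
#' @param substrate a `rough_surface`.
#' @return the corrected state.
#' @export
enforce_contact <- function(state, substrate) {
  viol <- state$z < substrate$heights
  if (any(viol)) {
    state$z[viol] <- substrate$heights[viol]
    state$v[viol] <- 0
  }
  state
}

#' One damped velocity-Verlet step with hard-wall projection
#'
#' Standard velocity-Verlet update of `z` and `v` under
#' [total_force()], with the viscous term handled semi-implicitly
#' (exactly reduces to plain velocity Verlet at zero damping), followed
#' by [enforce_contact()].  Deterministic given the state.
#'
#' @inheritParams total_force
#' @return the advanced state; `state$accel` caches the acceleration
#'   for the next step.
#' @export
verlet_step <- function(state, substrate, kernel, config) {
  dt <- if (is.null(config$dt)) choose_timestep(kernel, config$mass)
        else config$dt
  damping <- if (is.null(config$damping)) choose_damping(kernel, config$mass)
             else config$damping
  m <- config$mass
  if (is.null(state$accel)) {
    state$accel <- net_force(state$z, substrate, kernel, config) / m
  }
  ed <- damping * dt / 2
  vh <- state$v * (1 - ed) + 0.5 * dt * state$accel
  z_new <- state$z + dt * vh
  viol <- z_new < substrate$heights
  z_new[viol] <- substrate$heights[viol]
  vh[viol] <- 0
  a_new <- net_force(z_new, substrate, kernel, config) / m
  v_new <- (vh + 0.5 * dt * a_new) / (1 + ed)
  v_new[viol] <- 0
  if (any(!is.finite(z_new))) {
    stop("displacement diverged: the time step dt is likely above the stability bound")
  }
  list(z = z_new, v = v_new, accel = a_new,
       step = state$step + 1L)
}

#' Relax the sheet to mechanical equilibrium
#'
#' Iterates damped Verlet steps (with FIRE-style adaptive damping by
#' default, see [solver_config()]) until both the relative force
#' residual on non-contact points drops below `force_tol` and the
#' contact area is stationary to one part in 1e4 over three consecutive
#' checks, or `max_steps` is reached.  Non-convergence is reported via
#' `converged = FALSE`, not an error.
#'
#' @param substrate a `rough_surface` (finalised: max height 0).
#' @param kernel an `elastic_kernel` on the same grid.
#' @param config a [solver_config()].
#' @param state optional warm-start state (e.g. the `state` element of
#'   a previous result at a nearby load).
#' @return an object of class `"gfmd_contact"` with elements
#'   `area_fraction`, `mean_displacement`, `normalized_separation`,
#'   `Uel`, `Uad`, `Uad_potential`, `theta`, `converged`, `iterations`,
#'   `residual`, `state`, and (if `keep_fields`) `z`, `gap`, `contact`
#'   and `pressure` grids.
#' @export
relax <- function(substrate, kernel, config, state = NULL) {
  stopifnot(inherits(substrate, "rough_surface"),
            inherits(kernel, "elastic_kernel"),
            inherits(config, "solver_config"))
  if (substrate$n != kernel$n || abs(substrate$a - kernel$a) > 1e-12) {
    stop("substrate and kernel grids do not match")
  }
  n <- kernel$n
  a2 <- kernel$a^2
  h <- substrate$heights
  m <- config$mass
  dt0 <- if (is.null(config$dt)) choose_timestep(kernel, m) else config$dt
  eta0 <- if (is.null(config$damping)) choose_damping(kernel, m)
          else config$damping
  fire <- config$accelerator == "fire"

  ## force scale for the relative residual
  fscale <- config$sigma0 * a2
  if (fscale <= 0) {
    fscale <- a2 * max(config$gamma0 / max(config$rho, 1e-300),
                       1e-8 * kernel$layer$Estar)
  }

  if (is.null(state)) state <- initial_state(n)
  st <- enforce_contact(list(z = state$z, v = state$v), substrate)
  z <- st$z; v <- st$v
  dt <- dt0
  alpha0 <- 0.1; alpha <- alpha0; ngood <- 0L
  dtmax <- 2.5 * dt0; dtmin <- 0.02 * dt0

  Fo <- net_force(z, substrate, kernel, config)
  area_hist <- numeric(0)
  res <- NA_real_
  converged <- FALSE
  steps_done <- 0L

  for (s in seq_len(config$max_steps)) {
    if (fire) {
      vh <- v + 0.5 * dt * Fo / m
    } else {
      vh <- v * (1 - eta0 * dt / 2) + 0.5 * dt * Fo / m
    }
    z <- z + dt * vh
    viol <- z < h
    if (any(viol)) { z[viol] <- h[viol]; vh[viol] <- 0 }
    Fn <- net_force(z, substrate, kernel, config)
    if (fire) {
      v <- vh + 0.5 * dt * Fn / m
    } else {
      v <- (vh + 0.5 * dt * Fn / m) / (1 + eta0 * dt / 2)
    }
    v[viol] <- 0
    if (fire) {
      P <- sum(v * Fn)
      if (P > 0) {
        ngood <- ngood + 1L
        vn <- sqrt(sum(v^2)); fn <- sqrt(sum(Fn^2))
        if (fn > 0) v <- (1 - alpha) * v + alpha * (vn / fn) * Fn
        if (ngood > 5L) {
          dt <- min(dt * 1.1, dtmax)
          alpha <- alpha * 0.99
        }
      } else {
        v[] <- 0
        dt <- max(dt * 0.5, dtmin)
        alpha <- alpha0
        ngood <- 0L
      }
    }
    Fo <- Fn
    steps_done <- s
    if (any(!is.finite(z))) {
      stop("displacement diverged: the time step dt is likely above the stability bound")
    }
    if (s %% config$check_every == 0L) {
      contact <- (z - h) <= config$contact_tol
      res <- if (all(contact)) 0 else max(abs(Fn[!contact])) / fscale
      ar <- mean(contact)
      area_hist <- c(area_hist, ar)
      nh <- length(area_hist)
      if (res <= config$force_tol && nh >= 3 &&
          diff(range(area_hist[(nh - 2):nh])) <= 1e-4 * max(ar, 1e-12)) {
        converged <- TRUE
        break
      }
    }
  }

  contact <- (z - h) <= config$contact_tol
  area_fraction <- mean(contact)
  u <- -mean(z)
  umax <- -mean(h)
  s_tilde <- if (umax > 0) 1 - u / umax else NA_real_
  Uel <- elastic_energy(z, kernel)
  A_contact <- area_fraction * length(z) * a2
  Uad <- if (config$adhesion) config$gamma0 * A_contact else 0
  Uad_pot <- if (config$adhesion) {
    a2 * config$gamma0 * sum(exp(-pmax(z - h, 0) / config$rho))
  } else 0
  theta <- if (config$adhesion && Uad > 0) Uel / Uad else NA_real_

  out <- list(area_fraction = area_fraction,
              mean_displacement = u,
              normalized_separation = s_tilde,
              Uel = Uel, Uad = Uad, Uad_potential = Uad_pot,
              theta = theta,
              converged = converged, iterations = steps_done,
              residual = res,
              sigma0 = config$sigma0,
              state = list(z = z, v = v, step = steps_done))
  if (config$keep_fields) {
    Fn <- net_force(z, substrate, kernel, config)
    pressure <- matrix(0, n, n)
    pressure[contact] <- -Fn[contact] / a2   # reaction carried by the wall
    out$z <- z
    out$gap <- z - h
    out$contact <- contact
    out$pressure <- pressure
  }
  structure(out, class = "gfmd_contact")
}

#' @export
print.gfmd_contact <- function(x, ...) {
  cat("GFMD contact equilibrium\n")
  cat(sprintf("  load sigma0        : %.6g\n", x$sigma0))
  cat(sprintf("  area fraction A/A0 : %.5f\n", x$area_fraction))
  cat(sprintf("  mean displacement  : %.5g (s_tilde = %.4f)\n",
              x$mean_displacement, x$normalized_separation))
  cat(sprintf("  elastic energy Uel : %.6g\n", x$Uel))
  if (x$Uad > 0) {
    cat(sprintf("  adhesion energy Uad: %.6g (theta = %.4g)\n",
                x$Uad, x$theta))
  }
  cat(sprintf("  %s in %d steps (residual %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  invisible(x)
}

#' @export
summary.gfmd_contact <- function(object, ...) {
  print(object)
  if (!is.null(object$pressure)) {
    p <- object$pressure[object$contact]
    if (length(p)) {
      cat(sprintf("  contact pressure   : mean %.4g, max %.4g\n",
                  mean(p), max(p)))
    }
    cat(sprintf("  mean reaction over cell: %.6g (load balance vs sigma0)\n",
                sum(object$pressure) / length(object$pressure)))
  }
  invisible(object)
}
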
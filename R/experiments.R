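#' Configuration for the standard numerical experiments
#'
#' Bundles surface, layer, load-ladder and solver parameters for the
#' sweep/scan drivers.  Defaults follow the desk-scale study
#' conditions: `lambda_s = 4 a`, `lambda_r = 16 lambda_s`, Hurst
#' exponent 0.8, unit rms gradient, `E* = 1`, and a ladder of 8
#' log-spaced dimensionless loads spanning area fractions of roughly
#' 2\% to 60\%.  Thin-layer ladders are pre-scaled by the
#' Persson-broadening ratio so every width covers a comparable area
#' range.
#'
#' @param n grid points per side.
#' @param a grid spacing.
#' @param lambda_s,lambda_r short-wavelength cut-off and roll-off
#'   wavelengths.
#' @param H Hurst exponent.
#' @param seeds integer vector of surface seeds.
#' @param widths dimensionless widths `W = w / lambda_s` to simulate;
#'   `Inf` denotes the half-space reference.
#' @param Estar contact modulus.
#' @param loads optional explicit dimensionless load ladder for the
#'   half-space; `NULL` builds `n_loads` log-spaced values over
#'   `load_range`.
#' @param n_loads,load_range ladder size and dimensionless load range.
#' @param gamma0,rho adhesion energy per area and range (for the theta
#'   scan).
#' @param area_targets target area fractions of the theta scan.  The
#'   defaults sit in the area range every studied width can actually
#'   reach: with short-range adhesion a very thin sheet snaps into
#'   large contact even at vanishing load (around 44\% of the nominal
#'   area for `W = 0.0625` at the default adhesion strength), so
#'   smaller targets would be unreachable for the thinnest layers.
#' @param force_tol,max_steps solver settings.
#' @return an object of class `"experiment_config"`.
#' @export
experiment_config <- function(n = 512L, a = 1, lambda_s = 4 * a,
                              lambda_r = 16 * lambda_s, H = 0.8,
                              seeds = 1:3,
                              widths = c(0.0625, 0.125, 0.25, 0.5, Inf),
                              Estar = 1, loads = NULL, n_loads = 8L,
                              load_range = c(0.012, 0.35),
                              gamma0 = 0, rho = 0.1 * lambda_s,
                              area_targets = c(0.5, 0.55, 0.6),
                              force_tol = 1e-4, max_steps = 50000L) {
  stopifnot(n %% 2 == 0, length(seeds) >= 1, all(widths > 0))
  if (is.null(loads)) {
    loads <- exp(seq(log(load_range[1]), log(load_range[2]),
                     length.out = n_loads))
  }
  stopifnot(all(loads > 0), !is.unsorted(loads))
  structure(list(n = as.integer(n), a = a, lambda_s = lambda_s,
                 lambda_r = lambda_r, H = H, seeds = as.integer(seeds),
                 widths = widths, Estar = Estar, loads = loads,
                 gamma0 = gamma0, rho = rho, area_targets = area_targets,
                 force_tol = force_tol, max_steps = as.integer(max_steps)),
            class = "experiment_config")
}

## spectrum implied by an experiment config
config_spectrum <- function(config) {
  spectrum_spec(qr = 2 * pi / config$lambda_r,
                qs = 2 * pi / config$lambda_s, H = config$H)
}

## dimensionless-load scale factor for a width: thinner layers reach
## the same area at loads smaller by the broadening ratio
load_scale_for_width <- function(config, W) {
  sp <- config_spectrum(config)
  hs <- persson_broadening(sp, layer_spec(config$Estar, Inf),
                           n = config$n, a = config$a)
  if (is.infinite(W)) return(1)
  persson_broadening(sp, layer_spec(config$Estar, W * config$lambda_s),
                     n = config$n, a = config$a) / hs
}

## warm-started relaxation up a load ladder; returns list of results
run_ladder <- function(substrate, kernel, loads, config,
                       gamma0 = 0, rho = NULL) {
  state <- NULL
  results <- vector("list", length(loads))
  for (i in seq_along(loads)) {
    sc <- solver_config(sigma0 = loads[i], gamma0 = gamma0, rho = rho,
                        force_tol = config$force_tol,
                        max_steps = config$max_steps,
                        keep_fields = FALSE)
    r <- relax(substrate, kernel, sc, state = state)
    state <- r$state
    results[[i]] <- r
  }
  results
}

#' Area-load sweep over widths and seeds
#'
#' For every width and every seed: generate the surface, build the
#' kernel, and relax up the (width-rescaled) load ladder with warm
#' starts.  Non-converged points are flagged in the curve, never
#' dropped.
#'
#' @param config an [experiment_config()].
#' @param widths optional subset of `config$widths`.
#' @return list with `curves` (nested list `curves[[width]][[seed]]` of
#'   [area_load_curve()]s), `table` (all rows bound together with a
#'   `seed` column) and `aggregate` (per width and ladder rung: the
#'   geometric mean over seeds of load and area fraction, with the
#'   log-space spread of the area).
#' @export
run_area_load_sweep <- function(config, widths = config$widths) {
  sp <- config_spectrum(config)
  curves <- list()
  rows <- list()
  for (W in widths) {
    wkey <- format(W)
    w <- if (is.infinite(W)) Inf else W * config$lambda_s
    kern <- NULL
    scale <- load_scale_for_width(config, W)
    curves[[wkey]] <- list()
    for (seed in config$seeds) {
      surf <- generate_heightfield(sp, n = config$n, a = config$a,
                                   seed = seed)
      if (is.null(kern)) {
        kern <- build_kernel(layer_spec(config$Estar, w,
                                        lambda_s = config$lambda_s),
                             n = config$n, a = config$a)
      }
      res <- run_ladder(surf, kern, config$loads * scale * config$Estar,
                        config, gamma0 = config$gamma0, rho = config$rho)
      cur <- area_load_curve(W, res, Estar = config$Estar,
                             rms_grad = surf$rms_gradient)
      cur$seed <- seed
      curves[[wkey]][[as.character(seed)]] <- cur
      rows[[length(rows) + 1L]] <- cur
    }
  }
  tab <- do.call(rbind, rows)
  tab$rung <- stats::ave(tab$sigma0, tab$W, tab$seed,
                         FUN = function(x) rank(x, ties.method = "first"))
  agg <- do.call(rbind, lapply(split(tab, list(tab$W, tab$rung),
                                     drop = TRUE), function(d) {
    data.frame(W = d$W[1], rung = d$rung[1],
               sigma0 = exp(mean(log(d$sigma0))),
               area_fraction = exp(mean(log(pmax(d$area_fraction, 1e-12)))),
               log_area_spread = stats::sd(log(pmax(d$area_fraction, 1e-12))),
               n_seeds = nrow(d))
  }))
  agg <- agg[order(agg$W, agg$rung), ]
  rownames(agg) <- NULL
  list(curves = curves, table = tab, aggregate = agg)
}

#' Width scan of the load-collapse coefficient
#'
#' Runs area-load sweeps for all finite widths plus the half-space
#' master, computes the collapse coefficient `c(W)` against the master
#' (per seed, geometric mean over seeds), and fits the small-W power
#' law of `c(W)`.
#'
#' @param config an [experiment_config()]; `config$widths` must
#'   contain `Inf`.
#' @param fit_max_W upper end of the power-law fit window.
#' @return list with `table` (W, c), `fit` (a `scaling_fit`) and the
#'   underlying `sweep`.
#' @export
run_width_scan <- function(config, fit_max_W = 0.5) {
  if (!any(is.infinite(config$widths))) {
    stop("the width scan needs the half-space master (width Inf) in config$widths")
  }
  sweep <- run_area_load_sweep(config)
  finite_W <- sort(config$widths[is.finite(config$widths)])
  master <- sweep$curves[[format(Inf)]]
  cs <- vapply(finite_W, function(W) {
    percs <- vapply(as.character(config$seeds), function(s) {
      collapse_coefficient(sweep$curves[[format(W)]][[s]], master[[s]])
    }, numeric(1))
    exp(mean(log(percs)))
  }, numeric(1))
  tab <- data.frame(W = finite_W, c = cs)
  fit <- if (sum(tab$W <= fit_max_W) >= 3) {
    fit_power_exponent(tab$W, tab$c, window = c(0, fit_max_W))
  }
  list(table = tab, fit = fit, sweep = sweep)
}

## secant iteration (in logs) for the load reaching a target area
find_load_for_area <- function(substrate, kernel, config, target,
                               curve, results,
                               rel_tol = 0.02, max_iter = 6L) {
  la <- log(curve$area_fraction)
  ls <- log(curve$sigma0)
  if (target < min(curve$area_fraction) || target > max(curve$area_fraction)) {
    return(NULL)   # unreachable within the ladder bounds
  }
  i <- findInterval(log(target), la)
  state <- results[[max(i, 1L)]]$state
  guess <- exp(stats::approx(la, ls, xout = log(target))$y)
  pts <- data.frame(ls = ls, la = la)
  r <- NULL
  for (it in seq_len(max_iter)) {
    sc <- solver_config(sigma0 = guess, gamma0 = config$gamma0,
                        rho = config$rho, force_tol = config$force_tol,
                        max_steps = config$max_steps, keep_fields = FALSE)
    r <- relax(substrate, kernel, sc, state = state)
    state <- r$state
    if (abs(r$area_fraction - target) <= rel_tol * target) break
    pts <- rbind(pts, data.frame(ls = log(guess), la = log(r$area_fraction)))
    pts <- pts[order(pts$la), ]
    guess <- exp(stats::approx(pts$la, pts$ls, xout = log(target),
                               rule = 2)$y)
  }
  r
}

#' Width scan of the adhesion parameter theta
#'
#' For every finite width, relaxes with adhesion up a load ladder, then
#' locates by secant iteration on the load the equilibria whose area
#' fractions hit the configured targets, and records
#' \eqn{\theta = U_{el}/U_{ad}} there.  Fits the small-W power law of
#' theta for each target and reports the mean exponent.
#'
#' @param config an [experiment_config()] with `gamma0 > 0`.
#' @param fit_max_W upper end of the power-law fit window.
#' @return list with `table` (W, target, sigma0, area_fraction, theta),
#'   `fits` (one `scaling_fit` per target), and `exponent` (mean over
#'   targets).
#' @export
run_theta_scan <- function(config, fit_max_W = 0.5) {
  if (config$gamma0 <= 0) stop("the theta scan requires gamma0 > 0")
  sp <- config_spectrum(config)
  finite_W <- sort(config$widths[is.finite(config$widths)])
  seed <- config$seeds[1]
  surf <- generate_heightfield(sp, n = config$n, a = config$a, seed = seed)
  rows <- list()
  for (W in finite_W) {
    kern <- build_kernel(layer_spec(config$Estar, W * config$lambda_s,
                                    lambda_s = config$lambda_s),
                         n = config$n, a = config$a)
    scale <- load_scale_for_width(config, W)
    loads <- config$loads * scale * config$Estar
    res <- run_ladder(surf, kern, loads, config,
                      gamma0 = config$gamma0, rho = config$rho)
    areas <- vapply(res, `[[`, numeric(1), "area_fraction")
    ## auto-extend the ladder until the targets are bracketed (adhesion
    ## sets a floor on the area at vanishing load, so the downward
    ## extension can saturate; such targets stay flagged unreachable)
    extra <- 0L
    while (max(areas) < 1.02 * max(config$area_targets) &&
           max(areas) < 0.95 && extra < 4L) {
      lo <- 1.8 * max(loads)
      sc <- solver_config(sigma0 = lo, gamma0 = config$gamma0,
                          rho = config$rho, force_tol = config$force_tol,
                          max_steps = config$max_steps, keep_fields = FALSE)
      r <- relax(surf, kern, sc, state = res[[length(res)]]$state)
      loads <- c(loads, lo); res <- c(res, list(r))
      areas <- c(areas, r$area_fraction)
      extra <- extra + 1L
    }
    extra <- 0L
    while (min(areas) > 0.98 * min(config$area_targets) && extra < 4L) {
      prev_min <- min(areas)
      lo <- min(loads) / 3
      sc <- solver_config(sigma0 = lo, gamma0 = config$gamma0,
                          rho = config$rho, force_tol = config$force_tol,
                          max_steps = config$max_steps, keep_fields = FALSE)
      r <- relax(surf, kern, sc, state = res[[which.min(loads)]]$state)
      loads <- c(loads, lo); res <- c(res, list(r))
      areas <- c(areas, r$area_fraction)
      extra <- extra + 1L
      if (r$area_fraction > 0.995 * prev_min) break   # adhesion floor
    }
    ord <- order(loads)
    res <- res[ord]
    cur <- area_load_curve(W, res, Estar = config$Estar)
    for (tgt in config$area_targets) {
      r <- find_load_for_area(surf, kern, config, tgt, cur, res)
      rows[[length(rows) + 1L]] <- data.frame(
        W = W, target = tgt,
        sigma0 = if (is.null(r)) NA_real_ else r$sigma0,
        area_fraction = if (is.null(r)) NA_real_ else r$area_fraction,
        theta = if (is.null(r)) NA_real_ else r$theta,
        reached = !is.null(r))
    }
  }
  tab <- do.call(rbind, rows)
  fits <- lapply(config$area_targets, function(tgt) {
    d <- tab[tab$target == tgt & tab$reached & is.finite(tab$theta), ]
    if (nrow(d) >= 3) fit_power_exponent(d$W, d$theta,
                                         window = c(0, fit_max_W))
  })
  names(fits) <- format(config$area_targets)
  exps <- vapply(fits, function(f)
    if (is.null(f)) NA_real_ else f$exponent, numeric(1))
  list(table = tab, fits = fits, exponent = mean(exps, na.rm = TRUE))
}

#' Persson-theory width dependence of the area-load coefficient
#'
#' Evaluates the pressure broadening \eqn{\Delta\sigma(W)} over a width
#' grid and converts it to the low-load area/load proportionality
#' coefficient \eqn{\propto 1/\Delta\sigma}; fits the small-W power
#' law.  Optionally tabulates the simulated low-load coefficient from a
#' previously run sweep for comparison.
#'
#' @param config an [experiment_config()].
#' @param W_grid widths at which to evaluate the theory (defaults to a
#'   log grid over [1e-2, 1e-1], deep in the thin-plate regime).
#' @param sweep optional result of [run_area_load_sweep()] whose
#'   simulated low-load coefficients are appended for matching widths.
#' @return list with `table` (W, delta_sigma, coeff_theory, and
#'   `coeff_sim` where available) and `fit` (a `scaling_fit` of
#'   `coeff_theory` vs W).
#' @export
run_theory_comparison <- function(config,
                                  W_grid = exp(seq(log(1e-2), log(1e-1),
                                                   length.out = 9)),
                                  sweep = NULL) {
  sp <- config_spectrum(config)
  ds <- vapply(W_grid, function(W) {
    persson_broadening(sp, layer_spec(config$Estar, W * config$lambda_s),
                       n = config$n, a = config$a)
  }, numeric(1))
  tab <- data.frame(W = W_grid, delta_sigma = ds, coeff_theory = 1 / ds)
  if (!is.null(sweep)) {
    sim <- vapply(W_grid, function(W) {
      wkey <- format(W)
      if (is.null(sweep$curves[[wkey]])) return(NA_real_)
      mean(vapply(sweep$curves[[wkey]], function(cur) {
        low <- utils::head(cur[cur$area_fraction > 0, ], 3)
        mean(low$area_fraction / low$sigma0)
      }, numeric(1)))
    }, numeric(1))
    tab$coeff_sim <- sim
  }
  fit <- if (length(W_grid) >= 3) {
    fit_power_exponent(tab$W, tab$coeff_theory)
  }
  fit_sim <- if (!is.null(tab$coeff_sim) &&
                 sum(is.finite(tab$coeff_sim)) >= 3) {
    ok <- is.finite(tab$coeff_sim)
    fit_power_exponent(tab$W[ok], tab$coeff_sim[ok])
  }
  list(table = tab, fit = fit, fit_sim = fit_sim)
}
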
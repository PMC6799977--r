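#' Restricted-region threshold
#'
#' The reaction-diffusion equations are only solved where the phase field
#' exceeds `chi = 1/2 + tanh(-3 eps0/epsilon)/2`, i.e. within a band
#' `eps0` outside the `phi = 1/2` contour; activator and inhibitor are
#' held at zero elsewhere.
#'
#' @param epsilon interface width, um
#' @param eps0 margin outside the contour, um
#' @return threshold value (~0.0025 at the defaults)
#' @export
restricted_region_threshold <- function(epsilon = 2, eps0 = 2) {
  0.5 + 0.5 * tanh(-3 * eps0 / epsilon)
}

#' Simulation configuration
#'
#' Assembles the full configuration for the coupled solver: biochemical
#' and mechanical parameters, grid, time stepping, initial condition and
#' variant flags.
#'
#' Variants: `"oscillator"` is the reference model; `"excitable"`
#' overrides `c2 = 30, sigma = 0.1` (rest state stable, waves need a
#' perturbation); `"relaxed-area"` overrides `BS = 0.1` so the cell area
#' can oscillate visibly.
#'
#' @param biochem a [biochem_params()] object
#' @param mech a [mech_params()] object (its `S0` is reset from `r0`)
#' @param grid a [pf_grid()]
#' @param dt time step, s
#' @param T total model time, s
#' @param r0 initial disk radius, um
#' @param seed integer RNG seed
#' @param init_mode `"noise"` (A = R = 0, noise-driven) or
#'   `"asymmetric"` (A = At on the half of the disk with x below the
#'   center, R = 0)
#' @param variant `"oscillator"`, `"excitable"` or `"relaxed-area"`
#' @param record_every trajectory/area recording cadence, s
#' @param snapshot_every full-field snapshot cadence, s (0 = final state
#'   only)
#' @param eps0 restricted-region margin, um
#' @param literal_noise use the per-cell `sqrt(sigma dt)` noise recipe
#'   instead of the spatial-density-normalized `sqrt(sigma dt/(dx dy))`
#'   default
#' @return object of class `sim_config`
#' @export
sim_config <- function(biochem = biochem_params(), mech = mech_params(),
                       grid = pf_grid(), dt = 0.001, T = 100, r0 = 8,
                       seed = 1L, init_mode = c("noise", "asymmetric"),
                       variant = c("oscillator", "excitable", "relaxed-area"),
                       record_every = 1, snapshot_every = 0, eps0 = 2,
                       literal_noise = FALSE) {
  init_mode <- match.arg(init_mode)
  variant <- match.arg(variant)
  if (variant == "excitable") {
    biochem$c2 <- 30
    biochem$sigma <- 0.1
  } else if (variant == "relaxed-area") {
    mech$BS <- 0.1
  }
  mech$S0 <- pi * r0^2
  # explicit stability guards for the forward Euler scheme
  if (mech$gamma * dt / (mech$xi * grid$dx^2) > 0.25)
    stop("CFL guard: gamma * dt / (xi * dx^2) > 0.25; reduce dt")
  if (max(biochem$DA, biochem$DR) * dt / grid$dx^2 > 0.25)
    stop("CFL guard: D * dt / dx^2 > 0.25; reduce dt")
  structure(list(biochem = biochem, mech = mech, grid = grid, dt = dt,
                 T = T, r0 = r0, seed = as.integer(seed),
                 init_mode = init_mode, variant = variant,
                 record_every = record_every,
                 snapshot_every = snapshot_every, eps0 = eps0,
                 literal_noise = literal_noise),
            class = "sim_config")
}

#' Gaussian noise increment field
#'
#' One Wiener-process increment for a concentration field on a grid with
#' cell size `dx * dy`: per-cell standard deviation
#' `sqrt(sigma dt/(dx dy))` (the spatial-density normalization implied by
#' the units of `sigma`, uM^2/um^2/s), or `sqrt(sigma dt)` when
#' `literal = TRUE`.
#'
#' @param sigma noise intensity, uM^2/um^2/s
#' @param dt time step, s
#' @param dx,dy grid spacings, um
#' @param n number of draws (grid cells)
#' @param literal drop the 1/(dx dy) density factor
#' @return numeric vector of length `n`, uM
#' @export
noise_increment <- function(sigma, dt, dx, dy = dx, n, literal = FALSE) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(numeric(n))
  amp <- if (literal) sqrt(sigma * dt) else sqrt(sigma * dt / (dx * dy))
  amp * rnorm(n)
}

#' Run the coupled phase-field / reaction-diffusion simulation
#'
#' Alternates, at every time step, a forward-Euler update of the phase
#' field under the force balance (protrusion + tension + area
#' conservation over friction) with a forward-Euler update of the masked
#' reaction-diffusion equations using the product-rule discretization of
#' `d(phi A)/dt` (both the pre- and post-update phase field enter).  The
#' reaction-diffusion solve is restricted to `phi > chi`
#' ([restricted_region_threshold()]); concentrations are held at zero
#' outside.  Small noise-driven negative excursions of A or R are clipped
#' to zero and counted.
#'
#' @param config a [sim_config()]
#' @param eta_final if supplied, the protrusive strength is ramped
#'   linearly from `mech$eta` to this value over the run (used by
#'   quasi-static sweeps)
#' @param init_state optional list with `phi`, `A`, `R` matrices to warm
#'   start from (e.g. the `final` element of a previous run)
#' @return object of class `sim_output`: list with `trajectory`
#'   (data.frame t, x, y, area, eta), `snapshots`, `final` state fields,
#'   `clip_count` and the echoed `config`
#' @export
run_sim <- function(config, eta_final = NULL, init_state = NULL) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$grid
  if (!is.null(init_state)) {
    phi <- init_state$phi; A <- init_state$A; R <- init_state$R
    stopifnot(nrow(phi) == g$nx, ncol(phi) == g$ny)
  } else {
    phi <- init_disk(config$r0, g, config$mech$epsilon)
    A <- matrix(0, g$nx, g$ny)
    R <- matrix(0, g$nx, g$ny)
    if (config$init_mode == "asymmetric") {
      co <- grid_coords(g)
      left <- outer(co$x < g$Lx / 2, rep(TRUE, g$ny))
      A[phi > 0.5 & left] <- config$biochem$At
    }
  }
  chi <- restricted_region_threshold(config$mech$epsilon, config$eps0)
  p <- c(unclass(config$biochem), unclass(config$mech), list(chi = chi))
  nsteps <- round(config$T / config$dt)
  rec_traj <- max(1L, round(config$record_every / config$dt))
  rec_snap <- if (config$snapshot_every > 0)
    max(1L, round(config$snapshot_every / config$dt)) else 0L
  set.seed(config$seed)
  out <- cell2d_run_cpp(phi, A, R, p, g$dx, g$dy, config$dt, nsteps,
                        rec_traj, rec_snap,
                        if (is.null(eta_final)) -1 else eta_final,
                        config$literal_noise)
  out$config <- config
  for (f in c("phi", "A", "R")) {
    attr(out$final[[f]], "grid") <- g
    attr(out$final[[f]], "epsilon") <- config$mech$epsilon
  }
  class(out) <- "sim_output"
  out
}

#' @export
print.sim_output <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf(paste0("Coupled simulation: %.0f s model time, %d trajectory",
                     " points, %d snapshots\n"),
              max(tr$t), nrow(tr), length(x$snapshots)))
  v <- mean_speed(sim_trajectory(x))
  cat(sprintf("  mean post-transient speed %.4f um/s; final area %.1f um^2\n",
              v, tail(tr$area, 1)))
  invisible(x)
}

#' Convert between simulation and physical units
#'
#' The biochemical timescales are compressed in simulation units to keep
#' runs short; the mapping to physical units multiplies times by 5,
#' divides speeds by 5 and doubles the inhibitor timescale `tau`.  This
#' is pure bookkeeping, never applied inside the solver.
#'
#' @param quantity numeric value(s) in simulation units
#' @param kind one of `"time"`, `"speed"`, `"tau"`
#' @return value(s) in physical units
#' @export
#' @examples
#' to_physical(0.6, "speed")  # 0.12 um/s
to_physical <- function(quantity, kind = c("time", "speed", "tau")) {
  kind <- match.arg(kind)
  switch(kind,
         time = quantity * 5,
         speed = quantity / 5,
         tau = quantity * 2)
}
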
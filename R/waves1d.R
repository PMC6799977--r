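#' Simulate the 1D reaction-diffusion system
#'
#' Forward-Euler integration of the activator-inhibitor system on a line,
#' used to measure traveling-front speeds and wave-train spacings.
#'
#' Initial conditions: `init = "bump"` places an excited slab
#' (`A = At`) of width `bump_width` at the left end over a uniform
#' inhibitor background `R_bg`; `init = "ring_pulse"` seeds one period of
#' the well-mixed limit cycle around a periodic ring, i.e. a
#' traveling-pulse ansatz whose refractory tail fills the ring (the ring
#' length then plays the role of the wave-train spacing); `init = "custom"`
#' takes `A0`/`R0` vectors.
#'
#' @param p a [biochem_params()] object
#' @param L domain length, um
#' @param dx grid spacing, um
#' @param dt time step, s
#' @param T duration, s
#' @param init `"bump"`, `"ring_pulse"` or `"custom"`
#' @param bc `"noflux"` or `"periodic"` (forced periodic for ring_pulse)
#' @param bump_width excited-slab width, um
#' @param R_bg uniform inhibitor background for `"bump"`, uM
#' @param A0,R0 custom initial fields
#' @param clamp_R freeze the inhibitor at its initial profile
#' @param sigma noise intensity (0 = deterministic)
#' @param record_every recording cadence, s
#' @param n_pulses number of limit-cycle pulses laid around a
#'   `"ring_pulse"` domain
#' @return object of class `wave_history`: list with `t`, `x`, `A`, `R`
#'   (time-by-space matrices) and the parameter echo
#' @export
simulate_front_1d <- function(p = biochem_params(), L = 100, dx = 0.1,
                              dt = 0.001, T = 60,
                              init = c("bump", "ring_pulse", "custom"),
                              bc = c("noflux", "periodic"),
                              bump_width = 5, R_bg = 0, A0 = NULL, R0 = NULL,
                              clamp_R = FALSE, sigma = 0, record_every = 0.5,
                              n_pulses = 1) {
  init <- match.arg(init)
  bc <- match.arg(bc)
  if (max(p$DA, p$DR) * dt / dx^2 > 0.25)
    stop("CFL guard: D * dt / dx^2 > 0.25; reduce dt or coarsen dx")
  nx <- round(L / dx)
  x <- (seq_len(nx) - 0.5) * dx
  if (init == "bump") {
    A0 <- ifelse(x < bump_width, p$At, 0)
    R0 <- rep(R_bg, nx)
  } else if (init == "ring_pulse") {
    bc <- "periodic"
    cyc <- limit_cycle(p)
    period <- cyc$period
    # phase grows with distance behind each front (fronts move +x);
    # compress one full cycle onto each of the n_pulses ring segments
    seg <- L / n_pulses
    phase <- ((-x) %% seg) / seg * period
    A0 <- approx(cyc$t, cyc$A, phase, rule = 2)$y
    R0 <- approx(cyc$t, cyc$R, phase, rule = 2)$y
  } else {
    stopifnot(length(A0) == nx, length(R0) == nx)
  }
  rec <- max(1L, round(record_every / dt))
  out <- rd1d_run_cpp(A0, R0, p, dx, dt, round(T / dt), rec,
                      if (bc == "periodic") 0L else 1L, 0L, clamp_R, sigma,
                      numeric(4))
  structure(list(t = out$t, x = x, A = out$A, R = out$R, params = p,
                 bc = bc, clip_count = out$clip_count),
            class = "wave_history")
}

# one period of the well-mixed limit cycle, aligned to start at the
# upward crossing of A through the fixed point (the wave front)
limit_cycle <- function(p, T = 400, dt = 0.001) {
  wm <- simulate_well_mixed(p, T = T, dt = dt, record_every = 0.02)
  if (!length(wm$crossings) || is.na(wm$period))
    stop("parameters do not sustain a limit cycle")
  t0 <- wm$crossings[length(wm$crossings) - 1]
  t1 <- wm$crossings[length(wm$crossings)]
  keep <- wm$series$t >= t0 & wm$series$t <= t1
  list(t = wm$series$t[keep] - t0, A = wm$series$A[keep],
       R = wm$series$R[keep], period = t1 - t0)
}

# front positions (level crossings) in one spatial profile
front_positions <- function(A, x, threshold, direction = c("down", "up")) {
  direction <- match.arg(direction)
  nx <- length(x)
  dx <- x[2] - x[1]
  if (direction == "down") {
    i <- which(A[-nx] >= threshold & A[-1] < threshold)
    if (!length(i)) return(numeric(0))
    x[i] + dx * (A[i] - threshold) / (A[i] - A[i + 1])
  } else {
    i <- which(A[-nx] < threshold & A[-1] >= threshold)
    if (!length(i)) return(numeric(0))
    x[i] + dx * (threshold - A[i]) / (A[i + 1] - A[i])
  }
}

#' Measure speed and wavelength of a simulated wave
#'
#' Locates the activator front as the `A = At/2` level crossing in each
#' recorded profile, tracks the leading front, and fits its position
#' against time over the second half of the record.  The front is flagged
#' `steady` when the fit has R^2 > 0.99 and the front amplitude sits
#' within 5% of its plateau.  When several fronts coexist in the final
#' profiles their mean spacing is reported as the wavelength.
#'
#' @param history a `wave_history` from [simulate_front_1d()]
#' @param threshold crossing level, uM (default At/2)
#' @param side `"right"` or `"left"`: which propagation direction to track
#' @param min_cells minimum front displacement, in grid cells, for a
#'   speed estimate
#' @return object of class `wave_measurement`: list with `speed`,
#'   `r_squared`, `steady`, `wavelength`, `front_positions`
#'   (data.frame t, x), `n_fronts`
#' @export
measure_wave <- function(history, threshold = history$params$At / 2,
                         side = c("right", "left"), min_cells = 10) {
  side <- match.arg(side)
  x <- history$x; ts <- history$t
  dx <- x[2] - x[1]
  dirn <- if (side == "right") "down" else "up"
  pos <- rep(NA_real_, length(ts))
  amp <- rep(NA_real_, length(ts))
  L <- max(x) + dx / 2
  prev <- NA_real_
  for (k in seq_along(ts)) {
    A <- history$A[k, ]
    fp <- front_positions(A, x, threshold, dirn)
    if (!length(fp)) next
    if (is.na(prev)) {
      p <- if (side == "right") max(fp) else min(fp)
    } else {
      dd <- fp - (prev %% L)
      if (history$bc == "periodic") {
        dd <- (dd + L / 2) %% L - L / 2
      }
      p <- prev + dd[which.min(abs(dd))]
    }
    prev <- p
    pos[k] <- p
    amp[k] <- max(A)
  }
  ok <- !is.na(pos)
  if (sum(ok) < 4)
    return(structure(list(speed = NA_real_, r_squared = NA_real_,
                          steady = FALSE, wavelength = NA_real_,
                          front_positions = NULL, n_fronts = 0L),
                     class = "wave_measurement"))
  late <- ok & ts > (min(ts) + max(ts)) / 2
  res <- list(front_positions = data.frame(t = ts[ok], x = pos[ok]))
  if (sum(late) >= 4 &&
      abs(diff(range(pos[late]))) >= min_cells * dx) {
    fit <- lm(pos[late] ~ ts[late])
    res$speed <- unname(coef(fit)[2])
    # suppress the essentially-perfect-fit warning on constructed inputs
    res$r_squared <- suppressWarnings(summary(fit)$r.squared)
    plateau <- median(amp[late], na.rm = TRUE)
    amp_ok <- all(abs(amp[late] - plateau) <= 0.05 * plateau, na.rm = TRUE)
    res$steady <- res$r_squared > 0.99 && amp_ok
  } else if (sum(late) >= 4) {
    res$speed <- 0
    res$r_squared <- NA_real_
    res$steady <- stats::var(pos[late]) < (dx / 2)^2
  } else {
    res$speed <- NA_real_; res$r_squared <- NA_real_; res$steady <- FALSE
  }
  # wavelength from spacing of coexisting fronts in the last profiles
  spacings <- c()
  nlast <- max(1L, round(length(ts) * 0.2))
  for (k in tail(seq_along(ts), nlast)) {
    fp <- sort(front_positions(history$A[k, ], x, threshold, dirn))
    if (length(fp) >= 2) {
      sp <- diff(fp)
      if (history$bc == "periodic") sp <- c(sp, L - sum(sp))
      spacings <- c(spacings, sp)
    }
  }
  res$wavelength <- if (length(spacings)) mean(spacings) else NA_real_
  res$n_fronts <- length(front_positions(history$A[length(ts), ], x,
                                         threshold, dirn))
  structure(res, class = "wave_measurement")
}

#' @export
print.wave_measurement <- function(x, ...) {
  cat(sprintf("wave: speed = %.4f um/s (R^2 = %.4f, %s), wavelength = %s um\n",
              x$speed, x$r_squared,
              if (isTRUE(x$steady)) "steady" else "unsteady",
              if (is.na(x$wavelength)) "NA" else sprintf("%.2f", x$wavelength)))
  invisible(x)
}

#' Analytic front speed of the cubic bistable equation
#'
#' For `du/dt = D u'' + k (u - u1)(u2 - u)(u - u3)` with ordered roots
#' `u1 < u2 < u3`, the unique front connecting `u1` and `u3` travels at
#' `c = sqrt(k D / 2) (u1 - 2 u2 + u3)`; positive speed means the `u3`
#' state invades.
#'
#' @param k reaction rate, 1/s (per uM^2)
#' @param D diffusion coefficient, um^2/s
#' @param u1,u2,u3 ordered roots
#' @return speed, um/s
#' @export
cubic_front_speed <- function(k, D, u1, u2, u3) {
  if (!(u1 < u2 && u2 < u3)) stop("roots must satisfy u1 < u2 < u3")
  sqrt(k * D / 2) * (u1 - 2 * u2 + u3)
}

#' Simulate a cubic-reaction front (oracle cross-check)
#'
#' Runs the single-field bistable equation used by [cubic_front_speed()]
#' so the analytic speed can be checked against the discretized solver.
#'
#' @param k,D,u1,u2,u3 as in [cubic_front_speed()]
#' @param L,dx,dt,T,record_every numerics as in [simulate_front_1d()]
#' @return a `wave_history` (with `At` set to `u1 + u3` so the default
#'   measurement threshold is the mid-level)
#' @export
simulate_cubic_front <- function(k, D, u1, u2, u3, L = 60, dx = 0.05,
                                 dt = 5e-4, T = 30, record_every = 0.25) {
  if (D * dt / dx^2 > 0.25) stop("CFL guard: D * dt / dx^2 > 0.25")
  nx <- round(L / dx)
  x <- (seq_len(nx) - 0.5) * dx
  A0 <- ifelse(x < 5, u3, u1)
  p <- biochem_params(DA = D, DR = 0)
  p$At <- u1 + u3  # so threshold At/2 = mid-level
  out <- rd1d_run_cpp(A0, rep(0, nx), p, dx, dt, round(T / dt),
                      max(1L, round(record_every / dt)), 1L, 1L, TRUE, 0,
                      c(k, u1, u2, u3))
  structure(list(t = out$t, x = x, A = out$A, R = out$R, params = p,
                 bc = "noflux", clip_count = 0),
            class = "wave_history")
}

#' Minimum stable wave speed and spacing from ring pulses
#'
#' A pulse circulating on a periodic ring of length `L` is an infinite
#' wave train of spacing `L`: each front propagates into the refractory
#' tail of the previous passage.  Shrinking the ring compresses the
#' train until the front can no longer outrun the inhibitor left behind
#' and propagation fails.  The smallest ring that still carries a steady
#' pulse gives the minimum stable spacing (the wavelength of the densest
#' train) and the speed measured there is the minimum stable wave speed.
#'
#' The measurement threshold is set relative to the late-time pulse
#' amplitude, since marginal trains run at reduced amplitude; a ring
#' whose late amplitude falls below `0.3` uM is counted as dead.  With
#' `continue = TRUE` each shorter ring is warm-started from the previous
#' ring's final profile (adiabatic continuation), which follows the
#' stable train branch all the way to its fold; a cold start from the
#' well-mixed-cycle ansatz instead probes which spacings a freshly
#' nucleated train can sustain.
#'
#' @param p a [biochem_params()] object
#' @param lambdas candidate ring lengths (spacings), um, scanned in
#'   decreasing order
#' @param T integration time per ring, s
#' @param dx,dt numerics
#' @param continue warm-start each ring from the previous one
#' @return list with `table` (data.frame lambda, speed, r_squared,
#'   amplitude, steady), `lambda_min`, `c_min`
#' @export
ring_pulse_scan <- function(p = biochem_params(), lambdas = seq(30, 8, by = -2),
                            T = 150, dx = 0.1, dt = 0.001, continue = FALSE) {
  rows <- NULL
  state <- NULL
  for (L in sort(lambdas, decreasing = TRUE)) {
    if (continue && !is.null(state)) {
      nx <- round(L / dx)
      sold <- seq(0, 1, length.out = length(state$A))
      snew <- seq(0, 1, length.out = nx)
      h <- simulate_front_1d(p, L = L, dx = dx, dt = dt, T = T,
                             init = "custom", bc = "periodic",
                             A0 = approx(sold, state$A, snew)$y,
                             R0 = approx(sold, state$R, snew)$y)
    } else {
      h <- simulate_front_1d(p, L = L, dx = dx, dt = dt, T = T,
                             init = "ring_pulse")
    }
    amp <- max(h$A[nrow(h$A), ])
    alive <- amp > 0.3
    m <- if (alive) measure_wave(h, threshold = 0.45 * amp)
         else measure_wave(h)
    steady <- alive && isTRUE(m$steady) && is.finite(m$speed) && m$speed > 0
    rows <- rbind(rows, data.frame(lambda = L, speed = m$speed,
                                   r_squared = m$r_squared,
                                   amplitude = amp, steady = steady))
    if (steady) state <- list(A = h$A[nrow(h$A), ], R = h$R[nrow(h$R), ])
    else if (continue) break
  }
  stable <- rows[rows$steady, , drop = FALSE]
  list(table = rows,
       lambda_min = if (nrow(stable)) min(stable$lambda) else NA_real_,
       c_min = if (nrow(stable)) stable$speed[which.min(stable$lambda)]
               else NA_real_)
}

#' Establish a wave train on a long 1D domain
#'
#' Seeds `k` equally spaced pulses of the well-mixed-cycle ansatz on a
#' periodic domain of length `L` (at least 100 um for a meaningful
#' spacing statistic), starting from the largest `k` requested and
#' decreasing until a train survives, then measures the realized mean
#' front spacing and speed.
#'
#' @param p a [biochem_params()] object
#' @param L domain length, um
#' @param k_values numbers of pulses to try (descending = densest first)
#' @param T integration time, s
#' @param dx,dt numerics
#' @return list with `k`, `spacing` (um), `speed` (um/s), `table` of
#'   attempts
#' @export
wave_train_1d <- function(p = biochem_params(), L = 112,
                          k_values = 9:4, T = 150, dx = 0.1, dt = 0.001) {
  k_values <- sort(k_values, decreasing = TRUE)
  rows <- NULL
  for (k in k_values) {
    h <- simulate_front_1d(p, L = L, dx = dx, dt = dt, T = T,
                           init = "ring_pulse", n_pulses = k)
    amp <- max(h$A[nrow(h$A), ])
    alive <- amp > 0.3
    m <- if (alive) measure_wave(h, threshold = 0.45 * amp)
         else measure_wave(h)
    ok <- alive && isTRUE(m$steady) && is.finite(m$speed) && m$speed > 0 &&
      m$n_fronts == k
    rows <- rbind(rows, data.frame(k = k, spacing = L / k, survived = ok,
                                   speed = m$speed,
                                   measured_spacing = m$wavelength))
    if (ok)
      return(list(k = k, spacing = m$wavelength, speed = m$speed,
                  table = rows))
  }
  list(k = NA_integer_, spacing = NA_real_, speed = NA_real_, table = rows)
}

#' Scan the minimum wave speed over inhibitor parameters
#'
#' Runs [ring_pulse_scan()] for each combination of inhibitor diffusion
#' `DR` and timescale `tau`; the front is only stable when it outruns the
#' inhibitor's spread (~ `sqrt(DR/tau)`), so `c_min` grows with `DR` and
#' with `1/tau`.
#'
#' @param p_base base [biochem_params()]
#' @param DR_values,tau_values scan grids (positive)
#' @param lambdas,T,dx,dt forwarded to [ring_pulse_scan()]
#' @return data.frame with columns DR, tau, c_min, lambda_min, stable
#' @export
min_speed_scan <- function(p_base = biochem_params(), DR_values = c(0.25, 0.5, 1),
                           tau_values = c(5, 10, 20),
                           lambdas = seq(26, 8, by = -2), T = 120,
                           dx = 0.1, dt = 0.001) {
  stopifnot(all(DR_values >= 0), all(tau_values > 0))
  rows <- NULL
  for (DR in DR_values) for (tau in tau_values) {
    p <- p_base; p$DR <- DR; p$tau <- tau
    res <- tryCatch(ring_pulse_scan(p, lambdas, T, dx, dt),
                    error = function(e) NULL)
    rows <- rbind(rows, data.frame(
      DR = DR, tau = tau,
      c_min = if (is.null(res)) NA_real_ else res$c_min,
      lambda_min = if (is.null(res)) NA_real_ else res$lambda_min,
      stable = !is.null(res) && is.finite(res$c_min)))
  }
  rows
}

#' Diffusion-decay wavelength estimate
#'
#' Order-of-magnitude estimate of the activator wave spacing from the
#' inhibitor's diffusion-decay length, `lambda = 2 sqrt(D tau)`.
#'
#' @param D diffusion coefficient, um^2/s
#' @param tau inhibitor timescale, s
#' @return wavelength, um
#' @export
wavelength_estimate <- function(D, tau) {
  if (any(D <= 0) || any(tau <= 0)) stop("D and tau must be > 0")
  2 * sqrt(D * tau)
}
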
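#' Biochemical parameters of the activator-inhibitor oscillator
#'
#' Rate constants and diffusion coefficients of the two-component
#' relaxation oscillator.  The activator A (standing in for PtdIns
#' phosphates) self-activates through a Hill term and is degraded by the
#' inhibitor R (standing in for PTEN); R is linearly activated by A on a
#' slow timescale `tau`:
#' \deqn{dA/dt = F(A) - G(R)A, \quad F(A) = [k_a A^2/(K_a^2+A^2) + b](A_t - A),
#'   \quad G(R) = d_1 + d_2 R}
#' \deqn{dR/dt = (c_2 A - c_1 R)/\tau}
#' Defaults are the model's reference parameter set.
#'
#' @param DA,DR diffusion coefficients of activator and inhibitor, um^2/s
#' @param ka activation rate, 1/s
#' @param Ka activation threshold, uM
#' @param b basal activation rate, 1/s
#' @param At total activator concentration, uM
#' @param d1 basal degradation rate, 1/s
#' @param d2 degradation rate from inhibitor, 1/(uM s)
#' @param c1 inhibitor degradation coefficient (dimensionless)
#' @param c2 inhibitor activation coefficient (dimensionless)
#' @param tau inhibitor timescale, s
#' @param sigma noise intensity, uM^2/um^2/s
#' @return an object of class `biochem_params` (named list)
#' @export
#' @examples
#' p <- biochem_params()
#' reaction_terms(0, 0, p)  # basal production b*At
biochem_params <- function(DA = 0.5, DR = 0.5, ka = 10, Ka = 1, b = 0.1,
                           At = 2, d1 = 1, d2 = 1, c1 = 1, c2 = 15,
                           tau = 10, sigma = 0.01) {
  p <- list(DA = DA, DR = DR, ka = ka, Ka = Ka, b = b, At = At,
            d1 = d1, d2 = d2, c1 = c1, c2 = c2, tau = tau, sigma = sigma)
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("biochemical parameters must be finite")
  if (any(vals[c("DA", "DR", "ka", "Ka", "b", "d1", "d2", "c1", "c2",
                 "sigma")] < 0))
    stop("rates and diffusion coefficients must be >= 0")
  if (At <= 0) stop("At must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  structure(p, class = "biochem_params")
}

#' @export
print.biochem_params <- function(x, ...) {
  cat("Activator-inhibitor oscillator parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Reaction terms of the oscillator
#'
#' Evaluates the local (well-mixed) reaction rates; vectorized over `A`
#' and `R`.
#'
#' @param A activator concentration, uM (>= 0)
#' @param R inhibitor concentration, uM (>= 0)
#' @param p a [biochem_params()] object
#' @return list with components `dA` and `dR`, uM/s
#' @export
reaction_terms <- function(A, R, p = biochem_params()) {
  if (any(A < 0) || any(R < 0)) stop("concentrations must be non-negative")
  FA <- (p$ka * A^2 / (p$Ka^2 + A^2) + p$b) * (p$At - A)
  list(dA = FA - (p$d1 + p$d2 * R) * A,
       dR = (p$c2 * A - p$c1 * R) / p$tau)
}

#' Nullclines of the oscillator
#'
#' The activator nullcline solves `dA/dt = 0` for R, i.e.
#' `R = (F(A)/A - d1)/d2` (singular at A = 0, reported as `NA`); the
#' inhibitor nullcline is the line `R = c2 A / c1`.
#'
#' @param p a [biochem_params()] object
#' @param A_grid activator sample points in `[0, At)`
#' @return data.frame with columns `A`, `R_act`, `R_inh`
#' @export
nullclines <- function(p = biochem_params(),
                       A_grid = seq(0, p$At * 0.999, length.out = 400)) {
  if (any(A_grid < 0) || any(A_grid >= p$At))
    stop("A_grid must lie in [0, At)")
  FA <- (p$ka * A_grid^2 / (p$Ka^2 + A_grid^2) + p$b) * (p$At - A_grid)
  R_act <- ifelse(A_grid > 0, (FA / A_grid - p$d1) / p$d2, NA_real_)
  data.frame(A = A_grid, R_act = R_act, R_inh = p$c2 * A_grid / p$c1)
}

#' Interior fixed point of the oscillator and its stability
#'
#' Finds the intersection of the two nullclines by a bracketed scalar
#' root search on `F(A) - (d1 + d2 c2 A / c1) A = 0` in `(0, At)`, then
#' classifies stability from the eigenvalues of the analytic 2x2 Jacobian
#' of the reaction terms.
#'
#' @param p a [biochem_params()] object
#' @param tol root tolerance (uM)
#' @return object of class `fixed_point`: list with `A_star`, `R_star`,
#'   `stable`, `eigenvalues`, or with `exists = FALSE` when no interior
#'   root is bracketed.
#' @export
fixed_point <- function(p = biochem_params(), tol = 1e-12) {
  g <- function(A) {
    FA <- (p$ka * A^2 / (p$Ka^2 + A^2) + p$b) * (p$At - A)
    FA - (p$d1 + p$d2 * p$c2 * A / p$c1) * A
  }
  lo <- 1e-12; hi <- p$At - 1e-12
  if (g(lo) * g(hi) > 0) {
    # scan for a sign change before giving up
    As <- seq(lo, hi, length.out = 512)
    gs <- g(As)
    i <- which(gs[-1] * gs[-length(gs)] <= 0)
    if (!length(i))
      return(structure(list(exists = FALSE), class = "fixed_point"))
    lo <- As[i[1]]; hi <- As[i[1] + 1]
  }
  A_star <- stats::uniroot(g, c(lo, hi), tol = tol)$root
  R_star <- p$c2 * A_star / p$c1
  # analytic Jacobian: d(dA)/dA, d(dA)/dR; d(dR)/dA, d(dR)/dR
  A <- A_star
  Fp <- p$ka * (2 * A * p$Ka^2 / (p$Ka^2 + A^2)^2) * (p$At - A) -
    (p$ka * A^2 / (p$Ka^2 + A^2) + p$b)
  J <- matrix(c(Fp - (p$d1 + p$d2 * R_star), -p$d2 * A_star,
                p$c2 / p$tau, -p$c1 / p$tau), 2, 2, byrow = TRUE)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(exists = TRUE, A_star = A_star, R_star = R_star,
                 jacobian = J, eigenvalues = ev,
                 stable = all(Re(ev) < 1e-9)),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  if (!x$exists) {
    cat("No interior fixed point in (0, At)\n")
  } else {
    cat(sprintf("Fixed point: A* = %.4f uM, R* = %.4f uM (%s)\n",
                x$A_star, x$R_star,
                if (x$stable) "stable" else "unstable"))
  }
  invisible(x)
}

#' Well-mixed (0D) dynamics of the oscillator
#'
#' Integrates the noise-free reaction system with a classical RK4 scheme
#' and estimates the oscillation period from linearly interpolated upward
#' crossings of A through the fixed-point level, after discarding the
#' first 20% of the series as transient.
#'
#' @param p a [biochem_params()] object
#' @param T duration, s
#' @param dt time step, s (should resolve the fast activator timescale
#'   `1/ka`)
#' @param A0,R0 initial concentrations, uM
#' @param record_every recording cadence, s
#' @return list with `series` (data.frame t, A, R), `period` (s, `NA` if
#'   no sustained oscillation) and `crossings`
#' @export
simulate_well_mixed <- function(p = biochem_params(), T = 200, dt = 0.001,
                                A0 = 0, R0 = 0, record_every = 0.01) {
  stopifnot(dt > 0, T > dt)
  rec <- max(1L, round(record_every / dt))
  out <- rk4_well_mixed_cpp(A0, R0, dt, round(T / dt), rec, p)
  series <- data.frame(t = out$t, A = out$A, R = out$R)
  if (any(series$A < -1e-9) || any(series$A > p$At + 1e-9))
    warning("activator left [0, At]")
  fp <- fixed_point(p)
  thr <- if (fp$exists) fp$A_star else p$At / 2
  keep <- series$t >= 0.2 * T
  tt <- series$t[keep]; AA <- series$A[keep]
  up <- which(AA[-length(AA)] < thr & AA[-1] >= thr)
  crossings <- tt[up] + (thr - AA[up]) / (AA[up + 1] - AA[up]) *
    (tt[up + 1] - tt[up])
  period <- if (length(crossings) >= 3) mean(diff(crossings)) else NA_real_
  list(series = series, period = period, crossings = crossings)
}
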
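#' Periodic simulation grid
#'
#' @param nx,ny number of grid cells in x and y
#' @param Lx,Ly physical extent, um
#' @return object of class `pf_grid` with spacings `dx`, `dy`
#' @export
pf_grid <- function(nx = 256, ny = 256, Lx = 50, Ly = 50) {
  stopifnot(nx >= 8, ny >= 8, Lx > 0, Ly > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), Lx = Lx, Ly = Ly,
                 dx = Lx / nx, dy = Ly / ny, periodic = TRUE),
            class = "pf_grid")
}

#' Cell coordinates of a grid
#'
#' Cell-centered coordinates of a [pf_grid()].
#' @param grid a [pf_grid()]
#' @return list with vectors `x`, `y`
#' @export
grid_coords <- function(grid) {
  list(x = (seq_len(grid$nx) - 0.5) * grid$dx,
       y = (seq_len(grid$ny) - 0.5) * grid$dy)
}

#' Mechanical parameters of the cell boundary
#'
#' Parameters of the force-balance equation for the phase field:
#' membrane (line) tension `gamma`, interface width `epsilon`, area
#' conservation strength `BS` towards target area `S0`, friction `xi`,
#' protrusive strength `eta`, and the sigmoidal protrusion activation
#' `M(A) = A^n/(A^n + A0^n)`.
#'
#' `A0` (the half-activation level of the protrusive force) defaults to
#' 0.35 uM: the protrusive force must stay off at the resting activator
#' level (~0.26 uM, giving M < 0.3) yet be near-saturated across the
#' activator band of a traveling wave (A of order 1 uM, giving M > 0.95),
#' which is what the near-saturated boundary-averaged activation and the
#' linear speed law of keratocyte-like cells require.
#'
#' @param gamma tension, pN um
#' @param epsilon interface width, um
#' @param BS area conservation strength, pN/um^2
#' @param xi friction coefficient, pN s/um^2
#' @param eta protrusive strength, pN
#' @param n_hill Hill coefficient of the protrusive force
#' @param A0 protrusion half-activation threshold, uM
#' @param S0 target area, um^2 (defaults to `pi * r0^2`)
#' @param r0 initial disk radius used to set `S0`, um
#' @return object of class `mech_params`
#' @export
mech_params <- function(gamma = 2, epsilon = 2, BS = 10, xi = 10, eta = 2,
                        n_hill = 3, A0 = 0.35, r0 = 8, S0 = pi * r0^2) {
  p <- list(gamma = gamma, epsilon = epsilon, BS = BS, xi = xi, eta = eta,
            n_hill = n_hill, A0 = A0, S0 = S0)
  if (any(!is.finite(unlist(p)))) stop("mechanical parameters must be finite")
  if (A0 <= 0) stop("A0 must be > 0")
  if (epsilon <= 0 || xi <= 0 || S0 <= 0) stop("epsilon, xi, S0 must be > 0")
  structure(p, class = "mech_params")
}

#' Initialize a tanh disk phase field
#'
#' `phi(r) = (1 + tanh(3 (r0 - r)/epsilon))/2`, equal to 1 in the cell
#' interior, 0 outside, and 1/2 on the circle of radius `r0`.  This
#' profile is the one-dimensional equilibrium of the double-well
#' functional used here, so a resting disk is (up to curvature) a
#' stationary state of the tension dynamics.
#'
#' @param r0 disk radius, um
#' @param grid a [pf_grid()]
#' @param epsilon interface width, um
#' @param center disk center `(x, y)`, um; defaults to the domain center
#' @return matrix `nx` x `ny` with attributes `grid`, `epsilon`
#' @export
init_disk <- function(r0, grid = pf_grid(), epsilon = 2,
                      center = c(grid$Lx / 2, grid$Ly / 2)) {
  if (r0 + 3 * epsilon > min(grid$Lx, grid$Ly) / 2)
    stop("disk (radius + 3 epsilon) does not fit inside the periodic domain")
  co <- grid_coords(grid)
  # minimal-image distances so off-center disks wrap across the seam
  ddx <- (co$x - center[1] + grid$Lx / 2) %% grid$Lx - grid$Lx / 2
  ddy <- (co$y - center[2] + grid$Ly / 2) %% grid$Ly - grid$Ly / 2
  r <- sqrt(outer(ddx^2, ddy^2, "+"))
  phi <- 0.5 * (1 + tanh(3 * (r0 - r) / epsilon))
  attr(phi, "grid") <- grid
  attr(phi, "epsilon") <- epsilon
  phi
}

#' Double-well potential of the phase field
#'
#' `G(phi) = 18 phi^2 (1-phi)^2` with derivative
#' `G'(phi) = 36 phi (1-phi)(1-2 phi)`.  The normalization is the unique
#' one that makes `phi(x) = (1 + tanh(3 x / epsilon))/2` the 1D
#' equilibrium profile of `epsilon^2 phi'' = G'(phi)`, so that `gamma`
#' acts as the line tension.
#'
#' @param phi phase-field values (any shape)
#' @return list with `G` and `Gp`
#' @export
double_well <- function(phi) {
  list(G = 18 * phi^2 * (1 - phi)^2,
       Gp = 36 * phi * (1 - phi) * (1 - 2 * phi))
}

# centered periodic finite differences on matrices
shift_mat <- function(m, di = 0, dj = 0) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- ((seq_len(n1) - 1 + di) %% n1) + 1
  j <- ((seq_len(n2) - 1 + dj) %% n2) + 1
  m[i, j, drop = FALSE]
}

#' Periodic centered gradient and Laplacian
#'
#' @param m matrix field on a periodic grid
#' @param dx,dy grid spacings
#' @return `pf_gradient`: list with `gx`, `gy`, `gmag`; `pf_laplacian`:
#'   matrix
#' @export
pf_gradient <- function(m, dx, dy = dx) {
  gx <- (shift_mat(m, 1, 0) - shift_mat(m, -1, 0)) / (2 * dx)
  gy <- (shift_mat(m, 0, 1) - shift_mat(m, 0, -1)) / (2 * dy)
  list(gx = gx, gy = gy, gmag = sqrt(gx^2 + gy^2))
}

#' @rdname pf_gradient
#' @export
pf_laplacian <- function(m, dx, dy = dx) {
  (shift_mat(m, 1, 0) + shift_mat(m, -1, 0) - 2 * m) / dx^2 +
    (shift_mat(m, 0, 1) + shift_mat(m, 0, -1) - 2 * m) / dy^2
}

#' Tension force density on the phase field
#'
#' The variational tension contribution to the force balance,
#' `gamma (lap phi - G'(phi)/epsilon^2)`.  It vanishes identically on an
#' equilibrium 1D tanh interface and reduces to `-gamma kappa |grad phi|`
#' (mean-curvature flow) in the sharp-interface limit.
#'
#' @param phi phase-field matrix (attributes as from [init_disk()])
#' @param gamma tension, pN um
#' @param epsilon interface width, um
#' @param dx,dy grid spacings, um
#' @return matrix, pN/um^2 scale force density
#' @export
tension_force <- function(phi, gamma, epsilon = attr(phi, "epsilon"),
                          dx = attr(phi, "grid")$dx,
                          dy = attr(phi, "grid")$dy) {
  gamma * (pf_laplacian(phi, dx, dy) - double_well(phi)$Gp / epsilon^2)
}

#' Area-conservation force density
#'
#' Restoring term `-BS (area - S0) |grad phi|`: shrinks the cell when its
#' area exceeds the target `S0` and grows it when below.
#'
#' @param phi phase-field matrix
#' @param BS conservation strength, pN/um^2
#' @param S0 target area, um^2
#' @param dx,dy grid spacings, um
#' @return matrix
#' @export
area_force <- function(phi, BS, S0, dx = attr(phi, "grid")$dx,
                       dy = attr(phi, "grid")$dy) {
  area <- sum(phi) * dx * dy
  -BS * (area - S0) * pf_gradient(phi, dx, dy)$gmag
}

#' Phase-field area
#'
#' @param phi phase-field matrix
#' @param dx,dy grid spacings, um
#' @return `integral phi dx dy`, um^2
#' @export
pf_area <- function(phi, dx = attr(phi, "grid")$dx,
                    dy = attr(phi, "grid")$dy) {
  sum(phi) * dx * dy
}

#' Protrusion activation function
#'
#' Sigmoidal dependence of the protrusive force on the local activator
#' level, `M(A) = A^n / (A^n + A0^n)`.
#'
#' @param A activator concentration, uM (>= 0); vectorized
#' @param n_hill Hill coefficient
#' @param A0 half-activation threshold, uM (> 0)
#' @return values in `[0, 1)`
#' @export
protrusion_activation <- function(A, n_hill = 3, A0 = 1) {
  if (A0 <= 0) stop("A0 must be > 0")
  if (any(A < 0)) stop("activator concentration must be >= 0")
  A^n_hill / (A^n_hill + A0^n_hill)
}
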
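#' Build a trajectory object
#'
#' @param t times, s
#' @param x,y center-of-mass coordinates, um
#' @param source `"simulation"` or `"tracking-table"`
#' @return object of class `cell_trajectory` (data.frame t, x, y)
#' @export
cell_trajectory <- function(t, x, y, source = "simulation") {
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(c(t, x, y)))) stop("coordinates must be finite")
  structure(data.frame(t = t, x = x, y = y),
            class = c("cell_trajectory", "data.frame"), source = source)
}

#' Trajectory of a simulation output
#'
#' @param sim a `sim_output` from [run_sim()]
#' @return a [cell_trajectory()]
#' @export
sim_trajectory <- function(sim) {
  tr <- sim$trajectory
  cell_trajectory(tr$t, tr$x, tr$y, source = "simulation")
}

#' Center of mass of a phase field
#'
#' phi-weighted centroid on a periodic domain, computed through circular
#' means so that a cell straddling the periodic seam yields a continuous
#' centroid rather than a domain-sized jump.
#'
#' @param phi phase-field matrix (grid attributes as from [init_disk()])
#' @param grid a [pf_grid()]; defaults to the attribute
#' @return numeric `(x, y)`, um, in `[0, L)`
#' @export
center_of_mass <- function(phi, grid = attr(phi, "grid")) {
  m <- sum(phi)
  if (!is.finite(m) || m <= sqrt(.Machine$double.eps))
    stop("cell has vanished: total phi is ~0")
  ax <- 2 * pi * ((seq_len(grid$nx) - 0.5) / grid$nx)
  ay <- 2 * pi * ((seq_len(grid$ny) - 0.5) / grid$ny)
  wx <- rowSums(phi); wy <- colSums(phi)
  xcm <- grid$Lx / (2 * pi) * atan2(sum(wx * sin(ax)) / m,
                                    sum(wx * cos(ax)) / m)
  ycm <- grid$Ly / (2 * pi) * atan2(sum(wy * sin(ay)) / m,
                                    sum(wy * cos(ay)) / m)
  c(x = xcm %% grid$Lx, y = ycm %% grid$Ly)
}

#' Discard the initial transient of a trajectory
#'
#' Removes the first `t_skip` seconds (or the first 10% when the track is
#' short) before statistics are computed.
#' @param traj a [cell_trajectory()]
#' @param t_skip transient duration, s
#' @return trimmed trajectory
#' @export
discard_transient <- function(traj, t_skip = 20) {
  span <- diff(range(traj$t))
  cut <- min(traj$t) + min(t_skip, 0.1 * span)
  out <- traj[traj$t >= cut, , drop = FALSE]
  attr(out, "source") <- attr(traj, "source")
  class(out) <- class(traj)
  out
}

#' Center-of-mass speed statistics
#'
#' `mean_speed` is the magnitude of the net center-of-mass displacement
#' divided by the elapsed time over the post-transient window (the mean
#' center-of-mass velocity); `path_speed` is the mean speed along the
#' path sampled at `interval`.
#'
#' @param traj a [cell_trajectory()]
#' @param t_skip transient to discard, s
#' @param interval resampling interval for `path_speed`, s
#' @return `mean_speed()`: scalar um/s.  `path_speed()`: scalar um/s.
#' @export
mean_speed <- function(traj, t_skip = 20) {
  tr <- discard_transient(traj, t_skip)
  n <- nrow(tr)
  if (n < 2) return(NA_real_)
  sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2) / (tr$t[n] - tr$t[1])
}

#' @rdname mean_speed
#' @export
path_speed <- function(traj, t_skip = 20, interval = 3) {
  tr <- discard_transient(traj, t_skip)
  rs <- resample_time(tr, interval)
  if (nrow(rs) < 2) return(NA_real_)
  steps <- sqrt(diff(rs$x)^2 + diff(rs$y)^2)
  sum(steps) / (rs$t[nrow(rs)] - rs$t[1])
}

resample_time <- function(traj, interval) {
  tt <- seq(min(traj$t), max(traj$t), by = interval)
  data.frame(t = tt,
             x = approx(traj$t, traj$x, tt)$y,
             y = approx(traj$t, traj$y, tt)$y)
}

# resample a trajectory to uniform arclength spacing
resample_arclength <- function(traj, ds = 0.5) {
  s <- c(0, cumsum(sqrt(diff(traj$x)^2 + diff(traj$y)^2)))
  L <- s[length(s)]
  if (L <= ds) return(NULL)
  keep <- !duplicated(s)
  ss <- seq(0, L, by = ds)
  data.frame(s = ss,
             x = approx(s[keep], traj$x[keep], ss)$y,
             y = approx(s[keep], traj$y[keep], ss)$y)
}

#' Mean curvature of a trajectory
#'
#' Local curvature from the circumscribed circle of consecutive point
#' triplets after resampling the track to uniform arclength (default
#' 0.5 um spacing, which stabilizes the triplet estimator against burst
#' sampling), averaged along the path.
#'
#' @param traj a [cell_trajectory()]
#' @param ds resampling arclength, um
#' @param t_skip transient to discard, s
#' @return mean curvature, 1/um (`NA` for a degenerate track)
#' @export
trajectory_curvature <- function(traj, ds = 0.5, t_skip = 20) {
  tr <- discard_transient(traj, t_skip)
  rs <- resample_arclength(tr, ds)
  if (is.null(rs) || nrow(rs) < 3) return(NA_real_)
  x <- rs$x; y <- rs$y; n <- nrow(rs)
  i <- 2:(n - 1)
  ax <- x[i - 1] - x[i]; ay <- y[i - 1] - y[i]
  bx <- x[i + 1] - x[i]; by <- y[i + 1] - y[i]
  cx <- x[i + 1] - x[i - 1]; cy <- y[i + 1] - y[i - 1]
  area2 <- abs(ax * by - ay * bx)           # 2 * triangle area
  denom <- sqrt(ax^2 + ay^2) * sqrt(bx^2 + by^2) * sqrt(cx^2 + cy^2)
  kappa <- ifelse(denom > 0, 2 * area2 / denom, 0)
  mean(kappa)
}

# circular standard deviation (degrees) of headings, centered on the
# circular mean; for tight distributions equals the naive SD
circ_sd_deg <- function(theta) {
  mu <- atan2(mean(sin(theta)), mean(cos(theta)))
  dev <- (theta - mu + pi) %% (2 * pi) - pi
  sd(dev) * 180 / pi
}

#' Angular dispersion of a trajectory
#'
#' Headings of successive displacement vectors sampled every `interval`
#' seconds, relative to a fixed axis; the spread is the circular-aware
#' standard deviation (headings unwrapped about their circular mean).
#' Zero-length displacement intervals are skipped and counted.
#'
#' @param traj a [cell_trajectory()]
#' @param interval sampling interval, s
#' @param n_intervals maximum number of intervals to use
#' @param t_skip transient to discard, s
#' @return list with `sd_deg`, `n_used`, `n_zero`
#' @export
angle_dispersion <- function(traj, interval = 3, n_intervals = 100,
                             t_skip = 20) {
  tr <- discard_transient(traj, t_skip)
  rs <- resample_time(tr, interval)
  if (nrow(rs) > n_intervals + 1) rs <- rs[seq_len(n_intervals + 1), ]
  dx <- diff(rs$x); dy <- diff(rs$y)
  len <- sqrt(dx^2 + dy^2)
  ok <- len > .Machine$double.eps
  if (sum(ok) < 2)
    return(list(sd_deg = 0, n_used = sum(ok), n_zero = sum(!ok)))
  list(sd_deg = circ_sd_deg(atan2(dy[ok], dx[ok])),
       n_used = sum(ok), n_zero = sum(!ok))
}

#' Classify a simulated cell's migration mode
#'
#' A cell is `oscillatory` when its mean center-of-mass speed vanishes
#' (below `v_threshold`); otherwise `keratocyte-like` when the mean
#' trajectory curvature is below `kappa_threshold` (persistent,
#' near-straight motion), with the angle-dispersion pathway
#' (< `angle_threshold` degrees) as an independent cross-check; anything
#' else is `amoeboid-like`.  When the two keratocyte pathways disagree
#' the curvature label wins and the disagreement is flagged.
#'
#' @param traj a [cell_trajectory()]
#' @param kappa_threshold curvature boundary, 1/um
#' @param angle_threshold angle-SD boundary, degrees
#' @param v_threshold vanishing-speed boundary, um/s
#' @param interval,n_intervals angle sampling (see [angle_dispersion()])
#' @param t_skip transient to discard, s
#' @return object of class `mode_label`: list with `mode`, `v_cm`,
#'   `kappa_mean`, `angle_sd`, `pathways_agree`
#' @export
classify_simulation <- function(traj, kappa_threshold = 0.02,
                                angle_threshold = 2, v_threshold = 0.02,
                                interval = 3, n_intervals = 100,
                                t_skip = 20) {
  v <- mean_speed(traj, t_skip)
  kap <- trajectory_curvature(traj, t_skip = t_skip)
  ang <- angle_dispersion(traj, interval, n_intervals, t_skip)$sd_deg
  if (!is.finite(v) || v < v_threshold) {
    mode <- "oscillatory"
    agree <- TRUE
  } else {
    by_kappa <- is.finite(kap) && kap < kappa_threshold
    by_angle <- ang < angle_threshold
    mode <- if (by_kappa) "keratocyte-like" else "amoeboid-like"
    agree <- by_kappa == by_angle
  }
  structure(list(mode = mode, v_cm = v, kappa_mean = kap, angle_sd = ang,
                 pathways_agree = agree),
            class = "mode_label")
}

#' @export
print.mode_label <- function(x, ...) {
  cat(sprintf("mode: %s (v_cm = %.4f um/s, <kappa> = %.4f 1/um, angle SD = %.1f deg)\n",
              x$mode, x$v_cm, x$kappa_mean, x$angle_sd))
  if (!x$pathways_agree) cat("  note: curvature and angle pathways disagree\n")
  invisible(x)
}

#' Classify an experiment-resolution track
#'
#' Mirrors the low-cadence experimental pipeline: headings between
#' successive positions separated by `interval` (30 s), standard
#' deviation over sliding windows of `window` consecutive pairs;
#' keratocyte-like where the window SD is strictly below
#' `angle_threshold` (25 degrees).  Gaps larger than twice the interval
#' split the track.
#'
#' @param track data.frame with columns `t_s`, `x_um`, `y_um` (optionally
#'   `area_um2`)
#' @param interval sampling interval, s
#' @param window number of consecutive heading pairs per window
#' @param angle_threshold window SD boundary, degrees
#' @return list with `windows` (data.frame t_mid, sd_deg, keratocyte),
#'   `mode` (majority label over windows), `fraction_keratocyte`
#' @export
classify_experiment <- function(track, interval = 30, window = 5,
                                angle_threshold = 25) {
  stopifnot(all(c("t_s", "x_um", "y_um") %in% names(track)))
  track <- track[order(track$t_s), ]
  gap <- c(FALSE, diff(track$t_s) > 2 * interval)
  seg_id <- cumsum(gap)
  wins <- NULL
  for (sid in unique(seg_id)) {
    seg <- track[seg_id == sid, ]
    if (nrow(seg) < window + 2) next
    rs <- data.frame(t = seq(min(seg$t_s), max(seg$t_s), by = interval))
    rs$x <- approx(seg$t_s, seg$x_um, rs$t)$y
    rs$y <- approx(seg$t_s, seg$y_um, rs$t)$y
    dx <- diff(rs$x); dy <- diff(rs$y)
    len <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    nw <- length(th) - window + 1
    if (nw < 1) next
    for (k in seq_len(nw)) {
      idx <- k:(k + window - 1)
      ok <- len[idx] > .Machine$double.eps
      sdw <- if (sum(ok) >= 2) circ_sd_deg(th[idx][ok]) else 0
      wins <- rbind(wins, data.frame(t_mid = mean(rs$t[idx]), sd_deg = sdw,
                                     keratocyte = sdw < angle_threshold))
    }
  }
  if (is.null(wins))
    return(list(windows = NULL, mode = NA_character_,
                fraction_keratocyte = NA_real_))
  frac <- mean(wins$keratocyte)
  list(windows = wins,
       mode = if (frac > 0.5) "keratocyte-like" else "amoeboid-like",
       fraction_keratocyte = frac)
}

#' Area-oscillation metrics
#'
#' Quantifies basal-area oscillations at experimental cadence: `COV` is
#' the mean coefficient of variation over 5-frame sliding windows (%);
#' `P` is the relative peak-to-valley ratio
#' `(<peak> - <valley>)/<peak>` (%) from local extrema of a 5-frame
#' moving-average-smoothed series (minimum prominence 1% of the mean);
#' `T_tot` (min) is the duration spanned by the alternating extrema.  A
#' series is oscillatory when `COV > 5`, `P > 19` and `T_tot > 40`.
#'
#' @param t_min frame times, minutes (cadence ~0.5 min)
#' @param area areas, um^2
#' @return list with `COV`, `P`, `T_tot`, `oscillatory`
#' @export
oscillation_metrics <- function(t_min, area) {
  stopifnot(length(t_min) == length(area))
  n <- length(area)
  if (n < 5)
    return(list(COV = 0, P = 0, T_tot = 0, oscillatory = FALSE))
  covs <- vapply(seq_len(n - 4), function(k) {
    w <- area[k:(k + 4)]
    if (mean(w) <= 0) 0 else sd(w) / mean(w)
  }, numeric(1))
  COV <- 100 * mean(covs)
  # 5-frame moving average, then local extrema with a prominence floor
  sm <- stats::filter(area, rep(1 / 5, 5), sides = 2)
  sm <- as.numeric(sm)
  ok <- !is.na(sm)
  smv <- sm[ok]; tv <- t_min[ok]
  pk <- vl <- numeric(0); tpk <- tvl <- numeric(0)
  prom <- 0.01 * mean(area)
  if (length(smv) >= 3) {
    i <- 2:(length(smv) - 1)
    is_pk <- smv[i] >= smv[i - 1] & smv[i] > smv[i + 1]
    is_vl <- smv[i] <= smv[i - 1] & smv[i] < smv[i + 1]
    cand <- data.frame(idx = i[is_pk | is_vl],
                       peak = is_pk[is_pk | is_vl])
    if (nrow(cand) >= 2) {
      # enforce alternation and prominence against neighbors
      keep <- rep(TRUE, nrow(cand))
      for (k in 2:nrow(cand)) {
        if (abs(smv[cand$idx[k]] - smv[cand$idx[k - 1]]) < prom)
          keep[k] <- FALSE
      }
      cand <- cand[keep, ]
      pk <- smv[cand$idx[cand$peak]]; tpk <- tv[cand$idx[cand$peak]]
      vl <- smv[cand$idx[!cand$peak]]; tvl <- tv[cand$idx[!cand$peak]]
    }
  }
  if (length(pk) >= 1 && length(vl) >= 1 && mean(pk) > 0) {
    P <- 100 * (mean(pk) - mean(vl)) / mean(pk)
    T_tot <- diff(range(c(tpk, tvl)))
  } else {
    P <- 0; T_tot <- 0
  }
  list(COV = COV, P = P, T_tot = T_tot,
       oscillatory = COV > 5 && P > 19 && T_tot > 40)
}

# shift coordinates so the cell (periodic) is centered in the domain
recenter_field <- function(phi, grid = attr(phi, "grid")) {
  com <- center_of_mass(phi, grid)
  si <- round(grid$nx / 2 + 0.5 - com[1] / grid$dx)
  sj <- round(grid$ny / 2 + 0.5 - com[2] / grid$dy)
  out <- shift_mat(phi, -si, -sj)
  attr(out, "grid") <- grid
  attr(out, "epsilon") <- attr(phi, "epsilon")
  out
}

#' Front-back distance of a cell
#'
#' Extent of the `phi > 1/2` region projected on the direction of
#' motion.  The field is recentered across the periodic seam first.
#'
#' @param phi phase-field matrix
#' @param direction unit vector of motion `(vx, vy)`; required
#' @param grid a [pf_grid()]
#' @return distance d, um
#' @export
front_back_distance <- function(phi, direction, grid = attr(phi, "grid")) {
  nv <- sqrt(sum(direction^2))
  if (!is.finite(nv) || nv == 0)
    stop("a motion direction must be supplied for a stationary cell")
  u <- direction / nv
  phc <- recenter_field(phi, grid)
  co <- grid_coords(grid)
  inside <- which(phc > 0.5, arr.ind = TRUE)
  if (!nrow(inside)) stop("no phi > 1/2 region")
  proj <- co$x[inside[, 1]] * u[1] + co$y[inside[, 2]] * u[2]
  diff(range(proj))
}

#' Boundary-averaged protrusion factor
#'
#' The average of the protrusion activation across the moving front:
#' `alpha = integral of M(A) phi over the front interface band
#' [-epsilon, epsilon] / (2 epsilon)`, evaluated along rays parallel to
#' the motion direction and averaged over the rays that cross the front.
#' For a resting tanh interface with `M = 1` the integral gives 0.5.
#'
#' @param phi phase-field matrix
#' @param A activator matrix
#' @param direction unit vector of motion
#' @param epsilon interface width, um
#' @param n_hill,A0 protrusion activation parameters
#' @param grid a [pf_grid()]
#' @param span half-width of the front arc sampled, um (rays offset
#'   perpendicular to the motion direction)
#' @return alpha (dimensionless), with attribute `n_rays`
#' @export
boundary_alpha <- function(phi, A, direction,
                           epsilon = attr(phi, "epsilon"),
                           n_hill = 3, A0 = 0.35, grid = attr(phi, "grid"),
                           span = NULL) {
  nv <- sqrt(sum(direction^2))
  if (!is.finite(nv) || nv == 0)
    stop("no coherent front: a motion direction is required")
  u <- direction / nv
  perp <- c(-u[2], u[1])
  phc <- recenter_field(phi, grid)
  # recentering moved phi and A by the same shift
  com0 <- center_of_mass(phi, grid)
  si <- round(grid$nx / 2 + 0.5 - com0[1] / grid$dx)
  sj <- round(grid$ny / 2 + 0.5 - com0[2] / grid$dy)
  Ac <- shift_mat(A, -si, -sj)
  com <- center_of_mass(phc, grid)
  if (is.null(span)) {
    # half the cell's lateral extent
    ext <- front_back_distance(phc, perp, grid)
    span <- 0.35 * ext
  }
  ds <- grid$dx / 2
  bilin <- function(m, px, py) {
    fx <- px / grid$dx + 0.5; fy <- py / grid$dy + 0.5
    i0 <- floor(fx); j0 <- floor(fy)
    wx <- fx - i0; wy <- fy - j0
    iw <- function(i) ((i - 1) %% grid$nx) + 1
    jw <- function(j) ((j - 1) %% grid$ny) + 1
    m[iw(i0), jw(j0)] * (1 - wx) * (1 - wy) +
      m[iw(i0 + 1), jw(j0)] * wx * (1 - wy) +
      m[iw(i0), jw(j0 + 1)] * (1 - wx) * wy +
      m[iw(i0 + 1), jw(j0 + 1)] * wx * wy
  }
  offsets <- seq(-span, span, by = grid$dy)
  vals <- c()
  for (off in offsets) {
    base <- com + off * perp
    svals <- seq(0, min(grid$Lx, grid$Ly) / 2 - 2 * epsilon, by = ds)
    prof <- vapply(svals, function(s)
      bilin(phc, base[1] + s * u[1], base[2] + s * u[2]), numeric(1))
    idx <- which(prof[-length(prof)] > 0.5 & prof[-1] <= 0.5)
    if (!length(idx)) next
    i <- idx[length(idx)]
    s_star <- svals[i] + ds * (prof[i] - 0.5) / (prof[i] - prof[i + 1])
    sb <- seq(s_star - epsilon, s_star + epsilon, by = ds / 2)
    phb <- vapply(sb, function(s)
      bilin(phc, base[1] + s * u[1], base[2] + s * u[2]), numeric(1))
    Ab <- vapply(sb, function(s)
      bilin(Ac, base[1] + s * u[1], base[2] + s * u[2]), numeric(1))
    Mb <- protrusion_activation(pmax(Ab, 0), n_hill, A0)
    vals <- c(vals, sum(Mb * phb) * (ds / 2) / (2 * epsilon))
  }
  if (!length(vals)) stop("no coherent front found along the motion direction")
  structure(mean(vals), n_rays = length(vals))
}
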
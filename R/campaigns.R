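#' Phase diagram in the (protrusive strength, cell size) plane
#'
#' Simulates and classifies a cell for every combination of protrusive
#' strength `eta` and initial radius `r`, then locates the two mode
#' boundaries along `eta` at each radius: `eta_c1` (oscillatory to
#' amoeboid-like; expected roughly independent of size) and `eta_c2`
#' (amoeboid-like to keratocyte-like; expected to grow with size and to
#' saturate for radii beyond the physiological range).  With several
#' seeds per grid cell the label is a majority vote.
#'
#' @param config_base a [sim_config()]; its `eta` and `r0` are overridden
#' @param eta_values protrusive strengths, pN
#' @param r_values initial radii, um
#' @param seeds_per_cell seeds per (eta, r) cell
#' @param t_skip transient discarded before classification, s
#' @return object of class `phase_diagram`: list with `cells`
#'   (data.frame eta, r, seed, mode, v_cm, kappa, angle_sd) and
#'   `boundaries` (data.frame r, eta_c1, eta_c2)
#' @export
phase_diagram <- function(config_base, eta_values = seq(1, 13, by = 2),
                          r_values = c(5, 8), seeds_per_cell = 1,
                          t_skip = 20) {
  cells <- NULL
  for (r in r_values) for (eta in eta_values) {
    for (sd_i in seq_len(seeds_per_cell)) {
      cfg <- config_base
      cfg$r0 <- r
      cfg$mech$S0 <- pi * r^2
      cfg$mech$eta <- eta
      cfg$seed <- config_base$seed + 1000L * (sd_i - 1L)
      lab <- tryCatch({
        sim <- run_sim(cfg)
        classify_simulation(sim_trajectory(sim), t_skip = t_skip)
      }, error = function(e) NULL)
      cells <- rbind(cells, data.frame(
        eta = eta, r = r, seed = cfg$seed,
        mode = if (is.null(lab)) NA_character_ else lab$mode,
        v_cm = if (is.null(lab)) NA_real_ else lab$v_cm,
        kappa = if (is.null(lab)) NA_real_ else lab$kappa_mean,
        angle_sd = if (is.null(lab)) NA_real_ else lab$angle_sd,
        failed = is.null(lab)))
    }
  }
  # majority label per (eta, r)
  maj <- do.call(rbind, lapply(split(cells, list(cells$eta, cells$r),
                                     drop = TRUE), function(d) {
    tab <- table(d$mode[!is.na(d$mode)])
    data.frame(eta = d$eta[1], r = d$r[1],
               mode = if (length(tab)) names(which.max(tab)) else NA_character_)
  }))
  bounds <- do.call(rbind, lapply(split(maj, maj$r), function(d) {
    d <- d[order(d$eta), ]
    m <- d$mode
    c1 <- d$eta[match(TRUE, m != "oscillatory" & !is.na(m))]
    c2 <- d$eta[match(TRUE, m == "keratocyte-like")]
    data.frame(r = d$r[1],
               eta_c1 = if (is.na(c1)) NA_real_ else c1,
               eta_c2 = if (is.na(c2)) NA_real_ else c2)
  }))
  structure(list(cells = cells, majority = maj, boundaries = bounds),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("Phase diagram:\n")
  print(x$boundaries, row.names = FALSE)
  invisible(x)
}

#' Quasi-static protrusive-strength ramp
#'
#' Steps `eta` slowly from `eta_start` to `eta_end`, continuing each step
#' from the previous end state and measuring the center-of-mass speed
#' over the second half of every hold.  Running the ramp both upward and
#' downward around the onset of motion exposes the subcritical
#' (hysteretic) character of the transition.
#'
#' @param config_base a [sim_config()]
#' @param eta_start,eta_end ramp limits, pN
#' @param d_eta step size, pN
#' @param hold_time model time per step, s
#' @param init_state optional warm-start state (e.g. the
#'   `"final_state"` attribute of a previous ramp), so a downward sweep
#'   can continue from the moving branch
#' @return data.frame with columns direction, eta, v_cm; the end state
#'   is attached as attribute `final_state`
#' @export
eta_ramp <- function(config_base, eta_start = 1, eta_end = 5, d_eta = 1,
                     hold_time = 60, init_state = NULL) {
  etas <- seq(eta_start, eta_end, by = if (eta_end >= eta_start) d_eta
                                       else -d_eta)
  dirn <- if (eta_end >= eta_start) "up" else "down"
  state <- init_state
  rows <- NULL
  for (k in seq_along(etas)) {
    cfg <- config_base
    cfg$mech$eta <- etas[k]
    cfg$T <- hold_time
    cfg$seed <- config_base$seed + k
    sim <- run_sim(cfg, init_state = state)
    state <- sim$final
    tr <- sim_trajectory(sim)
    v <- mean_speed(tr, t_skip = hold_time / 2)
    rows <- rbind(rows, data.frame(direction = dirn, eta = etas[k], v_cm = v))
  }
  attr(rows, "final_state") <- state
  rows
}

#' Parameter-variation suite for the keratocyte speed law
#'
#' Runs steady keratocyte-regime cells under the reference parameters and
#' under the canonical variations (doubled friction, doubled tension,
#' halved inhibitor timescale, ...), measures steady speeds, and fits the
#' speed law `v = alpha * eta / xi`.
#'
#' @param config_base a [sim_config()] with asymmetric initialization
#'   recommended
#' @param eta_values protrusive strengths per variation, pN
#' @param variations named list of parameter overrides; each element is a
#'   list with optional `mech` and `biochem` named values
#' @return list with `runs` (data.frame variation, eta, xi, v_cm, mode)
#'   and `alpha_fit` (slope of v against eta/xi through the origin)
#' @export
variation_suite <- function(config_base, eta_values = c(9, 11, 13),
                            variations = list(
                              default = list(),
                              xi2 = list(mech = list(xi = 20)),
                              gamma2 = list(mech = list(gamma = 4)),
                              tau_half = list(biochem = list(tau = 5)))) {
  rows <- NULL
  for (vn in names(variations)) {
    ov <- variations[[vn]]
    for (eta in eta_values) {
      cfg <- config_base
      for (nm in names(ov$mech)) cfg$mech[[nm]] <- ov$mech[[nm]]
      for (nm in names(ov$biochem)) cfg$biochem[[nm]] <- ov$biochem[[nm]]
      cfg$mech$eta <- eta
      sim <- run_sim(cfg)
      lab <- classify_simulation(sim_trajectory(sim))
      rows <- rbind(rows, data.frame(variation = vn, eta = eta,
                                     xi = cfg$mech$xi, v_cm = lab$v_cm,
                                     mode = lab$mode))
    }
  }
  keep <- rows$mode == "keratocyte-like" & is.finite(rows$v_cm)
  alpha <- if (any(keep)) {
    xr <- rows$eta[keep] / rows$xi[keep]
    unname(coef(lm(rows$v_cm[keep] ~ 0 + xr))[1])
  } else NA_real_
  list(runs = rows, alpha_fit = alpha)
}

#' Run a model variant and classify it
#'
#' `"excitable"` switches the biochemical module into the excitable
#' regime (c2 = 30, sigma = 0.1): the rest state is stable and waves need
#' noise to start.  `"relaxed-area"` weakens area conservation
#' (BS = 0.1) so oscillatory cells show measurable area oscillations.
#'
#' @param variant `"excitable"` or `"relaxed-area"`
#' @param config_base a [sim_config()] (variant overrides are applied on
#'   top)
#' @return list with `sim` (a `sim_output`), `label` (a `mode_label`) and,
#'   for relaxed-area runs, `area_cov` (% coefficient of variation of the
#'   post-transient area series)
#' @export
variant_run <- function(variant = c("excitable", "relaxed-area"),
                        config_base) {
  variant <- match.arg(variant)
  cfg <- sim_config(biochem = config_base$biochem, mech = config_base$mech,
                    grid = config_base$grid, dt = config_base$dt,
                    T = config_base$T, r0 = config_base$r0,
                    seed = config_base$seed,
                    init_mode = config_base$init_mode, variant = variant,
                    record_every = config_base$record_every,
                    snapshot_every = config_base$snapshot_every)
  sim <- run_sim(cfg)
  lab <- classify_simulation(sim_trajectory(sim))
  out <- list(sim = sim, label = lab)
  if (variant == "relaxed-area") {
    tr <- sim$trajectory
    a <- tr$area[tr$t >= 20]
    out$area_cov <- 100 * sd(a) / mean(a)
  }
  out
}
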
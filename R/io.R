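#' Read a simulation configuration from YAML
#'
#' The file may contain sections `biochem`, `mech`, `grid` and `run`;
#' keys within each section are the argument names of
#' [biochem_params()], [mech_params()], [pf_grid()] and [sim_config()]
#' respectively.  Missing keys fall back to the defaults.
#'
#' @param path YAML file path
#' @return a [sim_config()]
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  bio <- do.call(biochem_params, as.list(y$biochem))
  mech <- do.call(mech_params, as.list(y$mech))
  grid <- do.call(pf_grid, as.list(y$grid))
  run_args <- as.list(y$run)
  do.call(sim_config, c(list(biochem = bio, mech = mech, grid = grid),
                        run_args))
}

#' Write a simulation configuration to YAML
#'
#' @param config a [sim_config()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  y <- list(biochem = unclass(config$biochem),
            mech = unclass(config$mech),
            grid = unclass(config$grid)[c("nx", "ny", "Lx", "Ly")],
            run = config[c("dt", "T", "r0", "seed", "init_mode", "variant",
                           "record_every", "snapshot_every")])
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns `t_s`, `x_um`, `y_um` and, when available, `area_um2` -- the
#' same layout accepted by [read_track()] / [classify_experiment()].
#'
#' @param sim a `sim_output` or a [cell_trajectory()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(sim, path) {
  if (inherits(sim, "sim_output")) {
    tr <- sim$trajectory
    d <- data.frame(t_s = tr$t, x_um = tr$x, y_um = tr$y, area_um2 = tr$area)
  } else {
    d <- data.frame(t_s = sim$t, x_um = sim$x, y_um = sim$y)
  }
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell-tracking table
#'
#' CSV with header `t_s, x_um, y_um[, area_um2]`.
#'
#' @param path CSV file path
#' @return data.frame
#' @export
read_track <- function(path) {
  d <- read.csv(path)
  need <- c("t_s", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stop("track file must have columns t_s, x_um, y_um")
  d
}

#' Render a simulation state
#'
#' Draws the activator field inside the cell with the membrane
#' (`phi = 1/2` contour) overlaid; writes a PNG when `path` is given.
#'
#' @param state list with `phi` and `A` matrices (a snapshot or the
#'   `final` element of a `sim_output`)
#' @param grid a [pf_grid()]
#' @param path optional PNG output path
#' @return `path` (or `NULL` when drawing to the active device),
#'   invisibly
#' @export
plot_cell <- function(state, grid = attr(state$phi, "grid"), path = NULL) {
  if (!is.null(path)) grDevices::png(path, width = 720, height = 720)
  co <- grid_coords(grid)
  masked <- state$A * (state$phi > 0.5)
  graphics::image(co$x, co$y, masked, asp = 1, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (um)", ylab = "y (um)")
  graphics::contour(co$x, co$y, state$phi, levels = 0.5, add = TRUE,
                    col = "red", drawlabels = FALSE, lwd = 2)
  if (!is.null(path)) grDevices::dev.off()
  invisible(path)
}
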
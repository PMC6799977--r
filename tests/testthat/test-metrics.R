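test_that("center of mass is exact, equivariant, and seam-safe", {
  g <- test_grid(128)
  phi <- init_disk(6, g, 2)
  expect_equal(unname(center_of_mass(phi)), c(25, 25), tolerance = 1e-6)
  # translation equivariance
  phi2 <- init_disk(6, g, 2, center = c(27, 25))
  expect_equal(unname(center_of_mass(phi2)), c(27, 25), tolerance = 1e-6)
  # disk straddling the periodic seam: centroid continuous, no domain jump
  phi3 <- init_disk(6, g, 2, center = c(49, 25))
  expect_equal(unname(center_of_mass(phi3))[1], 49, tolerance = 0.05)
  expect_error(center_of_mass(matrix(0, g$nx, g$ny), g), "vanished")
})

test_that("trajectory curvature recovers circles and lines", {
  th <- seq(0, 4 * pi, length.out = 400)
  circ <- cell_trajectory(seq_along(th), 10 * cos(th), 10 * sin(th))
  expect_equal(trajectory_curvature(circ, t_skip = 0), 0.1, tolerance = 0.01)
  line <- cell_trajectory(1:100, seq(0, 50, length.out = 100),
                          rep(2, 100))
  expect_lt(trajectory_curvature(line, t_skip = 0), 1e-8)
  # degenerate (motionless) track flagged as NA
  still <- cell_trajectory(1:10, rep(1, 10), rep(1, 10))
  expect_true(is.na(trajectory_curvature(still, t_skip = 0)))
})

test_that("angle dispersion: straight tracks give 0, isotropic steps give the uniform limit", {
  line <- cell_trajectory(0:100, (0:100) * 0.5, (0:100) * 0.2)
  expect_equal(angle_dispersion(line, interval = 3, t_skip = 0)$sd_deg, 0,
               tolerance = 1e-8)
  # Monte-Carlo oracle: SD of uniform headings = 180/sqrt(3) = 103.9 deg
  set.seed(42)
  n <- 2e4
  th <- runif(n, -pi, pi)
  x <- cumsum(cos(th)); y <- cumsum(sin(th))
  rw <- cell_trajectory(seq_len(n), x, y)
  sdv <- angle_dispersion(rw, interval = 1, n_intervals = n, t_skip = 0)$sd_deg
  expect_equal(sdv, 180 / sqrt(3), tolerance = 3)
})

test_that("simulation classifier separates the three modes on synthetic tracks", {
  t <- seq(0, 150, by = 1)
  # straight runner
  ker <- cell_trajectory(t, 0.5 * t, 0.1 * t)
  lab <- classify_simulation(ker)
  expect_identical(lab$mode, "keratocyte-like")
  expect_true(lab$pathways_agree)
  # jittering but non-motile cell
  set.seed(1)
  osc <- cell_trajectory(t, 25 + 0.05 * rnorm(length(t)),
                         25 + 0.05 * rnorm(length(t)))
  expect_identical(classify_simulation(osc)$mode, "oscillatory")
  # strongly turning random walker
  set.seed(2)
  th <- cumsum(rnorm(length(t), sd = 0.5))
  amo <- cell_trajectory(t, cumsum(0.3 * cos(th)), cumsum(0.3 * sin(th)))
  expect_identical(classify_simulation(amo)$mode, "amoeboid-like")
  # zero-length displacement trace is oscillatory by definition
  expect_identical(classify_simulation(
    cell_trajectory(t, rep(1, length(t)), rep(1, length(t))))$mode,
    "oscillatory")
})

test_that("classifier is invariant under rotation and translation", {
  t <- seq(0, 150, by = 1)
  set.seed(2)
  th <- cumsum(rnorm(length(t), sd = 0.8))
  x <- cumsum(0.3 * cos(th)); y <- cumsum(0.3 * sin(th))
  l0 <- classify_simulation(cell_trajectory(t, x, y))
  phi <- 0.7
  xr <- 12 + cos(phi) * x - sin(phi) * y
  yr <- -3 + sin(phi) * x + cos(phi) * y
  l1 <- classify_simulation(cell_trajectory(t, xr, yr))
  expect_identical(l0$mode, l1$mode)
  expect_equal(l0$v_cm, l1$v_cm, tolerance = 1e-10)
  expect_equal(l0$kappa_mean, l1$kappa_mean, tolerance = 1e-6)
  expect_equal(l0$angle_sd, l1$angle_sd, tolerance = 1e-6)
})

test_that("experiment classifier applies the 30 s / 25 degree rule per window", {
  t <- seq(0, 1800, by = 30)
  straight <- data.frame(t_s = t, x_um = 0.1 * t, y_um = 0.02 * t)
  res <- classify_experiment(straight)
  expect_identical(res$mode, "keratocyte-like")
  expect_true(all(res$windows$keratocyte))
  # heading-decorrelated track is amoeboid-like
  set.seed(5)
  th <- cumsum(rnorm(length(t), sd = 1.5))
  wob <- data.frame(t_s = t, x_um = cumsum(3 * cos(th)),
                    y_um = cumsum(3 * sin(th)))
  expect_identical(classify_experiment(wob)$mode, "amoeboid-like")
  # the keratocyte rule is a strict inequality at 25 degrees
  n <- 6
  sd_target <- 25 * pi / 180
  # alternating headings +/- s have SD exactly s
  th2 <- rep(c(sd_target, -sd_target), length.out = 20)
  # inflate so the sample SD equals sd_target exactly
  th2 <- th2 * sd_target / sd(th2)
  xy <- cbind(cumsum(cos(th2)), cumsum(sin(th2)))
  tab <- data.frame(t_s = seq(0, by = 30, length.out = nrow(xy) + 1),
                    x_um = c(0, xy[, 1]), y_um = c(0, xy[, 2]))
  res2 <- classify_experiment(tab)
  expect_true(all(!res2$windows$keratocyte))
})

test_that("oscillation metrics implement the COV/P/T_tot rule", {
  t <- seq(0, 60, by = 0.5)  # minutes, 30 s cadence
  # constant area: nothing oscillates
  m0 <- oscillation_metrics(t, rep(100, length(t)))
  expect_equal(m0$COV, 0)
  expect_equal(m0$P, 0)
  expect_false(m0$oscillatory)
  # 10% amplitude: P ~ 18.2% fails the P > 19% gate
  s1 <- 100 + 10 * sin(2 * pi * t / 6)
  m1 <- oscillation_metrics(t, s1)
  expect_equal(m1$P, 100 * 20 / 110, tolerance = 2)
  expect_false(m1$oscillatory)
  # 15% amplitude over an hour: oscillatory
  s2 <- 100 + 15 * sin(2 * pi * t / 6)
  m2 <- oscillation_metrics(t, s2)
  expect_equal(m2$P, 100 * 30 / 115, tolerance = 2.5)
  expect_gt(m2$COV, 5)
  expect_gt(m2$T_tot, 40)
  expect_true(m2$oscillatory)
})

test_that("front-back distance of a disk is its diameter, any direction", {
  g <- test_grid(128)
  phi <- init_disk(7, g, 2)
  expect_equal(front_back_distance(phi, c(1, 0)), 14, tolerance = 0.4)
  expect_equal(front_back_distance(phi, c(1, 1)), 14, tolerance = 0.4)
  # seam-straddling disk unaffected
  phi2 <- init_disk(7, g, 2, center = c(49.5, 25))
  expect_equal(front_back_distance(phi2, c(1, 0)), 14, tolerance = 0.4)
  expect_error(front_back_distance(phi, c(0, 0)), "direction")
})

test_that("boundary alpha integrates the tanh half-profile correctly", {
  g <- test_grid(256)
  phi <- init_disk(8, g, 2)
  # saturating activator: M ~ 1 across the band -> alpha ~ 0.5
  A <- matrix(100, g$nx, g$ny)
  al <- boundary_alpha(phi, A, direction = c(1, 0), epsilon = 2)
  expect_equal(as.numeric(al), 0.5, tolerance = 0.02)
  # no activator: alpha = 0
  al0 <- boundary_alpha(phi, matrix(0, g$nx, g$ny), direction = c(1, 0),
                        epsilon = 2)
  expect_equal(as.numeric(al0), 0, tolerance = 1e-6)
})
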
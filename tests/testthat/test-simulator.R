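test_that("restricted-region threshold follows the tanh margin formula", {
  chi <- restricted_region_threshold(epsilon = 2, eps0 = 2)
  expect_equal(chi, 0.5 + 0.5 * tanh(-3), tolerance = 1e-12)
  # wider margin means a smaller threshold
  expect_lt(restricted_region_threshold(2, 3), chi)
})

test_that("noise increments have the density-normalized variance", {
  expect_identical(noise_increment(0, 0.001, 0.2, 0.2, 100), numeric(100))
  set.seed(9)
  n <- 1e5
  z <- noise_increment(0.01, 0.001, 0.4, 0.4, n)
  v_target <- 0.01 * 0.001 / 0.16
  se <- v_target * sqrt(2 / (n - 1))
  expect_lt(abs(var(z) - v_target), 3 * se)
  # literal recipe drops the density factor
  set.seed(9)
  zl <- noise_increment(0.01, 0.001, 0.4, 0.4, n, literal = TRUE)
  expect_lt(abs(var(zl) - 0.01 * 0.001), 3 * 0.01 * 0.001 * sqrt(2 / n))
})

test_that("identical configuration and seed reproduce the run exactly", {
  cfg <- test_config(eta = 4, T = 5, n = 64, dt = 0.004, seed = 7)
  s1 <- run_sim(cfg)
  s2 <- run_sim(cfg)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$final$A, s2$final$A)
  # a different seed gives a different noise stream
  cfg2 <- cfg; cfg2$seed <- 8L
  s3 <- run_sim(cfg2)
  expect_false(identical(s1$final$A, s3$final$A))
})

test_that("concentrations are exactly zero outside the restricted region", {
  cfg <- test_config(eta = 4, T = 10, n = 96, dt = 0.002, seed = 2,
                     snapshot_every = 5)
  out <- run_sim(cfg)
  chi <- restricted_region_threshold(cfg$mech$epsilon, cfg$eps0)
  for (sn in out$snapshots) {
    outside <- sn$phi <= chi
    expect_identical(max(abs(sn$A[outside])), 0)
    expect_identical(max(abs(sn$R[outside])), 0)
    expect_true(all(sn$A >= 0))
  }
})

test_that("masked diffusion conserves the total phi-weighted activator", {
  # reactions, noise and boundary motion all off: pure masked diffusion
  g <- test_grid(96)
  bio <- biochem_params(ka = 0, b = 0, d1 = 0, d2 = 0, c1 = 0, c2 = 0,
                        sigma = 0)
  cfg <- sim_config(biochem = bio, mech = mech_params(eta = 0, gamma = 0,
                                                      BS = 0),
                    grid = g, dt = 0.002, T = 5, r0 = 14, seed = 1,
                    record_every = 1)
  # blob well inside the masked region so no mass reaches the rim
  phi <- init_disk(14, g, 2)
  co <- grid_coords(g)
  blob <- outer(exp(-(co$x - 25)^2 / 2), exp(-(co$y - 25)^2 / 2))
  st <- list(phi = phi, A = blob, R = matrix(0, g$nx, g$ny))
  out <- run_sim(cfg, init_state = st)
  m0 <- sum(phi * blob)
  m1 <- sum(out$final$phi * out$final$A)
  expect_lt(abs(m1 - m0) / m0, 1e-8)
  # and the blob has actually spread
  expect_lt(max(out$final$A), max(blob))
})

test_that("noise-free symmetric initial conditions never break symmetry", {
  g <- test_grid(96)
  bio <- biochem_params(sigma = 0)
  cfg <- sim_config(biochem = bio, mech = mech_params(eta = 4),
                    grid = g, dt = 0.002, T = 30, r0 = 8, seed = 1,
                    record_every = 1)
  phi <- init_disk(8, g, 2)
  A <- matrix(0, g$nx, g$ny)
  A[phi > 0.5] <- bio$At   # radially symmetric excitation
  st <- list(phi = phi, A = A, R = matrix(0, g$nx, g$ny))
  out <- run_sim(cfg, init_state = st)
  tr <- out$trajectory
  expect_lt(max(abs(tr$x - 25)), g$dx)
  expect_lt(max(abs(tr$y - 25)), g$dy)
  # the biochemical fields did evolve
  expect_gt(max(abs(out$final$A - A)), 0.1)
})

test_that("uniform fields inside a static disk reduce to the well-mixed system", {
  g <- test_grid(96)
  bio <- biochem_params(sigma = 0)
  cfg <- sim_config(biochem = bio, mech = mech_params(eta = 0, gamma = 0,
                                                      BS = 0),
                    grid = g, dt = 0.001, T = 5, r0 = 10, seed = 1,
                    record_every = 1)
  phi <- init_disk(10, g, 2)
  A0v <- 1; R0v <- 2
  st <- list(phi = phi, A = matrix(A0v, g$nx, g$ny),
             R = matrix(R0v, g$nx, g$ny))
  out <- run_sim(cfg, init_state = st)
  wm <- simulate_well_mixed(bio, T = 5, dt = 0.001, A0 = A0v, R0 = R0v)
  ic <- round(g$nx / 2)
  expect_equal(out$final$A[ic, ic], tail(wm$series$A, 1), tolerance = 5e-3)
  expect_equal(out$final$R[ic, ic], tail(wm$series$R, 1), tolerance = 5e-3)
})

test_that("stability guards reject unsafe time steps", {
  expect_error(sim_config(grid = pf_grid(256, 256, 50, 50), dt = 0.05),
               "CFL")
  expect_error(simulate_front_1d(dx = 0.1, dt = 0.01), "CFL")
})

test_that("unit conversion maps simulation to physical scales", {
  expect_equal(to_physical(0.6, "speed"), 0.12)
  expect_equal(to_physical(100, "time"), 500)
  expect_equal(to_physical(10, "tau"), 20)
  expect_error(to_physical(1, "mass"))
})

test_that("configurations round-trip through YAML", {
  cfg <- test_config(eta = 3, T = 42, n = 64, dt = 0.004, seed = 5)
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$mech$eta, 3)
  expect_equal(cfg2$T, 42)
  expect_equal(cfg2$grid$nx, 64L)
  expect_equal(cfg2$seed, 5L)
  unlink(f)
})

test_that("trajectories round-trip through CSV tracking tables", {
  cfg <- test_config(eta = 4, T = 5, n = 64, dt = 0.004, seed = 7)
  sim <- run_sim(cfg)
  f <- tempfile(fileext = ".csv")
  write_trajectory(sim, f)
  d <- read_track(f)
  expect_equal(nrow(d), nrow(sim$trajectory))
  expect_equal(d$x_um, sim$trajectory$x)
  expect_true("area_um2" %in% names(d))
  unlink(f)
})
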
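test_that("measure_wave recovers the speed of a constructed front", {
  # synthetic history: tanh front moving right at 0.3 um/s
  x <- seq(0.05, 80, by = 0.1)
  ts <- seq(0, 60, by = 1)
  A <- t(vapply(ts, function(t) 2 / (1 + exp((x - 10 - 0.3 * t) / 0.5)),
                numeric(length(x))))
  h <- structure(list(t = ts, x = x, A = A, R = A * 0,
                      params = biochem_params(), bc = "noflux"),
                 class = "wave_history")
  m <- measure_wave(h)
  expect_equal(m$speed, 0.3, tolerance = 1e-3)
  expect_true(m$steady)
  # stationary profile: zero speed
  A0 <- matrix(rep(A[1, ], length(ts)), nrow = length(ts), byrow = TRUE)
  h0 <- structure(list(t = ts, x = x, A = A0, R = A0 * 0,
                       params = biochem_params(), bc = "noflux"),
                  class = "wave_history")
  expect_equal(measure_wave(h0)$speed, 0)
  # no crossings at all: flagged as "no front"
  hn <- h0; hn$A <- matrix(0, length(ts), length(x))
  mn <- measure_wave(hn)
  expect_true(is.na(mn$speed))
  expect_false(mn$steady)
})

test_that("cubic front speed formula and stall condition", {
  expect_equal(cubic_front_speed(2, 1, 0, 0.25, 1), 0.5)
  expect_equal(cubic_front_speed(1, 1, 0, 0.5, 1), 0)
  expect_error(cubic_front_speed(1, 1, 1, 0.5, 0), "roots")
})

test_that("simulated cubic-reaction front matches the analytic speed", {
  k <- 1; D <- 0.5; u <- c(0, 0.3, 1)
  c_exact <- cubic_front_speed(k, D, u[1], u[2], u[3])
  h <- simulate_cubic_front(k, D, u[1], u[2], u[3], L = 50, dx = 0.05,
                            dt = 5e-4, T = 40)
  m <- measure_wave(h)
  expect_true(m$steady)
  expect_equal(m$speed, c_exact, tolerance = 0.02 * c_exact)
})

test_that("mirror symmetry: centered bump emits equal and opposite fronts", {
  p <- biochem_params(tau = 20)
  nx <- round(120 / 0.1)
  x <- (seq_len(nx) - 0.5) * 0.1
  A0 <- ifelse(abs(x - 60) < 3, p$At, 0)
  R0 <- rep(4, nx)  # uniform inhibitor keeps the background quiet
  h <- simulate_front_1d(p, L = 120, dx = 0.1, dt = 1e-3, T = 25,
                         init = "custom", A0 = A0, R0 = R0, clamp_R = TRUE)
  mr <- measure_wave(h, side = "right")
  ml <- measure_wave(h, side = "left")
  expect_true(mr$steady && ml$steady)
  expect_gt(mr$speed, 0)
  expect_lt(ml$speed, 0)
  expect_lt(abs(mr$speed + ml$speed) / mr$speed, 0.005)
})

test_that("grid refinement changes the measured front speed by < 2%", {
  p <- biochem_params(tau = 20)
  sp <- vapply(c(0.1, 0.05), function(dxx) {
    h <- simulate_front_1d(p, L = 60, dx = dxx, dt = 2.5e-4, T = 30,
                           init = "bump", bump_width = 5, R_bg = 4,
                           clamp_R = TRUE)
    measure_wave(h)$speed
  }, numeric(1))
  expect_lt(abs(sp[1] - sp[2]) / sp[2], 0.02)
})

test_that("sub-threshold bumps decay instead of launching fronts", {
  p <- biochem_params(tau = 20)
  nx <- round(60 / 0.1)
  x <- (seq_len(nx) - 0.5) * 0.1
  # tiny amplitude bump over an inhibited background
  A0 <- ifelse(x < 5, 0.05, 0)
  h <- simulate_front_1d(p, L = 60, dx = 0.1, dt = 1e-3, T = 20,
                         init = "custom", A0 = A0, R0 = rep(4, nx),
                         clamp_R = TRUE)
  expect_lt(max(h$A[nrow(h$A), ]), 0.1)
  expect_equal(measure_wave(h)$n_fronts, 0)
})

test_that("frozen-inhibitor limit: DR = 0 with slow tau approaches the clamped speed", {
  p <- biochem_params(tau = 1e4, DR = 0)
  nx <- round(80 / 0.1)
  x <- (seq_len(nx) - 0.5) * 0.1
  A0 <- ifelse(x < 5, p$At, 0)
  h_free <- simulate_front_1d(p, L = 80, dx = 0.1, dt = 1e-3, T = 30,
                              init = "custom", A0 = A0, R0 = rep(4, nx))
  h_clamp <- simulate_front_1d(p, L = 80, dx = 0.1, dt = 1e-3, T = 30,
                               init = "custom", A0 = A0, R0 = rep(4, nx),
                               clamp_R = TRUE)
  v_free <- measure_wave(h_free)$speed
  v_clamp <- measure_wave(h_clamp)$speed
  expect_equal(v_free, v_clamp, tolerance = 0.02 * v_clamp)
})

test_that("wavelength estimate follows the square-root scaling", {
  expect_equal(wavelength_estimate(0.5, 10), 2 * sqrt(5))
  expect_equal(wavelength_estimate(0.5, 40), 2 * wavelength_estimate(0.5, 10))
  expect_error(wavelength_estimate(0, 1), "> 0")
})

test_that("ring pulses select a stable train whose spacing brackets the estimate", {
  p <- biochem_params(tau = 20)
  res <- run_cached("ring_scan_tau20", ring_pulse_scan(
    p, lambdas = c(24, 20, 16, 12), T = 120))
  stable <- res$table[res$table$steady, ]
  expect_gt(nrow(stable), 0)
  # dispersion: denser trains run slower
  expect_true(all(diff(stable$speed[order(stable$lambda)]) >= 0))
  # the diffusion-decay estimate is an order-of-magnitude guide:
  # measured minimal spacing within a factor ~3
  est <- wavelength_estimate(0.5, 20)
  expect_lt(res$lambda_min / est, 3.5)
  expect_gt(res$lambda_min / est, 1 / 3.5)
})

test_that("min_speed_scan tabulates c_min over inhibitor parameters", {
  res <- min_speed_scan(biochem_params(), DR_values = 0.5,
                        tau_values = c(10, 20),
                        lambdas = seq(24, 10, by = -2), T = 100)
  expect_equal(nrow(res), 2)
  expect_true(all(c("DR", "tau", "c_min", "lambda_min", "stable") %in%
                    names(res)))
  expect_true(all(res$stable))
  # the slower inhibitor supports slower (and denser) stable trains
  expect_gte(res$c_min[res$tau == 10], res$c_min[res$tau == 20])
})
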
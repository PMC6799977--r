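# Shared fixtures: small, fast simulation profiles used across tests.

default_biochem <- function(...) biochem_params(...)

# reduced-resolution 2D profile used throughout the suite
test_grid <- function(n = 128) pf_grid(n, n, 50, 50)

test_config <- function(eta, T = 150, r0 = 8, seed = 3,
                        init_mode = "noise", n = 128, dt = 0.002, ...) {
  sim_config(grid = test_grid(n), dt = dt, T = T, r0 = r0, seed = seed,
             mech = mech_params(eta = eta),
             init_mode = init_mode, ...)
}

# cache expensive simulations within one test run
run_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(key, expr) {
    if (!exists(key, envir = cache)) assign(key, force(expr), envir = cache)
    get(key, envir = cache)
  }
})
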
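# Waveform-relaxation solver on small networks.

test_that("symmetric identical neurons carry zero gap current", {
  # all neurons share parameters, initial state and (std = 0) noise, so
  # every pairwise potential difference vanishes along the trajectory.
  # At rest the exchanged interpolants are exact and the cancellation is
  # machine-precise with immediate convergence
  quiet <- list(N = 4L, K_gap = 2L, M = 2L, T = 1L, duration_ms = 5,
                init_ms = 0, noise = list(mean = 0, std = 0), seed = 5)
  at_rest <- run_simulation(quiet)
  expect_lte(max(at_rest$stats$wfr_iterations), 2L)
  un0 <- quiet
  un0$g <- 0
  expect_lt(max_V_diff(at_rest$recordings,
                       run_simulation(un0)$recordings), 1e-12)
  # under common drive each neuron sees its partners through the exchanged
  # interpolant, so the symmetric cancellation holds to interpolation
  # accuracy (one extra iteration corrects the constant initial guess)
  cfg <- list(N = 4L, K_gap = 2L, M = 2L, T = 1L, duration_ms = 5,
              init_ms = 0, noise = list(mean = 150, std = 0), seed = 5)
  coupled <- run_simulation(cfg)
  expect_lte(max(coupled$stats$wfr_iterations), 3L)
  un <- cfg
  un$g <- 0
  uncoupled <- run_simulation(un)
  expect_lt(max_V_diff(coupled$recordings, uncoupled$recordings), 1e-8)
})

test_that("a resting neuron stays at rest without noise or coupling", {
  cfg <- list(N = 4L, K_gap = 2L, M = 1L, T = 1L, g = 0,
              noise = list(mean = 0, std = 0),
              duration_ms = 100, init_ms = 0, seed = 1)
  out <- run_simulation(cfg)
  V0 <- out$recordings$V_mV[out$recordings$time_ms == 0][1]
  expect_lt(max(abs(out$recordings$V_mV - V0)), 1e-3)
})

test_that("iteration counts respect the configured maximum", {
  cfg <- list(N = 12L, K_gap = 4L, M = 2L, T = 1L, duration_ms = 10,
              init_ms = 0, seed = 2)
  out <- run_simulation(cfg)
  expect_true(all(out$stats$wfr_iterations <= 5L))
  expect_true(all(out$stats$wfr_iterations >= 1L))
  one <- cfg
  one$wfr <- list(max_iterations = 1L)
  expect_true(all(run_simulation(one)$stats$wfr_iterations == 1L))
})

test_that("trajectories are identical across communication modes", {
  cfg <- list(N = 12L, K_gap = 4L, M = 3L, T = 2L, duration_ms = 10,
              init_ms = 0, seed = 8)
  a <- run_simulation(cfg)
  g <- cfg
  g$mode <- "allgather"
  b <- run_simulation(g)
  expect_lt(max_V_diff(a$recordings, b$recordings), 1e-12)
})

test_that("trajectories are identical across rank counts", {
  base <- list(N = 12L, K_gap = 4L, duration_ms = 10, init_ms = 0, seed = 8)
  runs <- lapply(list(c(1L, 1L), c(2L, 3L), c(4L, 1L)), function(mt) {
    cfg <- base
    cfg$M <- mt[1]
    cfg$T <- mt[2]
    run_simulation(cfg)$recordings
  })
  expect_lt(max_V_diff(runs[[1]], runs[[2]]), 1e-9)
  expect_lt(max_V_diff(runs[[1]], runs[[3]]), 1e-9)
})

test_that("committed trajectory tracks the dense-exchange reference", {
  cfg <- list(N = 8L, K_gap = 4L, M = 2L, T = 1L, duration_ms = 10,
              init_ms = 0, seed = 3, abs_tol = 1e-9)
  wfr <- run_simulation(cfg)
  ref <- run_dense_reference(cfg)
  expect_lt(max_V_diff(wfr$recordings, ref), 10 * 1e-5)
})

test_that("gap junctions pull depolarized initial conditions together", {
  # staggered initial potentials, shared (deterministic) noise: the spread
  # across neurons must shrink under diffusive gap coupling
  cfg <- list(N = 6L, K_gap = 2L, M = 1L, T = 1L, g = 1.0,
              noise = list(mean = 100, std = 0),
              init_V = c(-75, -55, -70, -60, -65, -58),
              duration_ms = 100, init_ms = 0, seed = 4)
  out <- run_simulation(cfg)
  rec <- out$recordings
  spread <- function(t) {
    v <- rec$V_mV[rec$time_ms == t]
    max(v) - min(v)
  }
  expect_lt(spread(100), spread(0))
  # and specifically for a coupled pair
  v1 <- rec$V_mV[rec$gid == 1]
  v2 <- rec$V_mV[rec$gid == 2]
  expect_lt(abs(v1[length(v1)] - v2[length(v2)]),
            abs(v1[1] - v2[1]))
})

test_that("convergence residuals shrink over iterations on the benchmark", {
  # diagnostic: tightening tolerance forces more iterations, and residuals
  # from later iterations are (non-strictly) smaller in most intervals
  cfg <- list(N = 12L, K_gap = 6L, M = 1L, T = 1L, duration_ms = 20,
              init_ms = 0, seed = 6,
              wfr = list(tolerance = 1e-9, max_iterations = 6L))
  out <- run_simulation(cfg)
  expect_true(mean(out$stats$wfr_iterations >= 3) > 0.5)
  expect_true(all(is.finite(out$stats$wfr_residuals)))
})

test_that("zero-duration simulations report only the initial state", {
  cfg <- list(N = 6L, K_gap = 2L, duration_ms = 0, init_ms = 0, seed = 1)
  out <- run_simulation(cfg)
  expect_equal(unique(out$recordings$time_ms), 0)
  expect_equal(nrow(out$recordings), 6L)
  expect_equal(nrow(out$spikes), 0L)
})

test_that("error to the dense reference decreases with WFR tolerance", {
  base <- list(N = 8L, K_gap = 2L, M = 1L, T = 1L, duration_ms = 10,
               init_ms = 0, seed = 9, abs_tol = 1e-9)
  ref <- run_dense_reference(base)
  errs <- vapply(c(1e-3, 1e-5, 1e-7), function(tol) {
    cfg <- base
    cfg$wfr <- list(tolerance = tol, max_iterations = 20L)
    max_V_diff(run_simulation(cfg)$recordings, ref)
  }, 0)
  expect_true(all(diff(errs) <= 1e-12))
})
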
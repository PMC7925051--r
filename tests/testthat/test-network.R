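test_that("synaptic activation counts the fraction above threshold", {
  expect_equal(synaptic_activation(rep(0, 10), 50), 0)
  expect_equal(synaptic_activation(c(60, 40), 50), 0.5)
  expect_equal(synaptic_activation(c(51, 52, 53, 49), 50), 0.75)
  expect_error(synaptic_activation(numeric(0)), "empty")
})

test_that("an uncoupled neuron relaxes to the stable rest state", {
  ## eta + I = -1: rest at V = -1 (the root of V^2 - 1 with negative slope)
  p <- default_params(Je = 0, Ji = 0, eta_bar = -1, delta = 1e-12)
  st <- network_init(p, N_e = 1L, N_i = 1L, v0 = 0)
  for (i in 1:20000) st <- step_network(st, 1e-3, 0, p)$state
  expect_equal(st$V_e, -1, tolerance = 1e-5)
  ## a vanishing step leaves the state unchanged
  st2 <- network_init(p, N_e = 3L, N_i = 3L, v0 = 0.3)
  out <- step_network(st2, 1e-9, 0, p)
  expect_equal(out$state$V_e, st2$V_e, tolerance = 1e-6)
  expect_length(out$spikes_e, 0)
})

test_that("free-neuron inter-spike intervals match the closed-form QIF period", {
  p <- default_params(Je = 0, Ji = 0, eta_bar = 1, delta = 1e-12)
  sim <- run_network(p, N_e = 1L, N_i = 1L, constant_protocol(0, 40),
                     dt = 1e-3, seed = 1)
  isi <- diff(sim$raster$t[sim$raster$population == "e"])
  expect_gt(length(isi), 5)
  closed <- qif_isi_closed_form(1, p$Vpeak)
  expect_lt(abs(median(isi) - closed) / closed, 0.01)
})

test_that("all neurons at rest fire no spikes", {
  p <- default_params(Je = 0, Ji = 0, eta_bar = -1, delta = 1e-12)
  sim <- run_network(p, N_e = 50L, N_i = 50L, constant_protocol(0, 5),
                     dt = 1e-3, v0 = -1)
  expect_equal(nrow(sim$raster), 0L)
  expect_true(all(sim$rate_e$rate == 0))
})

test_that("population rate integrates back to the spike count and handles edge cases", {
  ## 100 neurons each spiking once inside a single unit-width bin
  raster <- data.frame(t = seq(0.3, 0.7, length.out = 100),
                       population = "e", neuron = 1:100)
  rt <- population_rate(raster, N = 100, bin_width = 1, t_range = c(0, 1))
  expect_equal(rt$rate, 1)
  ## empty raster -> zero trace, not an error
  rt0 <- population_rate(raster[0, ], N = 100, bin_width = 0.1,
                         t_range = c(0, 2))
  expect_true(all(rt0$rate == 0))
  ## unsmoothed rate integrates exactly to the spike count
  r2 <- fixture_signal("poisson_raster", seed = 3, rate = 0.2, N = 100L,
                       t_end = 100)
  rt2 <- population_rate(r2, N = 100, bin_width = 0.5, t_range = c(0, 100))
  expect_equal(sum(rt2$rate) * 0.5 * 100, nrow(r2))
  ## time-averaged estimate within 3 standard errors of the true rate
  est <- mean(rt2$rate)
  se <- sqrt(0.2 / (100 * 100))
  expect_lt(abs(est - 0.2), 3 * se)
  expect_error(population_rate(raster, 100, bin_width = 0), "positive")
})

test_that("gate traces stay in [0,1] and spikes are conserved in the raster", {
  p <- default_params()
  sim <- run_network(p, N_e = 200L, N_i = 200L, step_protocol(),
                     dt = 1e-3, seed = 1)
  expect_true(all(sim$gates$S_e >= 0 & sim$gates$S_e <= 1))
  expect_true(all(sim$gates$S_i >= 0 & sim$gates$S_i <= 1))
  expect_true(all(diff(sim$raster$t) >= 0))
  expect_true(all(sim$raster$neuron >= 1 &
                    sim$raster$neuron <= 200))
  ## every raster row is one threshold crossing: rebinning the raster at
  ## the Euler step returns the total count
  expect_equal(sum(sim$raster$population == "e") +
                 sum(sim$raster$population == "i"), nrow(sim$raster))
})

test_that("finite-size error of the quiescent rate shrinks with N", {
  p <- default_params()
  eq <- quiescent_equilibrium(p, 0)
  errs <- sapply(c(500L, 2000L, 8000L), function(N) {
    s <- run_network(p, N_e = N, N_i = N, constant_protocol(0, 20),
                     dt = 1e-3, seed = 1)
    abs(mean(s$rate_e$rate[s$rate_e$t > 8]) - eq$state[1]) / eq$state[1]
  })
  expect_true(all(diff(errs) < 0))
})

test_that("voltage distribution check matches its Lorentzian null", {
  set.seed(11)
  v0 <- -2
  r0 <- 0.5
  V <- v0 + pi * r0 * tan(pi * (runif(1e4) - 0.5))
  expect_lt(voltage_distribution_check(V, r0, v0, trim = 20), 0.03)
  ## a point mass sits at sup-distance 1/2 from any continuous null
  expect_equal(voltage_distribution_check(rep(v0, 500), r0, v0, trim = 20),
               0.5, tolerance = 1e-2)
  expect_error(voltage_distribution_check(V, 0, v0), "positive")
})

test_that("stationary network voltages are Lorentzian with half-width pi r", {
  p <- default_params()
  sim <- run_network(p, N_e = 4000L, N_i = 4000L, constant_protocol(0, 20),
                     dt = 1e-3, seed = 1)
  r_net <- mean(sim$rate_e$rate[sim$rate_e$t > 8])
  V <- sim$final$V_e
  D <- voltage_distribution_check(V, r_net, median(V), trim = 20)
  expect_lt(D, 0.1)
})

test_that("heterogeneity modes are reproducible and the blow-up error names the neuron", {
  p <- default_params()
  a <- network_init(p, 100L, 100L, het_mode = "sample", seed = 9)
  b <- network_init(p, 100L, 100L, het_mode = "sample", seed = 9)
  expect_identical(a$eta_e, b$eta_e)
  q <- network_init(p, 101L, 101L)
  expect_equal(q$eta_e[51], p$eta_bar)   # quantile median
  st <- network_init(p, 2L, 2L, v0 = 1e200)
  expect_error(step_network(st, 1, 0, p), "neuron")
})
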
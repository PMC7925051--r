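test_that("the synaptic gate has its closed-form values and limits", {
  expect_equal(synaptic_gate(10, 40, 50, gate_width = "r"), 0.25)
  expect_equal(synaptic_gate(3, 50, 50), 0.5)          # v at threshold
  expect_equal(synaptic_gate(0, 40, 50), 0)            # r -> 0+, v < Vth
  expect_equal(synaptic_gate(0, 60, 50), 1)
  expect_equal(synaptic_gate(0, 50, 50), 0.5)
  ## the two width conventions agree after rescaling r by pi
  expect_equal(synaptic_gate(2, 10, 50, "pi_r"),
               synaptic_gate(2 * pi, 10, 50, "r"))
})

test_that("gate is monotone in v, and in r below threshold (property)", {
  set.seed(1)
  r <- runif(1e4, 1e-3, 20)
  v <- runif(1e4, -80, 45)
  eps <- 1e-6
  up_v <- synaptic_gate(r, v + eps, 50) - synaptic_gate(r, v, 50)
  up_r <- synaptic_gate(r + eps, v, 50) - synaptic_gate(r, v, 50)
  expect_true(all(up_v > 0))
  expect_true(all(up_r > 0))
  expect_true(all(synaptic_gate(r, v, 50) > 0 & synaptic_gate(r, v, 50) < 1))
})

test_that("vector field matches the printed structure at zero rate and at roots", {
  p <- default_params()
  d <- mf_rhs(c(0, -1, 0, -1), p, 0)
  expect_equal(d[1], p$delta / pi)
  expect_equal(d[3], p$delta / pi)
  ## decoupled closed-form equilibrium is a root of the vector field
  p0 <- default_params(Je = 0, Ji = 0)
  eq <- decoupled_equilibrium(-5, 1)
  f <- mf_rhs(c(eq["r"], eq["v"], eq["r"], eq["v"]), p0, 0)
  expect_lt(sqrt(sum(f^2)), 1e-12)
  expect_error(mf_rhs(c(NA, 0, 0, 0), p, 0), "non-finite")
})

test_that("equilibria are invariant under integration and RK4 self-converges at order 4", {
  p <- default_params()
  eq <- quiescent_equilibrium(p, 0)
  tr <- mf_integrate(eq$state, constant_protocol(0, 100), p, dt = 1e-2)
  dev <- max(abs(mf_final_state(tr) - eq$state))
  expect_lt(dev, 1e-6)
  ## self-convergence on a smooth transient stretch, short enough that the
  ## error is truncation- rather than roundoff-dominated
  x0 <- eq$state + c(0.05, 1, 0.05, 1)
  ref <- mf_final_state(mf_integrate(x0, constant_protocol(0, 1), p,
                                     dt = 1e-3, keep_every = 1000L))
  hs <- c(4e-2, 2e-2, 1e-2)
  errs <- sapply(hs, function(h)
    max(abs(mf_final_state(mf_integrate(x0, constant_protocol(0, 1), p,
                                        dt = h,
                                        keep_every = round(1 / h))) - ref)))
  slope <- coef(lm(log(errs) ~ log(hs)))[2]
  expect_gt(slope, 3.5)
  expect_lt(slope, 4.5)
  ## halving the step barely moves a smooth-regime endpoint
  e1 <- mf_final_state(mf_integrate(x0, constant_protocol(0, 50), p,
                                    dt = 1e-2))
  e2 <- mf_final_state(mf_integrate(x0, constant_protocol(0, 50), p,
                                    dt = 5e-3))
  expect_lt(max(abs(e1 - e2)) / max(abs(e2)), 1e-5)
})

test_that("integrator agrees with an independent fixed-step RK4 (deSolve)", {
  skip_if_not_installed("deSolve")
  p <- default_params(Je = 20)
  x0 <- c(0.2, -1, 0.2, -1)
  ours <- mf_final_state(mf_integrate(x0, constant_protocol(2, 5), p,
                                      dt = 1e-2, keep_every = 1L))
  ds <- deSolve::rk4(y = x0, times = seq(0, 5, by = 1e-2),
                     func = function(t, y, parms) list(mf_rhs(y, p, 2)),
                     parms = NULL)
  expect_equal(as.numeric(ours), as.numeric(ds[nrow(ds), -1]),
               tolerance = 1e-9)
})

test_that("rates never cross below zero along trajectories (property)", {
  p <- default_params(Je = 50)
  tr <- mf_integrate(c(0.01, -8, 0.01, -8), constant_protocol(-3, 100), p,
                     dt = 1e-3)
  expect_gte(min(tr$r_e), 0)
  expect_gte(min(tr$r_i), 0)
  tr2 <- mf_integrate(c(5, 2, 5, 2), step_protocol(), default_params(),
                      dt = 1e-3)
  expect_gte(min(tr2$r_e), -1e-12)
})

test_that("the step-stimulus run goes from near-constant to oscillatory", {
  p <- default_params()
  eq <- quiescent_equilibrium(p, 0)
  tr <- mf_integrate(eq$state + c(1e-3, 0, 1e-3, 0), step_protocol(), p,
                     dt = 1e-3)
  pre <- tr$r_e[tr$t > 1 & tr$t < 2]
  post <- tr$r_e[tr$t > 6]
  expect_lt(max(pre) - min(pre), 1e-3)
  expect_gt(max(post) - min(post), 1)
  cv_pre <- sd(pre) / mean(pre)
  cv_post <- sd(post) / mean(post)
  expect_gt(cv_post / max(cv_pre, 1e-12), 5)
})

test_that("divergence raises an informative error", {
  p <- default_params()
  expect_error(mf_integrate(c(1, 1e8, 1, 1e8), constant_protocol(0, 1), p,
                            dt = 1e-2), "diverged")
})

test_that("identical traces compare as identical; disjoint windows error", {
  p <- default_params()
  tr <- mf_integrate(c(0.1, -2, 0.1, -2), constant_protocol(0, 5), p)
  self <- data.frame(t = tr$t, rate = tr$r_e)
  cmp <- compare_to_network(tr, self, c(0, 5))
  expect_equal(cmp$rms, 0)
  expect_equal(cmp$rel_mean_rate_error, 0)
  expect_error(compare_to_network(tr, self, c(8, 9)), "disjoint")
})
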
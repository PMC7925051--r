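test_that("peak detection recovers sinusoid peaks with sub-grid accuracy", {
  s <- fixture_signal("sinusoid", t_end = 20 * pi)
  pk <- detect_peaks(s)
  expect_equal(nrow(pk), 10L)
  expect_true(all(abs(pk$amplitude - 1) < 1e-4))
  expect_true(all(abs(diff(pk$t) - 2 * pi) < 1e-3))
  ## constant trace: no peaks
  flat <- data.frame(t = 0:100, y = rep(2, 101))
  expect_equal(nrow(detect_peaks(flat)), 0L)
  expect_error(detect_peaks(flat[1:2, ]), "too short")
})

test_that("period classification matches the fixtures' ground truth", {
  expect_identical(classify_period(detect_peaks(fixture_signal("sinusoid"))),
                   1L)
  a <- detect_peaks(fixture_signal("alternating_peaks"))
  expect_identical(classify_period(a), 2L)
  q <- detect_peaks(fixture_signal("period4_peaks"))
  expect_identical(classify_period(q), 4L)
  expect_error(classify_period(a[1:4, ]), "insufficient")
})

test_that("classification is invariant to time shift and amplitude scaling", {
  pk <- detect_peaks(fixture_signal("period4_peaks"))
  shifted <- transform(pk, t = t + 137.5)
  scaled <- transform(pk, amplitude = amplitude * 8.3)
  expect_identical(classify_period(shifted), classify_period(pk))
  expect_identical(classify_period(scaled), classify_period(pk))
})

test_that("a period-n classification shows n points on the Poincare return map", {
  pk <- detect_peaks(fixture_signal("alternating_peaks"))
  n <- classify_period(pk)
  ## peak amplitudes are the return-map observable: n clusters
  km <- kmeans(pk$amplitude, centers = n, nstart = 5)
  expect_equal(length(unique(km$cluster)), n)
  expect_gt(min(dist(km$centers)), 0.1)
})

test_that("an irregular peak sequence is labelled chaotic", {
  set.seed(4)
  pk <- data.frame(t = cumsum(runif(40, 0.5, 1.5)),
                   amplitude = runif(40, 1, 2))
  expect_identical(classify_period(pk), "chaotic")
})

test_that("the ISI sweep records intervals per grid point and survives one-point grids", {
  p <- default_params()
  sw <- isi_bifurcation_sweep(p, -3, 50, dt = 1e-3, t_transient = 150,
                              t_measure = 60)
  s <- attr(sw, "summary")
  expect_equal(nrow(s), 1L)
  expect_identical(s$class, "1")
  expect_identical(s$n_clusters, 1L)
  expect_true(all(sw$interval > 0))
})

test_that("continued and fixed initialization agree where one attractor exists", {
  p <- default_params()
  grid <- c(66, 70, 74)
  a <- attr(isi_bifurcation_sweep(p, 0, grid, dt = 1e-3,
                                  t_transient = 150, t_measure = 60,
                                  init_mode = "continue"), "summary")
  b <- attr(isi_bifurcation_sweep(p, 0, grid, dt = 1e-3,
                                  t_transient = 150, t_measure = 60,
                                  init_mode = "fixed"), "summary")
  expect_identical(a$class, b$class)
})

test_that("the largest Lyapunov exponent is negative at a stable focus and ~0 on a cycle", {
  p30 <- default_params(Je = 30)
  lam_focus <- lyapunov_max(p30, 5, state0 = c(3.3, 0.9, 3.3, 0.2),
                            t_settle = 100, t_total = 500, seed = 3)
  expect_lt(lam_focus, -0.05)
  p15 <- default_params()
  lam_cyc <- lyapunov_max(p15, 8, state0 = c(1, 0, 1, 0), t_settle = 100,
                          t_total = 1000, seed = 3)
  expect_lt(abs(lam_cyc), 0.01)
  ## determinism under the seed
  lam_cyc2 <- lyapunov_max(p15, 8, state0 = c(1, 0, 1, 0), t_settle = 100,
                           t_total = 1000, seed = 3)
  expect_identical(lam_cyc, lam_cyc2)
})

test_that("shooting converges on the synchronized cycle with a unit trivial multiplier", {
  p <- default_params()
  sd <- harvest_cycle_seed(p, 8, Je = 15, t_settle = 100, dt = 1e-3)
  expect_false(is.null(sd))
  lc <- find_limit_cycle(p, 8, sd$x0, sd$T0, dt = 1e-3)
  expect_true(lc$converged)
  expect_lt(lc$residual, 1e-8)
  expect_lt(lc$trivial_error, 1e-3)
  ## stability: every nontrivial multiplier inside the unit circle,
  ## cross-checked by time stepping a perturbed state back onto the cycle
  mu <- lc$multipliers
  triv <- which.min(Mod(mu - 1))
  expect_true(all(Mod(mu[-triv]) < 1))
  tr <- mf_integrate(lc$x0 * (1 + 1e-3), constant_protocol(8, 40), p,
                     dt = 1e-3)
  tl <- tr[tr$t > 20, ]
  pk <- detect_peaks(tl)
  expect_identical(classify_period(pk), 1L)
  expect_equal(median(diff(pk$t)), lc$period, tolerance = 1e-3)
})
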
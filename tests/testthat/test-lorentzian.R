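test_that("Lorentzian density has the closed-form peak, half-maximum and unit mass", {
  expect_equal(lorentzian_pdf(-5, -5, 1), 1 / pi)
  expect_equal(lorentzian_pdf(-4, -5, 1), 1 / (2 * pi))
  expect_true(all(lorentzian_pdf(seq(-50, 50, 0.5), 2, 0.3) > 0))
  ## symmetry about the center
  expect_equal(lorentzian_pdf(-5 + 1.7, -5, 1), lorentzian_pdf(-5 - 1.7, -5, 1))
  ## quadrature oracle: the density integrates to 1
  for (pars in list(c(-5, 1), c(0, 0.2), c(3, 4))) {
    mass <- integrate(lorentzian_pdf, -Inf, Inf, eta_bar = pars[1],
                      delta = pars[2], rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8)
  }
  expect_error(lorentzian_pdf(0, 0, -1), "positive")
  expect_error(lorentzian_pdf(0, 0, 0), "positive")
})

test_that("quantile grid hits exact equispaced probabilities of the CDF", {
  expect_equal(lorentzian_quantiles(0, 1, 1), 0)
  expect_equal(lorentzian_quantiles(-5, 1, 3), c(-6, -5, -4))
  q <- lorentzian_quantiles(-5, 1, 101)
  expect_true(all(diff(q) > 0))
  expect_equal(q[51], -5)                       # odd n: median = center
  ## CDF of the grid is exactly j/(n+1)
  n <- 257
  q <- lorentzian_quantiles(2, 0.5, n)
  expect_equal(lorentzian_cdf(q, 2, 0.5), seq_len(n) / (n + 1),
               tolerance = 1e-12)
  ## empirical CDF of the grid within 2/(n+1) of the true CDF everywhere
  n <- 1001
  q <- lorentzian_quantiles(-5, 1, n)
  sup <- max(abs(seq_len(n) / n - lorentzian_cdf(q, -5, 1)))
  expect_lt(sup, 2 / (n + 1))
  expect_error(lorentzian_quantiles(0, 1, 0), "positive integer")
})

test_that("random draws are seed-reproducible with the right center and scale", {
  a <- lorentzian_sample(-5, 1, 1000, seed = 42)
  b <- lorentzian_sample(-5, 1, 1000, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, lorentzian_sample(-5, 1, 1000, seed = 43)))
  ## median of a Cauchy sample estimates the center; order-statistic SE
  ## of the median is about pi/(2 sqrt(n)) * delta
  s <- lorentzian_sample(-5, 1, 1e5, seed = 7)
  expect_lt(abs(median(s) + 5), 0.05)
  ## degenerate width collapses every draw onto the center
  s0 <- lorentzian_sample(-5, 1e-12, 100, seed = 1)
  expect_true(all(abs(s0 + 5) < 1e-6))
})
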
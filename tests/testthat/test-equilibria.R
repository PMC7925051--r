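test_that("eigenvalue classification follows the standard taxonomy", {
  expect_equal(classify_eigenvalues(c(-1, -2, -3, -4)), "stable node")
  expect_equal(classify_eigenvalues(c(-0.1 + 2i, -0.1 - 2i, -1, -3)),
               "stable focus")
  expect_equal(classify_eigenvalues(c(0.5, -1, -2, -3)), "saddle")
  expect_equal(classify_eigenvalues(c(1, 2, 3, 4)), "unstable node")
  expect_equal(classify_eigenvalues(c(1e-9, -1, -2, -3)), "nonhyperbolic")
  expect_error(classify_eigenvalues(c(-1, -2)), "4 eigenvalues")
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(2)
  p_list <- list(default_params(), default_params(Je = 32),
                 default_params(rate_coupling = "full"),
                 default_params(gate_width = "r"))
  worst <- 0
  for (p in p_list) {
    for (k in 1:25) {
      x <- c(runif(1, 0.05, 8), runif(1, -30, 30),
             runif(1, 0.05, 8), runif(1, -30, 30))
      Iext <- runif(1, -5, 8)
      J <- mf_jacobian(x, p, Iext)
      Jfd <- matrix(0, 4, 4)
      for (j in 1:4) {
        h <- 1e-6 * max(1, abs(x[j]))
        e <- replace(numeric(4), j, h)
        Jfd[, j] <- (mf_rhs(x + e, p, Iext) - mf_rhs(x - e, p, Iext)) /
          (2 * h)
      }
      worst <- max(worst, max(abs(J - Jfd)) / max(abs(Jfd)))
    }
  }
  expect_lt(worst, 1e-5)
  expect_error(mf_jacobian(c(0, 0, 1, 0), default_params()), "r = 0")
})

test_that("decoupled populations give a block-diagonal Jacobian", {
  p0 <- default_params(Je = 0, Ji = 0)
  J <- mf_jacobian(c(1, 0, 2, -1), p0, 0)
  expect_equal(J[1:2, 3:4], matrix(0, 2, 2))
  expect_equal(J[3:4, 1:2], matrix(0, 2, 2))
})

test_that("the decoupled equilibrium matches the closed form to 1e-8", {
  p0 <- default_params(Je = 0, Ji = 0)
  eqs <- find_equilibria(p0, 0, n_starts = 256L)
  expect_equal(length(eqs), 1L)
  eq <- decoupled_equilibrium(-5, 1)
  expect_equal(unname(eqs[[1]]$state[c("r_e", "v_e")]),
               unname(eq), tolerance = 1e-8)
  expect_equal(unname(eqs[[1]]$state[c("r_i", "v_i")]),
               unname(eq), tolerance = 1e-8)
})

test_that("every reported equilibrium re-verifies (residual and classification)", {
  for (cfg in list(c(0, 15), c(-3, 32), c(5, 30))) {
    p <- default_params(Je = cfg[2])
    eqs <- find_equilibria(p, cfg[1], n_starts = 512L)
    for (e in eqs) {
      expect_lt(e$residual, 1e-9)
      J <- mf_jacobian(e$state, p, cfg[1])
      ev <- eigen(J, only.values = TRUE)$values
      expect_equal(classify_eigenvalues(ev), e$classification)
      f <- mf_rhs(e$state, p, cfg[1])
      expect_lt(sqrt(sum(f^2)), 1e-9)
    }
  }
})

test_that("root counts are stable when the number of starts doubles", {
  for (cfg in list(c(0, 15), c(-3, 32), c(-3, 50), c(5, 30))) {
    p <- default_params(Je = cfg[2])
    n1 <- length(find_equilibria(p, cfg[1], n_starts = 512L))
    n2 <- length(find_equilibria(p, cfg[1], n_starts = 1024L))
    expect_identical(n1, n2)
  }
})

test_that("sign-change scan finds no equilibrium cell the multistart missed", {
  ## coarse brute-force oracle on the (r_e, v_e) face: walk a grid of
  ## seeds through Newton and confirm the deduplicated root set matches
  ## find_equilibria at two parameter points
  for (cfg in list(c(-3, 32), c(0, 15))) {
    p <- default_params(Je = cfg[2])
    eqs <- find_equilibria(p, cfg[1], n_starts = 512L)
    found <- t(vapply(eqs, function(e) unname(e$state), numeric(4)))
    extra <- 0L
    for (r0 in c(0.05, 0.3, 1, 3, 8)) for (v0 in c(-5, -1, 0.5, 2)) {
      e <- refine_equilibrium(c(r0, v0, r0, v0), p, cfg[1])
      if (is.null(e)) next
      d <- min(sqrt(colSums((t(found) - unname(e$state))^2)))
      if (d > 1e-5) extra <- extra + 1L
    }
    expect_identical(extra, 0L)
  }
})
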
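test_that("branch continuation finds the fold pair, matching a brute-force scan", {
  p <- default_params()   # Je = 15
  eq <- quiescent_equilibrium(p, 0)
  br <- continue_equilibrium(p, "Iext", eq$state, 0, c(-6, 10), h0 = 0.05)
  sp <- branch_special_points(br)
  folds <- sort(sp$param[sp$type == "fold"])
  expect_equal(length(folds), 2L)
  ## brute-force oracle: the equilibrium count changes across each fold
  lo <- length(find_equilibria(p, folds[1] - 0.01, n_starts = 512L))
  mid <- length(find_equilibria(p, mean(folds), n_starts = 512L))
  hi <- length(find_equilibria(p, folds[2] + 0.01, n_starts = 512L))
  expect_identical(c(lo, mid, hi), c(1L, 3L, 1L))
  ## localization: count is already reduced 1e-3 beyond the fold
  expect_identical(length(find_equilibria(p, folds[2] + 1e-3,
                                          n_starts = 512L)), 1L)
  expect_identical(length(find_equilibria(p, folds[2] - 1e-3,
                                          n_starts = 512L)), 3L)
})

test_that("branch points re-verify against independent multistart roots", {
  p <- default_params(Je = 32)
  eqs <- find_equilibria(p, -3, n_starts = 512L)
  top <- eqs[[length(eqs)]]
  br <- continue_equilibrium(p, "Je", top$state, 32, c(25, 45),
                             Iext_fixed = -3, h0 = 0.2)
  d <- as.data.frame(br)
  pick <- round(seq(1, nrow(d), length.out = 8))
  for (i in pick) {
    pj <- default_params(Je = d$param[i])
    e <- refine_equilibrium(c(d$r_e[i], d$v_e[i], d$r_i[i], d$v_i[i]),
                            pj, -3)
    expect_false(is.null(e))
    expect_lt(max(abs(unname(e$state) -
                        c(d$r_e[i], d$v_e[i], d$r_i[i], d$v_i[i]))), 1e-5)
  }
})

test_that("the upper-branch Hopf is detected and matches eigenvalue grid bisection", {
  p <- default_params(Je = 32)
  eqs <- find_equilibria(p, -3, n_starts = 512L)
  top <- eqs[[length(eqs)]]
  br <- continue_equilibrium(p, "Je", top$state, 32, c(30, 50),
                             Iext_fixed = -3, h0 = 0.1)
  sp <- branch_special_points(br)
  hopf <- sp$param[sp$type == "hopf"]
  expect_equal(length(hopf), 1L)
  ## brute-force: bisect the leading real part of the focus pair on Je
  lead_re <- function(Je) {
    pj <- default_params(Je = Je)
    e <- refine_equilibrium(top$state + c(0.5, 0, 0.5, 0), pj, -3)
    ev <- e$eigenvalues
    max(Re(ev[Im(ev) > 1e-3]))
  }
  lo <- 38; hi <- 45
  for (k in 1:30) {
    mid <- (lo + hi) / 2
    if (lead_re(mid) < 0) lo <- mid else hi <- mid
  }
  expect_lt(abs(hopf - (lo + hi) / 2), 1e-3)
})

test_that("continuation retraces to its start point (reversibility)", {
  p <- default_params()
  eq <- quiescent_equilibrium(p, -2)
  fwd <- continue_equilibrium(p, "Iext", eq$state, -2, c(-6, 0.5),
                              h0 = 0.05)
  end <- as.data.frame(fwd)[nrow(fwd), ]
  back <- continue_equilibrium(p, "Iext",
                               c(end$r_e, end$v_e, end$r_i, end$v_i),
                               end$param, c(-6, 0.5), h0 = 0.05,
                               direction = -1)
  d <- as.data.frame(back)
  i <- which.min(abs(d$param - (-2)))
  expect_lt(abs(d$param[i] - (-2)), 0.05)
  j <- which.min(abs(as.data.frame(fwd)$param - d$param[i]))
  expect_lt(max(abs(unlist(d[i, c("r_e", "v_e", "r_i", "v_i")]) -
                  unlist(as.data.frame(fwd)[j, c("r_e", "v_e", "r_i",
                                                 "v_i")]))), 1e-3)
})

test_that("codim-2 fold and Hopf curve points satisfy their defining conditions", {
  p <- default_params(Je = 32)
  eqs <- find_equilibria(p, -3, n_starts = 512L)
  top <- eqs[[length(eqs)]]
  br_dn <- continue_equilibrium(p, "Je", top$state, 32, c(5, 80),
                                Iext_fixed = -3, h0 = 0.1, direction = -1)
  spd <- branch_special_points(br_dn)
  fs <- spd[spd$type == "fold", ][1, ]
  f <- trace_codim2_curve(default_params(), "fold",
                          seed = list(x = c(fs$r_e, fs$v_e, fs$r_i,
                                            fs$v_i),
                                      Iext = -3, Je = fs$param),
                          window = c(-6, 10, 5, 80), label = "f",
                          max_points = 60)
  d <- as.data.frame(f)
  pick <- round(seq(1, nrow(d), length.out = 6))
  for (i in pick) {
    pj <- default_params(Je = d$Je[i])
    J <- mf_jacobian(c(d$r_e[i], d$v_e[i], d$r_i[i], d$v_i[i]), pj,
                     d$Iext[i])
    ev <- eigen(J, only.values = TRUE)$values
    expect_lt(min(Mod(ev)), 1e-4)
  }
  br_up <- continue_equilibrium(p, "Je", top$state, 32, c(5, 80),
                                Iext_fixed = -3, h0 = 0.1)
  sph <- branch_special_points(br_up)
  hs <- sph[sph$type == "hopf", ][1, ]
  h <- trace_codim2_curve(default_params(), "hopf",
                          seed = list(x = c(hs$r_e, hs$v_e, hs$r_i,
                                            hs$v_i),
                                      Iext = -3, Je = hs$param),
                          window = c(-6, 10, 5, 80), label = "h2",
                          max_points = 40)
  dh <- as.data.frame(h)
  pick <- round(seq(1, nrow(dh), length.out = 6))
  for (i in pick) {
    pj <- default_params(Je = dh$Je[i])
    J <- mf_jacobian(c(dh$r_e[i], dh$v_e[i], dh$r_i[i], dh$v_i[i]), pj,
                     dh$Iext[i])
    ev <- eigen(J, only.values = TRUE)$values
    pair <- ev[Im(ev) > 1e-3]
    expect_gt(length(pair), 0)
    expect_lt(min(abs(Re(pair))), 1e-4)
  }
})

test_that("region counting handles the degenerate layouts exactly", {
  win <- c(-6, 10, 5, 80)
  expect_equal(partition_regions(list(), win, 64)$n_regions, 1L)
  line <- data.frame(Iext = c(-6, 10), Je = c(5, 80))
  expect_equal(partition_regions(list(line), win, 64)$n_regions, 2L)
  cross <- list(data.frame(Iext = c(-6, 10), Je = c(40, 40)),
                data.frame(Iext = c(2, 2), Je = c(5, 80)))
  expect_equal(partition_regions(cross, win, 64)$n_regions, 4L)
})
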
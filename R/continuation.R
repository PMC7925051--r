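## ---- one-parameter pseudo-arclength continuation of equilibria ----------

## vector field and Jacobians as functions of (x, p) for a chosen free
## parameter, holding the other at `fixed`
mf_funs <- function(params, free = c("Iext", "Je"), Iext_fixed = 0) {
  free <- match.arg(free)
  if (free == "Iext") {
    F <- function(x, p) .cpp_mf_rhs(x, param_vec(params), p)
    Jx <- function(x, p) .cpp_mf_jac(x, param_vec(params))
  } else {
    F <- function(x, p) {
      pp <- params
      pp$Je <- p
      .cpp_mf_rhs(x, param_vec(pp), Iext_fixed)
    }
    Jx <- function(x, p) {
      pp <- params
      pp$Je <- p
      .cpp_mf_jac(x, param_vec(pp))
    }
  }
  Jp <- function(x, p) {
    h <- 1e-6 * max(1, abs(p))
    (F(x, p + h) - F(x, p - h)) / (2 * h)
  }
  list(F = F, Jx = Jx, Jp = Jp)
}

## corrector: Newton on [F(x,p); tang . ((x,p) - u_pred)] = 0
palc_correct <- function(fn, u_pred, tang, tol = 1e-11, maxit = 12L) {
  u <- u_pred
  for (it in seq_len(maxit)) {
    f <- fn$F(u[1:4], u[5])
    g <- sum(tang * (u - u_pred))
    if (!all(is.finite(f))) return(NULL)
    if (sqrt(sum(f^2)) < tol && abs(g) < tol) return(u)
    A <- rbind(cbind(fn$Jx(u[1:4], u[5]), fn$Jp(u[1:4], u[5])), tang)
    du <- tryCatch(solve(A, -c(f, g)), error = function(e) NULL)
    if (is.null(du)) return(NULL)
    u <- u + du
    if (u[1] < 0) u[1] <- 1e-10
    if (u[3] < 0) u[3] <- 1e-10
  }
  f <- fn$F(u[1:4], u[5])
  if (sqrt(sum(f^2)) < 1e-9) u else NULL
}

palc_tangent <- function(fn, u, prev = NULL) {
  A <- cbind(fn$Jx(u[1:4], u[5]), fn$Jp(u[1:4], u[5]))  # 4 x 5
  ## null space of A via QR of t(A)
  qrA <- qr(t(A))
  tang <- qr.Q(qrA, complete = TRUE)[, 5L]
  tang <- tang / sqrt(sum(tang^2))
  if (!is.null(prev) && sum(tang * prev) < 0) tang <- -tang
  tang
}

## leading real part among genuinely complex eigenvalue pairs (Hopf test
## function); NA when no such pair exists.  The imaginary-part floor
## excludes the near-real pairs that form next to folds (neutral saddles),
## which would otherwise produce spurious Hopf flags.
hopf_testfun <- function(ev, im_floor = 1e-3) {
  cp <- ev[Im(ev) > im_floor]
  if (!length(cp)) return(NA_real_)
  max(Re(cp))
}

#' Pseudo-arclength continuation of an equilibrium branch
#'
#' Follows an equilibrium of the mean-field system as one parameter
#' (`Iext` or `Je`) varies, by predictor-corrector continuation with
#' adaptive arclength steps.  At every accepted point the Jacobian
#' eigenvalues are computed; fold points are flagged where the parameter
#' component of the tangent changes sign, Hopf points where the leading
#' real part of a complex eigenvalue pair crosses zero.  Both are
#' localized by bisection in arclength to a parameter tolerance of about
#' `1e-6`.
#'
#' @param params a [qif_params()] (its `Je` is the fixed value when
#'   `free = "Iext"`).
#' @param free which parameter varies: `"Iext"` or `"Je"`.
#' @param start equilibrium state at `p_start` (will be refined).
#' @param p_start starting parameter value.
#' @param p_range length-2 range; continuation stops on exit.
#' @param Iext_fixed the fixed external current when `free = "Je"`.
#' @param h0,h_min,h_max initial/minimum/maximum arclength step.
#' @param max_points cap on accepted points.
#' @param direction +1 or -1, initial direction of increasing parameter.
#' @return An object of class `eq_branch`: data frame with columns
#'   `param`, `r_e`, `v_e`, `r_i`, `v_i`, `max_re` (leading eigenvalue
#'   real part), `stable`; special points in `attr(, "special")` (data
#'   frame `type`, `param`, `r_e`, `v_e`, `r_i`, `v_i`).
#' @export
continue_equilibrium <- function(params, free = c("Iext", "Je"), start,
                                 p_start, p_range, Iext_fixed = 0,
                                 h0 = 0.01, h_min = 1e-5, h_max = 0.5,
                                 max_points = 4000L, direction = 1) {
  free <- match.arg(free)
  fn <- mf_funs(params, free, Iext_fixed)
  ## refine the start point at fixed parameter
  x <- as.numeric(start)
  for (it in 1:50) {
    f <- fn$F(x, p_start)
    if (sqrt(sum(f^2)) < 1e-12) break
    x <- x + solve(fn$Jx(x, p_start), -f)
  }
  u <- c(x, p_start)
  tang <- palc_tangent(fn, u)
  if (sign(tang[5]) != sign(direction) && tang[5] != 0) tang <- -tang
  h <- h0
  rows <- list()
  special <- list()
  ev_of <- function(u) eigen(fn$Jx(u[1:4], u[5]), only.values = TRUE)$values
  rec <- function(u) {
    ev <- ev_of(u)
    data.frame(param = u[5], r_e = u[1], v_e = u[2], r_i = u[3],
               v_i = u[4], max_re = max(Re(ev)),
               stable = all(Re(ev) < 0))
  }
  rows[[1L]] <- rec(u)
  ev_prev <- ev_of(u)
  hopf_prev <- hopf_testfun(ev_prev)
  n_acc <- 1L
  while (n_acc < max_points) {
    accepted <- FALSE
    while (h >= h_min) {
      u_pred <- u + h * tang
      u_new <- palc_correct(fn, u_pred, tang)
      if (!is.null(u_new) && sqrt(sum((u_new - u)^2)) < 3 * h + 1e-6) {
        accepted <- TRUE
        break
      }
      h <- h / 2
    }
    if (!accepted) break
    tang_new <- palc_tangent(fn, u_new, tang)
    ev_new <- ev_of(u_new)
    hopf_new <- hopf_testfun(ev_new)
    ## fold: parameter-direction reversal
    if (sign(tang_new[5]) != sign(tang[5]) && tang[5] != 0) {
      loc <- palc_bisect(fn, u, tang, h,
                         function(uu, tt) sign(tt[5]) != sign(tang[5]))
      if (!is.null(loc))
        special[[length(special) + 1L]] <-
          data.frame(type = "fold", param = loc[5], r_e = loc[1],
                     v_e = loc[2], r_i = loc[3], v_i = loc[4])
    }
    ## Hopf: complex-pair real part crosses zero
    if (is.finite(hopf_prev) && is.finite(hopf_new) &&
        sign(hopf_prev) != sign(hopf_new) && hopf_prev != 0) {
      loc <- palc_bisect(fn, u, tang, h, function(uu, tt) {
        hv <- hopf_testfun(eigen(fn$Jx(uu[1:4], uu[5]),
                                 only.values = TRUE)$values)
        is.finite(hv) && sign(hv) != sign(hopf_prev)
      })
      if (!is.null(loc)) {
        ## verify: a genuinely oscillatory pair sits on the imaginary axis
        ## (near-fold real pairs masquerade as Hopf with frequency ~ 0)
        evl <- ev_of(loc)
        pair <- evl[Im(evl) > 1e-3]
        genuine <- length(pair) > 0 &&
          min(abs(Re(pair))) < 1e-4 * max(1, max(abs(evl))) &&
          Im(pair[which.min(abs(Re(pair)))]) > 0.05
        if (genuine)
          special[[length(special) + 1L]] <-
            data.frame(type = "hopf", param = loc[5], r_e = loc[1],
                       v_e = loc[2], r_i = loc[3], v_i = loc[4])
      }
    }
    u <- u_new
    tang <- tang_new
    ev_prev <- ev_new
    hopf_prev <- hopf_new
    n_acc <- n_acc + 1L
    rows[[n_acc]] <- rec(u)
    h <- min(h * 1.3, h_max)
    if (u[5] < p_range[1] || u[5] > p_range[2]) break
    if (u[1] < -1e-6 || u[3] < -1e-6) break
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("eq_branch", "data.frame"),
            special = if (length(special)) do.call(rbind, special) else
              data.frame(type = character(0), param = numeric(0),
                         r_e = numeric(0), v_e = numeric(0),
                         r_i = numeric(0), v_i = numeric(0)),
            free = free, Iext_fixed = Iext_fixed, params = params)
}

## bisection in arclength between u and u + h*tang for the first point
## where `flips(u, tangent)` becomes TRUE; returns the located u
palc_bisect <- function(fn, u, tang, h, flips, tol = 1e-7, maxit = 60L) {
  lo <- 0
  hi <- h
  u_hi <- NULL
  for (it in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    u_mid <- palc_correct(fn, u + mid * tang, tang)
    if (is.null(u_mid)) {
      hi <- mid
      next
    }
    t_mid <- palc_tangent(fn, u_mid, tang)
    if (flips(u_mid, t_mid)) {
      hi <- mid
      u_hi <- u_mid
    } else lo <- mid
    if (hi - lo < tol) break
  }
  u_hi
}

#' @export
print.eq_branch <- function(x, ...) {
  cat(sprintf("equilibrium branch in %s: %d points, %s in [%g, %g]\n",
              attr(x, "free"), nrow(x), attr(x, "free"), min(x$param),
              max(x$param)))
  sp <- attr(x, "special")
  if (nrow(sp))
    for (i in seq_len(nrow(sp)))
      cat(sprintf("  %s at %s = %.6f (r_e = %.5f)\n", sp$type[i],
                  attr(x, "free"), sp$param[i], sp$r_e[i]))
  invisible(x)
}

#' Special points of a branch
#' @param branch an `eq_branch`.
#' @return Data frame of detected fold/Hopf points.
#' @export
branch_special_points <- function(branch) attr(branch, "special")

## ---- limit-cycle continuation with Floquet monitoring -------------------

#' Natural-parameter continuation of a limit cycle
#'
#' Steps the free parameter across a range, re-converging the periodic
#' orbit by single shooting at each value (seeded with the previous
#' solution) and recording the Floquet multipliers.  A period-doubling
#' point is flagged (and localized by bisection) whenever the real
#' multiplier closest to -1 crosses -1; a cycle fold whenever a
#' nontrivial multiplier crosses +1.
#'
#' @param params a [qif_params()].
#' @param Iext fixed external current (the free parameter is `Je`).
#' @param cycle a [find_limit_cycle()] result (or list with `x0`,
#'   `period`) at `Je_start`.
#' @param Je_start,Je_end continuation range endpoints.
#' @param h0,h_min initial and minimum parameter step.
#' @param dt shooting integration step.
#' @param max_points cap on accepted points.
#' @return An object of class `lc_branch`: data frame with columns `Je`,
#'   `period`, `mu_pd` (real multiplier nearest -1), `mu_max` (largest
#'   nontrivial multiplier modulus), `trivial_error`, `stable`; special
#'   points in `attr(, "special")`.
#' @export
continue_limit_cycle <- function(params, Iext, cycle, Je_start, Je_end,
                                 h0 = 0.5, h_min = 1e-4, dt = 1e-3,
                                 max_points = 400L) {
  dirn <- sign(Je_end - Je_start)
  solve_at <- function(Je, x0, T0) {
    p <- params
    p$Je <- Je
    lc <- find_limit_cycle(p, Iext, x0, T0, dt = dt, tol = 1e-9)
    if (!lc$converged || lc$residual > 1e-7) NULL else lc
  }
  pd_mult <- function(lc) {
    mu <- lc$multipliers
    ## nontrivial multipliers: drop the one closest to +1
    triv <- which.min(Mod(mu - 1))
    mu <- mu[-triv]
    re <- Re(mu[abs(Im(mu)) < 1e-6 * pmax(1, Mod(mu))])
    if (!length(re)) return(NA_real_)
    re[which.min(abs(re + 1))]
  }
  max_nontriv <- function(lc) {
    mu <- lc$multipliers
    triv <- which.min(Mod(mu - 1))
    max(Mod(mu[-triv]))
  }
  lc <- solve_at(Je_start, cycle$x0, cycle$period)
  if (is.null(lc)) stop("seed cycle failed to converge", call. = FALSE)
  rows <- list()
  special <- list()
  rec <- function(Je, lc) data.frame(
    Je = Je, period = lc$period, mu_pd = pd_mult(lc),
    mu_max = max_nontriv(lc), trivial_error = lc$trivial_error,
    stable = max_nontriv(lc) < 1 + 1e-6)
  Je <- Je_start
  rows[[1L]] <- rec(Je, lc)
  h <- h0
  n_acc <- 1L
  while (n_acc < max_points && dirn * (Je_end - Je) > 1e-12) {
    stepped <- FALSE
    while (h >= h_min) {
      Je_new <- Je + dirn * min(h, dirn * (Je_end - Je))
      lc_new <- solve_at(Je_new, lc$x0, lc$period)
      if (!is.null(lc_new) &&
          abs(lc_new$period - lc$period) < 0.5 * lc$period) {
        stepped <- TRUE
        break
      }
      h <- h / 2
    }
    if (!stepped) break
    m_old <- pd_mult(lc)
    m_new <- pd_mult(lc_new)
    if (is.finite(m_old) && is.finite(m_new) &&
        (m_old + 1) * (m_new + 1) < 0) {
      loc <- bisect_cycle(solve_at, pd_mult, Je, lc, Je_new, -1)
      if (!is.null(loc))
        special[[length(special) + 1L]] <- data.frame(
          type = "period_doubling", Je = loc$Je, period = loc$lc$period)
    }
    if (is.finite(m_old) && is.finite(m_new) &&
        (m_old - 1) * (m_new - 1) < 0) {
      loc <- bisect_cycle(solve_at, pd_mult, Je, lc, Je_new, +1)
      if (!is.null(loc))
        special[[length(special) + 1L]] <- data.frame(
          type = "cycle_fold", Je = loc$Je, period = loc$lc$period)
    }
    Je <- Je_new
    lc <- lc_new
    n_acc <- n_acc + 1L
    rows[[n_acc]] <- rec(Je, lc)
    h <- min(h * 1.3, h0)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("lc_branch", "data.frame"),
            special = if (length(special)) do.call(rbind, special) else
              data.frame(type = character(0), Je = numeric(0),
                         period = numeric(0)),
            Iext = Iext, last_cycle = lc)
}

bisect_cycle <- function(solve_at, testfun, Je_lo, lc_lo, Je_hi, level,
                         tol = 1e-4, maxit = 40L) {
  f_lo <- testfun(lc_lo) - level
  lc_best <- NULL
  Je_best <- NA
  for (it in seq_len(maxit)) {
    Je_mid <- (Je_lo + Je_hi) / 2
    lc_mid <- solve_at(Je_mid, lc_lo$x0, lc_lo$period)
    if (is.null(lc_mid)) return(if (is.null(lc_best)) NULL else
      list(Je = Je_best, lc = lc_best))
    f_mid <- testfun(lc_mid) - level
    if (!is.finite(f_mid)) return(NULL)
    if (sign(f_mid) == sign(f_lo)) {
      Je_lo <- Je_mid
      lc_lo <- lc_mid
      f_lo <- f_mid
    } else {
      Je_hi <- Je_mid
      lc_best <- lc_mid
      Je_best <- Je_mid
    }
    if (abs(Je_hi - Je_lo) < tol)
      return(list(Je = (Je_lo + Je_hi) / 2,
                  lc = if (is.null(lc_best)) lc_lo else lc_best))
  }
  list(Je = (Je_lo + Je_hi) / 2, lc = if (is.null(lc_best)) lc_lo else
    lc_best)
}

## ---- codimension-2 curves in the (Iext, Je) plane -----------------------

## G(u) for the fold curve: u = (x[4], q[4], Iext, Je), 9 equations
fold_G <- function(u, params) {
  p <- params
  p$Je <- u[10]
  x <- u[1:4]
  q <- u[5:8]
  J <- .cpp_mf_jac(x, param_vec(p))
  c(.cpp_mf_rhs(x, param_vec(p), u[9]), as.numeric(J %*% q),
    sum(q * q) - 1)
}

## G(u) for the Hopf curve: u = (x[4], qr[4], qi[4], omega, Iext, Je), 14 eqs
hopf_G <- function(u, params) {
  p <- params
  p$Je <- u[15]
  x <- u[1:4]
  qr <- u[5:8]
  qi <- u[9:12]
  w <- u[13]
  J <- .cpp_mf_jac(x, param_vec(p))
  c(.cpp_mf_rhs(x, param_vec(p), u[14]),
    as.numeric(J %*% qr) + w * qi,
    as.numeric(J %*% qi) - w * qr,
    sum(qr * qr) + sum(qi * qi) - 1,
    sum(qr * qi))
}

num_jac <- function(G, u, ...) {
  m <- length(G(u, ...))
  n <- length(u)
  J <- matrix(0, m, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * max(1, abs(u[j]))
    up <- u
    um <- u
    up[j] <- up[j] + h
    um[j] <- um[j] - h
    J[, j] <- (G(up, ...) - G(um, ...)) / (2 * h)
  }
  J
}

## generic pseudo-arclength tracer for an underdetermined system
## G: R^n -> R^(n-1); the last two components of u are (Iext, Je)
trace_defining_system <- function(G, u0, params, window, h0 = 0.05,
                                  h_min = 1e-5, h_max = 1, max_points = 800L,
                                  direction = 1, stopfun = NULL) {
  n <- length(u0)
  correct <- function(u_pred, tang) {
    u <- u_pred
    for (it in 1:12) {
      g <- G(u, params)
      cons <- sum(tang * (u - u_pred))
      if (!all(is.finite(g))) return(NULL)
      if (sqrt(sum(g^2)) < 1e-10 && abs(cons) < 1e-10) return(u)
      A <- rbind(num_jac(G, u, params), tang)
      du <- tryCatch(solve(A, -c(g, cons)), error = function(e) NULL)
      if (is.null(du)) return(NULL)
      u <- u + du
    }
    if (sqrt(sum(G(u, params)^2)) < 1e-8) u else NULL
  }
  tangent <- function(u, prev = NULL) {
    A <- num_jac(G, u, params)
    tg <- qr.Q(qr(t(A)), complete = TRUE)[, n]
    tg <- tg / sqrt(sum(tg^2))
    if (!is.null(prev) && sum(tg * prev) < 0) tg <- -tg
    tg
  }
  ## refine seed
  u <- u0
  for (it in 1:60) {
    g <- G(u, params)
    if (sqrt(sum(g^2)) < 1e-11) break
    A <- num_jac(G, u, params)
    du <- tryCatch(qr.solve(A, -g), error = function(e) NULL)
    if (is.null(du)) break
    u <- u + 0.8 * du
  }
  if (sqrt(sum(G(u, params)^2)) > 1e-8) return(NULL)
  tang <- tangent(u)
  if (direction < 0) tang <- -tang
  pts <- list(u)
  h <- h0
  inside <- function(u)
    u[n - 1] >= window[1] && u[n - 1] <= window[2] &&
    u[n] >= window[3] && u[n] <= window[4]
  for (k in seq_len(max_points)) {
    ok <- FALSE
    while (h >= h_min) {
      u_new <- correct(u + h * tang, tang)
      if (!is.null(u_new)) {
        ok <- TRUE
        break
      }
      h <- h / 2
    }
    if (!ok) break
    tang <- tangent(u_new, tang)
    u <- u_new
    pts[[length(pts) + 1L]] <- u
    h <- min(h * 1.4, h_max)
    if (!inside(u)) break
    if (!is.null(stopfun) && stopfun(u)) break
  }
  do.call(rbind, pts)
}

#' Trace a codimension-2 bifurcation curve in the (Iext, Je) plane
#'
#' Fold and Hopf curves are continued as solutions of augmented defining
#' systems (equilibrium condition plus a null-eigenvector or
#' imaginary-pair eigenvector condition) by pseudo-arclength
#' continuation, in both directions from the seed until the analysis
#' window is exited.  Period-doubling curves are assembled from dense
#' one-parameter slices: for a grid of `Iext` values the limit cycle is
#' continued in `Je` and the parameter value where a real Floquet
#' multiplier crosses -1 is located by bisection (see
#' [continue_limit_cycle()]); use [trace_pd_curve()] directly for
#' control over the slice grid.
#'
#' @param params a [qif_params()].
#' @param type `"fold"` or `"hopf"`.
#' @param seed a list with `x` (equilibrium state), `Iext`, `Je` at (or
#'   near) a codim-1 point of the given type.
#' @param window `c(Iext_min, Iext_max, Je_min, Je_max)`.
#' @param label curve label carried to outputs (e.g. `"f"`, `"h1"`).
#' @param h0 initial arclength step.
#' @param max_points per-direction cap.
#' @return An object of class `bif_curve`: data frame with columns
#'   `Iext`, `Je` ordered along the curve; attribute `label` and `type`.
#' @export
trace_codim2_curve <- function(params, type = c("fold", "hopf"), seed,
                               window = c(-6, 10, 5, 80), label = type,
                               h0 = 0.05, max_points = 800L) {
  type <- match.arg(type)
  p <- params
  p$Je <- seed$Je
  J <- .cpp_mf_jac(as.numeric(seed$x), param_vec(p))
  ev <- eigen(J)
  if (type == "fold") {
    k <- which.min(abs(Re(ev$values)) + abs(Im(ev$values)))
    q <- Re(ev$vectors[, k])
    q <- q / sqrt(sum(q^2))
    u0 <- c(as.numeric(seed$x), q, seed$Iext, seed$Je)
    G <- fold_G
  } else {
    cand <- which(Im(ev$values) > 1e-8)
    k <- cand[which.min(abs(Re(ev$values[cand])))]
    qc <- ev$vectors[, k]
    qr_ <- Re(qc)
    qi_ <- Im(qc)
    ## orthonormalize the real/imaginary parts
    nr <- sqrt(sum(qr_^2) + sum(qi_^2))
    qr_ <- qr_ / nr
    qi_ <- qi_ / nr
    ## rotate the complex phase so that qr . qi = 0
    th <- 0.5 * atan2(2 * sum(qr_ * qi_), sum(qr_^2) - sum(qi_^2))
    qr2 <- cos(th) * qr_ + sin(th) * qi_
    qi2 <- -sin(th) * qr_ + cos(th) * qi_
    w <- Im(ev$values[k])
    ## sign convention: J qr = -w qi
    if (sum((J %*% qr2 + w * qi2)^2) > sum((J %*% qr2 - w * qi2)^2)) {
      qi2 <- -qi2
    }
    u0 <- c(as.numeric(seed$x), qr2, qi2, w, seed$Iext, seed$Je)
    G <- hopf_G
  }
  ## a Hopf curve ends where the pair frequency collapses (Bogdanov-Takens
  ## point on the fold curve).  The defining system is symmetric under
  ## (q_i, omega) -> (-q_i, -omega), so continuation through omega = 0
  ## would silently retrace the same curve; detect the collapse by an
  ## omega sign change or small magnitude and stop there.
  mk_stopfun <- function() {
    w_prev <- u0[13]
    function(u) {
      hit <- abs(u[13]) < 1e-2 || sign(u[13]) != sign(w_prev)
      w_prev <<- u[13]
      hit
    }
  }
  fw <- trace_defining_system(G, u0, params, window, h0 = h0,
                              max_points = max_points, direction = 1,
                              stopfun = if (type == "hopf") mk_stopfun()
                              else NULL)
  bw <- trace_defining_system(G, u0, params, window, h0 = h0,
                              max_points = max_points, direction = -1,
                              stopfun = if (type == "hopf") mk_stopfun()
                              else NULL)
  n <- length(u0)
  pts <- rbind(if (!is.null(bw)) bw[rev(seq_len(nrow(bw))), , drop = FALSE],
               if (!is.null(fw)) fw[-1, , drop = FALSE])
  if (is.null(pts) || !nrow(pts))
    stop("codim-2 continuation failed from the given seed", call. = FALSE)
  out <- data.frame(Iext = pts[, n - 1], Je = pts[, n],
                    r_e = pts[, 1], v_e = pts[, 2], r_i = pts[, 3],
                    v_i = pts[, 4])
  if (type == "hopf") out$omega <- pts[, 13]
  structure(out, class = c("bif_curve", "data.frame"), label = label,
            type = type)
}

#' @export
print.bif_curve <- function(x, ...) {
  cat(sprintf("%s curve '%s': %d points, Iext in [%.3g, %.3g], Je in [%.3g, %.3g]\n",
              attr(x, "type"), attr(x, "label"), nrow(x), min(x$Iext),
              max(x$Iext), min(x$Je), max(x$Je)))
  invisible(x)
}

#' Assemble a period-doubling curve from one-parameter slices
#'
#' For each `Iext` in `Iext_grid`, finds the `Je` at which the monitored
#' real Floquet multiplier of the continued limit cycle crosses -1.  The
#' cycle seed for each slice is harvested from a settled trajectory at
#' `Je_seed` (continuing the previous slice's crossing as the next
#' bracket center).
#'
#' @param params a [qif_params()].
#' @param Iext_grid slice positions.
#' @param Je_window length-2 search window in `Je` for the crossing.
#' @param Je_seed starting `Je` for the first slice's cycle harvest
#'   (defaults to the lower window edge).
#' @param dt shooting step.
#' @param label curve label (e.g. `"PD1"`).
#' @param n_periods 1 to follow the base cycle (primary doubling), 2 to
#'   follow the doubled cycle (secondary doubling).
#' @return A `bif_curve` (possibly with fewer rows than slices when a
#'   slice has no crossing).
#' @export
trace_pd_curve <- function(params, Iext_grid, Je_window, Je_seed = NULL,
                           dt = 1e-3, label = "PD", n_periods = 1L) {
  if (is.null(Je_seed)) Je_seed <- Je_window[1]
  rows <- list()
  for (Iext in Iext_grid) {
    sd <- harvest_cycle_seed(params, Iext, Je = Je_seed,
                             n_periods = n_periods, dt = dt)
    if (is.null(sd)) next
    p <- params
    p$Je <- Je_seed
    lc <- find_limit_cycle(p, Iext, sd$x0, sd$T0, dt = dt)
    if (!lc$converged) next
    br <- tryCatch(
      continue_limit_cycle(params, Iext, lc, Je_seed, Je_window[2],
                           dt = dt),
      error = function(e) NULL)
    if (is.null(br)) next
    sp <- attr(br, "special")
    sp <- sp[sp$type == "period_doubling", , drop = FALSE]
    if (nrow(sp)) {
      rows[[length(rows) + 1L]] <- data.frame(Iext = Iext,
                                              Je = sp$Je[1])
    }
  }
  if (!length(rows))
    stop("no period-doubling crossing found on any slice", call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$Iext), ]
  structure(out, class = c("bif_curve", "data.frame"), label = label,
            type = "period_doubling")
}

## ---- region counting ----------------------------------------------------

#' Count the regions a set of curves cuts a window into
#'
#' Rasterizes every curve polyline onto a grid over the window (marking
#' each cell a segment passes through, by sub-cell sampling), then
#' flood-fills the unmarked complement with 4-connectivity and counts the
#' connected components.  The count should be checked for stability under
#' grid doubling: narrow regions that are unresolved at the given
#' resolution merge with neighbours.
#'
#' @param curves list of `bif_curve` objects (or data frames with `Iext`,
#'   `Je`).
#' @param window `c(Iext_min, Iext_max, Je_min, Je_max)`.
#' @param resolution grid cells per axis.
#' @param min_cells smallest component (in cells) counted as a region;
#'   the default, 0.02% of the grid, discards the isolated one-or-two
#'   cell pockets that rasterized curve crossings leave behind while
#'   keeping any region wider than the raster.
#' @return An object of class `region_partition`: list with `n_regions`,
#'   `mask` (integer matrix of region ids; 0 = curve cells), `region_sizes`,
#'   `window`, `resolution`.
#' @examples
#' line <- data.frame(Iext = c(-6, 10), Je = seq(5, 80, length.out = 2))
#' partition_regions(list(line), c(-6, 10, 5, 80), 64)$n_regions  # 2
#' @export
partition_regions <- function(curves, window = c(-6, 10, 5, 80),
                              resolution = 300L,
                              min_cells = max(4L, round(2e-4 *
                                as.integer(resolution)^2))) {
  nx <- as.integer(resolution)
  ny <- as.integer(resolution)
  dx <- (window[2] - window[1]) / nx
  dy <- (window[4] - window[3]) / ny
  blocked <- matrix(FALSE, nx, ny)
  cell <- function(Ix, Je) {
    i <- floor((Ix - window[1]) / dx) + 1
    j <- floor((Je - window[3]) / dy) + 1
    c(i, j)
  }
  for (cv in curves) {
    P <- cbind(cv$Iext, cv$Je)
    if (nrow(P) < 2L) next
    for (s in seq_len(nrow(P) - 1L)) {
      a <- P[s, ]
      b <- P[s + 1L, ]
      L <- max(abs(b[1] - a[1]) / dx, abs(b[2] - a[2]) / dy)
      m <- max(2L, ceiling(L * 3))
      ts <- seq(0, 1, length.out = m)
      xs <- a[1] + ts * (b[1] - a[1])
      ys <- a[2] + ts * (b[2] - a[2])
      ii <- floor((xs - window[1]) / dx) + 1
      jj <- floor((ys - window[3]) / dy) + 1
      ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
      blocked[cbind(ii[ok], jj[ok])] <- TRUE
    }
  }
  ## flood fill the complement: iterative BFS with a preallocated queue
  mask <- matrix(0L, nx, ny)
  region <- 0L
  qi <- integer(nx * ny)
  qj <- integer(nx * ny)
  for (j0 in seq_len(ny)) for (i0 in seq_len(nx)) {
    if (blocked[i0, j0] || mask[i0, j0] != 0L) next
    region <- region + 1L
    head <- 1L
    tail_ <- 1L
    qi[1L] <- i0
    qj[1L] <- j0
    mask[i0, j0] <- region
    while (head <= tail_) {
      i <- qi[head]
      j <- qj[head]
      head <- head + 1L
      if (i > 1L && !blocked[i - 1L, j] && mask[i - 1L, j] == 0L) {
        tail_ <- tail_ + 1L; qi[tail_] <- i - 1L; qj[tail_] <- j
        mask[i - 1L, j] <- region
      }
      if (i < nx && !blocked[i + 1L, j] && mask[i + 1L, j] == 0L) {
        tail_ <- tail_ + 1L; qi[tail_] <- i + 1L; qj[tail_] <- j
        mask[i + 1L, j] <- region
      }
      if (j > 1L && !blocked[i, j - 1L] && mask[i, j - 1L] == 0L) {
        tail_ <- tail_ + 1L; qi[tail_] <- i; qj[tail_] <- j - 1L
        mask[i, j - 1L] <- region
      }
      if (j < ny && !blocked[i, j + 1L] && mask[i, j + 1L] == 0L) {
        tail_ <- tail_ + 1L; qi[tail_] <- i; qj[tail_] <- j + 1L
        mask[i, j + 1L] <- region
      }
    }
  }
  sizes <- tabulate(mask[mask > 0L], nbins = region)
  structure(list(n_regions = sum(sizes >= min_cells), mask = mask,
                 region_sizes = sizes, window = window,
                 resolution = resolution, min_cells = min_cells),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("window Iext [%g, %g] x Je [%g, %g] at %dx%d: %d regions\n",
              x$window[1], x$window[2], x$window[3], x$window[4],
              x$resolution, x$resolution, x$n_regions))
  invisible(x)
}

## ---- full two-parameter scenario pipeline -------------------------------

#' Trace the two-parameter bifurcation scenario and count regions
#'
#' End-to-end pipeline over the `(Iext, Je)` analysis window: locates the
#' codimension-1 seeds automatically (fold and upper-branch Hopf from a
#' `Je` continuation at `Iext = -3`; the low-branch Hopf from an `Iext`
#' continuation at `Je = 20`), traces the fold curve and both Hopf
#' curves, attempts period-doubling slices across the window, closes
#' T-junctions (a Hopf curve ending at a Bogdanov-Takens point is snapped
#' onto the fold curve so the rasterized partition seals), and counts the
#' connected regions at the given resolution and at double resolution.
#'
#' @param params a [qif_params()].
#' @param window `c(Iext_min, Iext_max, Je_min, Je_max)`.
#' @param resolution base raster resolution for region counting.
#' @param pd_slices `Iext` positions for the period-doubling slices
#'   (`NULL` skips the PD search).
#' @param dt integration step for cycle work.
#' @return A list with `curves` (named list of `bif_curve`s), `n_regions`
#'   (at `resolution`), `n_regions_fine` (at `2 * resolution`),
#'   `partition`.
#' @export
two_parameter_scenario <- function(params, window = c(-6, 10, 5, 80),
                                   resolution = 400L, pd_slices = NULL,
                                   dt = 1e-3) {
  ## seeds from a Je continuation of the high-activity branch at Iext = -3
  p32 <- params
  p32$Je <- 32
  eqs <- find_equilibria(p32, -3, n_starts = 512L)
  if (length(eqs) < 3L)
    stop("expected the bistable equilibrium structure at (-3, 32)",
         call. = FALSE)
  top <- eqs[[length(eqs)]]
  br_up <- continue_equilibrium(p32, "Je", top$state, 32,
                                c(window[3], window[4]), Iext_fixed = -3,
                                h0 = 0.1)
  sp <- branch_special_points(br_up)
  hopf_hi <- sp[sp$type == "hopf", ][1, ]
  br_dn <- continue_equilibrium(p32, "Je", top$state, 32,
                                c(window[3], window[4]), Iext_fixed = -3,
                                h0 = 0.1, direction = -1)
  spd <- branch_special_points(br_dn)
  fold_seed <- spd[spd$type == "fold", ][1, ]
  if (!nrow(sp) || is.na(hopf_hi$param))
    stop("no upper-branch Hopf found", call. = FALSE)
  if (!nrow(spd) || is.na(fold_seed$param))
    stop("no fold found on the downward branch", call. = FALSE)
  h2 <- trace_codim2_curve(params, "hopf",
                           seed = list(x = c(hopf_hi$r_e, hopf_hi$v_e,
                                             hopf_hi$r_i, hopf_hi$v_i),
                                       Iext = -3, Je = hopf_hi$param),
                           window = window, label = "h2")
  f <- trace_codim2_curve(params, "fold",
                          seed = list(x = c(fold_seed$r_e, fold_seed$v_e,
                                            fold_seed$r_i, fold_seed$v_i),
                                      Iext = -3, Je = fold_seed$param),
                          window = window, label = "f")
  ## low-branch Hopf seed from an Iext continuation at Je = 20
  p20 <- params
  p20$Je <- 20
  eq20 <- quiescent_equilibrium(p20, window[1])
  br20 <- continue_equilibrium(p20, "Iext", eq20$state, window[1],
                               c(window[1], window[2]), h0 = 0.05)
  sp20 <- branch_special_points(br20)
  hp20 <- sp20[sp20$type == "hopf", ]
  curves <- list(f = f, h2 = h2)
  if (nrow(hp20)) {
    h1 <- tryCatch(trace_codim2_curve(
      params, "hopf",
      seed = list(x = c(hp20$r_e[1], hp20$v_e[1], hp20$r_i[1],
                        hp20$v_i[1]),
                  Iext = hp20$param[1], Je = 20),
      window = window, label = "h1"), error = function(e) NULL)
    if (!is.null(h1)) curves$h1 <- snap_curve_ends(h1, f, window)
  }
  ## period-doubling slices (often empty: the primary cycle in this system
  ## keeps its doubling multiplier well inside the unit circle)
  if (!is.null(pd_slices)) {
    ## seed the cycle where the oscillatory attractor is broadly present
    je_seed <- max(window[3], min(60, window[4]))
    pd <- tryCatch(trace_pd_curve(params, pd_slices,
                                  Je_window = c(window[3], window[4]),
                                  Je_seed = je_seed, dt = dt,
                                  label = "PD1"),
                   error = function(e) NULL)
    if (!is.null(pd)) curves$PD1 <- pd
  }
  pr <- partition_regions(curves, window, resolution)
  pr2 <- partition_regions(curves, window, 2L * resolution)
  list(curves = curves, n_regions = pr$n_regions,
       n_regions_fine = pr2$n_regions, partition = pr)
}

## snap loose curve ends onto another curve when they terminate close to
## it (T-junctions such as a Bogdanov-Takens point on the fold curve);
## prevents flood-fill leaks through the raster gap
snap_curve_ends <- function(curve, target, window, frac = 0.05) {
  sx <- diff(window[1:2])
  sy <- diff(window[3:4])
  d2 <- function(a, b) ((a[1] - b[, 1]) / sx)^2 + ((a[2] - b[, 2]) / sy)^2
  tp <- cbind(target$Iext, target$Je)
  for (end in c(1L, nrow(curve))) {
    pt <- c(curve$Iext[end], curve$Je[end])
    dd <- d2(pt, tp)
    k <- which.min(dd)
    if (sqrt(dd[k]) < frac) {
      new_row <- curve[end, ]
      new_row$Iext <- target$Iext[k]
      new_row$Je <- target$Je[k]
      curve <- if (end == 1L) rbind(new_row, curve) else
        rbind(curve, new_row)
    }
  }
  curve
}
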
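#' Detect local maxima of a scalar trace
#'
#' Local maxima exceeding a prominence floor, with quadratic sub-grid
#' refinement of both the peak time and amplitude.  Prominence is measured
#' here as height above the trace minimum; peaks closer than
#' `min_prominence` to the minimum are dropped.
#'
#' @param trace a data frame whose first column is time and second the
#'   signal (e.g. `t`, `r_e` columns of an `mf_trajectory`), or an
#'   `mf_trajectory` (uses `r_e`).
#' @param min_prominence minimum height above the trace minimum; default
#'   20% of the signal range.
#' @param column signal column to use when `trace` is an `mf_trajectory`.
#' @return A data frame with columns `t`, `amplitude` (possibly empty).
#' @examples
#' tt <- seq(0, 20 * pi, by = 0.01)
#' pk <- detect_peaks(data.frame(t = tt, y = sin(tt)))
#' nrow(pk)  # 10
#' @export
detect_peaks <- function(trace, min_prominence = NULL, column = "r_e") {
  if (inherits(trace, "mf_trajectory"))
    trace <- data.frame(t = trace$t, y = trace[[column]])
  t <- trace[[1L]]
  y <- trace[[2L]]
  n <- length(y)
  if (n < 3L) stop("trace too short for peak detection", call. = FALSE)
  rng <- max(y) - min(y)
  if (is.null(min_prominence)) min_prominence <- 0.2 * rng
  if (rng <= 0) return(data.frame(t = numeric(0), amplitude = numeric(0)))
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i <- i[y[i] >= min(y) + min_prominence]
  if (!length(i)) return(data.frame(t = numeric(0),
                                    amplitude = numeric(0)))
  tp <- ap <- numeric(length(i))
  for (k in seq_along(i)) {
    j <- i[k]
    a <- y[j - 1L]; b <- y[j]; cc <- y[j + 1L]
    den <- a - 2 * b + cc
    del <- if (abs(den) > 1e-14) 0.5 * (a - cc) / den else 0
    h <- t[j + 1L] - t[j]
    tp[k] <- t[j] + del * h
    ap[k] <- b - 0.25 * (a - cc) * del
  }
  data.frame(t = tp, amplitude = ap)
}

#' Period-n classification of a peak sequence
#'
#' Tests whether the sequence of (amplitude, inter-peak interval) pairs is
#' n-periodic within relative tolerances, for n = 1, 2, 4, ... up to
#' `n_max`, and returns the smallest n that fits; `"chaotic"` if none
#' does.  Amplitude deviations are measured relative to the largest peak
#' amplitude, interval deviations relative to the mean interval; period-n
#' structure whose amplitude and interval alternation both fall below the
#' tolerances is reported as the smaller period.
#'
#' The classification is invariant under uniform time shifts and uniform
#' amplitude scaling of the peak sequence.
#'
#' @param peaks data frame from [detect_peaks()] (needs >= 8 peaks).
#' @param amp_tol relative amplitude tolerance (default 2%).
#' @param interval_tol relative interval tolerance (default 2%).
#' @param n_max largest period class considered before declaring chaos.
#' @return An integer period class, or the character `"chaotic"`.
#' @export
classify_period <- function(peaks, amp_tol = 0.02, interval_tol = 0.02,
                            n_max = 16L) {
  if (nrow(peaks) < 8L)
    stop("insufficient data: need at least 8 peaks", call. = FALSE)
  amps <- peaks$amplitude
  ints <- diff(peaks$t)
  amps <- amps[-1L]                       # align with intervals
  m <- length(amps)
  amp_scale <- max(abs(amps))
  int_scale <- mean(ints)
  ns <- 1L
  while (ns[length(ns)] * 2L <= n_max) ns <- c(ns, ns[length(ns)] * 2L)
  for (n in ns) {
    k <- m %/% n
    if (k < 3L) break
    ai <- matrix(amps[(m - n * k + 1L):m], nrow = n)
    ii <- matrix(ints[(m - n * k + 1L):m], nrow = n)
    amp_dev <- max(apply(ai, 1L, function(z) max(z) - min(z))) / amp_scale
    int_dev <- max(apply(ii, 1L, function(z) max(z) - min(z))) / int_scale
    if (amp_dev < amp_tol && int_dev < interval_tol) {
      if (n == 1L) return(1L)
      ## require genuinely distinct clusters, else it is a smaller period
      mu <- rowMeans(ai)
      if (min(dist(mu)) / amp_scale > amp_tol) return(as.integer(n))
      mu2 <- rowMeans(ii)
      if (min(dist(mu2)) / int_scale > interval_tol) return(as.integer(n))
      return(1L)
    }
  }
  "chaotic"
}

#' Integrate past a transient and classify the attractor
#'
#' Runs the mean-field model under a protocol, drops the transient (the
#' first half of the run or the first 200 time units, whichever is
#' larger), and classifies the post-transient excitatory-rate signal as an
#' equilibrium (`"steady"`) or a period-n / chaotic oscillation.
#'
#' @inheritParams mf_integrate
#' @param settle_tol relative rate variation below which the state counts
#'   as steady.
#' @param ... passed to [classify_period()].
#' @return A list with `class` (`"steady"`, an integer, or `"chaotic"`),
#'   `peaks`, `trajectory_tail`, `final_state`.
#' @export
classify_attractor <- function(state0, protocol, params, dt = 1e-3,
                               settle_tol = 1e-4, ...) {
  ## full-resolution storage: sub-grid peak amplitudes of the sharp rate
  ## spikes are only reliable when every step is kept
  traj <- mf_integrate(state0, protocol, params, dt = dt,
                       keep_every = max(1L, round(0.002 / dt)))
  t_end <- traj$t[nrow(traj)]
  t_cut <- max(t_end / 2, min(200, 0.9 * t_end))
  tl <- traj[traj$t >= t_cut, ]
  rng <- max(tl$r_e) - min(tl$r_e)
  if (rng < settle_tol * max(abs(tl$r_e), 1e-12))
    return(list(class = "steady", peaks = NULL, trajectory_tail = tl,
                final_state = mf_final_state(traj)))
  pk <- detect_peaks(tl)
  cls <- if (nrow(pk) >= 8L) classify_period(pk, ...) else "steady"
  list(class = cls, peaks = pk, trajectory_tail = tl,
       final_state = mf_final_state(traj))
}

#' Inter-peak-interval bifurcation sweep
#'
#' For each value of `Je` on a grid (at fixed `Iext`), integrates the
#' mean-field model, drops the transient and records every inter-peak
#' interval of `r_e` — the numerical analogue of an orbit diagram: one
#' interval cluster per grid point means period-1, two clusters period-2,
#' a dust of intervals chaos.
#'
#' @param params a [qif_params()]; its `Je` is overridden along the grid.
#' @param Iext fixed external current.
#' @param Je_grid numeric vector of `Je` values.
#' @param dt integration step.
#' @param t_transient transient dropped before measuring.
#' @param t_measure measurement window length.
#' @param init_mode `"continue"` (initial condition inherited from the
#'   previous grid point — branch following) or `"fixed"`.
#' @param state0 initial state for the first grid point (and for every
#'   point under `"fixed"`); default starts on the high-activity side.
#' @return An object of class `isi_sweep`: data frame with columns `Je`,
#'   `interval`, plus a per-point summary in attribute `summary`
#'   (`Je`, `n_peaks`, `n_clusters`, `class`).
#' @export
isi_bifurcation_sweep <- function(params, Iext, Je_grid, dt = 1e-3,
                                  t_transient = 200, t_measure = 100,
                                  init_mode = c("continue", "fixed"),
                                  state0 = c(1, 0, 1, 0)) {
  init_mode <- match.arg(init_mode)
  x <- as_mf_state(state0)
  rows <- list()
  summ <- list()
  for (Je in Je_grid) {
    p <- params
    p$Je <- Je
    res <- tryCatch({
      tr <- mf_integrate(x, constant_protocol(Iext, t_transient + t_measure),
                         p, dt = dt,
                         keep_every = max(1L, round(0.002 / dt)))
      tl <- tr[tr$t >= t_transient, ]
      pk <- detect_peaks(tl)
      if (init_mode == "continue") x <<- mf_final_state(tr)
      list(pk = pk, tl = tl)
    }, error = function(e) NULL)
    if (is.null(res)) {
      if (init_mode == "continue") x <- as_mf_state(state0)
      summ[[length(summ) + 1L]] <- data.frame(Je = Je, n_peaks = NA,
                                              n_clusters = NA,
                                              class = "diverged")
      next
    }
    pk <- res$pk
    ints <- if (nrow(pk) >= 2L) diff(pk$t) else numeric(0)
    if (length(ints))
      rows[[length(rows) + 1L]] <- data.frame(Je = Je, interval = ints)
    cls <- if (nrow(pk) >= 8L) classify_period(pk) else "steady"
    summ[[length(summ) + 1L]] <- data.frame(
      Je = Je, n_peaks = nrow(pk),
      n_clusters = if (length(ints)) cluster_count(ints) else 0L,
      class = as.character(cls))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(Je = numeric(0), interval = numeric(0))
  structure(out, class = c("isi_sweep", "data.frame"),
            summary = do.call(rbind, summ), Iext = Iext)
}

## 1-d cluster count by splitting sorted values at gaps larger than
## max(rel_gap * spread, abs_floor)
cluster_count <- function(x, rel_gap = 0.05, abs_floor = NULL) {
  x <- sort(x)
  if (length(x) < 2L) return(length(x))
  spread <- max(x) - min(x)
  if (is.null(abs_floor)) abs_floor <- 0.01 * mean(x)
  if (spread <= abs_floor) return(1L)
  gaps <- diff(x)
  sum(gaps > max(rel_gap * spread, abs_floor)) + 1L
}

#' @export
print.isi_sweep <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("inter-peak-interval sweep at I_ext = %g: %d grid points\n",
              attr(x, "Iext"), nrow(s)))
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
plot.isi_sweep <- function(x, ...) {
  plot(x$Je, x$interval, pch = ".", cex = 2, xlab = "Je",
       ylab = "inter-peak interval", ...)
  invisible(x)
}

#' Largest Lyapunov exponent by the two-trajectory (Benettin) method
#'
#' Integrates a reference trajectory and a companion displaced by `d0`,
#' renormalizing the separation every `t_renorm`; the exponent is the
#' time-averaged log-stretch rate.  Negative at a stable equilibrium,
#' close to zero on a stable limit cycle (neutral direction along the
#' orbit), positive on a chaotic attractor.
#'
#' @param params a [qif_params()].
#' @param Iext,Je operating point (`Je` overrides `params$Je`).
#' @param state0 initial state; should already lie on (or near) the
#'   attractor of interest.
#' @param t_settle extra settling time integrated before measuring.
#' @param t_total measurement horizon.
#' @param t_renorm renormalization interval.
#' @param d0 separation scale.
#' @param dt integration step.
#' @param seed seed for the random initial perturbation direction.
#' @return The exponent estimate (numeric scalar).
#' @export
lyapunov_max <- function(params, Iext, Je = params$Je,
                         state0 = c(1, 0, 1, 0), t_settle = 200,
                         t_total = 2000, t_renorm = 1, d0 = 1e-7,
                         dt = 1e-3, seed = 1L) {
  p <- params
  p$Je <- Je
  x <- as_mf_state(state0)
  if (t_settle > 0) {
    tr <- mf_integrate(x, constant_protocol(Iext, t_settle), p, dt = dt,
                       keep_every = max(1L, round(t_settle / dt / 10)))
    x <- mf_final_state(tr)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  dir0 <- stats::rnorm(4L)
  .cpp_lyapunov(x, dir0, param_vec(p), Iext, t_total, t_renorm, d0, dt)
}

#' Locate a periodic orbit by single shooting
#'
#' Starting from a point near the orbit and a period estimate (both
#' typically harvested from a settled trajectory via [detect_peaks()]),
#' Newton-iterates on the residual `phi_T(x) - x` with the period as the
#' extra unknown, using the monodromy matrix from the variational
#' equations and a phase anchor (the Poincare condition that the vector
#' field component of largest magnitude stays fixed at its section
#' value).  Returns the converged cycle with its Floquet multipliers; for
#' an autonomous system one multiplier always equals 1, and its numerical
#' deviation from 1 is reported as an accuracy diagnostic.
#'
#' @param params a [qif_params()].
#' @param Iext external current.
#' @param x0 state near the orbit.
#' @param T0 period estimate.
#' @param dt integration step for shooting and monodromy.
#' @param tol Newton tolerance on the shooting residual.
#' @param maxit Newton iterations.
#' @return An object of class `limit_cycle`: list with `x0` (point on the
#'   orbit), `period`, `multipliers` (sorted by decreasing modulus),
#'   `trivial_error` (|multiplier closest to 1| - 1|), `residual`,
#'   `converged`.
#' @export
find_limit_cycle <- function(params, Iext, x0, T0, dt = 1e-3, tol = 1e-9,
                             maxit = 40L) {
  pv <- param_vec(params)
  shoot <- function(x, T) {
    tryCatch(.cpp_mf_variational(x, pv, Iext, T, dt),
             error = function(e) NULL)
  }
  x <- as.numeric(x0)
  T <- T0
  conv <- FALSE
  vr <- shoot(x, T)
  if (is.null(vr))
    stop("shooting seed integration diverged", call. = FALSE)
  res_norm <- sqrt(sum((vr$x - x)^2))
  for (it in seq_len(maxit)) {
    if (res_norm < tol) {
      conv <- TRUE
      break
    }
    res <- vr$x - x
    f_end <- .cpp_mf_rhs(vr$x, pv, Iext)
    f_start <- .cpp_mf_rhs(x, pv, Iext)
    ## anchor the phase along the largest component of the vector field
    k <- which.max(abs(f_start))
    A <- rbind(cbind(vr$M - diag(4), f_end),
               c(replace(numeric(4), k, 1), 0))
    step <- tryCatch(as.numeric(qr.solve(A, c(-res, 0))),
                     error = function(e) NULL)
    if (is.null(step)) break
    ## damped update: reject steps that blow up, go negative in rate, or
    ## fail to reduce the residual
    lam <- 1
    improved <- FALSE
    while (lam >= 1e-4) {
      xn <- x + lam * step[1:4]
      Tn <- T + lam * step[5]
      if (Tn > 0.05 * T0 && xn[1] > 0 && xn[3] > 0 &&
          all(is.finite(xn))) {
        vn <- shoot(xn, Tn)
        if (!is.null(vn)) {
          rn <- sqrt(sum((vn$x - xn)^2))
          if (is.finite(rn) && (rn < res_norm || lam == 1)) {
            x <- xn
            T <- Tn
            vr <- vn
            res_norm <- rn
            improved <- TRUE
            break
          }
        }
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  mult <- eigen(vr$M, only.values = TRUE)$values
  mult <- mult[order(-Mod(mult))]
  triv <- mult[which.min(Mod(mult - 1))]
  structure(list(x0 = x, period = T, multipliers = mult,
                 trivial_error = Mod(triv - 1),
                 residual = res_norm, converged = res_norm < tol,
                 Iext = Iext, params = params, dt = dt),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf("limit cycle: period %.6g, shooting residual %.2e (%s)\n",
              x$period, x$residual,
              if (x$converged) "converged" else "NOT converged"))
  cat("  Floquet multipliers:",
      paste(sprintf("%.4f%+.4fi", Re(x$multipliers), Im(x$multipliers)),
            collapse = ", "), "\n")
  cat(sprintf("  trivial-multiplier error: %.2e\n", x$trivial_error))
  invisible(x)
}

#' Harvest a shooting seed from a settled trajectory
#'
#' Integrates to the attractor, then returns a peak-anchored state and the
#' median inter-peak interval times `n_periods` as the period estimate.
#'
#' @inheritParams lyapunov_max
#' @param t_settle settling time before harvesting.
#' @param t_harvest window used to measure peaks.
#' @param n_periods how many base intervals make up one orbit period
#'   (e.g. 2 for a period-2 orbit).
#' @return A list with `x0`, `T0`, `peaks`, or `NULL` when the trajectory
#'   does not oscillate.
#' @export
harvest_cycle_seed <- function(params, Iext, Je = params$Je,
                               state0 = c(1, 0, 1, 0), t_settle = 200,
                               t_harvest = 60, dt = 1e-3, n_periods = 1L) {
  p <- params
  p$Je <- Je
  tr <- mf_integrate(state0, constant_protocol(Iext, t_settle + t_harvest),
                     p, dt = dt)
  tl <- tr[tr$t >= t_settle, ]
  pk <- detect_peaks(tl)
  if (nrow(pk) < 3L) return(NULL)
  Tbase <- median(diff(pk$t))
  ## anchor the seed at the quiet phase (rate minimum between the last two
  ## peaks): on relaxation-like orbits the spike is the worst-conditioned
  ## point for shooting, the slow segment the best
  seg <- tl[tl$t > pk$t[nrow(pk) - 1L] & tl$t < pk$t[nrow(pk)], ]
  i <- if (nrow(seg)) which.min(seg$r_e) else 1L
  if (!nrow(seg)) seg <- tl
  list(x0 = c(seg$r_e[i], seg$v_e[i], seg$r_i[i], seg$v_i[i]),
       T0 = Tbase * n_periods, peaks = pk)
}
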
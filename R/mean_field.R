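#' Mean-field synaptic gate
#'
#' Fraction of a population instantaneously above the gating threshold,
#' under the Lorentzian ansatz for the membrane-potential density with
#' center `v` and half-width `x`:
#' `S = (1/pi) * (pi/2 - atan((Vth - v) / x))`.
#'
#' With `gate_width = "pi_r"` (default) the half-width is the ansatz value
#' `x = pi * r`, the exact evaluation of the gating integral; with
#' `gate_width = "r"` the half-width is taken as `r` itself, the form the
#' source equations print.  At zero rate the one-sided limit is used
#' (0 below threshold, 1 above, 1/2 at threshold), so the vector field is
#' defined on the closed half-space \code{r >= 0}.
#'
#' @param r population firing rate (>= 0).
#' @param v population mean membrane potential.
#' @param Vth gating threshold.
#' @param gate_width `"pi_r"` or `"r"`.
#' @return Gate value in `[0, 1]`; strictly increasing in `v`, and in `r`
#'   whenever `v < Vth`.
#' @examples
#' synaptic_gate(10, 40, 50, gate_width = "r")  # 0.25
#' @export
synaptic_gate <- function(r, v, Vth = 50, gate_width = c("pi_r", "r")) {
  gate_width <- match.arg(gate_width)
  w <- if (gate_width == "pi_r") pi * r else r
  out <- ifelse(r > 0,
                (pi / 2 - atan((Vth - v) / w)) / pi,
                ifelse(v < Vth, 0, ifelse(v > Vth, 1, 0.5)))
  as.numeric(out)
}

#' Mean-field vector field
#'
#' Time derivatives of the four macroscopic variables
#' `(r_e, v_e, r_i, v_i)`: each population carries a firing-rate equation
#' `dr/dt = delta/pi + 2 r v - g r` and a mean-potential equation
#' `dv/dt = eta_bar + v^2 - pi^2 r^2 - Je (v - Ee) Se - Ji (v - Ei) Si
#' (+ I_ext)`, with the conductance gates of [synaptic_gate()].  In the
#' default (`rate_coupling = "own"`) form the rate equation of each
#' population carries only its own-type conductance (`g = Je Se` for the
#' excitatory, `g = Ji Si` for the inhibitory population), matching the
#' printed reduction; `"full"` uses `g = Je Se + Ji Si` in both.
#'
#' At zero rate the rate derivative equals `delta/pi > 0`, so rates cannot
#' cross below zero.
#'
#' @param state numeric length-4 vector `(r_e, v_e, r_i, v_i)` or a
#'   `mean_field_state`.
#' @param params a [qif_params()].
#' @param Iext external current (applied per `params$iext_target`).
#' @return Numeric length-4 derivative vector.
#' @export
mf_rhs <- function(state, params, Iext = 0) {
  state <- as_mf_state(state)
  if (any(!is.finite(state))) stop("non-finite mean-field state",
                                   call. = FALSE)
  .cpp_mf_rhs(state, param_vec(params), Iext)
}

as_mf_state <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 4L) stop("mean-field state must have 4 components",
                            call. = FALSE)
  x
}

#' Integrate the mean-field model under a stimulus protocol
#'
#' Classical fixed-step fourth-order Runge-Kutta.  Segment boundaries of
#' the piecewise-constant protocol are aligned to the time grid (each
#' segment is rounded to a whole number of steps).
#'
#' The default step `dt = 1e-3` resolves the sharp relaxation-like spikes
#' of the rate variable in strongly synchronized regimes; in smooth regimes
#' a coarser step such as `1e-2` is adequate (self-convergence is tested at
#' order 4).
#'
#' @param state0 initial `(r_e, v_e, r_i, v_i)`.
#' @param protocol a [stimulus_protocol()], or a single number interpreted
#'   as a constant current (then `t_end` must be given).
#' @param params a [qif_params()].
#' @param dt integration step.
#' @param t_end duration when `protocol` is a bare constant.
#' @param keep_every store every `keep_every`-th grid point (thinning for
#'   long runs; 1 stores all).
#' @return An object of class `mf_trajectory`: a data frame with columns
#'   `t, r_e, v_e, r_i, v_i, Iext` plus the integration settings as
#'   attributes.
#' @examples
#' p <- qif_params()
#' tr <- mf_integrate(c(0.1, -2, 0.1, -2), constant_protocol(0, 10), p)
#' tail(tr, 2)
#' @export
mf_integrate <- function(state0, protocol, params, dt = 1e-3, t_end = NULL,
                         keep_every = max(1L, round(0.01 / dt))) {
  if (is.numeric(protocol) && length(protocol) == 1L) {
    if (is.null(t_end)) stop("give 't_end' with a constant current",
                             call. = FALSE)
    protocol <- constant_protocol(protocol, t_end)
  }
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  state0 <- as_mf_state(state0)
  nstep <- round(diff(protocol$breaks) / dt)
  if (any(nstep < 1))
    stop("a protocol segment is shorter than one time step", call. = FALSE)
  res <- .cpp_mf_integrate(state0, param_vec(params), protocol$values,
                           as.integer(nstep), protocol$breaks[1], dt,
                           as.integer(keep_every))
  out <- data.frame(t = res$t, r_e = res$x[, 1], v_e = res$x[, 2],
                    r_i = res$x[, 3], v_i = res$x[, 4], Iext = res$Iext)
  structure(out, class = c("mf_trajectory", "data.frame"), dt = dt,
            keep_every = keep_every, params = params)
}

#' @export
print.mf_trajectory <- function(x, ...) {
  cat(sprintf("mean-field trajectory: %d stored points, t in [%g, %g]\n",
              nrow(x), x$t[1], x$t[nrow(x)]))
  cat(sprintf("  final state: r_e=%.4g v_e=%.4g r_i=%.4g v_i=%.4g\n",
              x$r_e[nrow(x)], x$v_e[nrow(x)], x$r_i[nrow(x)],
              x$v_i[nrow(x)]))
  invisible(x)
}

#' @export
plot.mf_trajectory <- function(x, which = "r_e", ...) {
  plot(x$t, x[[which]], type = "l", xlab = "t", ylab = which, ...)
  invisible(x)
}

#' Final state of a trajectory
#' @param traj an `mf_trajectory`.
#' @return Numeric length-4 state vector.
#' @export
mf_final_state <- function(traj) {
  n <- nrow(traj)
  c(r_e = traj$r_e[n], v_e = traj$v_e[n], r_i = traj$r_i[n],
    v_i = traj$v_i[n])
}

#' Compare a mean-field trajectory against a network rate trace
#'
#' Interpolates both rate signals onto a common grid over the requested
#' window and reports agreement metrics: root-mean-square difference, the
#' relative error of the time-averaged rates, and the relative mismatch of
#' the dominant oscillation period (median peak-to-peak spacing; `NA` when
#' either signal has fewer than three peaks).
#'
#' @param mf an `mf_trajectory`.
#' @param net a data frame with columns `t` and `rate` (e.g. one
#'   population's entry from [run_network()]), or any data frame whose
#'   second column is the rate.
#' @param t_window length-2 numeric window over which to compare.
#' @param population which mean-field rate to use, `"e"` or `"i"`.
#' @return A list with `rms`, `rel_mean_rate_error`, `rel_period_error`,
#'   `mean_rate_mf`, `mean_rate_net`, `period_mf`, `period_net`.
#' @export
compare_to_network <- function(mf, net, t_window, population = "e") {
  rcol <- if (population == "e") "r_e" else "r_i"
  t0 <- max(min(mf$t), min(net$t), t_window[1])
  t1 <- min(max(mf$t), max(net$t), t_window[2])
  if (t1 <= t0) stop("comparison windows are disjoint", call. = FALSE)
  grid <- seq(t0, t1, length.out = 2048L)
  a <- approx(mf$t, mf[[rcol]], grid)$y
  b <- approx(net$t, net[[2L]], grid)$y
  per <- function(t, y) {
    pk <- detect_peaks(data.frame(t = t, y = y),
                       min_prominence = 0.1 * (max(y) - min(y)))
    if (nrow(pk) < 3L) return(NA_real_)
    median(diff(pk$t))
  }
  pa <- per(grid, a)
  pb <- per(grid, b)
  list(rms = sqrt(mean((a - b)^2)),
       rel_mean_rate_error = abs(mean(a) - mean(b)) /
         max(abs(mean(a)), 1e-12),
       rel_period_error = if (is.na(pa) || is.na(pb)) NA_real_
       else abs(pa - pb) / pa,
       mean_rate_mf = mean(a), mean_rate_net = mean(b),
       period_mf = pa, period_net = pb)
}
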
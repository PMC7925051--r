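#' Instantaneous synaptic activation of a population
#'
#' Fraction of membrane potentials strictly above the gating threshold —
#' the Heaviside gate `S = (1/N) * sum(H(V - Vth))` that drives the
#' conductance synapses.
#'
#' @param V numeric vector of membrane potentials (non-empty).
#' @param Vth gating threshold.
#' @return A number in `[0, 1]`.
#' @examples
#' synaptic_activation(c(51, 52, 53, 49), 50)  # 0.75
#' @export
synaptic_activation <- function(V, Vth = 50) {
  if (!length(V)) stop("empty potential vector", call. = FALSE)
  mean(V > Vth)
}

#' Initialize a network state
#'
#' Per-neuron constant currents are drawn from the Lorentzian
#' heterogeneity either as deterministic quantiles (default; removes
#' sampling noise from the quenched disorder) or as random draws.
#' Membrane potentials start at `v0`.
#'
#' @param params a [qif_params()].
#' @param N_e,N_i population sizes.
#' @param het_mode `"quantile"` or `"sample"`.
#' @param seed seed for `het_mode = "sample"` and for shuffling.
#' @param v0 initial membrane potential for every neuron.
#' @return A list with `V_e`, `V_i`, `eta_e`, `eta_i`, `t`.
#' @export
network_init <- function(params, N_e = 1000L, N_i = 1000L,
                         het_mode = c("quantile", "sample"), seed = 1L,
                         v0 = -2) {
  het_mode <- match.arg(het_mode)
  eta <- function(n)
    if (het_mode == "quantile")
      lorentzian_quantiles(params$eta_bar, params$delta, n)
    else lorentzian_sample(params$eta_bar, params$delta, n, seed)
  list(V_e = rep(v0, N_e), V_i = rep(v0, N_i),
       eta_e = eta(N_e), eta_i = eta(N_i), t = 0)
}

#' One explicit-Euler step of the spiking network (reference implementation)
#'
#' Updates every neuron with the gates `S_e`, `S_i` evaluated from the
#' pre-step state; any neuron whose updated potential reaches `Vpeak` is
#' recorded as spiking and reset to `Vreset`.  This R implementation
#' defines the scheme; [run_network()] runs the same scheme in compiled
#' code.
#'
#' @param state a network state as from [network_init()].
#' @param dt time step (> 0).
#' @param Iext external current this step.
#' @param params a [qif_params()].
#' @return A list with the updated `state` and integer vectors
#'   `spikes_e`, `spikes_i` of neuron indices that fired.
#' @export
step_network <- function(state, dt, Iext, params) {
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  Se <- synaptic_activation(state$V_e, params$Vth)
  Si <- synaptic_activation(state$V_i, params$Vth)
  Ii <- if (params$iext_target == "both") Iext else 0
  Ve <- state$V_e + dt * (state$V_e^2 + state$eta_e + Iext -
                            params$Je * (state$V_e - params$Ee) * Se -
                            params$Ji * (state$V_e - params$Ei) * Si)
  Vi <- state$V_i + dt * (state$V_i^2 + state$eta_i + Ii -
                            params$Je * (state$V_i - params$Ee) * Se -
                            params$Ji * (state$V_i - params$Ei) * Si)
  if (any(!is.finite(Ve)) || any(!is.finite(Vi))) {
    bad <- if (any(!is.finite(Ve))) which(!is.finite(Ve))[1] else
      which(!is.finite(Vi))[1]
    stop(sprintf("network blow-up: neuron %d at t = %g", bad,
                 state$t + dt), call. = FALSE)
  }
  spikes_e <- which(Ve >= params$Vpeak)
  spikes_i <- which(Vi >= params$Vpeak)
  Ve[spikes_e] <- params$Vreset
  Vi[spikes_i] <- params$Vreset
  state$V_e <- Ve
  state$V_i <- Vi
  state$t <- state$t + dt
  list(state = state, spikes_e = spikes_e, spikes_i = spikes_i)
}

#' Simulate the two-population QIF network under a stimulus protocol
#'
#' Explicit Euler integration (a smooth higher-order scheme is ill-defined
#' across the discontinuous spike reset) with all-to-all mean coupling:
#' one global gate per population per step.  Returns the spike raster,
#' binned-and-smoothed population rate traces and the recorded gate
#' traces.
#'
#' @inheritParams network_init
#' @param protocol a [stimulus_protocol()].
#' @param dt Euler step (default 1e-3).
#' @param bin_width rate-estimator bin width.
#' @param smooth_bins moving-average window (number of bins) for the rate
#'   traces.
#' @param record_every store the gate values every this many steps.
#' @param v0 initial membrane potential.
#' @return An object of class `qif_network_sim`: a list with `raster`
#'   (data frame `t`, `population`, `neuron`), `rate_e` and `rate_i`
#'   (data frames `t`, `rate`), `gates` (data frame `t`, `S_e`, `S_i`),
#'   `final`, and the call settings.
#' @export
run_network <- function(params, N_e = 1000L, N_i = 1000L, protocol,
                        dt = 1e-3, seed = 1L,
                        het_mode = c("quantile", "sample"),
                        bin_width = 0.05, smooth_bins = 21L,
                        record_every = 10L, v0 = -2) {
  het_mode <- match.arg(het_mode)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  st <- network_init(params, N_e, N_i, het_mode, seed, v0)
  nstep <- round(diff(protocol$breaks) / dt)
  res <- .cpp_network_run(st$V_e, st$V_i, st$eta_e, st$eta_i,
                          param_vec(params), params$Vpeak, params$Vreset,
                          protocol$values, as.integer(nstep),
                          protocol$breaks[1], dt, as.integer(record_every))
  raster <- data.frame(
    t = c(res$spike_t_e, res$spike_t_i),
    population = rep(c("e", "i"),
                     c(length(res$spike_t_e), length(res$spike_t_i))),
    neuron = c(res$spike_id_e, res$spike_id_i))
  raster <- raster[order(raster$t, raster$population, raster$neuron), ]
  rownames(raster) <- NULL
  dur <- protocol_duration(protocol)
  rate_e <- population_rate(raster[raster$population == "e", ], N_e,
                            bin_width, smooth_bins, t_range = c(0, dur))
  rate_i <- population_rate(raster[raster$population == "i", ], N_i,
                            bin_width, smooth_bins, t_range = c(0, dur))
  structure(list(raster = raster, rate_e = rate_e, rate_i = rate_i,
                 gates = data.frame(t = res$rec_t, S_e = res$rec_Se,
                                    S_i = res$rec_Si),
                 final = list(V_e = res$Ve, V_i = res$Vi, eta_e = st$eta_e,
                              eta_i = st$eta_i, t = dur),
                 N_e = N_e, N_i = N_i, dt = dt, params = params,
                 protocol = protocol),
            class = "qif_network_sim")
}

#' @export
print.qif_network_sim <- function(x, ...) {
  cat(sprintf("QIF network simulation: N_e=%d N_i=%d, duration %g, dt=%g\n",
              x$N_e, x$N_i, protocol_duration(x$protocol), x$dt))
  cat(sprintf("  %d spikes (%d excitatory); mean excitatory rate %.4g\n",
              nrow(x$raster), sum(x$raster$population == "e"),
              mean(x$rate_e$rate)))
  invisible(x)
}

#' Population firing rate from a spike raster
#'
#' Binned spike count divided by `N * bin_width`, optionally smoothed with
#' a centered moving average.  Before smoothing, the rate integrates
#' exactly to the spike count: `sum(rate) * bin_width * N = nrow(raster)`.
#'
#' @param raster data frame with a column `t` of spike times (an empty
#'   raster yields an all-zero trace).
#' @param N number of neurons the raster was recorded from.
#' @param bin_width histogram bin width (> 0).
#' @param smooth_bins moving-average window in bins (1 = no smoothing;
#'   even values are increased to the next odd number).
#' @param t_range length-2 time range of the trace; defaults to the raster
#'   span.
#' @return A data frame with columns `t` (bin centers) and `rate`.
#' @export
population_rate <- function(raster, N, bin_width = 0.05, smooth_bins = 1L,
                            t_range = NULL) {
  if (bin_width <= 0) stop("'bin_width' must be positive", call. = FALSE)
  if (is.null(t_range))
    t_range <- if (nrow(raster)) range(raster$t) else c(0, bin_width)
  edges <- seq(t_range[1], t_range[2] + bin_width * 1e-9, by = bin_width)
  if (length(edges) < 2L) edges <- c(t_range[1], t_range[1] + bin_width)
  counts <- if (nrow(raster))
    tabulate(findInterval(raster$t, edges, rightmost.closed = TRUE),
             nbins = length(edges) - 1L)
  else rep(0L, length(edges) - 1L)
  rate <- counts / (N * bin_width)
  if (smooth_bins > 1L) {
    k <- as.integer(smooth_bins)
    if (k %% 2L == 0L) k <- k + 1L
    kern <- rep(1 / k, k)
    rate <- stats::filter(rate, kern, sides = 2)
    rate[is.na(rate)] <- 0
    rate <- as.numeric(rate)
  }
  data.frame(t = (edges[-length(edges)] + edges[-1]) / 2, rate = rate)
}

#' Kolmogorov-style check of the stationary voltage distribution
#'
#' Under the Lorentzian ansatz the stationary membrane-potential density
#' of a population is Lorentzian with center `v` and half-width `pi * r`.
#' This compares the empirical CDF of the potentials, trimmed to
#' `|V - v| <= trim` to avoid the spike-reset truncation, against the
#' matching (renormalized) truncated Lorentzian CDF, and returns the
#' sup-distance.
#'
#' @param V numeric vector of membrane potentials.
#' @param r population rate (> 0).
#' @param v population mean potential.
#' @param trim half-width of the comparison window.
#' @return The Kolmogorov sup-distance (a number in `[0, 1]`).
#' @export
voltage_distribution_check <- function(V, r, v, trim = 20) {
  if (r <= 0) stop("'r' must be positive", call. = FALSE)
  x <- pi * r
  keep <- abs(V - v) <= trim
  V <- sort(V[keep])
  if (!length(V)) return(1)
  cdf0 <- function(u) 0.5 + atan((u - v) / x) / pi
  lo <- cdf0(v - trim)
  hi <- cdf0(v + trim)
  theo <- (cdf0(V) - lo) / (hi - lo)
  n <- length(V)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1L) / n
  max(pmax(abs(emp_hi - theo), abs(emp_lo - theo)))
}
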
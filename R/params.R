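#' Model parameters for the QIF network and its mean-field reduction
#'
#' Container for all constants shared by the spiking network and the
#' four-dimensional mean-field model: synaptic conductances, reversal
#' potentials, the Lorentzian heterogeneity of the constant input current,
#' the synaptic gating threshold, and the network-only spike conventions.
#'
#' Defaults are the reference parameter set of the model: `Je = 15`,
#' `Ji = 8`, `Ee = 75`, `Ei = -75`, `eta_bar = -5`, `delta = 1`,
#' `Vth = 50`.  All quantities are in dimensionless model units; one model
#' time unit corresponds to the unit in which rate axes are conventionally
#' labelled.
#'
#' The two gate conventions (`gate_width`) differ in the half-width
#' attributed to the membrane-potential distribution when evaluating the
#' fraction of neurons above the gating threshold `Vth`:
#' `"pi_r"` uses the Lorentzian-ansatz half-width `x = pi * r` (the exact
#' evaluation of the gating integral, the default), `"r"` uses `r` itself.
#' See `vignette("qif-mean-field")` for why both are provided.
#'
#' @param Je excitatory synaptic conductance (>= 0).
#' @param Ji inhibitory synaptic conductance (>= 0).
#' @param Ee excitatory reversal potential.
#' @param Ei inhibitory reversal potential.
#' @param eta_bar center of the Lorentzian distribution of the per-neuron
#'   constant current.
#' @param delta half-width of the Lorentzian heterogeneity (> 0).
#' @param Vth synaptic gating threshold; must satisfy `Ei < Vth < Ee`.
#' @param Vpeak finite spike-detection threshold used by the network
#'   simulator (the idealized model resets from infinity).  The default
#'   300 keeps both finite-cutoff biases small: the inter-spike-interval
#'   shortening (about 2/Vpeak) and, more importantly for conductance
#'   gating, the loss of the Lorentzian tail mass above Vpeak that the
#'   gate integral counts (about x/(pi*Vpeak) for half-width x).
#' @param Vreset reset potential; the convention `Vreset = -Vpeak` is
#'   enforced.
#' @param gate_width `"pi_r"` or `"r"`, see Details.
#' @param rate_coupling `"own"` (each population's rate equation carries
#'   only its own-type conductance, the form used throughout) or `"full"`
#'   (both conductances act on both rate equations), a sensitivity variant.
#' @param iext_target which population(s) receive the external stimulus:
#'   `"excitatory"` (default) or `"both"`.
#'
#' @return An object of class `qif_params` (a named list).
#' @examples
#' p <- qif_params()
#' p
#' qif_params(Je = 32)$Je
#' @export
qif_params <- function(Je = 15, Ji = 8, Ee = 75, Ei = -75, eta_bar = -5,
                       delta = 1, Vth = 50, Vpeak = 300, Vreset = -Vpeak,
                       gate_width = c("pi_r", "r"),
                       rate_coupling = c("own", "full"),
                       iext_target = c("excitatory", "both")) {
  gate_width <- match.arg(gate_width)
  rate_coupling <- match.arg(rate_coupling)
  iext_target <- match.arg(iext_target)
  p <- list(Je = Je, Ji = Ji, Ee = Ee, Ei = Ei, eta_bar = eta_bar,
            delta = delta, Vth = Vth, Vpeak = Vpeak, Vreset = Vreset,
            gate_width = gate_width, rate_coupling = rate_coupling,
            iext_target = iext_target)
  validate_qif_params(p)
  class(p) <- "qif_params"
  p
}

validate_qif_params <- function(p) {
  num <- c("Je", "Ji", "Ee", "Ei", "eta_bar", "delta", "Vth", "Vpeak",
           "Vreset")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number",
           call. = FALSE)
  }
  if (p$delta <= 0)
    stop("parameter 'delta' must be positive (Lorentzian half-width)",
         call. = FALSE)
  if (p$Vreset != -p$Vpeak)
    stop("spike convention violated: Vreset must equal -Vpeak",
         call. = FALSE)
  if (!(p$Ei < p$Vth && p$Vth < p$Ee))
    stop("threshold ordering violated: need Ei < Vth < Ee", call. = FALSE)
  invisible(p)
}

#' @export
print.qif_params <- function(x, ...) {
  cat("QIF network / mean-field parameters\n")
  cat(sprintf("  Je=%g Ji=%g  Ee=%g Ei=%g  eta_bar=%g delta=%g  Vth=%g\n",
              x$Je, x$Ji, x$Ee, x$Ei, x$eta_bar, x$delta, x$Vth))
  cat(sprintf("  network: Vpeak=%g Vreset=%g\n", x$Vpeak, x$Vreset))
  cat(sprintf("  gate half-width: %s | rate coupling: %s | I_ext -> %s\n",
              if (x$gate_width == "pi_r") "pi*r (exact)" else "r (as printed)",
              x$rate_coupling, x$iext_target))
  invisible(x)
}

## numeric vector handed to the C++ kernels
param_vec <- function(p) {
  c(p$Je, p$Ji, p$Ee, p$Ei, p$eta_bar, p$delta, p$Vth,
    as.numeric(p$gate_width == "pi_r"),
    as.numeric(p$rate_coupling == "full"),
    as.numeric(p$iext_target == "both"))
}

#' Lorentzian (Cauchy) density of the input-current heterogeneity
#'
#' Density `g(eta) = (delta/pi) / ((eta - eta_bar)^2 + delta^2)`.  The heavy
#' tails of this distribution are what makes the mean-field reduction exact:
#' population averages close via the residue at the pole
#' `eta = eta_bar - i*delta`.
#'
#' @param eta evaluation point(s).
#' @param eta_bar center of the distribution.
#' @param delta half-width at half-maximum (> 0).
#' @return Density values, strictly positive.
#' @examples
#' lorentzian_pdf(-5, -5, 1)   # peak value 1/pi
#' @export
lorentzian_pdf <- function(eta, eta_bar = -5, delta = 1) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0)
    stop("'delta' must be a single positive number", call. = FALSE)
  (delta / pi) / ((eta - eta_bar)^2 + delta^2)
}

#' Lorentzian cumulative distribution function
#'
#' @inheritParams lorentzian_pdf
#' @return `P(X <= eta)` for `X ~ Lorentzian(eta_bar, delta)`.
#' @export
lorentzian_cdf <- function(eta, eta_bar = -5, delta = 1) {
  if (delta <= 0) stop("'delta' must be positive", call. = FALSE)
  0.5 + atan((eta - eta_bar) / delta) / pi
}

#' Deterministic Lorentzian quantile grid
#'
#' Returns the `n` equispaced-probability quantiles
#' `eta_j = eta_bar + delta * tan(pi * (2j - n - 1) / (2 (n + 1)))`,
#' `j = 1..n`, i.e. the inverse CDF evaluated at `j / (n + 1)`.  Assigning
#' these values as the per-neuron constant currents removes sampling noise
#' from the quenched heterogeneity, which sharpens finite-network
#' comparisons against the mean-field limit.
#'
#' @inheritParams lorentzian_pdf
#' @param n number of quantiles (>= 1).
#' @return Strictly increasing numeric vector of length `n`; for odd `n`
#'   the median element equals `eta_bar`.
#' @examples
#' lorentzian_quantiles(-5, 1, 3)  # -6 -5 -4
#' @export
lorentzian_quantiles <- function(eta_bar = -5, delta = 1, n) {
  if (delta <= 0) stop("'delta' must be positive", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  j <- seq_len(n)
  eta_bar + delta * tan(pi * (2 * j - n - 1) / (2 * (n + 1)))
}

#' Random Lorentzian draws via the inverse CDF
#'
#' @inheritParams lorentzian_quantiles
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return Numeric vector of `n` i.i.d. Lorentzian variates.
#' @export
lorentzian_sample <- function(eta_bar = -5, delta = 1, n, seed = 1L) {
  if (delta <= 0) stop("'delta' must be positive", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  u <- runif(n)
  eta_bar + delta * tan(pi * (u - 0.5))
}

## Halton low-discrepancy sequence, used for multi-start grids
halton_seq <- function(n, dim) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19)
  stopifnot(dim <= length(primes))
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    for (i in seq_len(n)) {
      f <- 1
      r <- 0
      k <- i
      while (k > 0) {
        f <- f / b
        r <- r + f * (k %% b)
        k <- k %/% b
      }
      out[i, d] <- r
    }
  }
  out
}
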
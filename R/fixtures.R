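#' Synthetic test signals with known ground truth
#'
#' Deterministic fixture generators used to exercise the peak detector,
#' the period classifier and the rate estimator without running the
#' model: a pure sinusoid (period class 1), pulse trains whose peak
#' amplitudes alternate with period 2 or 4, and a homogeneous Poisson
#' spike raster of known rate.
#'
#' @param kind one of `"sinusoid"`, `"alternating_peaks"`,
#'   `"period4_peaks"`, `"poisson_raster"`.
#' @param seed seed for the Poisson raster.
#' @param dt sample spacing for trace fixtures.
#' @param t_end duration.
#' @param rate,N Poisson raster rate per neuron and neuron count.
#' @return For trace kinds, a data frame `t`, `y` with attributes
#'   `true_class` (period class) and `true_period`; for
#'   `"poisson_raster"`, a data frame `t`, `population`, `neuron` with
#'   attribute `true_rate`.
#' @export
fixture_signal <- function(kind = c("sinusoid", "alternating_peaks",
                                    "period4_peaks", "poisson_raster"),
                           seed = 1L, dt = 0.01, t_end = 80,
                           rate = 0.2, N = 100L) {
  kind <- match.arg(kind)
  if (kind == "sinusoid") {
    t <- seq(0, t_end, by = dt)
    out <- data.frame(t = t, y = sin(t))
    attr(out, "true_class") <- 1L
    attr(out, "true_period") <- 2 * pi
    return(out)
  }
  if (kind %in% c("alternating_peaks", "period4_peaks")) {
    amps <- if (kind == "alternating_peaks") c(1, 0.5) else
      c(1, 0.4, 0.75, 0.55)
    t <- seq(0, t_end, by = dt)
    ## train of raised-cosine bumps, one per unit time, amplitude cycling
    y <- numeric(length(t))
    centers <- seq(0.5, t_end - 0.5, by = 1)
    for (k in seq_along(centers)) {
      a <- amps[(k - 1L) %% length(amps) + 1L]
      w <- abs(t - centers[k]) < 0.3
      y[w] <- y[w] + a * 0.5 * (1 + cos(pi * (t[w] - centers[k]) / 0.3))
    }
    out <- data.frame(t = t, y = y)
    attr(out, "true_class") <- length(amps)
    attr(out, "true_period") <- length(amps)
    return(out)
  }
  ## poisson_raster
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  counts <- rpois(N, rate * t_end)
  t <- unlist(lapply(counts, function(k) sort(runif(k, 0, t_end))))
  neuron <- rep(seq_len(N), counts)
  out <- data.frame(t = t, population = "e", neuron = neuron)
  out <- out[order(out$t), ]
  rownames(out) <- NULL
  attr(out, "true_rate") <- rate
  out
}
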
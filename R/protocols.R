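#' Piecewise-constant stimulus protocol
#'
#' A stimulus protocol is an ordered set of contiguous segments, each with a
#' constant external current `I_ext`, covering `[0, duration]`.
#'
#' @param breaks numeric vector of segment boundaries, starting at 0,
#'   strictly increasing; the last element is the total duration.
#' @param values numeric vector of `length(breaks) - 1` current values, one
#'   per segment.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' pr <- stimulus_protocol(c(0, 2, 10), c(0, 8))
#' protocol_current(pr, c(1, 5))
#' @export
stimulus_protocol <- function(breaks, values) {
  if (length(breaks) < 2L || breaks[1] != 0 || any(diff(breaks) <= 0))
    stop("'breaks' must start at 0 and be strictly increasing",
         call. = FALSE)
  if (length(values) != length(breaks) - 1L)
    stop("need one current value per segment", call. = FALSE)
  if (any(!is.finite(breaks)) || any(!is.finite(values)))
    stop("protocol entries must be finite", call. = FALSE)
  structure(list(breaks = as.numeric(breaks), values = as.numeric(values)),
            class = "stimulus_protocol")
}

#' Evaluate a protocol's external current at given times
#'
#' Segments are half-open `[t_k, t_{k+1})`; the final right endpoint takes
#' the last segment's value.
#'
#' @param protocol a [stimulus_protocol()].
#' @param t numeric vector of times in `[0, duration]`.
#' @return Numeric vector of `I_ext` values.
#' @export
protocol_current <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  idx <- findInterval(t, protocol$breaks, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(protocol$values)] <- length(protocol$values)
  protocol$values[idx]
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("stimulus protocol, duration", x$breaks[length(x$breaks)], "\n")
  for (k in seq_along(x$values))
    cat(sprintf("  [%g, %g): I_ext = %g\n", x$breaks[k], x$breaks[k + 1],
                x$values[k]))
  invisible(x)
}

#' Protocol duration
#' @param protocol a [stimulus_protocol()].
#' @return Total duration (numeric scalar).
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  protocol$breaks[length(protocol$breaks)]
}

#' Step-stimulus protocol of the network/mean-field comparison experiment
#'
#' No external input (`I_ext = 0`) on `[0, 2)`, then a step to `I_ext = 8`
#' until `t = 10`: the quiescent population is driven into collective
#' oscillation.
#'
#' @return A [stimulus_protocol()].
#' @export
step_protocol <- function() {
  stimulus_protocol(c(0, 2, 10), c(0, 8))
}

#' Transient-pulse protocol for probing bistability
#'
#' Holds the baseline current, applies a pulse on `[10, 12)`, then returns
#' to baseline until `t = t_end`.  With baseline -3 and pulse +3 this is
#' the attractor-switching experiment: the pulse kicks the quiescent state
#' onto the coexisting high-activity attractor, which persists after the
#' pulse is removed.
#'
#' @param base baseline current (default -3).
#' @param pulse pulse current (default 3).
#' @param t_end end of the observation window (default 25; a generous
#'   post-pulse window makes attractor classification robust).
#' @return A [stimulus_protocol()].
#' @export
bistability_protocol <- function(base = -3, pulse = 3, t_end = 25) {
  stopifnot(t_end > 12)
  stimulus_protocol(c(0, 10, 12, t_end), c(base, pulse, base))
}

#' Constant protocol
#' @param Iext the constant current.
#' @param t_end duration.
#' @return A [stimulus_protocol()].
#' @export
constant_protocol <- function(Iext, t_end) {
  stimulus_protocol(c(0, t_end), Iext)
}

#' Catalogue of reference experiments across the two-parameter plane
#'
#' Named `(I_ext, Je)` points spanning the model's dynamical repertoire,
#' one per region of the two-parameter bifurcation diagram plus a chaotic
#' point.  Each entry records two outcome tags:
#' \describe{
#'   \item{reported_class}{the behaviour attributed to that point in the
#'     source study's two-parameter scenario (its region label);}
#'   \item{model_class}{the behaviour of this package's default mean-field
#'     system (exact gate) at that exact point, as established by the test
#'     suite.  Where the two differ the diagram geometry is shifted in
#'     `Je` relative to the reported scenario; see the package vignette.}
#' }
#' Points tagged `pulse = TRUE` sit in (reported) bistable regions and are
#' probed with [bistability_protocol()]; the rest use a constant current.
#'
#' @return A data frame with columns `label`, `Iext`, `Je`, `pulse`,
#'   `reported_class`, `model_class`.
#' @export
experiment_catalogue <- function() {
  data.frame(
    label = c("region_I", "region_II", "region_III", "region_IV",
              "region_V", "region_VI", "region_VII", "region_VIII",
              "region_IX", "region_X", "chaos"),
    Iext = c(0, 8, 5, 5, 0, -0.85, -3, -3, -3, -3, -3),
    Je = c(15, 15, 30, 50, 70, 75, 32, 45, 51, 52.4, 53.5),
    pulse = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
              TRUE, TRUE, TRUE, TRUE, TRUE),
    reported_class = c("quiescent", "period-1", "focus", "period-1",
                       "period-2", "period-4", "bistable-focus",
                       "bistable-period-1", "bistable-period-2",
                       "bistable-period-4", "chaotic"),
    model_class = c("quiescent", "period-1", "focus", "period-1",
                    "period-1", "period-1", "bistable-focus",
                    "bistable-period-1", "bistable-period-1",
                    "bistable-period-1", "period-1"),
    stringsAsFactors = FALSE
  )
}
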
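#' Analytic Jacobian of the mean-field vector field
#'
#' Partial derivatives of [mf_rhs()] with respect to
#' `(r_e, v_e, r_i, v_i)`, including the gate partials
#' `dS/dr` and `dS/dv`.  Requires `r_e, r_i > 0` (the gate is not
#' differentiable at zero rate).
#'
#' @inheritParams mf_rhs
#' @return A 4x4 numeric matrix.
#' @export
mf_jacobian <- function(state, params, Iext = 0) {
  state <- as_mf_state(state)
  if (state[1] <= 0 || state[3] <= 0)
    stop("Jacobian undefined at r = 0 (gate not differentiable)",
         call. = FALSE)
  .cpp_mf_jac(state, param_vec(params))
}

#' Classify an equilibrium from its eigenvalues
#'
#' Labels follow the standard taxonomy: all eigenvalues with negative real
#' part give a stable node (all real) or stable focus (at least one complex
#' pair); all positive an unstable node/focus; mixed signs a saddle.  Any
#' eigenvalue with `|Re| < tol` makes the point nonhyperbolic.
#'
#' @param eigenvalues complex vector of the four Jacobian eigenvalues.
#' @param tol hyperbolicity tolerance on `|Re(lambda)|`.
#' @return One of `"stable node"`, `"stable focus"`, `"saddle"`,
#'   `"unstable node"`, `"unstable focus"`, `"nonhyperbolic"`.
#' @examples
#' classify_eigenvalues(c(-1, -2, -3, -4))          # stable node
#' classify_eigenvalues(c(-0.1 + 2i, -0.1 - 2i, -1, -3))  # stable focus
#' @export
classify_eigenvalues <- function(eigenvalues, tol = 1e-6) {
  ev <- as.complex(eigenvalues)
  if (length(ev) != 4L) stop("need 4 eigenvalues", call. = FALSE)
  re <- Re(ev)
  if (any(abs(re) < tol)) return("nonhyperbolic")
  cplx <- any(abs(Im(ev)) > tol)
  if (all(re < 0)) return(if (cplx) "stable focus" else "stable node")
  if (all(re > 0)) return(if (cplx) "unstable focus" else "unstable node")
  "saddle"
}

## Damped Newton on the mean-field vector field, keeping rates positive.
## Returns the root or NULL.
newton_mf <- function(x0, params, Iext, tol = 1e-12, maxit = 80L) {
  pv <- param_vec(params)
  x <- as.numeric(x0)
  for (it in seq_len(maxit)) {
    f <- .cpp_mf_rhs(x, pv, Iext)
    if (any(!is.finite(f))) return(NULL)
    nf <- sqrt(sum(f * f))
    if (nf < tol) return(x)
    if (x[1] <= 0 || x[3] <= 0) return(NULL)
    J <- .cpp_mf_jac(x, pv)
    dx <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * dx
      if (xn[1] > 1e-12 && xn[3] > 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) return(NULL)
    }
    x <- xn
  }
  f <- .cpp_mf_rhs(x, pv, Iext)
  if (sqrt(sum(f * f)) < 1e-9) x else NULL
}

make_equilibrium <- function(x, params, Iext, tol_hyp = 1e-6) {
  f <- mf_rhs(x, params, Iext)
  J <- mf_jacobian(x, params, Iext)
  ev <- eigen(J, only.values = TRUE)$values
  list(state = c(r_e = x[1], v_e = x[2], r_i = x[3], v_i = x[4]),
       eigenvalues = ev,
       classification = classify_eigenvalues(ev, tol_hyp),
       residual = sqrt(sum(f * f)))
}

#' Locate all equilibria of the mean-field system
#'
#' Multi-start damped Newton iteration from a Halton low-discrepancy grid
#' over a search box in `(r_e, v_e, r_i, v_i)`, with deduplication and
#' eigenvalue classification of every converged root.  The rate axes of
#' the deduplication metric are scaled by 10 to balance magnitudes against
#' the potential axes.
#'
#' @param params a [qif_params()].
#' @param Iext external current.
#' @param r_max upper limit of the rate search range (box is
#'   `[0, r_max]^2`).
#' @param v_range length-2 range for both mean potentials (default covers
#'   the reversal potentials).
#' @param n_starts number of Newton starts.
#' @param dedup_tol deduplication distance.
#' @return An object of class `mf_equilibria`: a list of equilibria, each
#'   with `state`, `eigenvalues`, `classification`, `residual`; sorted by
#'   increasing `r_e`.
#' @examples
#' eqs <- find_equilibria(qif_params(), Iext = 0, n_starts = 256)
#' length(eqs)
#' @export
find_equilibria <- function(params, Iext = 0, r_max = 20,
                            v_range = c(-80, 80), n_starts = 1024L,
                            dedup_tol = 1e-6) {
  h <- halton_seq(n_starts, 4L)
  roots <- list()
  scale <- c(10, 1, 10, 1)
  for (i in seq_len(n_starts)) {
    x0 <- c(1e-3 + h[i, 1] * r_max,
            v_range[1] + h[i, 2] * diff(v_range),
            1e-3 + h[i, 3] * r_max,
            v_range[1] + h[i, 4] * diff(v_range))
    r <- newton_mf(x0, params, Iext)
    if (is.null(r) || r[1] < -1e-8 || r[3] < -1e-8) next
    dup <- FALSE
    for (q in roots)
      if (sqrt(sum((scale * (r - q))^2)) < max(dedup_tol, 1e-6 * sum(abs(r))))
        dup <- TRUE
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  roots <- roots[order(vapply(roots, `[`, numeric(1), 1L))]
  out <- lapply(roots, make_equilibrium, params = params, Iext = Iext)
  structure(out, class = "mf_equilibria", Iext = Iext, params = params)
}

#' @export
print.mf_equilibria <- function(x, ...) {
  cat(sprintf("%d equilibri%s at I_ext = %g\n", length(x),
              if (length(x) == 1) "um" else "a", attr(x, "Iext")))
  for (e in x)
    cat(sprintf("  r_e=%.5f v_e=%8.4f r_i=%.5f v_i=%8.4f  %-14s |f|=%.1e\n",
                e$state[1], e$state[2], e$state[3], e$state[4],
                e$classification, e$residual))
  invisible(x)
}

#' Stable equilibria of a set
#' @param eqs an `mf_equilibria` object.
#' @return The subset whose classification starts with "stable".
#' @export
stable_equilibria <- function(eqs) {
  eqs[vapply(eqs, function(e) startsWith(e$classification, "stable"),
             logical(1))]
}

#' Refine a single equilibrium from a starting guess
#'
#' @param x0 starting state.
#' @inheritParams find_equilibria
#' @return A single equilibrium (list) or `NULL` when Newton fails.
#' @export
refine_equilibrium <- function(x0, params, Iext = 0) {
  r <- newton_mf(x0, params, Iext)
  if (is.null(r)) return(NULL)
  make_equilibrium(r, params, Iext)
}

#' Quiescent (lowest-rate) equilibrium
#'
#' Convenience wrapper returning the equilibrium with the smallest `r_e`,
#' typically the quiescent state used as the default initial condition of
#' the stimulation experiments.
#'
#' @inheritParams find_equilibria
#' @return A single equilibrium (list).
#' @export
quiescent_equilibrium <- function(params, Iext = 0) {
  ## the quiescent root is reliably reached from a low-rate start
  for (guess in list(c(0.06, -2.5, 0.07, -2.2), c(0.1, -2, 0.1, -2),
                     c(0.03, -5, 0.03, -5), c(0.3, -1, 0.3, -1))) {
    e <- refine_equilibrium(guess, params, Iext)
    if (!is.null(e)) return(e)
  }
  eqs <- find_equilibria(params, Iext, n_starts = 512L)
  if (!length(eqs)) stop("no equilibrium found", call. = FALSE)
  eqs[[1L]]
}
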
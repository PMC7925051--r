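#' Read a flat key = value configuration file
#'
#' Parses a plain-text configuration (one `key = value` per line, `#`
#' comments), validates every key against the model-parameter and
#' simulation-control vocabulary, and returns a full configuration with
#' unset fields at their defaults.
#'
#' @param path file path; a missing or empty file yields all defaults.
#' @return A list with elements `params` (a [qif_params()]) and
#'   `controls` (list with `dt`, `dt_network`, `N_e`, `N_i`, `seed`,
#'   `het_mode`, `bin_width`, `smooth_bins`).
#' @export
read_run_config <- function(path) {
  defaults <- list(Je = 15, Ji = 8, Ee = 75, Ei = -75, eta_bar = -5,
                   delta = 1, Vth = 50, Vpeak = 300,
                   gate_width = "pi_r", rate_coupling = "own",
                   iext_target = "excitatory",
                   dt = 1e-3, dt_network = 1e-3, N_e = 1000, N_i = 1000,
                   seed = 1, het_mode = "quantile", bin_width = 0.05,
                   smooth_bins = 21)
  chr_keys <- c("gate_width", "rate_coupling", "iext_target", "het_mode")
  vals <- defaults
  if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop("malformed config line: '", ln, "'", call. = FALSE)
      key <- trimws(kv[1])
      val <- trimws(kv[2])
      if (!key %in% names(defaults))
        stop("unknown config key '", key, "'; valid keys: ",
             paste(names(defaults), collapse = ", "), call. = FALSE)
      vals[[key]] <- if (key %in% chr_keys) val else {
        v <- suppressWarnings(as.numeric(val))
        if (is.na(v)) stop("non-numeric value for '", key, "'",
                           call. = FALSE)
        v
      }
    }
  }
  params <- qif_params(Je = vals$Je, Ji = vals$Ji, Ee = vals$Ee,
                       Ei = vals$Ei, eta_bar = vals$eta_bar,
                       delta = vals$delta, Vth = vals$Vth,
                       Vpeak = vals$Vpeak, gate_width = vals$gate_width,
                       rate_coupling = vals$rate_coupling,
                       iext_target = vals$iext_target)
  controls <- list(dt = vals$dt, dt_network = vals$dt_network,
                   N_e = as.integer(vals$N_e), N_i = as.integer(vals$N_i),
                   seed = as.integer(vals$seed), het_mode = vals$het_mode,
                   bin_width = vals$bin_width,
                   smooth_bins = as.integer(vals$smooth_bins))
  list(params = params, controls = controls)
}

#' Write a configuration back to a flat file
#'
#' The written file round-trips through [read_run_config()].
#'
#' @param config a list as returned by [read_run_config()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  p <- config$params
  ct <- config$controls
  lines <- c(
    sprintf("Je = %.17g", p$Je), sprintf("Ji = %.17g", p$Ji),
    sprintf("Ee = %.17g", p$Ee), sprintf("Ei = %.17g", p$Ei),
    sprintf("eta_bar = %.17g", p$eta_bar),
    sprintf("delta = %.17g", p$delta), sprintf("Vth = %.17g", p$Vth),
    sprintf("Vpeak = %.17g", p$Vpeak),
    sprintf("gate_width = %s", p$gate_width),
    sprintf("rate_coupling = %s", p$rate_coupling),
    sprintf("iext_target = %s", p$iext_target),
    sprintf("dt = %.17g", ct$dt),
    sprintf("dt_network = %.17g", ct$dt_network),
    sprintf("N_e = %d", ct$N_e), sprintf("N_i = %d", ct$N_i),
    sprintf("seed = %d", ct$seed),
    sprintf("het_mode = %s", ct$het_mode),
    sprintf("bin_width = %.17g", ct$bin_width),
    sprintf("smooth_bins = %d", ct$smooth_bins))
  writeLines(lines, path)
  invisible(path)
}

#' Write a spike raster as tab-separated text
#'
#' Three columns (`time`, `population`, `neuron_index`), header line,
#' times to six decimals — a fixed format so repeated runs with the same
#' seed are byte-identical.
#'
#' @param raster data frame with columns `t`, `population`, `neuron`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_raster_tsv <- function(raster, path) {
  df <- data.frame(time = sprintf("%.6f", raster$t),
                   population = raster$population,
                   neuron_index = raster$neuron)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a numeric trace table as CSV at fixed precision
#'
#' @param df data frame of numeric columns (e.g. a trajectory or rate
#'   trace).
#' @param path destination file.
#' @param digits decimal places for numeric columns.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(df, path, digits = 9L) {
  fmt <- paste0("%.", digits, "f")
  out <- as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) sprintf(fmt, col) else as.character(col)),
    stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run one catalogue experiment end to end
#'
#' Looks up a label in [experiment_catalogue()], integrates the
#' mean-field model from the quiescent equilibrium under the appropriate
#' protocol (constant, or the transient-pulse protocol for bistable
#' points), and classifies the post-transient attractor.
#'
#' @param label a catalogue label, e.g. `"region_VII"`.
#' @param params baseline [qif_params()] (the catalogue overrides `Je`).
#' @param t_end run length.
#' @param dt integration step.
#' @return A list with `experiment` (the catalogue row), `trajectory`,
#'   `class` (the classified attractor), `settled_rate` (mean
#'   post-transient `r_e`).
#' @export
run_experiment <- function(label, params = qif_params(), t_end = 400,
                           dt = 1e-3) {
  cat_ <- experiment_catalogue()
  row <- cat_[cat_$label == label, ]
  if (!nrow(row)) stop("unknown experiment label '", label, "'; known: ",
                       paste(cat_$label, collapse = ", "), call. = FALSE)
  p <- params
  p$Je <- row$Je
  ## start from rest (the quiescent state under zero external input), then
  ## apply the experiment's stimulus -- a tiny rate offset avoids starting
  ## exactly on an unstable equilibrium when the rest state is balanced
  eq <- quiescent_equilibrium(p, Iext = 0)
  x0 <- eq$state + c(1e-3, 0, 1e-3, 0)
  proto <- if (row$pulse) bistability_protocol(row$Iext, 3, t_end) else
    constant_protocol(row$Iext, t_end)
  cl <- classify_attractor(x0, proto, p, dt = dt)
  list(experiment = row, class = cl$class,
       settled_rate = mean(cl$trajectory_tail$r_e),
       final_state = cl$final_state, tail = cl$trajectory_tail)
}
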
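# Reproducible workflow wrappers: YAML config in, files out.  These back
# the `dendrosmooth` command-line script (inst/exec/dendrosmooth).

#' Load / save a run configuration
#'
#' Configs are plain YAML with blocks `paths` (swc, data, outdir),
#' `protocol` (bap_times, stim_window, sites_per_bin, n_bins, amp_soma,
#' length_const, optional epsp_*), `model` (delta, tau or "estimate",
#' noise, seed) and `optimizer` (gap_tol, newton_tol).  Defaults are filled
#' in for anything missing; the resolved config (seed included) is copied
#' into every output directory.
#'
#' @param path YAML file path (or, for `save_config`, output path).
#' @param config a config list.
#' @return `load_config`: the resolved config list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  resolve_config(cfg)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

resolve_config <- function(cfg) {
  dflt <- list(
    paths = list(swc = NULL, data = NULL, outdir = "."),
    protocol = list(bap_times = c(0.2, 0.5, 0.66), stim_window = c(0.1, 0.9),
                    sites_per_bin = 50L, n_bins = 100L, amp_soma = 1,
                    length_const = 200),
    model = list(delta = 0.01, tau = "estimate", noise = "gaussian",
                 sigma = 0.1, pmt_slope = 1, pmt_scale = 1, baseline = 100,
                 seed = 1L),
    optimizer = list(gap_tol = 1e-6, newton_tol = 1e-8),
    estimation = list(t_pre = 0.1, filter_width = 0.05, tol = 0.1,
                      s_init = 8L))
  for (blk in names(dflt)) {
    if (is.null(cfg[[blk]])) cfg[[blk]] <- list()
    for (k in names(dflt[[blk]]))
      if (is.null(cfg[[blk]][[k]])) cfg[[blk]][[k]] <- dflt[[blk]][[k]]
  }
  cfg
}

config_model <- function(cfg, n_compartments, tau = NULL) {
  m <- cfg$model
  noise <- if (identical(m$noise, "gamma_pmt"))
    pmt_noise(m$pmt_slope, m$pmt_scale) else gaussian_noise(m$sigma)
  calcium_model(delta = m$delta,
                tau = if (is.numeric(m$tau)) m$tau else tau,
                baseline = rep_len(m$baseline, n_compartments),
                noise = noise, amp = 1,
                rate = rate_schedule(cfg$protocol$n_bins, m$delta,
                                     cfg$protocol$stim_window[1],
                                     cfg$protocol$stim_window[2]))
}

#' Simulate an experiment from a config
#'
#' Reads the SWC morphology, simulates the stimulation protocol and the
#' random-access scan, and writes `measurements.csv` (bin, site, value),
#' `truth_states.csv`, `truth_innovations.csv`, `truth_events.csv` and the
#' resolved `config.yaml` into the output directory.  Deterministic given
#' the config seed.
#'
#' @param config a config list (see [load_config()]).
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- resolve_config(config)
  if (is.null(cfg$paths$swc)) stop("config paths$swc is required")
  tree <- read_swc(cfg$paths$swc)
  outdir <- cfg$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tau <- if (is.numeric(cfg$model$tau)) cfg$model$tau else 0.2
  cfg$model$tau <- tau
  model <- config_model(cfg, tree$n, tau = tau)
  basis <- tree_basis(tree, cfg$estimation$s_init)
  ex <- simulate_experiment(tree, basis, model, cfg$protocol,
                            seed = cfg$model$seed)
  utils::write.csv(as.data.frame(ex$data),
                   file.path(outdir, "measurements.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ex$truth$trajectory$a),
                   file.path(outdir, "truth_states.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ex$truth$trajectory$u),
                   file.path(outdir, "truth_innovations.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(bin = ex$truth$bap_bins),
                   file.path(outdir, "truth_events.csv"), row.names = FALSE)
  save_config(cfg, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

read_measurements <- function(path, n_sites) {
  df <- utils::read.csv(path)
  scan_data(df$bin, df$site, df$value, n_sites = n_sites)
}

#' Smooth recorded data from a config
#'
#' Full analysis chain: read SWC and measurements, prune the tree to the
#' imaged branches, estimate all model parameters ([estimate_parameters()]),
#' run the MAP smoother, extract events, and write `events.csv`,
#' `field.csv` (inferred delta F/F at every surviving compartment),
#' `weights.csv`, `report.json` (alpha, sigma summary, spline fit error,
#' barrier path) and the resolved config into the output directory.
#'
#' @param config a config list.
#' @param leave_out optional compartment indices (original SWC order) whose
#'   measurements are withheld; the cross-validated field at those
#'   compartments is written to `crossval_field.csv`.
#' @param subsample_factor optional integer k: keep only every k-th bin's
#'   measurements before smoothing.
#' @return list of class `smooth_run` with the fit, calibration, events and
#'   output directory.
#' @export
run_smooth <- function(config, leave_out = NULL, subsample_factor = NULL) {
  cfg <- resolve_config(config)
  if (is.null(cfg$paths$swc) || is.null(cfg$paths$data))
    stop("config paths$swc and paths$data are required")
  tree0 <- read_swc(cfg$paths$swc)
  data0 <- read_measurements(cfg$paths$data, tree0$n)
  outdir <- cfg$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(leave_out))
    data0 <- scan_data(data0$bin[!data0$site %in% leave_out],
                       data0$site[!data0$site %in% leave_out],
                       data0$value[!data0$site %in% leave_out],
                       n_bins = attr(data0, "n_bins"), n_sites = tree0$n)
  if (!is.null(subsample_factor) && subsample_factor > 1L) {
    keep <- data0$bin %% as.integer(subsample_factor) == 1L
    data0 <- scan_data(data0$bin[keep], data0$site[keep], data0$value[keep],
                       n_bins = attr(data0, "n_bins"), n_sites = tree0$n)
  }

  tree <- prune_tree(tree0, unique(data0$site))
  imap <- attr(tree, "index_map")
  data <- scan_data(data0$bin, imap[data0$site], data0$value,
                    n_bins = attr(data0, "n_bins"), n_sites = tree$n)

  cal <- estimate_parameters(data, tree, delta = cfg$model$delta,
                             t_pre = cfg$estimation$t_pre,
                             filter_width = cfg$estimation$filter_width,
                             stim_window = cfg$protocol$stim_window,
                             tol = cfg$estimation$tol,
                             s_init = cfg$estimation$s_init)
  fit <- calcium_smooth(cal$data_norm, cal$basis, cal$model,
                        control = smooth_control(
                          gap_tol = cfg$optimizer$gap_tol,
                          newton_tol = cfg$optimizer$newton_tol))
  events <- detect_events(fit)

  utils::write.csv(events, file.path(outdir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$field), file.path(outdir, "field.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$a), file.path(outdir, "weights.csv"),
                   row.names = FALSE)
  if (!is.null(leave_out)) {
    kept <- leave_out[!is.na(imap[leave_out])]
    cv <- as.data.frame(fit$field[, imap[kept], drop = FALSE])
    names(cv) <- as.character(kept)
    utils::write.csv(cv, file.path(outdir, "crossval_field.csv"),
                     row.names = FALSE)
  }
  report <- list(alpha = cal$alpha, tau = cal$tau,
                 sigma_median = stats::median(cal$sigma),
                 spline_spacing = cal$selection$spacing,
                 spline_rel_error = cal$selection$rel_error,
                 objective = fit$objective, converged = fit$converged,
                 n_events = nrow(events),
                 barrier_path = fit$barrier_path)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  save_config(cfg, file.path(outdir, "config.yaml"))
  structure(list(fit = fit, calibration = cal, events = events,
                 tree = tree, outdir = outdir),
            class = "smooth_run")
}

#' @export
print.smooth_run <- function(x, ...) {
  cat("dendrosmooth run ->", x$outdir, "\n")
  print(x$fit)
  invisible(x)
}
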
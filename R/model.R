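#' Generative model parameters
#'
#' Bundles the parameters of the state-space model for calcium-bound
#' indicator dynamics: temporal discretization, indicator unbinding decay,
#' per-compartment baseline fluorescence, measurement noise, and the
#' exponential innovation prior (per-state amplitude times a possibly
#' time-varying event rate).
#'
#' The hidden weights decay as `a_t = alpha * a_{t-1} + u_t` with
#' `alpha = 1 - delta / tau`, `u_t >= 0`.  Raw intensity at compartment x is
#' `F_b[x] * (1 + gain * field[x])` and the prior on innovation `u_{t,i}`
#' is exponential with mean `amp[i] * delta * rate[t]`.
#'
#' @param delta time-bin width (s).
#' @param tau indicator unbinding time constant (s); must exceed `delta`.
#' @param baseline per-compartment baseline fluorescence `F_b` (raw
#'   intensity units), strictly positive; recycled to length N as needed.
#' @param gain global proportionality between the relative bound-indicator
#'   concentration and relative fluorescence change; the signal is only
#'   identified up to an affine transformation, so the default is 1.
#' @param noise a noise model from [gaussian_noise()] or [pmt_noise()].
#' @param amp per-state prior transient amplitude `A_i` (delta F/F units);
#'   scalar or length-d vector.
#' @param rate expected event rate per second: scalar, length-T vector, or
#'   a function of time in seconds (see [rate_schedule()]).
#' @return object of class `calcium_model`.
#' @export
calcium_model <- function(delta, tau, baseline = 1, gain = 1,
                          noise = gaussian_noise(0.1), amp = 1, rate = 1) {
  stopifnot(delta > 0, tau > 0)
  if (delta >= tau) stop("delta must be smaller than tau (need 0 < alpha < 1)")
  if (any(baseline <= 0)) stop("baseline fluorescence must be positive")
  if (any(amp <= 0)) stop("prior amplitudes must be positive")
  if (gain <= 0) stop("gain must be positive")
  if (!inherits(noise, "noise_model")) stop("noise must be a noise model")
  structure(list(delta = delta, tau = tau, alpha = 1 - delta / tau,
                 baseline = baseline, gain = gain, noise = noise,
                 amp = amp, rate = rate),
            class = "calcium_model")
}

#' @export
print.calcium_model <- function(x, ...) {
  cat("Calcium state-space model\n")
  cat(sprintf("  bin width delta = %g s, tau = %g s, decay alpha = %.6g\n",
              x$delta, x$tau, x$alpha))
  cat("  noise:", x$noise$type,
      if (x$noise$type == "gaussian") sprintf("(sd %s)",
        paste(format(unique(x$noise$sd), digits = 3), collapse = "/"))
      else sprintf("(slope %g, scale %g)", x$noise$slope, x$noise$scale), "\n")
  cat("  prior amplitude:", paste(format(range(x$amp), digits = 3),
                                  collapse = " .. "), "dF/F\n")
  invisible(x)
}

#' Measurement noise models
#'
#' `gaussian_noise(sd)` is additive Gaussian noise with a global or per-site
#' standard deviation (raw intensity units when applied to raw intensities).
#'
#' `pmt_noise(slope, scale)` models photomultiplier-tube output as a gamma
#' distribution whose shape grows linearly with the incident intensity:
#' `y ~ Gamma(shape = slope * I, scale = scale)`, so the mean is
#' proportional to `I` and the skewness `2 / sqrt(slope * I)` shrinks with
#' intensity — exponential-like at low light, near-Gaussian at high light.
#'
#' @param sd standard deviation (scalar or per-site vector).
#' @param slope gamma shape per unit intensity.
#' @param scale gamma scale.
#' @return object of class `noise_model`.
#' @export
gaussian_noise <- function(sd) {
  stopifnot(all(sd >= 0))
  structure(list(type = "gaussian", sd = sd), class = "noise_model")
}

#' @rdname gaussian_noise
#' @export
pmt_noise <- function(slope, scale = 1) {
  stopifnot(slope > 0, scale > 0)
  structure(list(type = "gamma_pmt", slope = slope, scale = scale),
            class = "noise_model")
}

rate_at_bins <- function(rate, n_bins, delta) {
  if (is.function(rate)) {
    r <- rate((seq_len(n_bins) - 1) * delta)
  } else if (length(rate) == 1L) {
    r <- rep(rate, n_bins)
  } else {
    if (length(rate) != n_bins) stop("rate vector must have length T")
    r <- rate
  }
  if (any(r < 0)) stop("rate must be nonnegative")
  r
}

#' Simulate hidden-weight trajectories
#'
#' Runs the discrete dynamics `a_t = alpha a_{t-1} + u_t`, `a_0 = 0`, either
#' with deterministic events (a list of bins and nonnegative amplitude
#' vectors; the trajectory is then an exact superposition of decaying
#' exponentials) or with random innovations: per bin and state an event
#' occurs with probability `rate[t] * delta` and its amplitude is
#' exponential with mean `amp[i]`.
#'
#' @param model a [calcium_model()].
#' @param n_bins number of time bins T.
#' @param d number of hidden states.
#' @param events optional data.frame with column `bin` plus either a column
#'   `amplitude` (applied to all states) or columns `a1..ad` — or a list of
#'   `list(bin =, amplitude = <length-d vector>)`.  When `NULL`, innovations
#'   are drawn from the rate-modulated prior.
#' @param seed optional RNG seed.
#' @return object of class `state_trajectory`: list with `a` (T x d),
#'   `u` (T x d), `alpha`.
#' @export
simulate_states <- function(model, n_bins, d, events = NULL, seed = NULL) {
  stopifnot(inherits(model, "calcium_model"), n_bins >= 1, d >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(0, n_bins, d)
  if (!is.null(events)) {
    ev <- normalize_events(events, d)
    for (e in ev) {
      if (e$bin < 1 || e$bin > n_bins) stop("event bin out of range")
      if (any(e$amplitude < 0)) stop("event amplitudes must be nonnegative")
      u[e$bin, ] <- u[e$bin, ] + e$amplitude
    }
  } else {
    r <- rate_at_bins(model$rate, n_bins, model$delta)
    p <- pmin(1, r * model$delta)
    amp <- rep_len(model$amp, d)
    hit <- matrix(stats::runif(n_bins * d), n_bins, d) < p
    sz <- matrix(stats::rexp(n_bins * d), n_bins, d) *
      matrix(amp, n_bins, d, byrow = TRUE)
    u <- hit * sz
  }
  state_trajectory(u, model$alpha)
}

state_trajectory <- function(u, alpha) {
  a <- apply(u, 2L, function(col) stats::filter(col, alpha,
                                                method = "recursive"))
  a <- matrix(as.numeric(a), nrow(u), ncol(u))
  structure(list(a = a, u = u, alpha = alpha), class = "state_trajectory")
}

normalize_events <- function(events, d) {
  if (is.data.frame(events)) {
    lapply(seq_len(nrow(events)), function(i) {
      amp <- if ("amplitude" %in% names(events)) {
        rep_len(events$amplitude[i], d)
      } else {
        as.numeric(events[i, setdiff(names(events), "bin")])
      }
      list(bin = as.integer(events$bin[i]), amplitude = amp)
    })
  } else {
    lapply(events, function(e)
      list(bin = as.integer(e$bin), amplitude = rep_len(e$amplitude, d)))
  }
}

#' Render raw fluorescence intensities from a field
#'
#' `I[t, x] = baseline[x] * (1 + gain * field[t, x])`: the affine map from
#' relative bound-indicator concentration to emitted light.
#'
#' @param field T x N matrix (or length-N vector) of nonnegative relative
#'   concentrations, typically [evaluate_field()] output.
#' @param model a [calcium_model()]; `baseline` is recycled to N columns.
#' @return matrix (or vector) of strictly positive intensities.
#' @export
render_fluorescence <- function(field, model) {
  stopifnot(inherits(model, "calcium_model"))
  if (any(model$baseline <= 0)) stop("baseline must be positive")
  if (is.matrix(field)) {
    fb <- rep_len(model$baseline, ncol(field))
    sweep(1 + model$gain * field, 2L, fb, "*")
  } else {
    fb <- rep_len(model$baseline, length(field))
    fb * (1 + model$gain * field)
  }
}

#' Scan data: sparse per-bin measurements
#'
#' A long-format container for random-access scan measurements: one row per
#' sample with the time bin, the imaged compartment and the value.  The
#' number of samples per bin may vary (including zero).
#'
#' @param bin integer vector of time bins (1-based).
#' @param site integer vector of compartment indices.
#' @param value numeric measurement values.
#' @param n_bins total number of bins T (defaults to `max(bin)`).
#' @param n_sites number of compartments N (defaults to `max(site)`).
#' @param normalized logical: are values delta F / F (TRUE) or raw (FALSE)?
#' @return object of class `scan_data` (a data.frame with attributes).
#' @export
scan_data <- function(bin, site, value, n_bins = max(bin),
                      n_sites = max(site), normalized = FALSE) {
  bin <- as.integer(bin); site <- as.integer(site)
  stopifnot(length(bin) == length(site), length(site) == length(value))
  if (any(bin < 1L | bin > n_bins)) stop("bin out of range")
  if (any(site < 1L | site > n_sites)) stop("site out of range")
  structure(data.frame(bin = bin, site = site, value = as.numeric(value)),
            n_bins = as.integer(n_bins), n_sites = as.integer(n_sites),
            normalized = isTRUE(normalized),
            class = c("scan_data", "data.frame"))
}

#' @export
print.scan_data <- function(x, ...) {
  cat(sprintf("Scan data: %d samples, %d bins, %d of %d compartments imaged%s\n",
              nrow(x), attr(x, "n_bins"), length(unique(x$site)),
              attr(x, "n_sites"),
              if (attr(x, "normalized")) " (dF/F normalized)" else " (raw)"))
  invisible(x)
}

#' Sample noisy measurements from rendered intensities
#'
#' @param intensity T x N matrix of raw intensities.
#' @param schedule list of length T of integer site vectors (which
#'   compartments are imaged at each bin; may be empty).
#' @param model a [calcium_model()]; its `noise` component is used.
#' @param seed optional RNG seed.
#' @return a raw [scan_data()].
#' @export
sample_measurements <- function(intensity, schedule, model, seed = NULL) {
  stopifnot(inherits(model, "calcium_model"), is.list(schedule),
            length(schedule) == nrow(intensity))
  if (!is.null(seed)) set.seed(seed)
  n_bins <- nrow(intensity); n_sites <- ncol(intensity)
  bins <- rep.int(seq_len(n_bins), lengths(schedule))
  sites <- as.integer(unlist(schedule, use.names = FALSE))
  if (length(sites) && (min(sites) < 1L || max(sites) > n_sites))
    stop("schedule site out of range")
  mu <- intensity[cbind(bins, sites)]
  noise <- model$noise
  val <- if (noise$type == "gaussian") {
    sd <- rep_len(noise$sd, n_sites)[sites]
    mu + stats::rnorm(length(mu), 0, sd)
  } else {
    if (any(mu <= 0)) stop("gamma PMT noise requires positive intensities")
    stats::rgamma(length(mu), shape = noise$slope * mu, scale = noise$scale)
  }
  scan_data(bins, sites, val, n_bins = n_bins, n_sites = n_sites)
}

#' delta F / F normalization
#'
#' `(y - F_b) / F_b` per sample, the standard relative-fluorescence
#' transform; `dff_denormalize()` is the exact inverse.  For PMT (gamma)
#' data the raw values are first divided by the mean PMT gain
#' `slope * scale` so that the expected normalized value is the relative
#' concentration change.
#'
#' @param data a raw [scan_data()] or numeric vector.
#' @param baseline per-compartment baseline `F_b` (recycled to N).
#' @param site compartment indices when `data` is a bare vector.
#' @param pmt_gain optional mean PMT gain (`slope * scale`) dividing raw
#'   values before normalization; default 1.
#' @return normalized [scan_data()] (or numeric vector).
#' @export
dff_normalize <- function(data, baseline, site = NULL, pmt_gain = 1) {
  if (any(baseline <= 0)) stop("baseline must be strictly positive")
  if (inherits(data, "scan_data")) {
    if (attr(data, "normalized")) stop("data is already normalized")
    fb <- rep_len(baseline, attr(data, "n_sites"))[data$site]
    out <- scan_data(data$bin, data$site, (data$value / pmt_gain - fb) / fb,
                     n_bins = attr(data, "n_bins"),
                     n_sites = attr(data, "n_sites"), normalized = TRUE)
    out
  } else {
    fb <- if (is.null(site)) rep_len(baseline, length(data))
          else rep_len(baseline, max(site))[site]
    (data / pmt_gain - fb) / fb
  }
}

#' @rdname dff_normalize
#' @export
dff_denormalize <- function(data, baseline, site = NULL, pmt_gain = 1) {
  if (any(baseline <= 0)) stop("baseline must be strictly positive")
  if (inherits(data, "scan_data")) {
    if (!attr(data, "normalized")) stop("data is not normalized")
    fb <- rep_len(baseline, attr(data, "n_sites"))[data$site]
    scan_data(data$bin, data$site, (data$value * fb + fb) * pmt_gain,
              n_bins = attr(data, "n_bins"), n_sites = attr(data, "n_sites"),
              normalized = FALSE)
  } else {
    fb <- if (is.null(site)) rep_len(baseline, length(data))
          else rep_len(baseline, max(site))[site]
    (data * fb + fb) * pmt_gain
  }
}

#' Simulate a full random-access imaging experiment
#'
#' Emulates the bench protocol: a train of backpropagating action
#' potentials sweeps the tree instantaneously and unselectively, with
#' per-state transient amplitude decaying exponentially with the
#' topological distance of the state's center from the soma
#' (`A0 * exp(-dist / length_const)`).  Optional EPSP events add localized
#' amplitude only to states whose centers lie within `epsp_radius` hops of
#' the stimulated compartment.  At every bin `sites_per_bin` compartments
#' are drawn uniformly without replacement and imaged under the model's
#' noise.
#'
#' @param tree a [dendrite_tree()].
#' @param basis a [tree_basis()] on that tree.
#' @param model a [calcium_model()].
#' @param protocol list with elements `n_bins`; `bap_times` (s, possibly
#'   empty); `amp_soma` (`A0`, delta F/F at the soma); `length_const` (um);
#'   optional `epsp_times` (s), `epsp_sites`, `epsp_amp`, `epsp_radius`
#'   (hops, default `2 * spacing`); `sites_per_bin`.
#' @param seed optional RNG seed.
#' @return list of class `calcium_experiment` with `truth` (the
#'   `state_trajectory`, the T x N `field`, per-state `bap_amplitude`,
#'   `bap_bins`), `data` (raw [scan_data()]), `schedule`, plus the inputs.
#' @export
simulate_experiment <- function(tree, basis, model, protocol, seed = NULL) {
  stopifnot(inherits(tree, "dendrite_tree"), inherits(basis, "tree_basis"),
            inherits(model, "calcium_model"))
  if (!is.null(seed)) set.seed(seed)
  p <- protocol
  n_bins <- as.integer(p$n_bins)
  m <- as.integer(p$sites_per_bin)
  if (m > tree$n) stop("sites_per_bin exceeds the number of compartments")
  t_end <- n_bins * model$delta
  if (length(p$bap_times) && any(p$bap_times < 0 | p$bap_times >= t_end))
    stop("bap_times outside the recording window")

  dist_c <- tree$topo_distance[basis$centers]
  bap_amp <- p$amp_soma * exp(-dist_c / p$length_const)
  bap_bins <- time_to_bin(p$bap_times, model$delta)
  events <- lapply(bap_bins, function(b) list(bin = b, amplitude = bap_amp))

  if (!is.null(p$epsp_times)) {
    radius <- if (is.null(p$epsp_radius)) 2L * basis$spacing else p$epsp_radius
    eamp <- if (is.null(p$epsp_amp)) p$amp_soma else p$epsp_amp
    ebins <- time_to_bin(p$epsp_times, model$delta)
    for (k in seq_along(ebins)) {
      site <- p$epsp_sites[[min(k, length(p$epsp_sites))]]
      h <- hop_distances(tree, site, max_hops = radius)
      near <- is.finite(h[basis$centers])
      amp <- ifelse(near, eamp, 0)
      events[[length(events) + 1L]] <- list(bin = ebins[k], amplitude = amp)
    }
  }

  truth <- simulate_states(model, n_bins, basis$d, events = events)
  field <- evaluate_field(basis, truth$a)
  intensity <- render_fluorescence(field, model)
  schedule <- replicate(n_bins, sample.int(tree$n, m), simplify = FALSE)
  data <- sample_measurements(intensity, schedule, model)

  structure(list(truth = list(trajectory = truth, field = field,
                              bap_amplitude = bap_amp, bap_bins = bap_bins),
                 data = data, schedule = schedule, tree = tree,
                 basis = basis, model = model, protocol = p),
            class = "calcium_experiment")
}

time_to_bin <- function(t, delta) as.integer(floor(t / delta)) + 1L

#' @export
print.calcium_experiment <- function(x, ...) {
  cat("Simulated random-access imaging experiment\n")
  cat("  ", attr(x$data, "n_bins"), "bins x", x$tree$n, "compartments;",
      length(x$truth$bap_bins), "bAP(s) at bin(s)",
      paste(x$truth$bap_bins, collapse = ", "), "\n")
  print(x$data)
  invisible(x)
}
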
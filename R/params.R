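#' Per-site baseline fluorescence estimate
#'
#' Arithmetic mean of the raw measurements over the quiet pre-stimulation
#' window — the maximum-likelihood baseline under both Gaussian and gamma
#' measurement noise.
#'
#' @param data a raw [scan_data()].
#' @param t_pre end of the baseline window (s from recording start).
#' @param delta bin width (s).
#' @return named numeric vector of baselines, one entry per imaged site
#'   (names are compartment indices).
#' @export
estimate_baseline <- function(data, t_pre, delta) {
  stopifnot(inherits(data, "scan_data"))
  n_pre <- max(1L, floor(t_pre / delta))
  imaged <- sort(unique(data$site))
  pre <- data[data$bin <= n_pre, , drop = FALSE]
  missing <- setdiff(imaged, unique(pre$site))
  if (length(missing))
    stop("no pre-window samples for imaged site(s): ",
         paste(missing, collapse = ", "))
  means <- tapply(pre$value, factor(pre$site, levels = imaged), mean)
  stats::setNames(as.numeric(means), imaged)
}

#' Low-pass moving-average filter
#'
#' Centered box filter of width `round(width / delta)` bins (forced odd);
#' at the edges the window shrinks to the available samples.  `NA` entries
#' (unobserved bins) are ignored inside the window; an all-`NA` window
#' yields `NA`.
#'
#' @param trace numeric vector (one value per bin, `NA` where unobserved).
#' @param width filter width (s).
#' @param delta bin width (s).
#' @return filtered numeric vector of the same length.
#' @export
lowpass_filter <- function(trace, width, delta) {
  if (!length(trace)) stop("empty trace")
  if (width < delta) stop("filter width must be at least one bin")
  w <- round(width / delta)
  if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) %/% 2
  n <- length(trace)
  out <- numeric(n)
  for (t in seq_len(n)) {
    win <- trace[max(1, t - half):min(n, t + half)]
    out[t] <- mean(win, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Per-site time-bin traces from scan data
#'
#' Pivots long-format scan data into a T x n_sites matrix, averaging
#' duplicate samples within a bin and leaving `NA` where a site was not
#' imaged.
#'
#' @param data a [scan_data()].
#' @param sites which sites (default: all imaged sites, sorted).
#' @return T x length(sites) matrix with sites as column names.
#' @export
site_traces <- function(data, sites = sort(unique(data$site))) {
  stopifnot(inherits(data, "scan_data"))
  n_bins <- attr(data, "n_bins")
  out <- matrix(NA_real_, n_bins, length(sites),
                dimnames = list(NULL, sites))
  keep <- data$site %in% sites
  if (any(keep)) {
    key <- paste(data$bin[keep], data$site[keep])
    agg <- tapply(data$value[keep], key, mean)
    parts <- strsplit(names(agg), " ", fixed = TRUE)
    b <- as.integer(vapply(parts, `[[`, "", 1L))
    s <- match(vapply(parts, `[[`, "", 2L), as.character(sites))
    out[cbind(b, s)] <- as.numeric(agg)
  }
  out
}

#' AR(1) estimate of the indicator decay constant
#'
#' Pools all sites: with `z` the filtered, baseline-subtracted traces,
#' `alpha_hat = sum(z_t z_{t-1}) / sum(z_{t-1}^2)` over all sites and bins
#' after `t_start` (chosen shortly after the last evoked event, so the
#' traces are pure decays), and `tau_hat = delta / (1 - alpha_hat)`.
#'
#' @param traces T x S matrix of filtered traces (columns = sites, `NA`
#'   allowed for unobserved bins).
#' @param baseline per-site baseline to subtract (0 for delta F/F traces);
#'   scalar or length-S.
#' @param t_start start of the decay-only window (s).
#' @param delta bin width (s).
#' @param groups optional per-site grouping factor (e.g. subtree labels);
#'   when given, one estimate per group is returned alongside the pooled
#'   one.
#' @return list with `alpha`, `tau`, and (if grouped) `by_group`.  A
#'   warning is raised if `alpha` falls outside (0, 1).
#' @export
estimate_time_constant <- function(traces, baseline = 0, t_start, delta,
                                   groups = NULL) {
  traces <- as.matrix(traces)
  z <- sweep(traces, 2L, rep_len(baseline, ncol(traces)), "-")
  t0 <- max(1L, floor(t_start / delta) + 1L)
  if (t0 + 1L > nrow(z)) stop("fewer than 2 samples after t_start")
  fit1 <- function(cols) {
    zz <- z[t0:nrow(z), cols, drop = FALSE]
    num <- den <- 0
    for (j in seq_len(ncol(zz))) {
      v <- zz[, j]
      ok <- which(!is.na(v[-length(v)]) & !is.na(v[-1L]))
      num <- num + sum(v[ok] * v[ok + 1L])
      den <- den + sum(v[ok]^2)
    }
    if (den == 0) stop("all-zero traces: decay constant is unidentifiable")
    num / den
  }
  alpha <- fit1(seq_len(ncol(z)))
  if (alpha <= 0 || alpha >= 1)
    warning(sprintf("estimated alpha = %.4g outside (0, 1)", alpha))
  out <- list(alpha = alpha,
              tau = if (alpha < 1) delta / (1 - alpha) else Inf)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    out$by_group <- vapply(levels(groups),
                           function(g) fit1(which(groups == g)), 0)
  }
  out
}

#' Crude per-site transient amplitudes
#'
#' The maximum increase of the filtered delta F/F trace over the window
#' following the first evoked event, relative to its value just before the
#' event; floored at zero.
#'
#' @param traces T x S matrix of filtered delta F/F traces.
#' @param first_bap_time time of the first event (s).
#' @param window length of the search window after the event (s).
#' @param delta bin width (s).
#' @return length-S nonnegative vector of amplitude estimates.
#' @export
transient_amplitudes <- function(traces, first_bap_time, window, delta) {
  traces <- as.matrix(traces)
  b0 <- time_to_bin(first_bap_time, delta)
  b1 <- min(nrow(traces), time_to_bin(first_bap_time + window, delta))
  if (b1 <= b0) stop("empty amplitude search window")
  pre_bin <- max(1L, b0 - 1L)
  vapply(seq_len(ncol(traces)), function(j) {
    pre <- traces[pre_bin, j]
    if (is.na(pre)) pre <- mean(traces[max(1L, b0 - 5L):pre_bin, j],
                                na.rm = TRUE)
    peak <- suppressWarnings(max(traces[b0:b1, j], na.rm = TRUE))
    if (!is.finite(peak) || !is.finite(pre)) return(0)
    max(0, peak - pre)
  }, 0)
}

#' Adaptive spline-spacing selection with a nonnegative amplitude prior
#'
#' Starting from a coarse center spacing `s_init`, builds the tree basis at
#' each candidate spacing and solves the nonnegative least-squares problem
#' `min_{lambda >= 0} || B[sites, ] lambda - amp ||^2`, stopping at the
#' largest spacing whose Euclidean relative error is at most `tol` (or at
#' spacing 1).  The chosen `lambda` doubles as the per-state prior
#' transient amplitude.
#'
#' @param tree a [dendrite_tree()].
#' @param amp per-site crude transient amplitudes (nonnegative,
#'   delta F/F), aligned with `sites`.
#' @param sites imaged compartment indices.
#' @param tol relative-error stopping threshold (default 0.1).
#' @param s_init initial (largest) spacing to try.
#' @param form bump shape passed to [tree_basis()].
#' @return object of class `basis_selection`: list with `spacing`, `basis`
#'   (the selected [tree_basis()]), `amp_prior` (length-d, >= 0),
#'   `rel_error`, and `search` (data.frame of spacing vs error over the
#'   trajectory tried).
#' @export
select_basis_spacing <- function(tree, amp, sites, tol = 0.1, s_init,
                                 form = "bspline") {
  stopifnot(inherits(tree, "dendrite_tree"), length(amp) == length(sites),
            s_init >= 1)
  if (any(amp < 0)) stop("amplitudes must be nonnegative")
  nrm <- sqrt(sum(amp^2))
  if (nrm == 0) stop("all amplitude estimates are zero")
  search <- list()
  for (s in seq(as.integer(s_init), 1L)) {
    basis <- suppressWarnings(tree_basis(tree, s, form = form))
    Bs <- basis$B[sites, , drop = FALSE]
    fit <- nnls_fit(Bs, amp)
    rel <- sqrt(sum((Bs %*% fit - amp)^2)) / nrm
    search[[length(search) + 1L]] <- data.frame(spacing = s, d = basis$d,
                                                rel_error = rel)
    if (rel <= tol || s == 1L) {
      return(structure(list(spacing = s, basis = basis, amp_prior = fit,
                            rel_error = rel,
                            search = do.call(rbind, search)),
                       class = "basis_selection"))
    }
  }
}

# Nonnegative least squares; minimum-norm tie-break via a vanishing ridge
# when the design is column-rank-deficient.
nnls_fit <- function(A, b) {
  A <- as.matrix(A)
  fit <- tryCatch(pracma::lsqnonneg(A, as.numeric(b)),
                  error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$x))) {
    eps <- 1e-8 * max(abs(A))
    Aa <- rbind(A, diag(eps, ncol(A)))
    fit <- pracma::lsqnonneg(Aa, c(as.numeric(b), numeric(ncol(A))))
    if (any(!is.finite(fit$x)))
      stop("nonnegative least squares failed to converge")
  }
  as.numeric(fit$x)
}

#' @export
print.basis_selection <- function(x, ...) {
  cat(sprintf(paste0("Spline spacing selection: spacing %d (%d states), ",
                     "relative fit error %.4f\n"),
              x$spacing, x$basis$d, x$rel_error))
  invisible(x)
}

#' Time-varying event-rate schedule
#'
#' Piecewise rate in expected events per second: `r_low` before the
#' stimulation window, `r_high` inside `[t_on, t_off]`, and a smooth
#' exponential relaxation `r_low + (r_high - r_low) exp(-(t - t_off) /
#' decay_tau)` afterwards.  The schedule is continuous at the window end;
#' an abrupt drop there would make the prior infer a spurious event at the
#' discontinuity.
#'
#' @param n_bins number of bins T.
#' @param delta bin width (s).
#' @param t_on,t_off stimulation window (s), `0 <= t_on < t_off <= T*delta`.
#' @param r_high rate inside the window (default 10 events/s — e.g. ten
#'   evoked spikes in a one-second window).
#' @param r_low resting rate; must be positive so prior mass never
#'   vanishes.
#' @param decay_tau relaxation time constant after the window (s).
#' @return length-T positive vector (rate at each bin start).
#' @export
rate_schedule <- function(n_bins, delta, t_on, t_off, r_high = 10,
                          r_low = 0.01, decay_tau = 0.2) {
  if (r_low <= 0) stop("r_low must be positive")
  stopifnot(t_on >= 0, t_on < t_off, t_off <= n_bins * delta + 1e-12)
  t <- (seq_len(n_bins) - 1) * delta
  r <- rep(r_low, n_bins)
  r[t >= t_on & t <= t_off] <- r_high
  after <- t > t_off
  r[after] <- r_low + (r_high - r_low) * exp(-(t[after] - t_off) / decay_tau)
  r
}

#' Per-site measurement noise standard deviation
#'
#' Subtracts the low-pass filtered trace from the normalized data and takes
#' the standard deviation of the residual at each site, with the residual
#' mean fixed at zero (the filter already removes the mean).  Because the
#' filter was computed from the same samples, the residual of white noise
#' under a width-w moving average has variance `sigma^2 (w - 1) / w`; when
#' `ma_window` is supplied the estimate is rescaled by `sqrt(w / (w - 1))`
#' to undo this attenuation.
#'
#' @param data a normalized [scan_data()].
#' @param filtered T x S matrix of filtered traces with sites as column
#'   names (from [site_traces()] + [lowpass_filter()]).
#' @param bins optional subset of time bins to use (e.g. a quiet
#'   pre-stimulation window, where the trace is flat and the residual is
#'   pure measurement noise).
#' @param ma_window odd moving-average window length (bins) used to build
#'   `filtered`, enabling the attenuation correction; `NULL` for none.
#' @return named numeric vector of per-site sigma estimates.
#' @export
estimate_noise_sd <- function(data, filtered, bins = NULL,
                              ma_window = NULL) {
  stopifnot(inherits(data, "scan_data"))
  sites <- as.integer(colnames(filtered))
  corr <- if (is.null(ma_window)) 1 else sqrt(ma_window / (ma_window - 1))
  out <- stats::setNames(numeric(length(sites)), sites)
  for (j in seq_along(sites)) {
    rows <- data$site == sites[j]
    if (!is.null(bins)) rows <- rows & data$bin %in% bins
    res <- data$value[rows] - filtered[data$bin[rows], j]
    res <- res[!is.na(res)]
    if (length(res) < 2L)
      stop("fewer than 2 residual samples at site ", sites[j])
    out[j] <- corr * sqrt(mean(res^2))
  }
  out
}

#' Full data-driven calibration pipeline
#'
#' Runs the whole parameter-estimation chain on raw scan data: baseline
#' (pre-window mean), delta F/F normalization, low-pass filtering, AR(1)
#' decay constant, crude transient amplitudes, adaptive spline-spacing
#' selection with the nonnegative amplitude prior, per-site noise sigma,
#' and the time-varying rate schedule.
#'
#' @param data a raw [scan_data()].
#' @param tree the (pruned) [dendrite_tree()] the sites live on.
#' @param delta bin width (s).
#' @param t_pre baseline window length (s; default 0.4).
#' @param filter_width low-pass filter width (s; default 0.05).
#' @param stim_window `c(t_on, t_off)` stimulation window (s).
#' @param first_bap_time time of the first evoked event (s; default
#'   `stim_window[1]`).
#' @param amp_window search window for transient amplitudes (s; default
#'   0.1).
#' @param tol,s_init spline-selection stopping tolerance and initial
#'   spacing (see [select_basis_spacing()]).
#' @param r_high,r_low,decay_tau rate-schedule parameters.
#' @return object of class `calcium_calibration`: list with `baseline`
#'   (per imaged site), `alpha`, `tau`, `sigma` (per site), `amp_hat`
#'   (crude per-site amplitudes), `selection` (the [select_basis_spacing()]
#'   result), `basis`, `rate`, `model` (a ready [calcium_model()] whose
#'   baseline is filled at imaged sites and interpolated elsewhere from the
#'   site median), and `data_norm` (the normalized data).
#' @export
estimate_parameters <- function(data, tree, delta, t_pre = 0.4,
                                filter_width = 0.05, stim_window,
                                first_bap_time = stim_window[1],
                                amp_window = 0.1, tol = 0.1, s_init = 8L,
                                r_high = 10, r_low = 0.01, decay_tau = 0.2) {
  stopifnot(inherits(data, "scan_data"), inherits(tree, "dendrite_tree"))
  n_bins <- attr(data, "n_bins")
  sites <- sort(unique(data$site))

  fb <- estimate_baseline(data, t_pre, delta)
  fb_full <- rep(stats::median(fb), tree$n)
  fb_full[sites] <- fb
  data_norm <- dff_normalize(data, fb_full)

  traces <- site_traces(data_norm, sites)
  filtered <- apply(traces, 2L, lowpass_filter, width = filter_width,
                    delta = delta)
  colnames(filtered) <- colnames(traces)

  tc <- estimate_time_constant(filtered, baseline = 0,
                               t_start = stim_window[2], delta = delta)
  amp_hat <- transient_amplitudes(filtered, first_bap_time, amp_window,
                                  delta)
  sel <- select_basis_spacing(tree, amp_hat, sites, tol = tol,
                              s_init = s_init)
  w <- round(filter_width / delta); if (w %% 2 == 0) w <- w + 1
  quiet <- seq_len(max(2L, floor(stim_window[1] / delta)))
  enough <- all(vapply(sites, function(s)
    sum(data$site == s & data$bin %in% quiet) >= 2L, TRUE))
  # isolated samples leave a zero residual (the filter reproduces them);
  # widen the noise-estimation window until residuals carry information,
  # then fill any remaining degenerate site with the median of the rest
  w_noise <- w
  repeat {
    filt_noise <- if (w_noise == w) filtered else {
      fn <- apply(traces, 2L, lowpass_filter, width = w_noise * delta,
                  delta = delta)
      colnames(fn) <- colnames(traces)
      fn
    }
    sigma <- estimate_noise_sd(data_norm, filt_noise,
                               bins = if (enough) quiet,
                               ma_window = if (w_noise > 1) w_noise)
    if (any(sigma > 0) || w_noise > n_bins) break
    w_noise <- 2L * w_noise + 1L
  }
  if (!any(sigma > 0)) stop("noise sigma unidentifiable: no residuals")
  if (any(sigma <= 0))
    sigma[sigma <= 0] <- stats::median(sigma[sigma > 0])
  sigma_full <- rep(stats::median(sigma), tree$n)
  sigma_full[sites] <- sigma
  rate <- rate_schedule(n_bins, delta, stim_window[1], stim_window[2],
                        r_high = r_high, r_low = r_low,
                        decay_tau = decay_tau)
  amp_prior <- pmax(sel$amp_prior, 1e-3 * max(sel$amp_prior, 1e-6))
  model <- calcium_model(delta = delta, tau = max(tc$tau, 2 * delta),
                         baseline = fb_full,
                         noise = gaussian_noise(sigma_full),
                         amp = amp_prior, rate = rate)
  structure(list(baseline = fb, alpha = tc$alpha, tau = tc$tau,
                 sigma = sigma, amp_hat = amp_hat, selection = sel,
                 basis = sel$basis, rate = rate, model = model,
                 data_norm = data_norm, sites = sites),
            class = "calcium_calibration")
}

#' @export
print.calcium_calibration <- function(x, ...) {
  cat("Calcium model calibration\n")
  cat(sprintf("  alpha = %.4f (tau = %.3g s)\n", x$alpha, x$tau))
  cat(sprintf("  baseline: %d sites, median %.3g\n", length(x$baseline),
              stats::median(x$baseline)))
  cat(sprintf("  noise sigma: median %.3g dF/F\n", stats::median(x$sigma)))
  print(x$selection)
  invisible(x)
}
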
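# S3 methods for calcium_map fits.

#' @export
print.calcium_map <- function(x, ...) {
  ev <- detect_events(x)
  cat("Spatiotemporal calcium MAP smooth\n")
  cat(sprintf("  %d bins x %d hidden states on %d compartments\n",
              nrow(x$a), ncol(x$a), ncol(x$field)))
  cat(sprintf("  objective (neg log-posterior): %.6g; converged: %s\n",
              x$objective, x$converged))
  if (nrow(ev)) {
    cat("  events at bin(s):", paste(ev$bin, collapse = ", "), "\n")
  } else cat("  no events detected\n")
  invisible(x)
}

#' @export
summary.calcium_map <- function(object, ...) {
  ev <- detect_events(object)
  out <- list(n_bins = nrow(object$a), d = ncol(object$a),
              n_compartments = ncol(object$field),
              objective = object$objective, converged = object$converged,
              events = ev, barrier_path = object$barrier_path,
              min_u = min(object$u),
              likelihood = object$likelihood)
  class(out) <- "summary.calcium_map"
  out
}

#' @export
print.summary.calcium_map <- function(x, ...) {
  cat("Spatiotemporal calcium MAP smooth\n")
  cat(sprintf("  %d bins x %d hidden states on %d compartments (%s likelihood)\n",
              x$n_bins, x$d, x$n_compartments, x$likelihood))
  cat(sprintf("  objective %.6g, min innovation %.2e, converged %s\n",
              x$objective, x$min_u, x$converged))
  cat("  barrier path:\n")
  print(x$barrier_path, row.names = FALSE)
  if (nrow(x$events)) {
    cat("  events:\n")
    print(x$events, row.names = FALSE)
  } else cat("  no events detected\n")
  invisible(x)
}

#' Extract hidden weights from a fit
#'
#' @param object a [calcium_smooth()] fit.
#' @param what `"a"` (weights, default) or `"u"` (innovations).
#' @param ... ignored.
#' @return T x d matrix.
#' @export
coef.calcium_map <- function(object, what = c("a", "u"), ...) {
  object[[match.arg(what)]]
}

#' @export
fitted.calcium_map <- function(object, ...) object$field

#' Residuals of a calcium MAP fit
#'
#' Observed minus fitted delta F/F at every measured (bin, site) sample.
#'
#' @param object a [calcium_smooth()] fit.
#' @param ... ignored.
#' @return numeric vector aligned with the rows of the fitted data.
#' @export
residuals.calcium_map <- function(object, ...) {
  d <- object$data
  pred <- object$model$gain * object$field[cbind(d$bin, d$site)]
  d$value - pred
}

#' Predict the smoothed field at chosen compartments and bins
#'
#' @param object a [calcium_smooth()] fit.
#' @param compartments compartment indices (default all).
#' @param bins time bins (default all).
#' @param ... ignored.
#' @return matrix `length(bins)` x `length(compartments)`.
#' @export
predict.calcium_map <- function(object, compartments = NULL, bins = NULL,
                                ...) {
  if (is.null(compartments)) compartments <- seq_len(ncol(object$field))
  if (is.null(bins)) bins <- seq_len(nrow(object$field))
  object$field[bins, compartments, drop = FALSE]
}

#' Simulate replicate datasets from a fitted smooth
#'
#' Re-renders fluorescence from the fitted field and draws new measurement
#' noise on the original scan schedule — a parametric bootstrap of the
#' experiment.
#'
#' @param object a [calcium_smooth()] fit.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param ... ignored.
#' @return list of raw [scan_data()] objects (length `nsim`).
#' @export
simulate.calcium_map <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  schedule <- split(d$site, factor(d$bin, levels = seq_len(nrow(object$a))))
  schedule <- lapply(schedule, as.integer)
  intensity <- render_fluorescence(pmax(object$field, 0), object$model)
  replicate(nsim, sample_measurements(intensity, schedule, object$model),
            simplify = FALSE)
}

#' Plot inferred calcium traces
#'
#' Draws the inferred relative concentration at a few compartments over
#' time, with detected events marked, and overlays the measurements at
#' those compartments.
#'
#' @param x a [calcium_smooth()] fit.
#' @param compartments which compartments to draw (default: up to 5 spread
#'   over the tree).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.calcium_map <- function(x, compartments = NULL, ...) {
  N <- ncol(x$field)
  if (is.null(compartments))
    compartments <- unique(round(seq(1, N, length.out = min(5, N))))
  tt <- seq_len(nrow(x$field)) * x$model$delta
  graphics::matplot(tt, x$field[, compartments, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (s)",
                    ylab = expression(Delta * F / F), ...)
  d <- x$data
  keep <- d$site %in% compartments
  if (any(keep))
    graphics::points(d$bin[keep] * x$model$delta, d$value[keep], pch = ".",
                     col = "grey40")
  ev <- detect_events(x)
  if (nrow(ev)) graphics::abline(v = ev$bin * x$model$delta, lty = 3,
                                 col = "red")
  invisible(x)
}
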
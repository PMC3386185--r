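# MAP smoothing of hidden weights: negative log-posterior assembly,
# log-barrier interior-point loop, block-tridiagonal Newton direction,
# dense reference solver, known-spike-time MLE, event extraction.

# ---- problem assembly -------------------------------------------------

# Per-bin sufficient statistics for the Gaussian likelihood, and the
# exponential-prior coefficient matrix lambda[t, i] = 1 / (amp_i delta r_t).
map_prep <- function(data, basis, model, likelihood = "gaussian") {
  stopifnot(inherits(data, "scan_data"), inherits(basis, "tree_basis"),
            inherits(model, "calcium_model"))
  n_bins <- attr(data, "n_bins")
  n_sites <- attr(data, "n_sites")
  if (n_sites > basis$n) stop("data refers to more compartments than basis")
  d <- basis$d
  r <- rate_at_bins(model$rate, n_bins, model$delta)
  if (any(r <= 0)) stop("rate must be strictly positive for the prior")
  amp <- rep_len(model$amp, d)
  lambda <- 1 / (outer(r * model$delta, amp))

  rows_by_bin <- split(seq_len(nrow(data)), factor(data$bin,
                                                   levels = seq_len(n_bins)))
  if (likelihood == "gaussian") {
    if (!attr(data, "normalized"))
      stop("gaussian inference expects dF/F-normalized data")
    sigma <- rep_len(model$noise$sd, basis$n)
    if (any(sigma <= 0)) stop("sigma must be positive")
    w_site <- 1 / sigma^2
    Ct <- vector("list", n_bins)
    ct <- matrix(0, n_bins, d)
    const <- 0
    for (t in seq_len(n_bins)) {
      rows <- rows_by_bin[[t]]
      if (!length(rows)) next
      st <- data$site[rows]
      y <- data$value[rows]
      Bt <- basis$B[st, , drop = FALSE] * model$gain
      w <- w_site[st]
      Ct[[t]] <- crossprod(Bt * sqrt(w))
      ct[t, ] <- crossprod(Bt, w * y)
      const <- const + 0.5 * sum(w * y^2)
    }
    list(type = "gaussian", n_bins = n_bins, d = d, Ct = Ct, ct = ct,
         const = const, lambda = lambda, alpha = model$alpha,
         rows_by_bin = rows_by_bin, basis = basis, model = model,
         data = data)
  } else if (likelihood == "gamma") {
    if (attr(data, "normalized"))
      stop("gamma PMT inference expects raw intensity data")
    if (model$noise$type != "gamma_pmt")
      stop("gamma likelihood requires a pmt_noise() model")
    fb <- rep_len(model$baseline, basis$n)
    list(type = "gamma", n_bins = n_bins, d = d, lambda = lambda,
         alpha = model$alpha, rows_by_bin = rows_by_bin, basis = basis,
         model = model, data = data, fb = fb,
         g = model$noise$slope, s = model$noise$scale)
  } else stop("unknown likelihood: ", likelihood)
}

# Data-term value / gradient (T x d) / Hessian diagonal blocks at a.
data_term <- function(prep, a, want_grad = FALSE, want_hess = FALSE) {
  T_ <- prep$n_bins; d <- prep$d
  if (prep$type == "gaussian") {
    val <- prep$const
    grad <- if (want_grad) matrix(0, T_, d)
    Hd <- if (want_hess) vector("list", T_)
    for (t in seq_len(T_)) {
      C <- prep$Ct[[t]]
      if (!is.null(C)) {
        Ca <- C %*% a[t, ]
        val <- val + 0.5 * sum(a[t, ] * Ca) - sum(prep$ct[t, ] * a[t, ])
        if (want_grad) grad[t, ] <- Ca - prep$ct[t, ]
        if (want_hess) Hd[[t]] <- C
      }
    }
    list(value = val, grad = grad, Hd = Hd)
  } else {
    val <- 0
    grad <- if (want_grad) matrix(0, T_, d)
    Hd <- if (want_hess) vector("list", T_)
    gainB <- prep$basis$B * prep$model$gain
    for (t in seq_len(T_)) {
      rows <- prep$rows_by_bin[[t]]
      if (!length(rows)) next
      st <- prep$data$site[rows]
      y <- prep$data$value[rows]
      Bt <- gainB[st, , drop = FALSE]
      intensity <- prep$fb[st] * (1 + Bt %*% a[t, ])
      if (any(intensity <= 0)) return(list(value = Inf))
      sh <- prep$g * intensity
      val <- val + sum(lgamma(sh) + sh * log(prep$s) - (sh - 1) * log(y) +
                         y / prep$s)
      if (want_grad || want_hess) {
        dI <- prep$g * (digamma(sh) + log(prep$s) - log(y)) # d val / d I
        w1 <- dI * prep$fb[st]
        if (want_grad) grad[t, ] <- crossprod(Bt, w1)
        if (want_hess) {
          d2 <- prep$g^2 * trigamma(sh) * prep$fb[st]^2
          Hd[[t]] <- crossprod(Bt * sqrt(as.numeric(d2)))
        }
      }
    }
    list(value = val, grad = grad, Hd = Hd)
  }
}

innovations <- function(a, alpha) {
  u <- a
  if (nrow(a) > 1L)
    u[-1L, ] <- a[-1L, , drop = FALSE] - alpha * a[-nrow(a), , drop = FALSE]
  u
}

#' Negative log-posterior of a hidden-weight trajectory
#'
#' Evaluates `sum_t ||y_t - M_t B a_t||^2 / (2 sigma^2) +
#' sum_t lambda_t' (a_t - alpha a_{t-1})` with `a_0 = 0` and
#' `lambda[t, i] = 1 / (A_i delta r_t)` — the exponential-prior MAP
#' objective (additive constants independent of `a` are dropped, except the
#' quadratic data constant so that a perfect fit with `lambda = 0` scores
#' 0).  A gamma PMT likelihood variant on raw intensities is available via
#' `likelihood = "gamma"`.
#'
#' @param a T x d matrix of hidden weights.
#' @param data a normalized [scan_data()] (raw for the gamma variant).
#' @param basis a [tree_basis()].
#' @param model a [calcium_model()].
#' @param gradient,hessian also return the gradient (T x d) and the
#'   block-tridiagonal Hessian structure (diagonal blocks; the prior is
#'   linear so off-diagonal data blocks are zero).
#' @param likelihood `"gaussian"` (default) or `"gamma"`.
#' @return scalar value, or (when gradient/hessian requested) a list with
#'   `value`, `gradient`, `H_diag`.
#' @export
neg_log_posterior <- function(a, data, basis, model, gradient = FALSE,
                              hessian = FALSE,
                              likelihood = c("gaussian", "gamma")) {
  likelihood <- match.arg(likelihood)
  prep <- map_prep(data, basis, model, likelihood)
  a <- as.matrix(a)
  if (nrow(a) != prep$n_bins || ncol(a) != prep$d)
    stop("a must be T x d (", prep$n_bins, " x ", prep$d, ")")
  dt <- data_term(prep, a, want_grad = gradient, want_hess = hessian)
  u <- innovations(a, prep$alpha)
  val <- dt$value + sum(prep$lambda * u)
  if (!gradient && !hessian) return(val)
  out <- list(value = val)
  if (gradient) {
    lam <- prep$lambda
    lin <- lam
    if (nrow(lam) > 1L)
      lin[-nrow(lam), ] <- lam[-nrow(lam), , drop = FALSE] -
        prep$alpha * lam[-1L, , drop = FALSE]
    out$gradient <- dt$grad + lin
  }
  if (hessian) out$H_diag <- dt$Hd
  out
}

# ---- block-tridiagonal Newton direction -------------------------------

#' Solve a symmetric positive-definite block-tridiagonal system
#'
#' Block-Thomas forward elimination / back substitution for
#' `H x = -gradient`, where `H` has T diagonal d x d blocks and T-1
#' super-diagonal coupling blocks (given as full matrices or, for diagonal
#' couplings such as those produced by the temporal log-barrier, as
#' length-d vectors).  Work and memory are linear in T.
#'
#' @param gradient T x d matrix (right-hand side is its negation).
#' @param H_diag list of T symmetric positive-definite d x d matrices.
#' @param H_off list of T-1 coupling blocks; element t couples bins t and
#'   t + 1 (matrix, or vector for a diagonal block).
#' @return T x d matrix with the Newton step.
#' @export
newton_direction_block_tridiag <- function(gradient, H_diag, H_off) {
  T_ <- nrow(gradient); d <- ncol(gradient)
  stopifnot(length(H_diag) == T_, T_ == 1L || length(H_off) == T_ - 1L)
  off_mat <- function(t) {
    o <- H_off[[t]]
    if (is.matrix(o)) o else diag(o, d, d)
  }
  # rounding in the Schur-complement recurrence can nudge a barely-PD
  # block (extreme barrier curvature) indefinite; retry with a vanishing
  # jitter before declaring the block genuinely non-PD
  chol_safe <- function(S, t) {
    ch <- tryCatch(chol(S), error = function(e) NULL)
    jit <- 1e-12 * max(abs(diag(S)), 1)
    for (k in 1:3) {
      if (!is.null(ch)) return(ch)
      ch <- tryCatch(chol(S + diag(jit, nrow(S))),
                     error = function(e) NULL)
      jit <- jit * 1e3
    }
    if (is.null(ch)) stop("non-positive-definite block at t = ", t)
    ch
  }
  chols <- vector("list", T_)
  y <- matrix(0, T_, d)
  chols[[1L]] <- chol_safe(H_diag[[1L]], 1L)
  y[1L, ] <- -gradient[1L, ]
  for (t in seq_len(T_)[-1L]) {
    O <- off_mat(t - 1L)                        # couples t-1 and t
    SiO <- backsolve(chols[[t - 1L]],
                     forwardsolve(t(chols[[t - 1L]]), O))
    S <- H_diag[[t]] - crossprod(O, SiO)
    chols[[t]] <- chol_safe(S, t)
    y[t, ] <- -gradient[t, ] - crossprod(SiO, y[t - 1L, ])
  }
  x <- matrix(0, T_, d)
  x[T_, ] <- backsolve(chols[[T_]],
                       forwardsolve(t(chols[[T_]]), y[T_, ]))
  if (T_ > 1L) for (t in (T_ - 1L):1L) {
    rhs <- y[t, ] - off_mat(t) %*% x[t + 1L, ]
    x[t, ] <- backsolve(chols[[t]], forwardsolve(t(chols[[t]]), rhs))
  }
  x
}

# ---- the MAP smoother -------------------------------------------------

#' Control parameters for the MAP smoother
#'
#' @param barrier_mu0 initial barrier weight; `NULL` (default) sets it so
#'   the barrier contributes roughly 10% of the initial objective.
#' @param mu_growth geometric growth factor of the barrier weight.
#' @param gap_tol terminate when `(T * d) / weight` — the barrier
#'   suboptimality bound — falls below this.
#' @param newton_tol stop Newton when half the squared Newton decrement is
#'   below this.
#' @param max_newton maximum Newton iterations per barrier stage.
#' @param u0 feasible-start innovation level (constant, > 0).
#' @param step_frac fraction of the distance to the feasible boundary the
#'   line search may take (< 1).
#' @return list of class `smooth_control`.
#' @export
smooth_control <- function(barrier_mu0 = NULL, mu_growth = 10,
                           gap_tol = 1e-6, newton_tol = 1e-8,
                           max_newton = 50L, u0 = NULL, step_frac = 0.99) {
  stopifnot(mu_growth > 1, gap_tol > 0, newton_tol > 0, max_newton >= 1,
            step_frac > 0, step_frac < 1)
  structure(list(barrier_mu0 = barrier_mu0, mu_growth = mu_growth,
                 gap_tol = gap_tol, newton_tol = newton_tol,
                 max_newton = as.integer(max_newton), u0 = u0,
                 step_frac = step_frac),
            class = "smooth_control")
}

#' MAP smoothing of calcium signals on a dendritic tree
#'
#' Computes the maximum a-posteriori hidden-weight trajectory under the
#' state-space model: Gaussian (or gamma PMT) likelihood of the sparse
#' per-bin measurements, AR(1) decay of the weights, and an exponential
#' prior on the nonnegative innovations `u_t = a_t - alpha a_{t-1}`.  Only
#' `u >= 0` is constrained; `a >= 0` follows automatically from `a_0 = 0`
#' and `alpha` in (0, 1).  The constraints are handled by a log-barrier
#' interior-point method; each barrier stage is solved by damped Newton
#' with backtracking line search, and the Newton direction exploits the
#' block-tridiagonal Hessian so each iteration costs time linear in the
#' number of bins.
#'
#' @param data a normalized [scan_data()] (raw intensities for
#'   `likelihood = "gamma"`).
#' @param basis a [tree_basis()].
#' @param model a [calcium_model()] supplying `alpha`, noise, prior
#'   amplitudes and the rate schedule.
#' @param control a [smooth_control()].
#' @param likelihood `"gaussian"` (default) or `"gamma"`.
#' @return object of class `calcium_map`: list with `a` (T x d weights),
#'   `u` (T x d innovations, >= 0 up to 1e-8), `field` (T x N estimated
#'   relative concentration at every compartment), `objective` (negative
#'   log-posterior, barrier excluded), `barrier_path` (data.frame: weight,
#'   newton iterations, objective per stage), `converged`, plus the basis,
#'   model and data used.
#' @examples
#' tr <- synthetic_tree(40, seed = 1)
#' bs <- tree_basis(tr, 4)
#' md <- calcium_model(delta = 0.01, tau = 0.2, amp = 1, rate = 5,
#'                     noise = gaussian_noise(0.05))
#' ex <- simulate_experiment(tr, bs, md,
#'   protocol = list(n_bins = 60, bap_times = 0.2, amp_soma = 1,
#'                   length_const = 50, sites_per_bin = 20), seed = 2)
#' yn <- dff_normalize(ex$data, md$baseline)
#' fit <- calcium_smooth(yn, bs, md)
#' fit
#' @export
calcium_smooth <- function(data, basis, model, control = smooth_control(),
                           likelihood = c("gaussian", "gamma")) {
  likelihood <- match.arg(likelihood)
  prep <- map_prep(data, basis, model, likelihood)
  T_ <- prep$n_bins; d <- prep$d; alpha <- prep$alpha
  lam <- prep$lambda
  lin <- lam                                 # gradient of prior wrt a
  if (T_ > 1L)
    lin[-T_, ] <- lam[-T_, , drop = FALSE] - alpha * lam[-1L, , drop = FALSE]

  u0 <- control$u0
  if (is.null(u0)) u0 <- max(0.05 * mean(rep_len(model$amp, d)), 1e-4)
  u <- matrix(u0, T_, d)
  a <- state_trajectory(u, alpha)$a

  f_of <- function(a) {
    dt <- data_term(prep, a)
    dt$value + sum(lam * innovations(a, alpha))
  }
  m <- T_ * d
  f0 <- f_of(a)
  w <- control$barrier_mu0
  if (is.null(w))
    w <- 10 * m * max(1, abs(log(u0))) / max(abs(f0), 1)
  w <- max(w, 1)

  path <- list()
  converged <- TRUE
  repeat {
    res <- newton_stage(prep, a, lam, lin, w, control)
    a <- res$a
    path[[length(path) + 1L]] <- data.frame(weight = w,
                                            newton_iters = res$iters,
                                            objective = res$f)
    if (!res$ok) converged <- FALSE
    if (m / w < control$gap_tol) break
    w <- min(w * control$mu_growth, 1.01 * m / control$gap_tol)
  }
  u <- innovations(a, alpha)
  structure(list(a = a, u = u, field = evaluate_field(basis, a),
                 objective = f_of(a),
                 barrier_path = do.call(rbind, path),
                 converged = converged, lambda = lam, basis = basis,
                 model = model, data = data, likelihood = likelihood,
                 call = match.call()),
            class = "calcium_map")
}

# One barrier stage: damped Newton on f(a) - (1/w) sum(log u(a)).
newton_stage <- function(prep, a, lam, lin, w, control) {
  T_ <- prep$n_bins; d <- prep$d; alpha <- prep$alpha
  phi_of <- function(a, u) {
    dt <- data_term(prep, a)
    if (!is.finite(dt$value)) return(Inf)
    if (any(u <= 0)) return(Inf)
    dt$value + sum(lam * u) - sum(log(u)) / w
  }
  u <- innovations(a, alpha)
  phi <- phi_of(a, u)
  ok <- FALSE
  iter <- 0L
  while (iter < control$max_newton) {
    iter <- iter + 1L
    dt <- data_term(prep, a, want_grad = TRUE, want_hess = TRUE)
    iu <- 1 / pmax(u, 1e-14)        # u below this is numerically active
    iu2 <- iu^2
    grad <- dt$grad + lin - iu / w
    if (T_ > 1L)
      grad[-T_, ] <- grad[-T_, , drop = FALSE] +
        (alpha / w) * iu[-1L, , drop = FALSE]
    H_diag <- vector("list", T_)
    for (t in seq_len(T_)) {
      Dt <- iu2[t, ] / w
      if (t < T_) Dt <- Dt + (alpha^2 / w) * iu2[t + 1L, ]
      H_diag[[t]] <- if (is.null(dt$Hd[[t]])) diag(Dt, d, d)
                     else dt$Hd[[t]] + diag(Dt, d, d)
    }
    H_off <- if (T_ > 1L)
      lapply(seq_len(T_ - 1L),
             function(t) -(alpha / w) * iu2[t + 1L, ])
    p <- newton_direction_block_tridiag(grad, H_diag, H_off)
    dec2 <- -sum(grad * p)                  # squared Newton decrement
    if (dec2 / 2 < control$newton_tol * max(1, abs(phi))) {
      ok <- TRUE
      break
    }
    up <- innovations(p, alpha)
    neg <- up < 0
    eta <- if (any(neg)) min(1, control$step_frac *
                               min(-u[neg] / up[neg])) else 1
    # backtracking Armijo
    accepted <- FALSE
    for (k in 1:40) {
      a_new <- a + eta * p
      u_new <- u + eta * up
      phi_new <- phi_of(a_new, u_new)
      if (is.finite(phi_new) && phi_new <= phi - 1e-4 * eta * dec2) {
        accepted <- TRUE; break
      }
      eta <- eta / 2
    }
    if (!accepted) {                         # line search stalled: accept if
      ok <- dec2 / 2 < 1e-4 * max(1, abs(phi))  # essentially converged
      break
    }
    progress <- phi - phi_new
    a <- a_new; u <- u_new; phi <- phi_new
    if (progress < 1e-10 * max(1, abs(phi))) { ok <- TRUE; break }
  }
  f_val <- {
    dt <- data_term(prep, a)
    dt$value + sum(lam * u)
  }
  list(a = a, iters = iter, f = f_val, ok = ok)
}

# ---- dense reference solver ------------------------------------------

#' Dense constrained reference solver for the MAP problem
#'
#' Solves the same MAP objective as [calcium_smooth()] by a generic
#' box-constrained quasi-Newton method (`optim` L-BFGS-B) over the full
#' innovation vector with explicit `u >= 0` bounds.  Intended as an
#' independent correctness check for the structured solver; refuses
#' problems with more than `max_unknowns` variables.
#'
#' @param data a normalized [scan_data()].
#' @param basis a [tree_basis()].
#' @param model a [calcium_model()].
#' @param max_unknowns refuse problems with `T * d` above this (default
#'   2000).
#' @return list with `a`, `u`, `objective`, `converged`.
#' @export
map_reference_dense <- function(data, basis, model, max_unknowns = 2000L) {
  prep <- map_prep(data, basis, model, "gaussian")
  T_ <- prep$n_bins; d <- prep$d; alpha <- prep$alpha
  if (T_ * d > max_unknowns)
    stop("problem too large for the dense reference solver (",
         T_ * d, " unknowns)")
  lam <- prep$lambda
  fn <- function(uv) {
    u <- matrix(uv, T_, d)
    a <- state_trajectory(u, alpha)$a
    dt <- data_term(prep, a)
    dt$value + sum(lam * u)
  }
  gr <- function(uv) {
    u <- matrix(uv, T_, d)
    a <- state_trajectory(u, alpha)$a
    dt <- data_term(prep, a, want_grad = TRUE)
    g <- dt$grad
    q <- g                                  # reverse-time accumulation
    if (T_ > 1L) for (t in (T_ - 1L):1L)
      q[t, ] <- g[t, ] + alpha * q[t + 1L, ]
    as.numeric(q + lam)
  }
  res <- stats::optim(rep(0.01, T_ * d), fn, gr, method = "L-BFGS-B",
                      lower = 0,
                      control = list(maxit = 5000L, factr = 10))
  u <- matrix(res$par, T_, d)
  a <- state_trajectory(u, alpha)$a
  list(a = a, u = u, objective = res$value, converged = res$convergence == 0)
}

# ---- known spike times ------------------------------------------------

#' Constrained amplitude estimation with known event times
#'
#' When the event bins are known, the innovations are forced to zero off
#' those bins and the per-event amplitude vectors are the nonnegative
#' least-squares solution of the induced linear model (weighted by the
#' per-site noise); with `lambda_prior = 0` this is the pure constrained
#' MLE.  Events with no subsequent observations are underdetermined; a
#' warning is raised and the minimum-norm solution returned.
#'
#' @param data a normalized [scan_data()].
#' @param basis a [tree_basis()].
#' @param model a [calcium_model()].
#' @param spike_bins integer vector of event bins.
#' @param lambda_prior optional exponential-prior coefficient (scalar or
#'   length-d) added as a linear penalty.
#' @return K x d matrix of nonnegative amplitude vectors (rows = events).
#' @export
known_times_mle <- function(data, basis, model, spike_bins,
                            lambda_prior = 0) {
  stopifnot(inherits(data, "scan_data"), inherits(basis, "tree_basis"))
  spike_bins <- sort(as.integer(spike_bins))
  K <- length(spike_bins)
  d <- basis$d
  alpha <- model$alpha
  sigma <- rep_len(model$noise$sd, basis$n)
  sw <- 1 / sigma[data$site]
  nobs <- nrow(data)
  A <- matrix(0, nobs, K * d)
  for (k in seq_len(K)) {
    after <- data$bin >= spike_bins[k]
    if (!any(after))
      warning("no observations at or after event bin ", spike_bins[k],
              "; amplitudes underdetermined (minimum-norm returned)")
    cols <- (k - 1L) * d + seq_len(d)
    decay <- alpha^(data$bin[after] - spike_bins[k])
    A[after, cols] <- model$gain * decay *
      basis$B[data$site[after], , drop = FALSE]
  }
  Aw <- A * sw
  bw <- data$value * sw
  lam <- rep_len(lambda_prior, d)
  if (all(lam == 0)) {
    x <- nnls_fit(Aw, bw)
  } else {
    lam_full <- rep(lam, K)
    fn <- function(x) 0.5 * sum((Aw %*% x - bw)^2) + sum(lam_full * x)
    gr <- function(x) as.numeric(crossprod(Aw, Aw %*% x - bw)) + lam_full
    res <- stats::optim(rep(0.01, K * d), fn, gr, method = "L-BFGS-B",
                        lower = 0, control = list(maxit = 2000L,
                                                  factr = 100))
    x <- res$par
  }
  matrix(x, K, d, byrow = TRUE)
}

# ---- event extraction -------------------------------------------------

#' Extract discrete events from an inferred trajectory
#'
#' Sums the inferred innovations over states (`s_t = sum_i u_{t,i}`) and
#' reports one event per maximal contiguous run of bins with
#' `s_t > threshold_frac * max(s)`, located at the run's peak bin.
#'
#' @param trajectory a `state_trajectory`, a [calcium_smooth()] fit, or a
#'   T x d innovation matrix.
#' @param threshold_frac run threshold as a fraction of the peak
#'   tree-summed innovation (default 0.1).
#' @return data.frame with columns `bin` and `amplitude` (tree-summed
#'   innovation at the peak bin) and attribute `per_state` (one row per
#'   event).  Zero rows when `u` is identically zero.
#' @export
detect_events <- function(trajectory, threshold_frac = 0.1) {
  u <- if (inherits(trajectory, c("state_trajectory", "calcium_map")))
    trajectory$u else as.matrix(trajectory)
  s <- rowSums(u)
  empty <- data.frame(bin = integer(0), amplitude = numeric(0))
  if (max(s) <= 0) {
    attr(empty, "per_state") <- matrix(0, 0L, ncol(u))
    return(empty)
  }
  above <- s > threshold_frac * max(s)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  bins <- vapply(runs, function(k) {
    idx <- starts[k]:ends[k]
    idx[which.max(s[idx])]
  }, 0L)
  out <- data.frame(bin = bins, amplitude = s[bins])
  attr(out, "per_state") <- u[bins, , drop = FALSE]
  out
}
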
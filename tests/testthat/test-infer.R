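test_that("the negative log-posterior matches hand and brute-force values", {
  tr <- path_tree(4)
  bs <- tree_basis(tr, 2)
  # lambda ~ 0: one sample y = 1 against prediction 0, sigma = 1 -> 1/2
  md <- calcium_model(delta = 0.01, tau = 0.2, baseline = 1,
                      noise = gaussian_noise(1), amp = 1e8, rate = 1e8)
  d1 <- scan_data(1, 1, 1, n_bins = 3, n_sites = 4, normalized = TRUE)
  a0 <- matrix(0, 3, bs$d)
  expect_equal(neg_log_posterior(a0, d1, bs, md), 0.5, tolerance = 1e-6)

  # perfect prediction scores zero
  a1 <- matrix(0, 3, bs$d); a1[1, 1] <- 1
  dfit <- scan_data(1, 1, bs$B[1, 1], n_bins = 3, n_sites = 4,
                    normalized = TRUE)
  expect_equal(neg_log_posterior(a1, dfit, bs, md), 0, tolerance = 1e-6)

  # random tiny instance vs an explicit double-loop oracle
  set.seed(3)
  md2 <- calcium_model(delta = 0.01, tau = 0.2, baseline = 1,
                       noise = gaussian_noise(0.3), amp = 0.7, rate = 4)
  d <- scan_data(bin = sample(1:3, 6, TRUE), site = sample(1:4, 6, TRUE),
                 value = rnorm(6), n_bins = 3, n_sites = 4,
                 normalized = TRUE)
  a <- matrix(runif(3 * bs$d), 3, bs$d)
  lambda <- 1 / (outer(rep(4 * 0.01, 3), rep(0.7, bs$d)))
  expect_equal(neg_log_posterior(a, d, bs, md2),
               brute_neg_log_posterior(a, d, bs$B, rep(0.3, 4), lambda,
                                       md2$alpha),
               tolerance = 1e-10)

  # gradient agrees with numerical differentiation
  g <- neg_log_posterior(a, d, bs, md2, gradient = TRUE)$gradient
  eps <- 1e-6
  for (k in sample(length(a), 4)) {
    ap <- a; ap[k] <- ap[k] + eps
    am <- a; am[k] <- am[k] - eps
    fd <- (neg_log_posterior(ap, d, bs, md2) -
             neg_log_posterior(am, d, bs, md2)) / (2 * eps)
    expect_equal(g[k], fd, tolerance = 1e-4)
  }
})

test_that("block-tridiagonal Newton direction matches dense solves", {
  # identity Hessian: step is the negated gradient
  g <- matrix(rnorm(12), 4, 3)
  Hd <- replicate(4, diag(3), simplify = FALSE)
  Ho <- replicate(3, numeric(3), simplify = FALSE)
  expect_equal(newton_direction_block_tridiag(g, Hd, Ho), -g)

  # decoupled blocks: per-bin independent solves
  set.seed(6)
  Hd <- lapply(1:4, function(i) crossprod(matrix(rnorm(9), 3)) + diag(3))
  x <- newton_direction_block_tridiag(g, Hd, Ho)
  for (t in 1:4) expect_equal(x[t, ], solve(Hd[[t]], -g[t, ]),
                              tolerance = 1e-10)

  # random SPD block-tridiagonal vs dense linear algebra, T = 20, d = 5
  T_ <- 20L; d <- 5L
  Hd <- lapply(seq_len(T_),
               function(i) crossprod(matrix(rnorm(d * d), d)) + 5 * diag(d))
  Ho <- lapply(seq_len(T_ - 1L), function(i) rnorm(d, 0, 0.3))
  g <- matrix(rnorm(T_ * d), T_, d)
  Hfull <- matrix(0, T_ * d, T_ * d)
  for (t in seq_len(T_)) {
    idx <- (t - 1) * d + seq_len(d)
    Hfull[idx, idx] <- Hd[[t]]
    if (t < T_) {
      Hfull[idx, idx + d] <- diag(Ho[[t]])
      Hfull[idx + d, idx] <- diag(Ho[[t]])
    }
  }
  x <- newton_direction_block_tridiag(g, Hd, Ho)
  expect_equal(as.numeric(t(x)), solve(Hfull, -as.numeric(t(g))),
               tolerance = 1e-8)

  # an indefinite block is reported with its time index
  Hbad <- Hd; Hbad[[7]] <- -diag(d)
  expect_error(newton_direction_block_tridiag(g, Hbad, Ho), "t = 7")
})

test_that("the smoother shrinks to zero on empty data and recovers clean transients", {
  tr <- path_tree(10)
  bs <- tree_basis(tr, 3)
  md <- quick_model(sigma = 0.1, amp = 0.5, rate = 2)
  # zero observations at all bins: prior shrinks everything to ~0
  d0 <- scan_data(rep(1:30, each = 10), rep(1:10, 30), rep(0, 300),
                  n_bins = 30, n_sites = 10, normalized = TRUE)
  fit0 <- calcium_smooth(d0, bs, md)
  expect_lt(max(abs(fit0$a)), 1e-3)
  expect_true(all(fit0$u > -1e-8))

  # noise-free full observation, weak prior: field recovered to 1e-3
  md_gen <- quick_model(sigma = 0, amp = 1, rate = 2)
  traj <- simulate_states(md_gen, 40, bs$d,
                          events = list(list(bin = 8, amplitude =
                                               runif(bs$d, 0.5, 1))))
  field <- evaluate_field(bs, traj$a)
  dat <- field_to_scan(field)
  md_fit <- quick_model(sigma = 0.02, amp = 1e4, rate = 100)
  fit <- calcium_smooth(dat, bs, md_fit)
  expect_lt(max(abs(fit$field - field)) / max(field), 1e-3)
  expect_true(fit$converged)
})

test_that("feasibility and objective descent hold along the barrier path", {
  set.seed(14)
  tr <- synthetic_tree(25, branch_prob = 0.15)
  bs <- tree_basis(tr, 3)
  md <- quick_model(sigma = 0.1, amp = 0.8, rate = 3)
  ex <- simulate_experiment(tr, bs, md,
                            list(n_bins = 50, bap_times = c(0.1, 0.3),
                                 amp_soma = 1, length_const = 30,
                                 sites_per_bin = 10), seed = 15)
  nn <- dff_normalize(ex$data, md$baseline)
  fit <- calcium_smooth(nn, bs, md)
  expect_gte(min(fit$u), -1e-8)
  expect_gte(min(fit$a), -1e-8)
  expect_true(all(diff(fit$barrier_path$objective) < 1e-8))
  # recursion consistency of the returned trajectory
  resid <- fit$a - rbind(0, md$alpha * fit$a[-nrow(fit$a), ]) - fit$u
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("known-spike-time MLE solves the constrained least-squares exactly", {
  tr <- path_tree(6)
  bs <- suppressWarnings(tree_basis(tr, 10))   # single state
  md <- quick_model(sigma = 0.1)
  alpha <- md$alpha

  # one site, one spike, noise-free: amplitude recovered exactly
  amp_true <- 0.8
  bins <- 3:20
  vals <- amp_true * alpha^(bins - 3) * bs$B[2, 1]
  d <- scan_data(bins, rep(2L, length(bins)), vals, n_bins = 20,
                 n_sites = 6, normalized = TRUE)
  est <- known_times_mle(d, bs, md, spike_bins = 3L)
  expect_equal(as.numeric(est), amp_true, tolerance = 1e-6)

  # noise driving the unconstrained estimate negative: clipped at zero
  dneg <- scan_data(bins, rep(2L, length(bins)), -vals, n_bins = 20,
                    n_sites = 6, normalized = TRUE)
  estneg <- known_times_mle(dneg, bs, md, spike_bins = 3L)
  expect_equal(as.numeric(estneg), 0)

  # two well-separated events match their per-event independent fits
  md2 <- calcium_model(delta = 0.01, tau = 0.05, baseline = 1,
                       noise = gaussian_noise(0.1), amp = 1, rate = 1)
  a2 <- md2$alpha
  b1 <- 5L; b2 <- 150L
  amps <- c(0.6, 1.1)
  bins2 <- c(5:40, 150:185)
  vals2 <- c(amps[1] * a2^(5:40 - b1), amps[2] * a2^(150:185 - b2)) *
    bs$B[2, 1]
  d2 <- scan_data(bins2, rep(2L, length(bins2)), vals2, n_bins = 200,
                  n_sites = 6, normalized = TRUE)
  est2 <- known_times_mle(d2, bs, md2, spike_bins = c(b1, b2))
  expect_equal(as.numeric(est2), amps, tolerance = 1e-5)

  # event after the last observation: warned, minimum-norm zero
  expect_warning(
    est3 <- known_times_mle(d, bs, md, spike_bins = c(3L, 25L)),
    "underdetermined")
  expect_equal(est3[2, 1], 0, tolerance = 1e-4)
})

test_that("event extraction follows the run-length definition", {
  u <- matrix(0, 30, 2)
  u[10, ] <- c(1, 0.5)
  ev <- detect_events(u)
  expect_equal(ev$bin, 10L)
  expect_equal(ev$amplitude, 1.5)

  expect_equal(nrow(detect_events(matrix(0, 10, 2))), 0L)

  # two runs separated by a sub-threshold gap are two events
  u2 <- matrix(0, 30, 1)
  u2[5:6, 1] <- c(0.9, 1)
  u2[7, 1] <- 0.05          # below 10% of max
  u2[20, 1] <- 0.8
  ev2 <- detect_events(u2)
  expect_equal(ev2$bin, c(6L, 20L))
})

test_that("gamma PMT likelihood inference runs and finds the transient", {
  tr <- path_tree(12)
  bs <- tree_basis(tr, 3)
  md <- calcium_model(delta = 0.01, tau = 0.2, baseline = 200,
                      noise = pmt_noise(1, 1), amp = 1, rate = 2)
  ex <- simulate_experiment(tr, bs, md,
                            list(n_bins = 40, bap_times = 0.1,
                                 amp_soma = 1, length_const = 30,
                                 sites_per_bin = 12), seed = 77)
  fit <- calcium_smooth(ex$data, bs, md, likelihood = "gamma")
  ev <- detect_events(fit)
  expect_true(11L %in% ev$bin)
  expect_gte(min(fit$u), -1e-8)
})
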
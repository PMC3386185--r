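test_that("state dynamics superpose decaying exponentials exactly", {
  md <- calcium_model(delta = 0.1, tau = 0.2, amp = 1, rate = 1)  # alpha 0.5
  expect_equal(md$alpha, 0.5)
  tr1 <- simulate_states(md, 3, 1, events = list(list(bin = 1, amplitude = 1)))
  expect_equal(as.numeric(tr1$a), c(1, 0.5, 0.25))
  tr2 <- simulate_states(md, 3, 1,
                         events = list(list(bin = 1, amplitude = 1),
                                       list(bin = 3, amplitude = 1)))
  expect_equal(as.numeric(tr2$a), c(1, 0.5, 1.25))
  tr0 <- simulate_states(md, 4, 2, events = list())
  expect_true(all(tr0$a == 0))
  expect_error(simulate_states(md, 3, 1,
                               events = list(list(bin = 1, amplitude = -1))),
               "nonnegative")
})

test_that("the a/u recursion holds to machine precision for random draws", {
  md <- quick_model(rate = 20, amp = 0.5)
  for (seed in 1:5) {
    tr <- simulate_states(md, 200, 6, seed = seed)
    expect_true(all(tr$u >= 0))
    expect_true(all(tr$a >= 0))
    resid <- tr$a - rbind(0, md$alpha * tr$a[-200, , drop = FALSE]) - tr$u
    expect_lt(max(abs(resid)), 1e-12)
  }
})

test_that("fluorescence rendering is affine and inverts through dF/F", {
  md <- quick_model(baseline = 2)
  field <- matrix(0, 4, 3)
  expect_equal(render_fluorescence(field, md), matrix(2, 4, 3))
  expect_equal(render_fluorescence(0.5, md), 3)

  set.seed(1)
  field <- matrix(runif(12), 4, 3)
  intensity <- render_fluorescence(field, md)
  back <- (intensity - 2) / 2
  expect_equal(back, md$gain * field, tolerance = 1e-12)
})

test_that("dF/F normalization and its inverse are exact", {
  expect_equal(dff_normalize(3, 2), 0.5)
  expect_equal(dff_normalize(2, 2), 0)
  sd0 <- scan_data(bin = c(1, 1, 2), site = c(1, 2, 1),
                   value = c(3, 4, 5), n_sites = 2)
  nn <- dff_normalize(sd0, c(2, 2))
  expect_equal(nn$value, c(0.5, 1, 1.5))
  expect_true(attr(nn, "normalized"))
  rt <- dff_denormalize(nn, c(2, 2))
  expect_equal(rt$value, sd0$value)
  expect_error(dff_normalize(sd0, c(0, 2)), "positive")
})

test_that("noise-free sampling reproduces the intensities exactly", {
  md <- quick_model(sigma = 0)
  intensity <- matrix(1:12, 4, 3)
  sched <- replicate(4, 1:3, simplify = FALSE)
  dat <- sample_measurements(intensity, sched, md)
  expect_equal(dat$value, as.numeric(t(intensity)))
})

test_that("gamma PMT noise has exponential-to-Gaussian statistics", {
  md <- calcium_model(delta = 0.01, tau = 0.2, noise = pmt_noise(1, 1))
  n <- 1e5

  # shape 1: exponential law, variance / mean^2 = 1
  set.seed(42)
  dat <- sample_measurements(matrix(1, n, 1),
                             replicate(n, 1L, simplify = FALSE), md)
  y <- dat$value
  expect_equal(var(y) / mean(y)^2, 1, tolerance = 0.05)

  # shape 400: skewness 2 / sqrt(shape) = 0.1
  set.seed(43)
  dat <- sample_measurements(matrix(400, n, 1),
                             replicate(n, 1L, simplify = FALSE), md)
  v <- dat$value
  skew <- mean((v - mean(v))^3) / sd(v)^3
  expect_equal(skew, 0.1, tolerance = 4 * sqrt(6 / n) / 0.1)

  # mean calibration: E[y / (slope * scale)] = I within 3 standard errors
  se <- sd(v) / sqrt(n)
  expect_lt(abs(mean(v) - 400), 3 * se)

  expect_error(sample_measurements(matrix(-1, 1, 1), list(1L), md),
               "positive")
})

test_that("simulated experiments obey the distance-decay law and jump structure", {
  tr <- synthetic_tree(60, branch_prob = 0.1, seed = 31)
  bs <- tree_basis(tr, 4)
  md <- quick_model(sigma = 0, baseline = 10)
  proto <- list(n_bins = 100, bap_times = c(0.19, 0.49, 0.65),
                amp_soma = 2, length_const = 20, sites_per_bin = tr$n)
  ex <- simulate_experiment(tr, bs, md, proto, seed = 1)

  # per-state amplitude: A0 exp(-dist/L); at the soma center exactly A0
  dist_c <- tr$topo_distance[bs$centers]
  expect_equal(ex$truth$bap_amplitude, 2 * exp(-dist_c / 20))
  expect_equal(ex$truth$bap_amplitude[dist_c == 0], 2)

  # the three bAPs land at bins 20, 50 and 66 and are the only jumps
  expect_equal(ex$truth$bap_bins, c(20L, 50L, 66L))
  jump_bins <- which(apply(ex$truth$trajectory$u, 1, max) > 0)
  expect_equal(jump_bins, c(20L, 50L, 66L))

  # noise-free full observation reproduces the rendered intensity
  intensity <- render_fluorescence(ex$truth$field, md)
  expect_equal(ex$data$value, intensity[cbind(ex$data$bin, ex$data$site)])

  # dF/F of noise-free data equals gain * M B a (the inference model)
  nn <- dff_normalize(ex$data, md$baseline)
  pred <- md$gain * ex$truth$field[cbind(nn$bin, nn$site)]
  expect_equal(nn$value, pred, tolerance = 1e-12)

  expect_error(
    simulate_experiment(tr, bs, md, modifyList(proto,
                                               list(sites_per_bin = tr$n + 1))),
    "sites_per_bin")
})

test_that("EPSP events only touch states near the stimulated site", {
  tr <- path_tree(30)
  bs <- tree_basis(tr, 4)
  md <- quick_model(sigma = 0)
  proto <- list(n_bins = 50, bap_times = numeric(0), amp_soma = 1,
                length_const = 10, sites_per_bin = 5,
                epsp_times = 0.2, epsp_sites = list(25L), epsp_amp = 1,
                epsp_radius = 4)
  ex <- simulate_experiment(tr, bs, md, proto, seed = 2)
  u <- ex$truth$trajectory$u
  active <- which(colSums(u) > 0)
  h <- hop_distances(tr, 25L)
  expect_true(all(h[bs$centers[active]] <= 4))
  expect_true(length(active) >= 1)
})
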
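# Shared fixtures: tiny trees, SWC writers, small models.

path_tree <- function(n, edge = 1) {
  dendrite_tree(c(0L, seq_len(n - 1L)),
                edge_length = c(0, rep(edge, n - 1L)))
}

# Y tree: root-1-2 trunk then two branches of given lengths off node 3.
y_tree <- function(trunk = 3L, arm1 = 2L, arm2 = 2L) {
  parent <- c(0L, seq_len(trunk - 1L))
  bp <- trunk
  for (k in seq_len(arm1)) parent <- c(parent, if (k == 1L) bp else length(parent))
  a1_end <- length(parent)
  for (k in seq_len(arm2)) parent <- c(parent, if (k == 1L) bp else length(parent))
  dendrite_tree(parent)
}

swc_file <- function(rows) {
  path <- tempfile(fileext = ".swc")
  writeLines(rows, path)
  path
}

# chain of 3 nodes on the x axis, unit spacing
swc_chain3 <- function() swc_file(c(
  "# test chain",
  "1 1 0 0 0 1 -1",
  "2 3 1 0 0 1 1",
  "3 3 2 0 0 1 2"))

quick_model <- function(delta = 0.01, tau = 0.2, sigma = 0.05, amp = 1,
                        rate = 5, baseline = 1) {
  calcium_model(delta = delta, tau = tau, baseline = baseline,
                noise = gaussian_noise(sigma), amp = amp, rate = rate)
}

# full-observation noise-free normalized data from a given field
field_to_scan <- function(field, gain = 1) {
  n_bins <- nrow(field); n_sites <- ncol(field)
  scan_data(rep(seq_len(n_bins), each = n_sites),
            rep(seq_len(n_sites), n_bins),
            as.numeric(t(field)) * gain,
            n_bins = n_bins, n_sites = n_sites, normalized = TRUE)
}

# independent brute-force objective: explicit loops, no shared code paths
brute_neg_log_posterior <- function(a, data, B, sigma, lambda, alpha,
                                    gain = 1) {
  T_ <- nrow(a)
  val <- 0
  for (r in seq_len(nrow(data))) {
    t <- data$bin[r]; x <- data$site[r]
    pred <- 0
    for (i in seq_len(ncol(a))) pred <- pred + gain * B[x, i] * a[t, i]
    val <- val + (data$value[r] - pred)^2 / (2 * sigma[x]^2)
  }
  for (t in seq_len(T_)) for (i in seq_len(ncol(a))) {
    u <- a[t, i] - if (t > 1) alpha * a[t - 1, i] else 0
    val <- val + lambda[t, i] * u
  }
  val
}
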
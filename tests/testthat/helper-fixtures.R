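# Shared in-code fixtures for the suite.

# Bright disk of the given radius on a flat background.
disk_image <- function(n = 128, cx = n / 2, cy = n / 2, r = 30,
                       value = 1) {
  d2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cy)^2, "+")
  (d2 <= r^2) * value
}

disk_mask <- function(...) (disk_image(...) > 0) * 1L

# Random binary mask with approximately the given fill fraction.
random_mask <- function(n = 32, fill = 0.3) {
  matrix(as.integer(stats::runif(n * n) < fill), n, n)
}

# Small parameter set for fast synthetic samples.
small_params <- function(...) {
  sim_params(width = 48, height = 48, n_bands = 8, ...)
}

# Hand-executable step-down Holm oracle, independent of stats::p.adjust.
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- (m - i + 1) * p[ord[i]]
    running <- max(running, val)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Brute-force periodized db2 analysis operator as an explicit dense matrix,
# built by direct index arithmetic (independent of analysis code paths).
brute_analysis_matrix <- function(n) {
  s3 <- sqrt(3)
  g <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  h <- c(g[4], -g[3], g[2], -g[1])
  W <- matrix(0, n, n)
  for (i in 1:(n / 2)) {
    for (k in 1:4) {
      j <- ((2 * (i - 1) + k - 1) %% n) + 1
      W[i, j] <- W[i, j] + g[k]
      W[n / 2 + i, j] <- W[n / 2 + i, j] + h[k]
    }
  }
  W
}
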
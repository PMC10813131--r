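# Independent brute-force oracles used across the suite. These deliberately
# reimplement the quantities under test with the most literal algorithms
# available (explicit loops, Floyd-Warshall, full enumeration) and must not
# call the package's own code paths.

# Floyd-Warshall all-pairs shortest paths, edge length 1/weight.
fw_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && W[i, j] > 0) D[i, j] <- 1 / W[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Brute-force weighted/binary small-world metrics: Onnela clustering by
# explicit triangle loops, CPL over finite pairs, Ge as mean inverse
# distance, Le as neighborhood-subgraph efficiency, ND as strength.
bf_graph_metrics <- function(W) {
  n <- nrow(W)
  diag(W) <- 0
  mx <- max(W)
  if (mx > 0) W <- W / mx
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        s <- s + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    cc[i] <- s / (k * (k - 1))
  }
  D <- fw_distances(W)
  off <- D[upper.tri(D)]
  cpl <- mean(off[is.finite(off)])
  ge <- mean(ifelse(is.finite(off), 1 / off, 0))
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    Dn <- fw_distances(W[nb, nb, drop = FALSE])
    offn <- Dn[upper.tri(Dn)]
    le[i] <- mean(ifelse(is.finite(offn), 1 / offn, 0))
  }
  list(cc = cc, le = le, nd = rowSums(W), cpl = cpl, ge = ge)
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j>=i} m p_(j)/j, clipped.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- running
  }
  pmin(q, 1)
}

# Full-enumeration two-sided rank-sum p-value on mid-ranks.
ranksum_enum_oracle <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  idx <- combn(N, n)
  Ws <- colSums(matrix(r[idx], nrow = n))
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}

# Random-walk narrowband phase pair, independent channels: the generator's
# phase model restated directly (low-rate frequency random walk, linear
# interpolation, linear carrier term).
oracle_phase_pair <- function(n, fs, f0, freq_sd, fs_low = 25) {
  n_low <- ceiling(n / fs * fs_low) + 2L
  sigma <- 2 * pi * freq_sd / fs_low
  th <- apply(matrix(rnorm(n_low * 2, sd = sigma), n_low, 2), 2, cumsum)
  th <- sweep(th, 2, runif(2, 0, 2 * pi), "+")
  t_hi <- (0:(n - 1)) / fs * fs_low + 1
  i0 <- pmin(floor(t_hi), n_low - 1L)
  w <- t_hi - i0
  up <- th[i0, ] * (1 - w) + th[i0 + 1L, ] * w
  up + 2 * pi * f0 * (0:(n - 1)) / fs
}

# Epoch-averaged PLV of a phase-pair matrix, computed literally.
oracle_epoch_plv <- function(phi, spe) {
  ne <- nrow(phi) %/% spe
  mean(vapply(seq_len(ne), function(e) {
    d <- phi[((e - 1) * spe + 1):(e * spe), 1] -
      phi[((e - 1) * spe + 1):(e * spe), 2]
    Mod(mean(exp(1i * d)))
  }, 0))
}

# Small helpers for building fixtures.
toy_montage <- function(n) data.frame(name = paste0("ch", seq_len(n)))

toy_epochs <- function(x, fs = 100, band = "broadband") {
  if (is.matrix(x)) x <- array(x, c(1, nrow(x), ncol(x)))
  eeg_epochs(x, fs, paste0("ch", seq_len(dim(x)[2])), band)
}
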
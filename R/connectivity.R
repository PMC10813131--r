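# ---- analytic signal ---------------------------------------------------------

hilbert_mask <- function(n) {
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

# Analytic signal of every epoch/channel: S x (E*C) complex matrix.
analytic_mat <- function(epochs) {
  m <- epochs_to_mat(epochs$x)
  n <- nrow(m)
  mvfft(mvfft(m) * hilbert_mask(n), inverse = TRUE) / n
}

#' Instantaneous phase of band-filtered epochs
#'
#' The phase of the analytic signal (the real signal plus i times its
#' quadrature, obtained with the FFT Hilbert transform), per channel and
#' epoch, in (-pi, pi]. Input epochs should be narrowband (band-filtered);
#' the phase of a broadband signal is not interpretable.
#'
#' @param epochs An [eeg_epochs()].
#' @return Numeric array of phases (radians), same shape as `epochs$x`.
#' @export
instantaneous_phase <- function(epochs) {
  if (!inherits(epochs, "eeg_epochs")) stop_invalid("epochs must be eeg_epochs")
  za <- analytic_mat(epochs)
  ph <- Arg(za)
  ph[ph <= -pi] <- pi  # half-open convention (-pi, pi]
  mat_to_epochs(ph, dim(epochs$x)[1], dim(epochs$x)[2])
}

#' Phase locking value of two phase series
#'
#' `PLV = | mean_t exp(i (phi_i(t) - phi_j(t))) |`, in \[0, 1\]: 1 for a
#' constant phase difference, approaching 0 for independent phases (the null
#' expectation for N independent samples is ~ sqrt(pi)/(2 sqrt(N))).
#'
#' @param phase_i,phase_j Numeric phase series (radians) of equal length
#'   N >= 2.
#' @return PLV in \[0, 1\].
#' @export
plv <- function(phase_i, phase_j) {
  if (!is.numeric(phase_i) || !is.numeric(phase_j))
    stop_invalid("phases must be numeric")
  if (length(phase_i) != length(phase_j))
    stop_invalid("phase series lengths differ (%d vs %d)",
                 length(phase_i), length(phase_j))
  if (length(phase_i) < 2L) stop_invalid("need at least 2 samples")
  min(1, Mod(mean(exp(1i * (phase_i - phase_j)))))
}

#' Per-subject PLV connectivity matrix
#'
#' @param values Symmetric matrix in \[0, 1\] with unit diagonal.
#' @param channels Channel names.
#' @param band Band name, [band_spec()], or `"broadband"`.
#' @param stage Stage code.
#' @param subject_id Subject identifier.
#' @param n_epochs Number of epochs averaged.
#' @return Object of class `plv_matrix`.
#' @export
plv_matrix <- function(values, channels, band, stage = NA_character_,
                       subject_id = NA_character_, n_epochs = NA_integer_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_invalid("PLV matrix must be square")
  if (max(abs(values - t(values))) > 1e-10)
    stop_invalid("PLV matrix must be symmetric")
  if (any(values < -1e-10 | values > 1 + 1e-10))
    stop_invalid("PLV values must be in [0, 1]")
  if (max(abs(diag(values) - 1)) > 1e-10)
    stop_invalid("PLV matrix must have unit diagonal")
  values <- pmin(pmax((values + t(values)) / 2, 0), 1)
  diag(values) <- 1
  channels <- as.character(channels)
  if (length(channels) != nrow(values))
    stop_invalid("channel names do not match matrix size")
  dimnames(values) <- list(channels, channels)
  if (!identical(band, "broadband")) band <- as_band(band)
  structure(list(values = values, channels = channels, band = band,
                 stage = stage, subject_id = subject_id,
                 n_epochs = as.integer(n_epochs)),
            class = "plv_matrix")
}

#' @export
print.plv_matrix <- function(x, ...) {
  bn <- if (identical(x$band, "broadband")) "broadband" else x$band$name
  off <- x$values[upper.tri(x$values)]
  cat(sprintf(
    "<plv_matrix> %s %s @ %s: %d channels, %d epochs; mean off-diag PLV %.3f\n",
    x$subject_id, bn, x$stage, length(x$channels), x$n_epochs, mean(off)))
  invisible(x)
}

# Per-epoch PLV matrices from unit-normalized analytic columns of one epoch.
# u: S x C complex with |u| = 1. Three real crossprods give
# |sum_t u_i conj(u_j)| without forming complex matrices.
epoch_plv <- function(u) {
  Re_m <- Re(u); Im_m <- Im(u)
  ReP <- crossprod(Re_m) + crossprod(Im_m)
  X <- crossprod(Im_m, Re_m)
  ImP <- X - t(X)
  sqrt(ReP^2 + ImP^2) / nrow(u)
}

#' Build the PLV connectivity matrix of an epoch set
#'
#' PLV is computed within each epoch for every unordered channel pair, then
#' averaged across epochs (the segmentation unit bounds non-stationarity).
#' The result is symmetric with unit diagonal.
#'
#' @param epochs A band-filtered [eeg_epochs()] with >= 1 epoch.
#' @return A [plv_matrix()].
#' @export
build_matrix <- function(epochs) {
  if (!inherits(epochs, "eeg_epochs")) stop_invalid("epochs must be eeg_epochs")
  d <- dim(epochs$x)
  E <- d[1]; C <- d[2]
  za <- analytic_mat(epochs)
  za <- za / Mod(za)
  M <- matrix(0, C, C)
  for (e in seq_len(E)) {
    u <- za[, e + (seq_len(C) - 1L) * E, drop = FALSE]
    M <- M + epoch_plv(u)
  }
  M <- M / E
  diag(M) <- 1
  M <- pmin(pmax((M + t(M)) / 2, 0), 1)
  plv_matrix(M, epochs$channels, epochs$band, epochs$stage,
             epochs$subject_id, E)
}

# ---- fused pipeline path -----------------------------------------------------

# One subject/stage -> one plv_matrix per band, sharing a single forward FFT.
# Mathematically identical to segment -> broadband_filter -> baseline_correct
# -> rereference_average -> band_filter -> build_matrix: all steps are linear
# and act either per channel in the frequency domain (filters, DC removal) or
# across channels per sample (average reference), so they commute; equality
# with the literal operation chain is covered by tests.
stage_connectivity <- function(rec, stage, bands, epoch_s = 2,
                               broadband = c(0.1, 60), reref = TRUE) {
  ep <- segment(rec, stage, epoch_s)
  if (reref) ep <- rereference_average(ep)
  d <- dim(ep$x); E <- d[1]; C <- d[2]; S <- d[3]
  Fm <- mvfft(epochs_to_mat(ep$x))
  bb <- if (is.null(broadband)) rep(1, S) else
    cascade_gain(S, ep$fs, broadband[1], broadband[2],
                 order_lp = 8, order_hp = 4)
  hm <- hilbert_mask(S)
  hm[1] <- 0  # per-epoch baseline correction = zero DC
  out <- list()
  for (b in bands) {
    b <- as_band(b)
    g <- cascade_gain(S, ep$fs, b$low_hz, b$high_hz, order_lp = 8,
                      order_hp = 8)
    za <- mvfft(Fm * (bb * g * hm), inverse = TRUE) / S
    za <- za / Mod(za)
    M <- matrix(0, C, C)
    for (e in seq_len(E)) {
      u <- za[, e + (seq_len(C) - 1L) * E, drop = FALSE]
      M <- M + epoch_plv(u)
    }
    M <- M / E
    diag(M) <- 1
    M <- pmin(pmax((M + t(M)) / 2, 0), 1)
    out[[b$name]] <- plv_matrix(M, ep$channels, b, stage, ep$subject_id, E)
  }
  out
}
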
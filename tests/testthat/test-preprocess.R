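make_rec <- function(data, fs, stages) {
  eeg_recording(data, fs, paste0("ch", seq_len(nrow(data))), stages, "tst")
}

test_that("segmentation applies the per-span floor rule and concatenates spans", {
  fs <- 600
  rec <- make_rec(matrix(rnorm(2 * 120 * fs), 2), fs,
                  data.frame(stage = "RS", start_s = 0, end_s = 120))
  ep <- segment(rec, "RS", 2)
  expect_equal(dim(ep$x), c(60, 2, 1200))

  rec5 <- make_rec(matrix(rnorm(2 * 5 * fs), 2), fs,
                   data.frame(stage = "LM", start_s = 0, end_s = 5))
  expect_equal(dim(segment(rec5, "LM", 2)$x)[1], 2)  # 1 s remainder dropped

  rec2span <- make_rec(matrix(rnorm(2 * 10 * fs), 2), fs,
                       data.frame(stage = c("LM", "LM"), start_s = c(0, 5),
                                  end_s = c(3, 8)))
  expect_equal(dim(segment(rec2span, "LM", 2)$x)[1], 2)  # floor per span

  expect_error(segment(rec, "FO", 2), "not present")
  expect_error(segment(rec2span, "LM", 4), "no span")
})

test_that("segments preserve the annotated samples they cover", {
  fs <- 100
  x <- matrix(seq_len(3 * 10 * fs), 3)
  rec <- make_rec(x, fs, data.frame(stage = "RS", start_s = 0, end_s = 10))
  ep <- segment(rec, "RS", 2)
  expect_equal(ep$x[1, , ], x[, 1:200])
  expect_equal(ep$x[3, , ], x[, 401:600])
})

test_that("broadband filter passes 5 Hz, rejects 80 Hz, keeps zeros", {
  fs <- 600; n <- 3600; t <- (0:(n - 1)) / fs
  amp_at <- function(x, f) 2 * abs(fft(x))[round(f * n / fs) + 1] / n
  y5 <- broadband_filter(toy_epochs(matrix(sin(2 * pi * 5 * t), 1), fs))
  expect_equal(amp_at(as.vector(y5$x), 5), 1, tolerance = 0.05)
  y80 <- broadband_filter(toy_epochs(matrix(sin(2 * pi * 80 * t), 1), fs))
  expect_lt(20 * log10(amp_at(as.vector(y80$x), 80)), -20)
  y0 <- broadband_filter(toy_epochs(matrix(0, 1, n), fs))
  expect_equal(max(abs(y0$x)), 0)
  expect_error(broadband_filter(y0, low = 10, high = 5), "band edges")
  # same response on the continuous-recording method
  rec <- make_rec(matrix(sin(2 * pi * 5 * t), 1), fs,
                  data.frame(stage = "RS", start_s = 0, end_s = 6))
  expect_equal(amp_at(broadband_filter(rec)$data[1, ], 5), 1, tolerance = 0.05)
})

test_that("band filter passes in-band, rejects out-of-band, adds no lag", {
  fs <- 600; n <- 3600; t <- (0:(n - 1)) / fs
  amp_at <- function(x, f) 2 * abs(fft(x))[round(f * n / fs) + 1] / n
  x10 <- matrix(sin(2 * pi * 10 * t), 1)
  ya <- band_filter(toy_epochs(x10, fs), "alpha")
  expect_equal(amp_at(as.vector(ya$x), 10), 1, tolerance = 0.05)
  expect_equal(ya$band$name, "alpha")
  yg <- band_filter(toy_epochs(x10, fs), "gamma")
  expect_lt(20 * log10(amp_at(as.vector(yg$x), 10)), -20)
  # zero-phase contract: cross-correlation peak at lag 0
  cc <- ccf(as.vector(ya$x), as.vector(x10), lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(band_filter(toy_epochs(x10, fs = 60), "gamma"), "Nyquist")
})

test_that("band filtering matches an IIR filtfilt oracle away from the edges", {
  fs <- 600; n <- 3600
  set.seed(1)
  x <- rnorm(n)
  lp <- signal::cheby1(8, 0.05, 13 / (fs / 2), type = "low")
  hp <- signal::cheby1(8, 0.05, 8 / (fs / 2), type = "high")
  oracle <- signal::filtfilt(hp, signal::filtfilt(lp, x))
  got <- as.vector(band_filter(toy_epochs(matrix(x, 1), fs), "alpha")$x)
  mid <- 1000:2600
  expect_lt(max(abs(oracle[mid] - got[mid])), 1e-3 * sd(oracle[mid]))
})

test_that("band filtering is linear", {
  fs <- 200; n <- 800
  set.seed(2)
  x <- matrix(rnorm(2 * n), 2)
  f1 <- band_filter(toy_epochs(x, fs), "theta")
  f5 <- band_filter(toy_epochs(5 * x, fs), "theta")
  expect_lt(max(abs(f5$x - 5 * f1$x)), 1e-9 * max(abs(f5$x)))
})

test_that("the canonical bands tile 1-50 Hz without gaps", {
  b <- canonical_bands()
  edges <- vapply(b, function(x) c(x$low_hz, x$high_hz), numeric(2))
  expect_equal(unname(edges[1, 1]), 1)
  expect_equal(unname(edges[2, 5]), 50)
  expect_equal(unname(edges[1, -1]), unname(edges[2, -5]))  # abutting
})

test_that("average reference zeroes the channel mean everywhere", {
  x <- matrix(rnorm(400), 4, 100)
  rec <- make_rec(x, 100, data.frame(stage = "RS", start_s = 0, end_s = 1))
  rr <- rereference_average(rec)
  expect_lt(max(abs(colSums(rr$data))), 1e-10)
  # identical channels become zero
  same <- make_rec(rbind(x[1, ], x[1, ]), 100,
                   data.frame(stage = "RS", start_s = 0, end_s = 1))
  expect_lt(max(abs(rereference_average(same)$data)), 1e-12)
  # antisymmetric pair is already average-referenced
  anti <- make_rec(rbind(x[1, ], -x[1, ]), 100,
                   data.frame(stage = "RS", start_s = 0, end_s = 1))
  expect_equal(rereference_average(anti)$data, anti$data)
  ep <- rereference_average(toy_epochs(array(rnorm(2 * 3 * 50, 5), c(2, 3, 50))))
  expect_lt(max(abs(apply(ep$x, c(1, 3), sum))), 1e-10)
  expect_error(rereference_average(make_rec(x[1, , drop = FALSE], 100, NULL)),
               "2 channels")
})

test_that("baseline correction removes per-epoch channel means only", {
  const <- toy_epochs(array(7, c(2, 2, 40)))
  expect_lt(max(abs(baseline_correct(const)$x)), 1e-12)
  t <- seq(0, 2, length.out = 100)
  sine <- array(rep(sin(2 * pi * 4 * t) - mean(sin(2 * pi * 4 * t)),
                    each = 1), c(1, 1, 100))
  expect_equal(baseline_correct(toy_epochs(sine))$x, sine, tolerance = 1e-10)
  offset <- toy_epochs(sine + 3)
  corr <- baseline_correct(offset)
  expect_equal(corr$x, sine, tolerance = 1e-10)
})

test_that("ICA removes a planted spike train but not Gaussian noise", {
  set.seed(11)
  fs <- 100; n <- 3000; C <- 8
  clean <- matrix(rnorm(C * n), C)
  rec <- make_rec(clean, fs, data.frame(stage = "RS", start_s = 0, end_s = 30))
  out <- suppressWarnings(remove_artifacts_ica(rec))
  expect_length(attr(out, "ica_report")$removed, 0)

  # channel-localized spike train
  spike_t <- seq(100, n, by = 250)
  dirty <- clean
  dirty[3, spike_t] <- dirty[3, spike_t] + 25
  recd <- make_rec(dirty, fs, data.frame(stage = "RS", start_s = 0, end_s = 30))
  cleaned <- suppressWarnings(remove_artifacts_ica(recd))
  rep <- attr(cleaned, "ica_report")
  expect_gte(length(rep$removed), 1)
  e_before <- sum(dirty[3, spike_t]^2)
  e_after <- sum(cleaned$data[3, spike_t]^2)
  expect_lt(e_after, 0.5 * e_before)

  # infinite threshold: identity round-trip
  same <- suppressWarnings(remove_artifacts_ica(recd, kurtosis_z = Inf))
  expect_equal(same$data, recd$data, tolerance = 1e-6)
})
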
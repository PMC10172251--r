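test_that("preprocessing leaves a constant scene spatially flat", {
  fr <- array(7, c(32, 8, 8))
  st <- image_stack(fr, fs_hz = 21)
  out <- suppressWarnings(preprocess_stack(st))  # flat means: bleach skipped
  expect_equal(dim(out$frames), dim(fr))
  # temporal-min background removes the constant floor entirely
  expect_true(all(out$frames == 0))
})

test_that("bleach correction flattens a known exponential decay", {
  T <- 128; fs <- 21
  tt <- (seq_len(T) - 1) / fs
  fr <- array(rep(100 * exp(-tt / 3), 10 * 10), c(T, 10, 10))
  st <- image_stack(fr, fs_hz = fs)
  # isolate the bleach-correction step: no background or smoothing
  out <- preprocess_stack(st, background = "none", smooth = "none")
  means <- apply(out$frames, 1, mean)
  expect_lt(diff(range(means)) / mean(means), 0.01)
})

test_that("smoothing spreads a single bright pixel over its 3x3 block", {
  fr <- array(0, c(2, 9, 9))
  fr[, 5, 5] <- 9
  st <- image_stack(fr, fs_hz = 21)
  out <- suppressWarnings(preprocess_stack(st, background = "none",
                                           bleach = "none"))
  expect_equal(out$frames[1, 4:6, 4:6], matrix(1, 3, 3))
  expect_equal(out$frames[1, 3, 3], 0)
})

test_that("kymogram sampling reproduces static structure", {
  # constant image -> constant kymogram
  st <- image_stack(array(5, c(4, 10, 20)), fs_hz = 21)
  ky <- extract_kymogram(st, rbind(c(1, 4), c(15, 4)))
  expect_true(all(abs(ky$values - 5) < 1e-12))
  expect_equal(ncol(ky$values), 4)

  # horizontal gradient: each position reads its x coordinate, all frames equal
  fr <- array(0, c(3, 10, 20))
  for (t in 1:3) fr[t, , ] <- matrix(rep(0:19, each = 10), 10, 20)
  st <- image_stack(fr, fs_hz = 21)
  ky <- extract_kymogram(st, rbind(c(2, 5), c(12, 5)))
  expect_equal(ky$values[, 1], seq(2, 12, by = 1), tolerance = 1e-12)
  expect_equal(ky$values[, 1], ky$values[, 3])

  expect_error(extract_kymogram(st, rbind(c(-5, 5), c(12, 5))), "bounds")
})

test_that("kymogram of an oscillating spot is periodic at the true frequency", {
  sim <- generate_stack(video_params(n_cilia = 1, true_freqs_hz = 3,
                                     noise_sd = 0, bleach_tau_s = Inf,
                                     n_frames = 210, seed = 8))
  ky <- extract_kymogram(sim$stack, sim$polylines[[1]])
  tr <- colMeans(ky$values)
  tr <- tr - mean(tr)
  lag <- round(21 / 3)   # one period at fs = 21
  ac <- cor(tr[seq_len(length(tr) - lag)], tr[-seq_len(lag)])
  expect_gt(ac, 0.95)
})

test_that("trace reduction is the per-frame mean, with a row option", {
  vals <- rbind(sin(1:50), -sin(1:50))
  ky <- structure(list(values = vals, polyline = rbind(c(0, 0), c(1, 0)),
                       fs_hz = 21), class = "kymogram")
  expect_equal(trace_from_kymogram(ky)$values, rep(0, 50))  # cancellation
  expect_equal(trace_from_kymogram(ky, method = "row", row = 1)$values,
               sin(1:50))
  one <- structure(list(values = vals[1, , drop = FALSE],
                        polyline = rbind(c(0, 0), c(1, 0)), fs_hz = 21),
                   class = "kymogram")
  expect_equal(trace_from_kymogram(one)$values, sin(1:50))
})

test_that("a pure sinusoid is located at the nearest FFT bin", {
  fs <- 21; T <- 600
  tt <- (0:(T - 1)) / fs
  est <- estimate_cbf(cbf_trace(sin(2 * pi * 5 * tt), fs_hz = fs))
  expect_true(est$valid)
  expect_equal(est$freq_hz, 143 * fs / T, tolerance = 1e-9)  # bin 143 = 5.005 Hz
  expect_lt(abs(est$freq_hz - 5), fs / T)
})

test_that("a constant trace yields an invalid estimate", {
  est <- estimate_cbf(cbf_trace(rep(3, 600), fs_hz = 21))
  expect_false(est$valid)
  expect_true(is.na(est$freq_hz))
})

test_that("frequencies beyond Nyquist alias to fs - f", {
  fs <- 21; T <- 600
  tt <- (0:(T - 1)) / fs
  est <- estimate_cbf(cbf_trace(sin(2 * pi * 12 * tt), fs_hz = fs))
  expect_true(est$valid)
  expect_lt(abs(est$freq_hz - 9), fs / T + 1e-9)
})

test_that("noiseless recovery is within one bin over the working band", {
  fs <- 21; T <- 600
  tt <- (0:(T - 1)) / fs
  for (f in seq(1, 9, by = 0.5)) {
    est <- estimate_cbf(cbf_trace(100 + 40 * sin(2 * pi * f * tt + 1), fs_hz = fs))
    expect_true(est$valid)
    expect_lte(abs(est$freq_hz - f), fs / T)
  }
})

test_that("estimates survive realistic noise and bleaching", {
  # SNR 3, tau 10 s: recovery within two bins nearly always
  v <- video_params(true_freqs_hz = list(mean = 5, sd = 1.2),
                    amplitude = 60, noise_sd = 20, bleach_tau_s = 10,
                    seed = 77)
  errs <- sapply(1:200, function(i) {
    g <- generate_trace(v, i)
    est <- estimate_cbf(g$trace)
    if (!est$valid) Inf else abs(est$freq_hz - g$true_freq_hz)
  })
  expect_gte(mean(errs <= 2 * 21 / 600), 0.99)
})

test_that("frequency estimation is amplitude-invariant", {
  g <- generate_trace(video_params(seed = 9))
  e0 <- estimate_cbf(g$trace)
  for (s in c(1e-4, 0.1, 42, 1e6)) {
    es <- estimate_cbf(cbf_trace(g$trace$values * s, fs_hz = g$trace$fs_hz))
    expect_identical(es$valid, e0$valid)
    expect_equal(es$freq_hz, e0$freq_hz)
  }
})

test_that("full video pipeline recovers per-cilium frequencies", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    sim <- generate_stack(video_params(n_cilia = 4, seed = 100 + s))
    pre <- preprocess_stack(sim$stack)
    for (i in seq_len(4)) {
      est <- estimate_cbf(trace_from_kymogram(
        extract_kymogram(pre, sim$polylines[[i]])))
      total <- total + 1
      if (est$valid && abs(est$freq_hz - sim$true_freqs_hz[i]) <= 2 * 21 / 600)
        hits <- hits + 1
    }
  }
  expect_gte(hits, total - 1)
})

test_that("summarize_cbf pools, excludes invalid and tests groups", {
  mk <- function(f) structure(list(freq_hz = f, valid = TRUE), class = "cbf_estimate")
  bad <- structure(list(freq_hz = NA_real_, valid = FALSE), class = "cbf_estimate")
  a <- c(lapply(c(5, 5.1, 4.9), mk), list(bad))
  b <- lapply(c(5, 5.1, 4.9), mk)
  s <- summarize_cbf(a, b)
  expect_equal(s$a$n, 3); expect_equal(s$a$n_invalid, 1)
  expect_equal(s$a$mean, 5, tolerance = 1e-9)
  expect_equal(s$test$t, 0, tolerance = 1e-9)
  expect_equal(s$test$p_value, 1, tolerance = 1e-9)

  # distinct true frequency populations separate
  va <- video_params(true_freqs_hz = list(mean = 4, sd = 0.3), seed = 1)
  vb <- video_params(true_freqs_hz = list(mean = 7, sd = 0.3), seed = 2)
  ea <- lapply(1:10, function(i) estimate_cbf(generate_trace(va, i)$trace))
  eb <- lapply(1:10, function(i) estimate_cbf(generate_trace(vb, i)$trace))
  s2 <- summarize_cbf(ea, eb)
  expect_lt(s2$test$p_value, 0.001)
})
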
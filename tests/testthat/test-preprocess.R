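test_that("outlier removal implements the +/- k SD rule on the original series", {
  set.seed(1)
  s <- tibble::tibble(time_s = 1:200, value = rnorm(200))
  m <- mean(s$value); sdv <- sd(s$value)
  spike_at <- 57
  s$value[spike_at] <- m + 5 * sdv
  cl <- remove_outliers(s, k = 3)
  # brute-force recompute of the threshold on the contaminated series
  m2 <- mean(s$value); sd2 <- sd(s$value)
  expected <- which(abs(s$value - m2) > 3 * sd2)
  expect_identical(attr(cl, "flagged"), expected)
  expect_true(spike_at %in% expected)
  expect_true(all(abs(cl$value - m2) <= 3 * sd2))

  const <- tibble::tibble(time_s = 1:20, value = rep(5, 20))
  cc <- remove_outliers(const)
  expect_identical(nrow(cc), 20L)
  expect_identical(attr(cc, "flagged"), integer(0))

  expect_error(remove_outliers(s, k = 0), "positive")
  expect_error(remove_outliers(s[1:5, ]), "10")
})

test_that("spline resampling reproduces polynomials and smooth sinusoids", {
  mk_rec <- function(f) {
    t1 <- sort(c(0, cumsum(pmin(pmax(rlnorm(400, log(1), 0.2), 0.5), 1.6))))
    t1 <- t1[t1 <= 300]
    chans <- list(
      ABP = tibble::tibble(time_s = t1, value = f(t1)),
      ETCO2 = tibble::tibble(time_s = seq(0, 300, 4), value = f(seq(0, 300, 4))),
      OXY = tibble::tibble(time_s = seq(0, 300, 0.5), value = f(seq(0, 300, 0.5)))
    )
    physio_recording("r", chans, 300)
  }
  set.seed(2)
  # linear ramp: cubic splines are exact on low-degree polynomials
  rec <- mk_rec(function(t) 2 + 0.01 * t)
  out <- synchronize_resample(rec, Ts = 1)
  expect_equal(out$ABP, 2 + 0.01 * out$time_s, tolerance = 1e-9)
  # channel already uniform at Ts reproduces its samples exactly
  expect_equal(out$OXY[out$time_s %in% seq(0, 300, 0.5)],
               2 + 0.01 * out$time_s[out$time_s %in% seq(0, 300, 0.5)],
               tolerance = 1e-12)
  # 0.05 Hz sinusoid sampled at jittered ~1 s: < 1% amplitude error
  set.seed(3)
  rec2 <- mk_rec(function(t) sin(2 * pi * 0.05 * t))
  out2 <- synchronize_resample(rec2, Ts = 1)
  expect_lt(max(abs(out2$ABP - sin(2 * pi * 0.05 * out2$time_s))), 0.01)
})

test_that("short overlap windows are rejected as unusable", {
  chans <- list(
    ABP = tibble::tibble(time_s = seq(0, 100, 1), value = rnorm(101)),
    ETCO2 = tibble::tibble(time_s = seq(0, 130, 4), value = rnorm(33)),
    OXY = tibble::tibble(time_s = seq(0, 130, 0.5), value = rnorm(261))
  )
  rec <- physio_recording("r", chans, 130)
  expect_error(synchronize_resample(rec, 1), class = "hemodyn_unusable_recording")
})

test_that("high-pass filter removes DC and sub-cutoff power, keeps the passband", {
  t <- 0:479
  expect_equal(highpass_detrend(rep(3.7, 480), 1), rep(0, 480), tolerance = 1e-12)

  x_lo <- sin(2 * pi * 0.002 * t) # ~1 cycle over the record
  x_hi <- 2 * sin(2 * pi * 0.05 * t) # 24 exact cycles
  y <- highpass_detrend(x_lo + x_hi, 1)
  amp <- function(v, f) {
    X <- fft(v); k <- round(f * length(v)) + 1
    2 * Mod(X[k]) / length(v)
  }
  # >= 20 dB attenuation at 0.002 Hz, < 1% loss at 0.05 Hz
  expect_lt(amp(y, 0.002), 0.1 * amp(x_lo, 0.002))
  expect_equal(amp(y, 0.05), amp(x_hi, 0.05), tolerance = 0.01)
  expect_lt(abs(mean(y)), 1e-10)
  # idempotence on passband content
  y2 <- highpass_detrend(y, 1)
  expect_lt(max(abs(y2 - y)) / max(abs(y)), 1e-6)
  expect_error(highpass_detrend(rnorm(50), 1, f_cut = 0.005), "cut-off")
})

test_that("preprocessing composes cleanly and reports per-channel QC", {
  rec <- noiseless_recording(seed = 21)
  s <- preprocess_recording(rec)
  expect_true(all(attr(s, "removed_fraction") == 0))
  expect_true(all(abs(colMeans(s[, -1])) < 1e-8))
  expect_identical(attr(s, "Ts"), 1)

  # spike-laden recording: flagged indices recover the injection sidecar
  spec <- subject_spec("sp", kernel_specs = inbasis_kernel_specs(),
                       noise_sd = c(CBV = 0.6, OXY = 0.15), artifact_rate = 2)
  hits <- unlist(lapply(1:5, function(i) {
    rec2 <- generate_subject_recording(spec, 480, seed = 500 + i)
    s2 <- suppressWarnings(preprocess_recording(rec2))
    tr <- attr(rec2, "meta")$truth$artifacts
    fl <- attr(s2, "flags")
    c(tr$CBV$idx %in% fl$CBV, tr$OXY$idx %in% fl$OXY)
  }))
  expect_gte(mean(hits), 0.9)

  # recordings without a usable TCD channel still process the OXY pathway
  chans <- list(
    ABP = recording_channel(rec, "ABP"),
    ETCO2 = recording_channel(rec, "ETCO2"),
    OXY = recording_channel(rec, "OXY")
  )
  rec_no_cbv <- physio_recording("no_tcd", chans, attr(rec, "duration_s"))
  s3 <- preprocess_recording(rec_no_cbv)
  expect_false("CBV" %in% names(s3))
  expect_true("OXY" %in% names(s3))
  m <- fit_kernel_model(s3, "OXY")
  expect_s3_class(m, "kernel_model")
  expect_error(fit_kernel_model(s3, "CBV"), class = "hemodyn_missing_channel")
})

test_that("channel order does not change preprocessing results", {
  rec <- noiseless_recording(seed = 33)
  chans <- lapply(c(ABP = "ABP", ETCO2 = "ETCO2", CBV = "CBV", OXY = "OXY"),
                  function(nm) recording_channel(rec, nm))
  rec_rev <- physio_recording("rev", rev(chans), attr(rec, "duration_s"))
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec_rev)
  for (nm in c("ABP", "ETCO2", "CBV", "OXY")) expect_equal(a[[nm]], b[[nm]])
})

test_that("output grid depends only on the overlap window and Ts", {
  rec <- noiseless_recording(seed = 34)
  s <- preprocess_recording(rec, Ts = 1)
  t0 <- max(sapply(c("ABP", "ETCO2", "CBV", "OXY"), function(nm) {
    min(recording_channel(rec, nm)$time_s)
  }))
  expect_equal(s$time_s[1], t0)
  expect_equal(unique(round(diff(s$time_s), 9)), 1)
})

test_that("re-preprocessing an already clean uniform series is a near-no-op", {
  rec <- noiseless_recording(seed = 35)
  s <- preprocess_recording(rec)
  chans <- lapply(c(ABP = "ABP", ETCO2 = "ETCO2", CBV = "CBV", OXY = "OXY"),
                  function(nm) tibble::tibble(time_s = s$time_s, value = s[[nm]] + 100))
  rec2 <- physio_recording("again", chans, attr(rec, "duration_s"))
  s2 <- preprocess_recording(rec2)
  # interior samples unchanged apart from edge effects of the second filter
  keep <- 60:(nrow(s2) - 60)
  scale_ref <- sd(s$ABP)
  expect_lt(max(abs(s2$ABP[keep] - s$ABP[keep])) / scale_ref, 1e-3)
})
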
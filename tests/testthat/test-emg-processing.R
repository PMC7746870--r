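# Envelope extraction, normalization schemes, gait-cycle time normalization.

test_that("filtering removes sub-cutoff content and passes envelope shape", {
  fs <- 1000
  # a pure 5 Hz sinusoid is far below the 40 Hz high-pass: envelope ~ 0
  raw <- toy_raw_trial(function(t, j) sin(2 * pi * 5 * t), fs = fs)
  env <- filter_envelope(raw)
  expect_lt(max(env), 0.05)
  expect_true(all(env >= 0))
  # an all-zero channel stays zero
  raw0 <- toy_raw_trial(function(t, j) if (j == 1) 0 * t else sin(2 * pi * 60 * t))
  env0 <- filter_envelope(raw0)
  expect_true(all(env0[, 1] == 0))
  expect_gt(max(env0[, 2]), 0)
})

test_that("low-pass cutoff scales with the gait-cycle period", {
  # t_f = 1 s: cutoff 3.5 Hz.  A 60 Hz carrier modulated at 2 Hz keeps its
  # modulation; modulation at 10 Hz (above cutoff) is attenuated away.
  mk <- function(fmod) toy_raw_trial(function(t, j)
    (1 + sin(2 * pi * fmod * t)) * sin(2 * pi * 60 * t), t_f = 1.0,
    channels = "ch1")
  slow_mod <- filter_envelope(mk(2))
  fast_mod <- filter_envelope(mk(10))
  expect_gt(stats::sd(slow_mod), 3 * stats::sd(fast_mod))
  # configuration errors
  raw <- mk(2)
  expect_error(filter_envelope(raw, hp_cutoff = 600), "Nyquist")
})

test_that("the five normalization schemes compute the documented constants", {
  e1 <- matrix(c(0.2, 0.8, 0.4, 0.1), 2, 2,
               dimnames = list(NULL, c("a", "b")))
  e2 <- matrix(c(0.4, 1.6, 0.3, 0.4), 2, 2,
               dimnames = list(NULL, c("a", "b")))
  # MaxOver: channel max over both trials (1.6 for 'a'); global max becomes 1
  mo <- normalize_emg(list(e1, e2), "MaxOver")
  expect_equal(unname(mo$constants["a"]), 1.6)
  expect_equal(max(sapply(mo$trials, function(E) max(E[, "a"]))), 1)
  # MaxPer: per-trial maxima
  mp <- normalize_emg(list(e1, e2), "MaxPer")
  expect_equal(unname(mp$constants[[1]]["a"]), 0.8)
  expect_equal(unname(mp$constants[[2]]["a"]), 1.6)
  # MagPer: 2-norm; [3,4] -> [0.6, 0.8]
  e3 <- matrix(c(3, 4), 2, 1, dimnames = list(NULL, "a"))
  mg <- normalize_emg(list(e3), "MagPer")
  expect_equal(as.numeric(mg$trials[[1]]), c(0.6, 0.8))
  # VarOver / VarPer divide by standard deviations
  vo <- normalize_emg(list(e1, e2), "VarOver")
  expect_equal(unname(vo$constants["a"]), stats::sd(c(0.2, 0.8, 0.4, 1.6)))
  vp <- normalize_emg(list(e1, e2), "VarPer")
  expect_equal(unname(vp$constants[[1]]["b"]), stats::sd(c(0.4, 0.1)))
  # degenerate channels are named in the error
  const <- matrix(c(0.5, 0.5, 1, 2), 2, 2, dimnames = list(NULL, c("flat", "ok")))
  expect_error(normalize_emg(list(const), "VarPer"), "flat")
  zero <- matrix(c(0, 0, 1, 2), 2, 2, dimnames = list(NULL, c("z", "ok")))
  expect_error(normalize_emg(list(zero), "MaxPer"), "z")
})

test_that("normalization is idempotent (Max schemes) and scale-equivariant", {
  set.seed(42)
  mk <- function() matrix(stats::runif(40, 0.1, 2), 20, 2,
                          dimnames = list(NULL, c("a", "b")))
  envs <- list(mk(), mk())
  for (scheme in c("MaxOver", "MaxPer")) {
    once <- normalize_emg(envs, scheme)$trials
    twice <- normalize_emg(once, scheme)$trials
    expect_lt(max(abs(unlist(once) - unlist(twice))), 1e-12)
  }
  # scaling one channel's raw envelope leaves its normalized output unchanged
  for (scheme in c("MaxOver", "MaxPer", "VarOver", "VarPer", "MagPer")) {
    base <- normalize_emg(envs, scheme)$trials
    scaled <- lapply(envs, function(E) { E[, "a"] <- 3.7 * E[, "a"]; E })
    renorm <- normalize_emg(scaled, scheme)$trials
    expect_lt(max(abs(unlist(base) - unlist(renorm))), 1e-12)
  }
})

test_that("time normalization yields 101 + round(10/t_f) frames", {
  # t_f = 1.0 -> n_pad = 10 (111 frames); t_f = 0.8 -> 12.5 rounds up to 13
  expect_equal(n_pad_frames(1.0), 10L)
  expect_equal(n_pad_frames(0.8), 13L)
  expect_equal(n_pad_frames(1.25), 8L)
  raw <- toy_raw_trial(function(t, j) 0.5 + 0 * t, t_f = 1.0, channels = "ch1")
  pt <- time_normalize(raw$samples, raw)
  expect_s3_class(pt, "processed_emg_trial")
  expect_equal(nrow(pt$frames), 111)
  expect_equal(pt$n_pad, 10L)
  # a constant envelope resamples to the same constant
  expect_series_equal(pt$frames[, 1], rep(0.5, 111), tol = 1e-9)
  # spline resampling keeps values near the original range
  raw2 <- toy_raw_trial(function(t, j) 0.5 + 0.4 * sin(2 * pi * t), t_f = 1.0,
                        channels = "ch1")
  pt2 <- time_normalize(raw2$samples, raw2)
  expect_lt(max(pt2$frames), 0.9 * 1.05)
  expect_true(all(pt2$frames >= 0))
})

test_that("insufficient pre-cycle data raises a padding error", {
  time <- seq(0, 1.5, by = 1e-3)
  samples <- matrix(1, length(time), 1, dimnames = list(NULL, "ch1"))
  expect_error(
    raw_emg_trial(samples, "ch1", 1000, cycle_events = c(0.05, 1.05),
                  time = time),
    "before the cycle start")
})

test_that("the full processing chain produces padded non-negative envelopes", {
  set.seed(1)
  raws <- lapply(1:2, function(i)
    toy_raw_trial(function(t, j)
      (0.5 + 0.4 * sin(2 * pi * t + j)) * sin(2 * pi * 80 * t + i), t_f = 1.0))
  pts <- process_emg(raws, scheme = "MaxOver")
  expect_length(pts, 2)
  for (pt in pts) {
    expect_equal(nrow(pt$frames), 111)
    expect_true(all(pt$frames >= 0))
    expect_false(anyNA(pt$frames))
    expect_equal(pt$normalization, "MaxOver")
  }
  expect_equal(max(sapply(pts, function(p) max(p$frames))), 1, tolerance = 0.06)
})
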
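# Conditioning chain: filter behaviour against an analytic frequency-response
# oracle, resampling against analytically sampled sinusoids, padding rules,
# quality gate, patient splits and the balanced sampler.

butter_response <- function(f, fs, config = preprocess_config()) {
  # |H| of the cascaded zero-phase high/low-pass at frequency f:
  # an order-n Butterworth has |H|^2 = 1/(1+(f/fc)^2n) (low-pass) and
  # 1/(1+(fc/f)^2n) (high-pass); filtfilt squares each magnitude.
  n <- config$filter_order
  hlp <- 1 / (1 + (f / config$band_high)^(2 * n))
  hhp <- 1 / (1 + (config$band_low / f)^(2 * n))
  hlp * hhp  # |H|^2 each -> combined two-pass magnitude
}

test_that("band-pass suppresses DC and matches the analytic response in and out of band", {
  fs <- 500
  cfg <- preprocess_config()
  t <- (0:4999) / fs
  dc <- bandpass_filter(matrix(2.5, 1, 5000), fs, cfg)
  expect_lt(max(abs(dc)), 1e-3 * 2.5)

  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_filter(x10, fs, cfg)
  gain10 <- stats::sd(y10) / stats::sd(x10)
  expect_lt(abs(gain10 - 1), 0.05)
  expect_lt(abs(gain10 - butter_response(10, fs, cfg)), 0.05)

  x120 <- sin(2 * pi * 120 * t)
  y120 <- bandpass_filter(x120, fs, cfg)
  gain120 <- stats::sd(y120) / stats::sd(x120)
  expect_lt(abs(gain120 - butter_response(120, fs, cfg)),
            0.1 * butter_response(120, fs, cfg) + 1e-3)

  expect_error(bandpass_filter(x10, fs = 90, cfg), "Nyquist")
})

test_that("the filter is linear", {
  set.seed(2)
  fs <- 250
  x <- rnorm(1000); y <- rnorm(1000)
  lhs <- bandpass_filter(2 * x - 3 * y, fs)
  rhs <- 2 * bandpass_filter(x, fs) - 3 * bandpass_filter(y, fs)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-6)
})

test_that("z-score normalization centers, scales, guards constants and is affine-invariant", {
  set.seed(3)
  x <- matrix(rnorm(600, mean = 4, sd = 3), 2, 300)
  z <- zscore_normalize(x)
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, stats::sd) - 1)), 1e-9)
  expect_identical(zscore_normalize(matrix(7, 1, 50)), matrix(0, 1, 50))
  expect_equal(zscore_normalize(5 * x + 2), z, tolerance = 1e-9)
})

test_that("resampling has exact length arithmetic and reproduces analytic sinusoids", {
  x <- matrix(rnorm(5000), 1)
  expect_equal(ncol(resample(x, 500, 250)), 2500L)
  expect_identical(resample(x, 250, 250), x)
  expect_error(resample(x, 250, 500), "upsampling")

  t500 <- (0:4999) / 500
  s <- sin(2 * pi * 5 * t500)
  r <- resample(s, 500, 250)
  ref <- sin(2 * pi * 5 * (0:2499) / 250)
  expect_gt(stats::cor(r, ref), 0.999)
})

test_that("fixed-length standardization truncates, pads by mode and hits the 64-divisibility contract", {
  cfg <- preprocess_config(target_fs = 250, target_len_s = 20,
                           pad_mode = "eval_end")
  long <- matrix(rnorm(12 * 7500), 12)    # 30 s at 250 Hz
  out <- fix_length(long, 250, cfg)
  expect_equal(ncol(out), 5056L)          # 79 * 64
  expect_true(all(out[, 5001:5056] == 0)) # divisibility padding is zeros

  short <- matrix(1, 12, 2500)            # 10 s
  oute <- fix_length(short, 250, cfg)
  expect_true(all(oute[, 1:2500] == 1))
  expect_true(all(oute[, 2501:5056] == 0))

  cfg$pad_mode <- "train_random"
  outr1 <- fix_length(short, 250, cfg, seed = 5L)
  outr2 <- fix_length(short, 250, cfg, seed = 5L)
  expect_identical(outr1, outr2)
  lp <- attr(outr1, "left_pad")
  expect_true(lp >= 0L && lp <= 2500L)
  expect_true(all(outr1[, lp + (1:2500)] == 1))
})

test_that("fixed-length output is constant across a dataset and divisible by 64", {
  data <- tiny_dataset(seed = 4L, n_patients = 4L)
  lens <- vapply(c(data$train, data$val, data$test),
                 function(r) ncol(r$signal), 1L)
  expect_length(unique(lens), 1L)
  expect_equal(lens[1L] %% 64L, 0L)
})

test_that("the quality gate drops incomplete and out-of-range records with reasons", {
  ds <- simulate_dataset(sim_spec(n_patients = 5L, records_per_patient = 1L,
                                  duration_s = c(4, 4), seed = 6L))
  recs <- ds$records
  recs[[2L]]$signal[3L, 10L] <- NaN
  recs[[4L]]$signal[1L, ] <- recs[[4L]]$signal[1L, ] * 10 *
    preprocess_config()$amplitude_limit
  qf <- quality_filter(recs)
  expect_length(qf$records, 3L)
  expect_setequal(qf$excluded$reason, c("incomplete", "amplitude"))
  all_clean <- quality_filter(ds$records)
  expect_length(all_clean$records, 5L)
  expect_equal(nrow(all_clean$excluded), 0L)
})

test_that("patient-level splitting matches 7:1:2, never leaks and is seed-stable", {
  mf <- data.frame(record_id = sprintf("R%02d", 1:10),
                   patient_id = sprintf("P%02d", 1:10))
  sp <- split_patients(mf, seed = 3L)
  expect_equal(unname(table(sp$split)[c("train", "val", "test")]),
               c(7L, 1L, 2L), ignore_attr = TRUE)
  by_split <- split(sp$patient_id, sp$split)
  expect_length(Reduce(intersect, by_split), 0L)
  expect_identical(sp, split_patients(mf, seed = 3L))
  expect_error(split_patients(mf[1:2, ], seed = 1L), "at least 3 patients")

  # patients with several records never span splits
  ds <- simulate_dataset(sim_spec(n_patients = 9L, records_per_patient = 4L,
                                  duration_s = c(4, 4), seed = 8L))
  sp2 <- split_patients(ds, seed = 2L)
  spans <- tapply(sp2$split, sp2$patient_id, function(s) length(unique(s)))
  expect_true(all(spans == 1L))
})

test_that("the balanced sampler equalizes class draw frequencies and is seed-stable", {
  labels <- c(rep(1L, 100L), 2L)
  draw <- balanced_sampler(labels, seed = 9L)
  idx <- draw(10000L)
  freq2 <- mean(labels[idx] == 2L)
  # binomial 3-sigma band around 1/2
  expect_lt(abs(freq2 - 0.5), 3 * sqrt(0.25 / 10000))

  draw_a <- balanced_sampler(labels, seed = 10L)
  draw_b <- balanced_sampler(labels, seed = 10L)
  expect_identical(draw_a(100L), draw_b(100L))

  single <- balanced_sampler(rep(1L, 5L), seed = 1L)
  expect_true(all(single(50L) %in% 1:5))
})

test_that("preprocess chain output unites quality survivors across disjoint splits", {
  ds <- simulate_dataset(sim_spec(n_patients = 6L, records_per_patient = 2L,
                                  duration_s = c(4, 5), seed = 12L))
  ds$records[[1L]]$signal[1L, 1L] <- Inf
  split <- split_patients(ds, seed = 1L)
  pp <- preprocess_records(ds, preprocess_config(target_fs = 125,
                                                 target_len_s = 4),
                           split = split, seed = 2L)
  ids_out <- vapply(pp$records, function(r) r$record_id, "")
  survivors <- setdiff(ds$manifest$record_id, pp$excluded$record_id)
  expect_setequal(ids_out, survivors)
})
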
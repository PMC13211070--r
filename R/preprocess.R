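# Signal conditioning chain: quality exclusion, band-pass filtering, FFT
# resampling, per-lead z-scoring, fixed-length standardization, patient-level
# splitting and class-balanced sampling.

#' Preprocessing configuration
#'
#' @param band_low,band_high Band-pass corner frequencies in Hz (defaults
#'   0.05 and 48).
#' @param filter_order Butterworth order (default 3).
#' @param target_fs Output sampling frequency in Hz (default 250; only
#'   downsampling is supported).
#' @param target_len_s Fixed record length in seconds after standardization
#'   (default 20).
#' @param pad_mode `"train_random"` splits the zero-padding deficit uniformly
#'   before/after the signal; `"eval_end"` pads only at the end.
#' @param amplitude_limit Quality gate: records with any sample exceeding
#'   this absolute amplitude (millivolts, pre-normalization) are excluded.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low = 0.05, band_high = 48, filter_order = 3L,
                              target_fs = 250, target_len_s = 20,
                              pad_mode = c("train_random", "eval_end"),
                              amplitude_limit = 20) {
  pad_mode <- match.arg(pad_mode)
  if (!(band_low > 0 && band_low < band_high && band_high < target_fs / 2)) {
    stop("need 0 < band_low < band_high < target_fs/2")
  }
  if (filter_order < 1L) stop("filter_order must be at least 1")
  structure(list(band_low = band_low, band_high = band_high,
                 filter_order = as.integer(filter_order), target_fs = target_fs,
                 target_len_s = target_len_s, pad_mode = pad_mode,
                 amplitude_limit = amplitude_limit),
            class = "preprocess_config")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Removes the per-lead mean, then applies a forward-backward (zero-phase)
#' Butterworth high-pass at `band_low` followed by a low-pass at `band_high`.
#' The cascade of third-order sections is numerically robust at the very low
#' normalized high-pass corner (0.05 Hz), where a single band-pass transfer
#' function is ill-conditioned. Output length equals input length and QRS
#' morphology is not phase-distorted.
#'
#' @param signal A `leads x N` numeric matrix (or a vector, one lead).
#' @param fs Sampling frequency in Hz; must exceed `2 * band_high`.
#' @param config A [preprocess_config()].
#' @return Filtered signal, same shape as the input.
#' @export
bandpass_filter <- function(signal, fs, config = preprocess_config()) {
  if (fs <= 2 * config$band_high) {
    stop("Nyquist violation: fs = ", fs, " must exceed 2 * band_high = ",
         2 * config$band_high)
  }
  vec <- !is.matrix(signal)
  if (vec) signal <- matrix(signal, nrow = 1L)
  hp <- signal::butter(config$filter_order, config$band_low / (fs / 2), type = "high")
  lp <- signal::butter(config$filter_order, config$band_high / (fs / 2), type = "low")
  out <- signal
  for (i in seq_len(nrow(signal))) {
    x <- signal[i, ] - mean(signal[i, ])
    out[i, ] <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  }
  if (vec) out[1L, ] else out
}

#' Per-lead z-score normalization
#'
#' Subtracts the mean and divides by the standard deviation of each lead.
#' Constant leads map to all zeros (guarded division).
#'
#' @param signal A `leads x N` matrix (or a vector).
#' @return Normalized signal, same shape.
#' @export
zscore_normalize <- function(signal) {
  vec <- !is.matrix(signal)
  if (vec) signal <- matrix(signal, nrow = 1L)
  out <- signal
  for (i in seq_len(nrow(signal))) {
    s <- stats::sd(signal[i, ])
    out[i, ] <- if (!is.finite(s) || s < 1e-12) 0 else (signal[i, ] - mean(signal[i, ])) / s
  }
  if (vec) out[1L, ] else out
}

fft_resample_vec <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  xf <- stats::fft(x)
  h <- floor(min(n, n_out) / 2)
  y <- complex(length.out = n_out)
  y[seq_len(h + 1L)] <- xf[seq_len(h + 1L)]
  if (h > 0L) y[(n_out - h + 1L):n_out] <- xf[(n - h + 1L):n]
  Re(stats::fft(y, inverse = TRUE)) / n
}

#' Downsample a signal by Fourier-domain truncation
#'
#' Resamples each lead by truncating its discrete spectrum to the new
#' bandwidth and inverse-transforming, which is exact for band-limited
#' content. Output length is `round(N * fs_out / fs_in)`.
#'
#' @param signal A `leads x N` matrix (or a vector).
#' @param fs_in,fs_out Input and output sampling frequencies; upsampling
#'   (`fs_out > fs_in`) is not supported.
#' @return Resampled signal.
#' @export
resample <- function(signal, fs_in, fs_out) {
  if (fs_out > fs_in) stop("upsampling (fs_out > fs_in) is not supported")
  vec <- !is.matrix(signal)
  if (vec) signal <- matrix(signal, nrow = 1L)
  if (fs_out == fs_in) return(if (vec) signal[1L, ] else signal)
  n_out <- round(ncol(signal) * fs_out / fs_in)
  out <- matrix(0, nrow(signal), n_out)
  for (i in seq_len(nrow(signal))) out[i, ] <- fft_resample_vec(signal[i, ], n_out)
  if (vec) out[1L, ] else out
}

#' Standardize a record to a fixed length
#'
#' Truncates records longer than `target_len_s` (keeping the first window)
#' and zero-pads shorter ones: in `"train_random"` mode the deficit is split
#' uniformly at random before/after the signal, in `"eval_end"` mode all
#' padding goes at the end. The result is then right-padded with zeros to
#' the next multiple of 64, the extractor's total time-downsampling factor,
#' so the token count N/64 is integral.
#'
#' @param signal A `leads x N` matrix.
#' @param fs Sampling frequency of `signal`.
#' @param config A [preprocess_config()] (uses `target_len_s`, `pad_mode`).
#' @param seed Optional seed for a reproducible random pad split.
#' @return A `leads x M` matrix with `M = 64 * ceiling(target_len_s * fs / 64)`;
#'   the realized left-pad length is attached as attribute `"left_pad"`.
#' @export
fix_length <- function(signal, fs, config = preprocess_config(), seed = NULL) {
  stopifnot(is.matrix(signal))
  window <- round(config$target_len_s * fs)
  n <- ncol(signal)
  if (n >= window) {
    out <- signal[, seq_len(window), drop = FALSE]
    left <- 0L
  } else {
    deficit <- window - n
    left <- if (config$pad_mode == "train_random") {
      draw <- function() sample.int(deficit + 1L, 1L) - 1L
      if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    } else 0L
    out <- cbind(matrix(0, nrow(signal), left), signal,
                 matrix(0, nrow(signal), deficit - left))
  }
  total <- 64L * ceiling(window / 64)
  if (total > window) out <- cbind(out, matrix(0, nrow(signal), total - window))
  attr(out, "left_pad") <- as.integer(left)
  out
}

#' Exclude incomplete or out-of-range records
#'
#' Drops records containing non-finite samples (reason `"incomplete"`) or
#' any sample with absolute amplitude above `config$amplitude_limit`
#' (reason `"amplitude"`).
#'
#' @param records A list of `ecg_record`s or an `ecg_dataset`.
#' @param config A [preprocess_config()].
#' @return A list with `records` (survivors) and `excluded` (data frame of
#'   record_id and reason).
#' @export
quality_filter <- function(records, config = preprocess_config()) {
  if (inherits(records, "ecg_dataset")) records <- records$records
  keep <- list()
  excl_id <- character(0)
  excl_reason <- character(0)
  for (r in records) {
    if (any(!is.finite(r$signal))) {
      excl_id <- c(excl_id, r$record_id); excl_reason <- c(excl_reason, "incomplete")
    } else if (max(abs(r$signal)) > config$amplitude_limit) {
      excl_id <- c(excl_id, r$record_id); excl_reason <- c(excl_reason, "amplitude")
    } else {
      keep[[length(keep) + 1L]] <- r
    }
  }
  list(records = keep,
       excluded = data.frame(record_id = excl_id, reason = excl_reason,
                             stringsAsFactors = FALSE))
}

#' Patient-level train/validation/test split
#'
#' Shuffles patients with the given seed and assigns each patient's whole
#' record set greedily to the split with the largest remaining record-count
#' deficit, so the realized fractions approach `ratios` (default 7:1:2) as
#' closely as patient granularity allows. No patient ever spans splits.
#'
#' @param records A list of `ecg_record`s, an `ecg_dataset`, or a manifest
#'   data frame with `record_id` and `patient_id` columns.
#' @param ratios Length-3 positive weights for train/val/test.
#' @param seed Integer seed for the patient shuffle.
#' @return A data frame (`record_id`, `patient_id`, `split`) with
#'   `split` in `train`/`val`/`test`.
#' @export
split_patients <- function(records, ratios = c(7, 1, 2), seed = 1L) {
  manifest <- if (is.data.frame(records)) {
    records
  } else {
    if (inherits(records, "ecg_dataset")) records <- records$records
    data.frame(record_id = vapply(records, function(r) r$record_id, ""),
               patient_id = vapply(records, function(r) r$patient_id, ""),
               stringsAsFactors = FALSE)
  }
  patients <- unique(manifest$patient_id)
  if (length(patients) < 3L) stop("need at least 3 patients to split")
  counts <- table(manifest$patient_id)
  n <- nrow(manifest)
  targets <- ratios / sum(ratios) * n
  assigned <- c(train = 0, val = 0, test = 0)
  splits <- c("train", "val", "test")
  patient_split <- character(length(patients))
  names(patient_split) <- withr::with_seed(seed, sample(patients))
  for (p in names(patient_split)) {
    deficit <- targets - assigned
    s <- splits[which.max(deficit)]
    patient_split[p] <- s
    assigned[s] <- assigned[s] + counts[[p]]
  }
  data.frame(record_id = manifest$record_id,
             patient_id = manifest$patient_id,
             split = unname(patient_split[manifest$patient_id]),
             stringsAsFactors = FALSE)
}

#' Class-balanced sampler with replacement
#'
#' Returns a draw function over record indices: each draw first picks a
#' class uniformly, then a record uniformly within that class (with
#' replacement), so minority classes are oversampled. The sampler carries
#' its own RNG state, so a fixed seed gives an identical index stream
#' regardless of surrounding RNG use.
#'
#' @param labels Integer (or factor) class label per record; every class
#'   must have at least one record.
#' @param seed Integer seed of the sampler's private RNG stream.
#' @return A function `f(n)` returning the next `n` indices of the stream.
#' @export
balanced_sampler <- function(labels, seed = 1L) {
  labels <- as.integer(as.factor(labels))
  by_class <- split(seq_along(labels), labels)
  if (any(lengths(by_class) == 0L)) stop("every class needs at least one record")
  k <- length(by_class)
  state <- withr::with_seed(seed, .Random.seed)
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state, globalenv())
    idx <- vapply(seq_len(n), function(i) {
      cls <- by_class[[sample.int(k, 1L)]]
      cls[sample.int(length(cls), 1L)]
    }, 1L)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    idx
  }
}

#' Run the full conditioning chain on a set of records
#'
#' Applies quality exclusion, band-pass filtering (at the native rate),
#' downsampling to `target_fs`, per-lead z-scoring and fixed-length
#' standardization, with the pad mode chosen per record from its split
#' (`train` records use `train_random` padding, others `eval_end`). The
#' random pad realization is drawn once per record here, so a frozen
#' teacher and its student always see the same padded signal.
#'
#' @param records A list of `ecg_record`s or an `ecg_dataset`.
#' @param config A [preprocess_config()].
#' @param split Optional data frame from [split_patients()]; when absent all
#'   records are padded in `eval_end` mode.
#' @param seed Seed controlling the per-record pad draws.
#' @return A list with `records` (processed `ecg_record`s, each annotated
#'   with `$split`) and `excluded` (quality-exclusion log).
#' @export
preprocess_records <- function(records, config = preprocess_config(),
                               split = NULL, seed = 1L) {
  qf <- quality_filter(records, config)
  split_of <- if (is.null(split)) NULL else stats::setNames(split$split, split$record_id)
  out <- withr::with_seed(seed, lapply(qf$records, function(r) {
    s <- if (is.null(split_of)) "eval" else split_of[[r$record_id]]
    x <- bandpass_filter(r$signal, r$fs, config)
    x <- resample(x, r$fs, config$target_fs)
    x <- zscore_normalize(x)
    cfg <- config
    cfg$pad_mode <- if (identical(s, "train")) "train_random" else "eval_end"
    x <- fix_length(x, config$target_fs, cfg)
    r$signal <- x
    r$fs <- config$target_fs
    r$split <- s
    r
  }))
  list(records = out, excluded = qf$excluded)
}
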
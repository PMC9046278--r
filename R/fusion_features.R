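#' Multichannel time series container
#'
#' @param time Strictly increasing time axis in seconds.
#' @param values Numeric matrix, time x channels.
#' @param channel_labels Optional channel names.
#' @return An object of class `fusion_timeseries` with a `rate` (Hz) derived
#'   from the time axis.
#' @export
timeseries <- function(time, values, channel_labels = NULL) {
  values <- as.matrix(values)
  if (length(time) != nrow(values)) {
    stop("time axis length must match rows of values", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("time axis must be strictly increasing", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- colnames(values)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(ncol(values)))
    }
  }
  colnames(values) <- channel_labels
  structure(list(time = as.numeric(time), values = values,
                 rate = 1 / stats::median(diff(time)),
                 channel_labels = as.character(channel_labels)),
            class = "fusion_timeseries")
}

#' Event-locked epoch container
#'
#' Time x channels array aligned so the event marker sits at time zero.
#' Under the half-open window convention `[start, end)` the sample count is
#' exactly `round((end - start) * rate)`.
#'
#' @param values Numeric matrix, time x channels.
#' @param rate Sampling rate in Hz.
#' @param start,end Window bounds in seconds relative to the marker.
#' @param channel_labels Optional channel names.
#' @return An object of class `epoched_signal`.
#' @export
epoched_signal <- function(values, rate, start, end, channel_labels = NULL) {
  values <- as.matrix(values)
  n_expect <- round((end - start) * rate)
  if (nrow(values) != n_expect) {
    stop(sprintf("window [%g, %g) at %g Hz implies %d samples, got %d",
                 start, end, rate, n_expect, nrow(values)), call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- colnames(values)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(ncol(values)))
    }
  }
  colnames(values) <- channel_labels
  structure(list(values = values, rate = rate, start = start, end = end,
                 channel_labels = as.character(channel_labels)),
            class = "epoched_signal")
}

#' @export
print.epoched_signal <- function(x, ...) {
  cat(sprintf("<epoched_signal: [%g, %g) s at %g Hz, %d x %d>\n",
              x$start, x$end, x$rate, nrow(x$values), ncol(x$values)))
  invisible(x)
}

signal_rate <- function(x) {
  if (inherits(x, c("fusion_timeseries", "epoched_signal"))) return(x$rate)
  stop("expected a fusion_timeseries or epoched_signal", call. = FALSE)
}

replace_values <- function(x, values) {
  colnames(values) <- x$channel_labels
  x$values <- values
  x
}

# Causal linear convolution via zero-padded FFT at a fast (2-3-5-smooth)
# length; stats::convolve at length n + k - 1 can hit near-prime FFT sizes
# with quadratic cost on long recordings.
fast_causal_conv <- function(x, k) {
  n <- length(x)
  m <- stats::nextn(n + length(k) - 1, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - n)))
  K <- stats::fft(c(k, numeric(m - length(k))))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(n)] / m
}

# FFT analytic signal (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase band-pass with reflection padding to tame edge transients.
bandpass_channel <- function(x, low, high, rate, order = 4L) {
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  npad <- min(length(x) - 1, round(rate))
  xp <- c(rev(x[seq_len(npad) + 1]), x, rev(x[length(x) - seq_len(npad)]))
  y <- signal::filtfilt(bf, xp)
  y[(npad + 1):(npad + length(x))]
}

#' Time-resolved band power via the analytic envelope
#'
#' Band-passes each channel to `[band_low, band_high]` (zero-phase
#' Butterworth, reflection padding) and returns the squared magnitude of
#' the analytic signal — the instantaneous power in the band.  With the
#' defaults this is the mu-band (8-13 Hz) power whose event-related
#' decrease indexes sensorimotor engagement in EEG.
#'
#' @param sig A `fusion_timeseries` or `epoched_signal`.
#' @param band_low,band_high Band edges in Hz (default 8 and 13).
#' @return The same container with power values (nonnegative, same shape).
#' @export
mu_band_power <- function(sig, band_low = 8, band_high = 13) {
  rate <- signal_rate(sig)
  if (band_high * 2 >= rate) {
    stop(sprintf("band edge %g Hz exceeds the Nyquist limit of %g Hz",
                 band_high, rate / 2), call. = FALSE)
  }
  if (band_low <= 0 || band_low >= band_high) {
    stop("require 0 < band_low < band_high", call. = FALSE)
  }
  v <- apply(sig$values, 2, function(x) {
    if (all(x == 0)) return(numeric(length(x)))
    xf <- bandpass_channel(x, band_low, band_high, rate)
    Mod(analytic_signal(xf))^2
  })
  replace_values(sig, v)
}

#' Invert band power so decreases become increases
#'
#' The mu-band power *drops* during action observation/execution while the
#' hemodynamic (HbO) response *rises*; inverting the power puts both
#' modalities on the same sign convention before HRF convolution.
#'
#' @param power A `fusion_timeseries` or `epoched_signal` with nonnegative
#'   values.
#' @param mode `"reciprocal"` (default): `1 / (power + epsilon)`;
#'   `"negate"`: mean(power) minus power.
#' @param epsilon Positive guard added in reciprocal mode.
#' @return The same container with inverted values.
#' @export
invert_power <- function(power, mode = c("reciprocal", "negate"),
                         epsilon = 1e-8) {
  mode <- match.arg(mode)
  v <- power$values
  if (any(v < 0)) stop("power must be nonnegative", call. = FALSE)
  out <- if (mode == "reciprocal") {
    if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
    1 / (v + epsilon)
  } else {
    sweep(-v, 2, -colMeans(v), "-")
  }
  replace_values(power, out)
}

#' Gamma-shaped hemodynamic response kernel
#'
#' Single-gamma HRF \eqn{h(t) \propto t^{shape-1} e^{-t/scale}} sampled on
#' `[0, duration)` and normalized to unit area (`sum(h) * dt = 1`) so that
#' convolution preserves the scale of a sustained input.  The analytic peak
#' sits at `(shape - 1) * scale` seconds — 5 s with the defaults, the
#' canonical hemodynamic delay.
#'
#' @param shape Gamma shape (> 1).
#' @param scale Gamma scale in seconds (> 0).
#' @param duration Kernel length in seconds.
#' @param rate Sampling rate in Hz.
#' @return An object of class `hrf_kernel`.
#' @export
gamma_hrf <- function(shape = 6, scale = 1, duration = 30, rate = 10) {
  if (shape <= 1 || scale <= 0) {
    stop("require shape > 1 and scale > 0", call. = FALSE)
  }
  peak <- (shape - 1) * scale
  if (duration < peak) {
    warning(sprintf("duration %g s truncates the kernel before its %g s peak",
                    duration, peak), call. = FALSE)
  }
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  h <- t^(shape - 1) * exp(-t / scale)
  h <- h / (sum(h) / rate)
  structure(list(shape = shape, scale = scale, duration = duration,
                 rate = rate, kernel = h, peak_time = peak),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("<hrf_kernel: shape %g, scale %g s, peak %g s, %d samples at %g Hz>\n",
              x$shape, x$scale, x$peak_time, length(x$kernel), x$rate))
  invisible(x)
}

#' Convolve a signal with an HRF kernel
#'
#' Causal linear convolution truncated to the input length; the output lags
#' the input by the kernel's peak time.  A unit step converges to the
#' kernel's (unit) area.
#'
#' @param sig A `fusion_timeseries` or `epoched_signal`.
#' @param kernel An [gamma_hrf()] kernel with a matching sampling rate.
#' @return The same container, convolved.
#' @export
convolve_hrf <- function(sig, kernel) {
  rate <- signal_rate(sig)
  if (abs(rate - kernel$rate) > 1e-6 * rate) {
    stop(sprintf("sampling rates differ: signal %g Hz vs kernel %g Hz",
                 rate, kernel$rate), call. = FALSE)
  }
  k <- kernel$kernel / rate   # absorb dt so a sustained input keeps scale
  v <- apply(sig$values, 2, fast_causal_conv, k = k)
  replace_values(sig, v)
}

#' Extract event-locked epochs
#'
#' For each marker, returns the samples falling in the half-open window
#' `[marker + start_s, marker + end_s)`, i.e. exactly
#' `round((end_s - start_s) * rate)` samples per epoch (3 s at 1000 Hz gives
#' 3000, 30 s at 10 Hz gives 300).  Markers whose window leaves the
#' recording are skipped with a warning and listed in the `"skipped"`
#' attribute.
#'
#' @param ts A `fusion_timeseries`.
#' @param markers Numeric vector of event times in seconds (or a data frame
#'   with a `time` column).
#' @param start_s,end_s Window bounds relative to each marker.
#' @return List of `epoched_signal` objects with attribute `skipped`.
#' @export
epoch_around_markers <- function(ts, markers, start_s, end_s) {
  if (is.data.frame(markers)) markers <- markers$time
  rate <- ts$rate
  n <- round((end_s - start_s) * rate)
  if (n == 0) warning("zero-length window: empty epochs", call. = FALSE)
  epochs <- list()
  skipped <- numeric(0)
  for (m in markers) {
    i0 <- round((m + start_s - ts$time[1]) * rate) + 1
    if (i0 < 1 || i0 + n - 1 > nrow(ts$values)) {
      skipped <- c(skipped, m)
      next
    }
    idx <- seq(i0, length.out = n)
    epochs[[length(epochs) + 1]] <-
      epoched_signal(ts$values[idx, , drop = FALSE], rate, start_s, end_s,
                     ts$channel_labels)
  }
  if (length(skipped) > 0) {
    warning(sprintf("%d marker(s) outside recording bounds skipped: %s",
                    length(skipped),
                    paste(format(skipped), collapse = ", ")),
            call. = FALSE)
  }
  attr(epochs, "skipped") <- skipped
  epochs
}

#' Average epochs across trials
#'
#' Pointwise mean across identically shaped epochs, optionally followed by
#' baseline correction (subtracting each channel's mean over a pre-marker
#' window, e.g. `c(-5, 0)` for the hemodynamic trials).
#'
#' @param epochs List of `epoched_signal` objects with identical shape,
#'   rate and window.
#' @param baseline Optional length-2 window (seconds, relative to the
#'   marker) whose per-channel mean is subtracted.
#' @return A single `epoched_signal`.
#' @export
average_trials <- function(epochs, baseline = NULL) {
  if (length(epochs) < 1) stop("need at least one epoch", call. = FALSE)
  ref <- epochs[[1]]
  for (e in epochs) {
    if (!identical(dim(e$values), dim(ref$values)) ||
        abs(e$rate - ref$rate) > 1e-9) {
      stop("epochs must share shape and sampling rate", call. = FALSE)
    }
  }
  acc <- Reduce(`+`, lapply(epochs, `[[`, "values")) / length(epochs)
  out <- replace_values(ref, acc)
  if (!is.null(baseline)) {
    t_axis <- ref$start + (seq_len(nrow(acc)) - 1) / ref$rate
    sel <- t_axis >= baseline[1] & t_axis < baseline[2]
    if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
    out$values <- sweep(out$values, 2, colMeans(acc[sel, , drop = FALSE]), "-")
  }
  out
}

# Fourier-domain resampling (ideal anti-alias filter): keep the lowest
# frequencies that fit in the target grid, respecting conjugate symmetry.
resample_fft <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  K <- min(n, m)
  half <- floor((K - 1) / 2)
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(m - half + 1):m] <- X[(n - half + 1):n]
  }
  if (K %% 2 == 0) {
    nyq <- K / 2 + 1
    if (m < n) {
      # fold the two source bins that alias onto the target Nyquist bin
      Y[nyq] <- X[nyq] + X[n - K / 2 + 1]
    } else {
      Y[nyq] <- X[nyq] / 2
      Y[m - K / 2 + 1] <- Conj(X[nyq]) / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample an epoch to an exact sample count
#'
#' Fourier-domain resampling (an ideal low-pass anti-alias filter) to
#' exactly `target_samples` rows; the window endpoints are preserved and
#' the rate is updated accordingly.  Used to bring the 3000-sample EEG
#' epochs onto the 300-sample hemodynamic grid.
#'
#' @param sig An `epoched_signal`.
#' @param target_samples Desired number of rows (>= 2).
#' @return An `epoched_signal` with `target_samples` rows.
#' @export
resample_to <- function(sig, target_samples) {
  if (target_samples < 2) stop("target_samples must be >= 2", call. = FALSE)
  n <- nrow(sig$values)
  if (target_samples > 100 * n) {
    stop("refusing to upsample beyond 100x (likely misconfiguration)",
         call. = FALSE)
  }
  if (target_samples == n) return(sig)
  v <- apply(sig$values, 2, resample_fft, m = target_samples)
  new_rate <- target_samples / (sig$end - sig$start)
  epoched_signal(v, new_rate, sig$start, sig$end, sig$channel_labels)
}

#' Build the commensurate EEG and fNIRS fusion matrices
#'
#' Runs the full feature-construction pipeline.  EEG: mu-band power via the
#' analytic envelope, inversion (so desynchronization maps to activation),
#' convolution with a gamma HRF, event-locked epoching, trial averaging,
#' and Fourier resampling onto the hemodynamic grid.  fNIRS: event-locked
#' epoching of the HbO traces, trial averaging with pre-stimulus baseline
#' correction, and aggregation of channels into ROI means.  The outputs
#' share the sample (time) dimension and feed the multiset solvers
#' directly.
#'
#' @param eeg,fnirs `fusion_timeseries` recordings.
#' @param eeg_markers,fnirs_markers Event times in seconds (vectors or data
#'   frames with a `time` column), the action-start convention at 0.
#' @param roi_map Data frame with columns `channel` and `roi` mapping fNIRS
#'   channels to region labels; ROI value = unweighted mean of member
#'   channels.
#' @param band Mu band edges in Hz.
#' @param hrf An [gamma_hrf()] kernel; `NULL` builds the default at the EEG
#'   rate.
#' @param eeg_window,fnirs_window Epoch windows in seconds.
#' @param target_samples Common number of rows for both matrices.
#' @param invert_mode Passed to [invert_power()].
#' @param baseline fNIRS baseline-correction window (default the
#'   pre-stimulus segment).
#' @return List with `E` and `N`, both `feature_matrix` objects with
#'   `set_id` `"EEG"` and `"fNIRS"`.
#' @export
assemble_fusion_matrices <- function(eeg, eeg_markers, fnirs, fnirs_markers,
                                     roi_map, band = c(8, 13), hrf = NULL,
                                     eeg_window = c(-1.5, 1.5),
                                     fnirs_window = c(-5, 25),
                                     target_samples = 300,
                                     invert_mode = "reciprocal",
                                     baseline = c(-5, 0)) {
  if (is.null(hrf)) gamma_kernel <- gamma_hrf(rate = eeg$rate)
  else gamma_kernel <- hrf
  pw <- mu_band_power(eeg, band[1], band[2])
  inv <- invert_power(pw, mode = invert_mode)
  conv <- convolve_hrf(inv, gamma_kernel)
  eeg_epochs <- epoch_around_markers(conv, eeg_markers,
                                     eeg_window[1], eeg_window[2])
  if (length(eeg_epochs) == 0) stop("no usable EEG epochs", call. = FALSE)
  eeg_avg <- average_trials(eeg_epochs)
  eeg_rs <- resample_to(eeg_avg, target_samples)
  E <- feature_matrix(eeg_rs$values, eeg$channel_labels, set_id = "EEG")

  fn_epochs <- epoch_around_markers(fnirs, fnirs_markers,
                                    fnirs_window[1], fnirs_window[2])
  if (length(fn_epochs) == 0) stop("no usable fNIRS epochs", call. = FALSE)
  fn_avg <- average_trials(fn_epochs, baseline = baseline)
  if (nrow(fn_avg$values) != target_samples) {
    fn_avg <- resample_to(fn_avg, target_samples)
  }
  rois <- unique(as.character(roi_map$roi))
  nmat <- vapply(rois, function(r) {
    chans <- as.character(roi_map$channel[roi_map$roi == r])
    missing <- setdiff(chans, fnirs$channel_labels)
    if (length(missing) > 0) {
      stop(sprintf("roi_map channels absent from fNIRS recording: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    rowMeans(fn_avg$values[, chans, drop = FALSE])
  }, numeric(nrow(fn_avg$values)))
  N <- feature_matrix(nmat, rois, set_id = "fNIRS")
  if (nrow(E$values) != nrow(N$values)) {
    stop(sprintf("row counts differ after resampling: E has %d, N has %d",
                 nrow(E$values), nrow(N$values)), call. = FALSE)
  }
  list(E = E, N = N)
}

#' Read a multichannel time series from delimited text
#'
#' First column is time in seconds; remaining columns are channels.
#' @param path File path.
#' @param sep Field separator.
#' @return A `fusion_timeseries`.
#' @export
read_timeseries <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  timeseries(df[[1]], as.matrix(df[, -1, drop = FALSE]),
             colnames(df)[-1])
}

#' Write a multichannel time series as delimited text
#' @param ts A `fusion_timeseries`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_timeseries <- function(ts, path, sep = "\t") {
  df <- data.frame(time = ts$time, ts$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event-marker file (columns: time, label)
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame with `time` and `label`.
#' @export
read_markers <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  names(df)[1:2] <- c("time", "label")
  df
}

#' Write an event-marker file
#' @param markers Numeric times or a data frame with `time` (and `label`).
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_markers <- function(markers, path, sep = "\t") {
  if (!is.data.frame(markers)) {
    markers <- data.frame(time = markers, label = "SA")
  }
  utils::write.table(markers, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a channel-to-ROI map (columns: channel, roi)
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame with `channel` and `roi`.
#' @export
read_roi_map <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  names(df)[1:2] <- c("channel", "roi")
  df
}
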
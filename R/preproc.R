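## Deterministic signal conditioning: zero-delay FIR filtering (windowed-sinc
## Hamming designs applied by FFT convolution with group-delay compensation),
## average re-referencing, fixed-length epoching and amplitude-threshold
## artifact rejection.

## Number of taps (odd) for a Hamming windowed-sinc design with the given
## transition bandwidth in Hz: the classic 3.3/(normalized width) rule.
fir_ntaps <- function(trans_hz, fs_hz) {
  n <- ceiling(3.3 * fs_hz / trans_hz)
  if (n %% 2 == 0) n <- n + 1
  n
}

## Apply a linear-phase FIR `h` (odd length) to each row of `x` by FFT
## convolution, compensating the (length-1)/2 sample group delay so the
## output is delay-free. Zero padding at the edges.
fir_apply <- function(x, h) {
  nt <- length(h)
  ns <- ncol(x)
  nfft <- stats::nextn(ns + nt - 1, c(2, 3, 5))
  H <- stats::fft(c(h, rep(0, nfft - nt)))
  X <- stats::mvfft(rbind(t(x), matrix(0, nfft - ns, nrow(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  d <- (nt - 1) / 2
  t(y[(d + 1):(d + ns), , drop = FALSE])
}

#' Zero-delay FIR band-pass filter
#'
#' Hamming windowed-sinc band-pass applied without phase delay. The
#' transition bandwidth is 25% of the lower edge, floored at 0.5 Hz, which
#' keeps slow drifts out without ringing across the band.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Pass-band edges in Hz, `0 < low < high < fs/2`.
#' @return A filtered [eeg_recording()].
#' @examples
#' rec <- eeg_recording(matrix(rnorm(32 * 500), 32), 250, montage_1010())
#' out <- bandpass_filter(rec, 2, 20)
#' @export
bandpass_filter <- function(rec, low_hz, high_hz) {
  fs <- rec$fs_hz
  stop_if(!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2),
          "band edges must satisfy 0 < low < high < fs/2 (got %g-%g at fs %g)",
          low_hz, high_hz, fs)
  trans <- max(0.25 * low_hz, 0.5)
  nt <- fir_ntaps(trans, fs)
  h <- signal::fir1(nt - 1, c(low_hz, high_hz) / (fs / 2), type = "pass")
  rec$data <- fir_apply(rec$data, h)
  rec
}

#' Zero-delay FIR notch filter
#'
#' Hamming windowed-sinc band-stop centred on a line frequency (default
#' width 5 Hz), for mains interference removal.
#'
#' @param rec An [eeg_recording()].
#' @param freq_hz Line frequency in Hz, `0 < freq < fs/2`.
#' @param width_hz Total stop-band width in Hz.
#' @return A filtered [eeg_recording()].
#' @export
notch_filter <- function(rec, freq_hz, width_hz = 5) {
  fs <- rec$fs_hz
  stop_if(!(freq_hz > 0 && freq_hz < fs / 2),
          "notch frequency must lie in (0, fs/2); got %g at fs %g", freq_hz, fs)
  half <- width_hz / 2
  stop_if(freq_hz - half <= 0 || freq_hz + half >= fs / 2,
          "notch band [%g, %g] must lie inside (0, fs/2)",
          freq_hz - half, freq_hz + half)
  nt <- fir_ntaps(half, fs)
  h <- signal::fir1(nt - 1, c(freq_hz - half, freq_hz + half) / (fs / 2),
                    type = "stop")
  rec$data <- fir_apply(rec$data, h)
  rec
}

#' Re-montage to the common average reference
#'
#' Subtracts the instantaneous mean across channels from every sample, so
#' each column of the data matrix sums to zero. Idempotent.
#'
#' @param rec An [eeg_recording()].
#' @return The re-referenced [eeg_recording()] with `reference = "average"`.
#' @export
rereference_average <- function(rec) {
  stop_if(n_channels(rec) < 2, "average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec$reference <- "average"
  rec
}

#' Cut a recording into consecutive fixed-length epochs
#'
#' Non-overlapping windows from the start of the recording; a trailing
#' remainder shorter than one epoch is discarded.
#'
#' @param rec An [eeg_recording()].
#' @param length_s Epoch duration in seconds.
#' @return An [eeg_epochs()] object.
#' @export
epoch_fixed_length <- function(rec, length_s) {
  ns_ep <- round(rec$fs_hz * length_s)
  n_ep <- n_samples(rec) %/% ns_ep
  stop_if(n_ep < 1, "recording (%d samples) is shorter than one %g-s epoch",
          n_samples(rec), length_s)
  eps <- lapply(seq_len(n_ep), function(i)
    rec$data[, ((i - 1) * ns_ep + 1):(i * ns_ep), drop = FALSE])
  eeg_epochs(eps, rec$fs_hz, length_s, montage = rec$montage)
}

#' Amplitude-threshold epoch rejection
#'
#' Marks every epoch containing any sample with absolute amplitude strictly
#' above the threshold as rejected (the threshold itself is kept). Epoch data
#' are left untouched; only `kept_mask` changes.
#'
#' @param ep An [eeg_epochs()] object.
#' @param threshold_uv Rejection threshold in microvolts (default 100).
#' @return The [eeg_epochs()] with an updated `kept_mask`.
#' @export
reject_artifacts_amplitude <- function(ep, threshold_uv = 100) {
  stop_if(threshold_uv <= 0, "threshold must be positive")
  ok <- vapply(ep$epochs, function(e) max(abs(e)) <= threshold_uv, logical(1))
  ep$kept_mask <- ep$kept_mask & ok
  ep
}
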
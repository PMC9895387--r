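#' EEG recording container
#'
#' A light container for multichannel EEG: a channels-by-samples matrix in
#' microvolts plus the sampling rate and montage. All package stages accept
#' and return this class.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs_hz Sampling rate in Hz.
#' @param montage Data frame with columns `name`, `x`, `y`, `z` (unit-sphere
#'   electrode positions), one row per channel; see [montage_1010()].
#' @param reference Reference tag, e.g. `"recorded"` or `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs_hz, montage, reference = "recorded") {
  data <- as.matrix(data)
  stop_if(!is.numeric(data) || any(!is.finite(data)),
          "recording data must be a finite numeric matrix")
  stop_if(!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0,
          "fs_hz must be a single positive number")
  stop_if(nrow(montage) != nrow(data),
          "montage has %d rows but data has %d channels",
          nrow(montage), nrow(data))
  structure(list(data = data, fs_hz = fs_hz, montage = montage,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs_hz,
              ncol(x$data) / x$fs_hz, x$reference))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Fixed-length epoch container
#'
#' @param epochs List of channels x samples matrices of equal shape.
#' @param fs_hz Sampling rate in Hz.
#' @param epoch_length_s Epoch duration in seconds.
#' @param kept_mask Logical vector, one flag per epoch (`TRUE` = retained).
#' @param montage Electrode montage (carried along for source analysis).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(epochs, fs_hz, epoch_length_s,
                       kept_mask = rep(TRUE, length(epochs)),
                       montage = NULL) {
  want <- round(fs_hz * epoch_length_s)
  ok <- vapply(epochs, function(e) ncol(e) == want, logical(1))
  stop_if(!all(ok), "every epoch must have exactly fs * epoch_length samples")
  stop_if(length(kept_mask) != length(epochs),
          "kept_mask length must equal the number of epochs")
  structure(list(epochs = epochs, fs_hz = fs_hz,
                 epoch_length_s = epoch_length_s, kept_mask = kept_mask,
                 montage = montage),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs of %g s @ %g Hz (%d kept)\n",
              length(x$epochs), x$epoch_length_s, x$fs_hz, sum(x$kept_mask)))
  invisible(x)
}

kept_epochs <- function(ep) ep$epochs[ep$kept_mask]
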
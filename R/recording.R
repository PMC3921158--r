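#' Multichannel recording container
#'
#' Holds a channels x samples signal matrix together with its sampling rate
#' and channel labels.
#'
#' @param signals numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `signals`.
#' @return Object of class `"eeg_recording"`: a list with `signals`,
#'   `sampling_rate`, `channel_labels`.
#' @export
recording <- function(signals, sampling_rate, channel_labels) {
  signals <- as.matrix(signals)
  channel_labels <- as.character(channel_labels)
  if (nrow(signals) != length(channel_labels))
    stop("number of signal rows (", nrow(signals),
         ") does not match number of channel labels (",
         length(channel_labels), ")")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (!all(is.finite(signals))) stop("signals contain non-finite values")
  rownames(signals) <- channel_labels
  structure(list(signals = signals,
                 sampling_rate = sampling_rate,
                 channel_labels = channel_labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$sampling_rate,
              ncol(x$signals) / x$sampling_rate))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$signals)
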
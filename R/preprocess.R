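#' Wrap phase angles to (-pi, pi]
#'
#' @param x numeric vector or matrix of angles in radians.
#' @return Angles wrapped to the half-open interval (-pi, pi\].
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass (forward-backward, so zero
#' phase distortion and no group delay) to every channel.
#'
#' @param rec an [recording()].
#' @param band a [band_def()]; edges must lie below the Nyquist frequency.
#' @return A filtered [recording()] of the same length.
#' @export
bandpass <- function(rec, band) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_def"))
  nyq <- rec$sampling_rate / 2
  if (band$high >= nyq)
    stop("band edge ", band$high, " Hz is at or above Nyquist (", nyq, " Hz)")
  bf <- signal::butter(2, c(band$low, band$high) / nyq, type = "pass")
  out <- t(filtfilt_columns(bf$b, bf$a, t(rec$signals)))
  r <- recording(out, rec$sampling_rate, rec$channel_labels)
  r$band <- band
  r
}

#' Cut a recording into fixed-length epochs
#'
#' Contiguous, non-overlapping epochs are taken from the start of the
#' recording, in order.
#'
#' @param rec an [recording()].
#' @param n_epochs number of epochs.
#' @param epoch_length epoch length in samples.
#' @return List of class `"epoched_recording"`: `epochs` (list of channels x
#'   epoch_length matrices), `sampling_rate`, `channel_labels`, `band`.
#' @export
make_epochs <- function(rec, n_epochs = 6, epoch_length = 4096) {
  stopifnot(inherits(rec, "eeg_recording"))
  need <- n_epochs * epoch_length
  have <- ncol(rec$signals)
  if (have < need)
    stop("recording has ", have, " samples but ", need,
         " are required for ", n_epochs, " epochs of ", epoch_length)
  epochs <- lapply(seq_len(n_epochs), function(e) {
    idx <- ((e - 1) * epoch_length + 1):(e * epoch_length)
    rec$signals[, idx, drop = FALSE]
  })
  structure(list(epochs = epochs,
                 sampling_rate = rec$sampling_rate,
                 channel_labels = rec$channel_labels,
                 band = rec$band),
            class = "epoched_recording")
}

# forward-backward IIR filtering of every column: identical arithmetic to
# signal::filtfilt (zero initial conditions, 2*max(na,nb) zero-padding at
# the tail), but one C-level pass over all channels at once
filtfilt_columns <- function(b, a, x) {
  b <- b / a[1]
  ar <- a / a[1]
  one_pass <- function(m) iir_filter_cols(b, ar, m)
  n <- nrow(x)
  npad <- 2 * max(length(ar), length(b))
  y <- one_pass(rbind(x, matrix(0, npad, ncol(x))))
  ny <- nrow(y)
  y <- one_pass(y[ny:1, , drop = FALSE])
  y[ny:1, , drop = FALSE][seq_len(n), , drop = FALSE]
}

# analytic signal of one real series via the frequency-domain Hilbert method
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the argument of the Hilbert-transform analytic signal for each
#' channel of one epoch. Phases are wrapped to (-pi, pi\]; a channel that
#' lags in time has negative phase difference relative to the leader.
#'
#' @param epoch numeric matrix, channels x samples.
#' @return Matrix of wrapped phases (radians), same shape, class
#'   `"phase_epoch"`.
#' @export
instantaneous_phase <- function(epoch) {
  epoch <- as.matrix(epoch)
  if (!all(is.finite(epoch))) stop("epoch contains non-finite samples")
  zero <- apply(epoch, 1, function(x) all(x == 0))
  if (any(zero))
    stop("phase undefined for all-zero channel(s): ",
         paste(which(zero), collapse = ", "))
  ph <- t(apply(epoch, 1, function(x) Arg(analytic_signal(x))))
  ph[ph <= -pi] <- pi               # Arg returns [-pi, pi]; wrap to (-pi, pi]
  rownames(ph) <- rownames(epoch)
  structure(ph, class = c("phase_epoch", class(ph)))
}

#' Band power per channel
#'
#' Mean squared amplitude of the band-limited signal, per channel, averaged
#' over epochs. Pass either an already band-filtered
#' `epoched_recording`, or a broadband [recording()] together with `band`
#' (it is then filtered and epoched internally).
#'
#' @param x an `epoched_recording` or an [recording()].
#' @param band a [band_def()]; required when `x` is an unfiltered recording.
#' @param n_epochs,epoch_length epoching geometry used when `x` is a
#'   recording.
#' @return Named numeric vector of per-channel power values.
#' @export
band_power <- function(x, band = NULL, n_epochs = 6, epoch_length = 4096) {
  if (inherits(x, "eeg_recording")) {
    if (is.null(band) && is.null(x$band))
      stop("band must be given for an unfiltered recording")
    if (!is.null(band)) x <- bandpass(x, band)
    x <- make_epochs(x, n_epochs, epoch_length)
  }
  stopifnot(inherits(x, "epoched_recording"))
  if (length(x$epochs) == 0) stop("no epochs to compute power from")
  p <- sapply(x$epochs, function(e) rowMeans(e^2))
  p <- if (is.matrix(p)) rowMeans(p) else mean(p)
  stats::setNames(as.numeric(p), x$channel_labels)
}
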
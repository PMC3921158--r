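#' Electrode montages and frequency bands
#'
#' `default_montage()` returns the 26-channel 10/20 montage used throughout
#' the package (Fp1 ... O2, 500 Hz). `montage()` builds a custom montage.
#'
#' @param labels character vector of unique channel labels, in recording order.
#' @param sampling_rate sampling rate in Hz.
#' @return A list with elements `labels` and `sampling_rate`, class `"montage"`.
#' @export
montage <- function(labels, sampling_rate = 500) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("montage labels must be unique")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  structure(list(labels = labels, sampling_rate = sampling_rate),
            class = "montage")
}

#' @rdname montage
#' @export
default_montage <- function() {
  montage(c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "FC1", "FCz", "FC2", "FC6",
            "T7", "C3", "Cz", "C4", "T8",
            "CP1", "CP2",
            "P7", "P3", "Pz", "P4", "P8",
            "O1", "Oz", "O2"),
          sampling_rate = 500)
}

#' Frontal and posterior electrode clusters
#'
#' Default clusters for short-range (within-cluster) and long-range
#' (fronto-posterior) connectivity summaries: 7 frontal and 6
#' parietal/occipital electrodes, giving 21 within-frontal, 15
#' within-posterior and 42 cross pairs.
#'
#' @return Named list with character vectors `frontal` and `posterior`.
#' @export
default_clusters <- function() {
  list(frontal   = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"),
       posterior = c("P3", "Pz", "P4", "O1", "Oz", "O2"))
}

#' Frequency band definition
#'
#' @param name band name.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return List with `name`, `low`, `high`, class `"band_def"`.
#' @export
band_def <- function(name, low, high) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low)
    stop("band edges must satisfy 0 < low < high")
  structure(list(name = as.character(name), low = low, high = high),
            class = "band_def")
}

#' Canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha_low 8-10, alpha_high 10-13, beta 13-30,
#' gamma 30-45 Hz.
#'
#' @return Named list of [band_def()] objects.
#' @export
eeg_bands <- function() {
  list(delta      = band_def("delta", 0.5, 4),
       theta      = band_def("theta", 4, 8),
       alpha_low  = band_def("alpha_low", 8, 10),
       alpha_high = band_def("alpha_high", 10, 13),
       beta       = band_def("beta", 13, 30),
       gamma      = band_def("gamma", 30, 45))
}
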
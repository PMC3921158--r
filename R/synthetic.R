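#' Simulation configuration for synthetic EEG cohorts
#'
#' Defines the geometry and spectral content of a synthetic multichannel
#' recording. Each channel is a sum of band-limited phase-diffusion
#' oscillators (one per entry of `band_components`) plus 1/f background
#' noise. Pairwise phase-lag coupling is added separately via
#' [coupling_spec()].
#'
#' @param n_channels number of channels.
#' @param sampling_rate sampling rate in Hz.
#' @param duration recording length in seconds. The default gives exactly
#'   six 4096-sample epochs at 500 Hz.
#' @param channel_labels channel labels; length must equal `n_channels`.
#' @param band_components data frame with columns `band` (name), `freq`
#'   (center frequency, Hz), `amplitude` (>= 0) and `sigma` (phase-diffusion
#'   standard deviation, rad/sqrt(sample)). See [default_band_components()].
#' @param noise_amplitude scale of the 1/f background noise (unit-variance
#'   pink noise multiplied by this factor).
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(n_channels = 26,
                              sampling_rate = 500,
                              duration = 6 * 4096 / 500,
                              channel_labels = default_montage()$labels,
                              band_components = default_band_components(),
                              noise_amplitude = 0.2) {
  if (length(channel_labels) != n_channels)
    stop("n_channels (", n_channels, ") does not match length of channel_labels (",
         length(channel_labels), ")")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (duration <= 0) stop("duration must be positive")
  req <- c("band", "freq", "amplitude", "sigma")
  if (!all(req %in% names(band_components)))
    stop("band_components must have columns: ", paste(req, collapse = ", "))
  if (is.null(band_components$freq_jitter)) band_components$freq_jitter <- 0
  if (any(band_components$amplitude < 0)) stop("amplitudes must be >= 0")
  if (any(band_components$sigma < 0)) stop("sigma must be >= 0")
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  structure(list(n_channels = n_channels,
                 sampling_rate = sampling_rate,
                 duration = duration,
                 channel_labels = as.character(channel_labels),
                 band_components = band_components,
                 noise_amplitude = noise_amplitude),
            class = "simulation_config")
}

#' Default oscillator components, one per canonical band
#'
#' Center frequencies sit at the band midpoints. Two noise scales keep the
#' components band-limited while still decorrelating uncoupled channels
#' within one 4096-sample epoch: a modest phase diffusion (sigma 0.12
#' rad/sqrt(sample), about 1 Hz linewidth at 500 Hz) and a per-channel
#' center-frequency jitter (`freq_jitter`, sd in Hz, emulating individual
#' peak-frequency variation) whose linear phase drift makes the signs of
#' uncoupled phase differences cancel over an epoch.
#'
#' @return data.frame with columns `band`, `freq`, `amplitude`, `sigma`,
#'   `freq_jitter`.
#' @export
default_band_components <- function() {
  freq <- c(2.25, 6, 9, 11.5, 21.5, 37.5)
  data.frame(band = c("delta", "theta", "alpha_low", "alpha_high", "beta", "gamma"),
             freq = freq,
             amplitude = 1,
             sigma = 0.15,
             freq_jitter = pmin(pmax(1.2, 0.1 * freq), 0.45 * freq),
             stringsAsFactors = FALSE)
}

#' Pairwise phase-lag coupling specification
#'
#' Couples the band-specific phase of a follower channel to the phase of a
#' leader channel minus `phase_lag`. At `strength = 1` (and zero phase
#' diffusion) the pair maintains a constant nonzero lag, giving PLI = 1
#' downstream; at `strength = 0` the phases are independent.
#'
#' @param pair character vector of two distinct channel labels,
#'   `c(leader, follower)`.
#' @param band band name, matching a row of the config's `band_components`.
#' @param strength coupling strength in \[0, 1\].
#' @param phase_lag phase lag in radians, in (-pi, pi\]; must be nonzero for
#'   the coupling to be visible to the PLI.
#' @return List of class `"coupling_spec"`.
#' @export
coupling_spec <- function(pair, band, strength, phase_lag = pi / 3) {
  pair <- as.character(pair)
  if (length(pair) != 2 || pair[1] == pair[2])
    stop("pair must be two distinct channel labels")
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  if (phase_lag <= -pi || phase_lag > pi) stop("phase_lag must be in (-pi, pi]")
  structure(list(pair = pair, band = as.character(band),
                 strength = strength, phase_lag = phase_lag),
            class = "coupling_spec")
}

# unit-variance 1/f (pink) noise via spectrally shaped white noise
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  fmag <- pmin(k, n - k)            # two-sided frequency magnitude (bins)
  s <- ifelse(fmag == 0, 0, 1 / sqrt(fmag))
  x <- Re(stats::fft(W * s, inverse = TRUE) / n)
  x / stats::sd(x)
}

# deterministic per-subject seed: Lehmer-style hash of (master, index),
# exact in doubles, result in [1, 2^31 - 2]
subject_seed <- function(master, index) {
  m <- as.numeric(master) %% 2147483647
  h <- (m * 48271) %% 2147483647
  h <- (h + as.numeric(index) * 104729) %% 2147483647
  as.integer(h + 1)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  expr
}

#' Generate a synthetic multichannel recording
#'
#' Each channel c carries, for every band component b, a phase process
#' \eqn{\theta_{cb}(t+1) = \theta_{cb}(t) + 2\pi f_{cb} / f_s + \sigma_b \epsilon_t}
#' (Gaussian phase diffusion around a per-channel center frequency
#' \eqn{f_{cb} = f_b + } jitter drawn once per channel). A
#' [coupling_spec()] replaces the follower's band phase by the argument of
#' the weighted circular mixture
#' \eqn{(1-s)\,e^{i\theta_{free}} + s\,e^{i(\theta_{leader} - lag)}},
#' so phase tracking tightens monotonically with strength `s`. The signal is
#' the amplitude-weighted sum of the band cosines plus 1/f noise.
#'
#' Identical `(config, couplings, seed)` give bit-identical output; the
#' caller's RNG state is left untouched.
#'
#' @param config a [simulation_config()].
#' @param couplings list of [coupling_spec()], applied in order.
#' @param seed integer seed.
#' @param keep_phases if `TRUE`, the returned recording carries the
#'   oscillator phase matrices (wrapped, channels x samples, one per band)
#'   in element `phases`.
#' @return An [recording()] object (with `$phases` when `keep_phases`).
#' @export
generate_recording <- function(config, couplings = list(), seed,
                               keep_phases = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (missing(seed)) stop("seed is required")
  if (inherits(couplings, "coupling_spec")) couplings <- list(couplings)
  labels <- config$channel_labels
  comps <- config$band_components
  for (cs in couplings) {
    if (!all(cs$pair %in% labels))
      stop("unknown channel label in coupling: ",
           paste(setdiff(cs$pair, labels), collapse = ", "))
    if (!cs$band %in% comps$band)
      stop("coupling references band '", cs$band,
           "' absent from band_components")
  }
  fs <- config$sampling_rate
  nsamp <- floor(config$duration * fs)
  nch <- config$n_channels

  with_preserved_rng({
    set.seed(as.integer(seed))
    phases <- list()
    for (b in seq_len(nrow(comps))) {
      ph <- matrix(0, nch, nsamp, dimnames = list(labels, NULL))
      for (ch in seq_len(nch)) {
        f <- comps$freq[b] + comps$freq_jitter[b] * stats::rnorm(1)
        ph[ch, ] <- stats::runif(1, -pi, pi) +
          cumsum(2 * pi * f / fs + comps$sigma[b] * stats::rnorm(nsamp))
      }
      phases[[comps$band[b]]] <- ph
    }
    for (cs in couplings) {
      il <- match(cs$pair[1], labels)
      jf <- match(cs$pair[2], labels)
      s <- cs$strength
      ph <- phases[[cs$band]]
      pinned <- ph[il, ] - cs$phase_lag
      ph[jf, ] <- Arg((1 - s) * exp(1i * ph[jf, ]) + s * exp(1i * pinned))
      phases[[cs$band]] <- ph
    }
    signals <- matrix(0, nch, nsamp)
    for (b in seq_len(nrow(comps)))
      signals <- signals + comps$amplitude[b] * cos(phases[[comps$band[b]]])
    if (config$noise_amplitude > 0)
      for (ch in seq_len(nch))
        signals[ch, ] <- signals[ch, ] + config$noise_amplitude * pink_noise(nsamp)

    rec <- recording(signals, fs, labels)
    if (keep_phases) rec$phases <- lapply(phases, wrap_phase)
    rec
  })
}

#' Apply an instantaneous (zero-lag) mixing matrix
#'
#' Models volume conduction / common sources: every output sample vector is
#' `mixing %*%` the input sample vector, with no temporal delay. The
#' identity matrix returns the input unchanged.
#'
#' @param rec an [recording()].
#' @param mixing numeric `n_channels x n_channels` matrix of finite weights.
#' @return A new [recording()] with mixed signals.
#' @export
apply_mixing <- function(rec, mixing) {
  stopifnot(inherits(rec, "eeg_recording"))
  mixing <- as.matrix(mixing)
  nch <- nrow(rec$signals)
  if (!all(dim(mixing) == c(nch, nch)))
    stop("mixing matrix is ", nrow(mixing), "x", ncol(mixing),
         " but recording has ", nch, " channels")
  if (!all(is.finite(mixing))) stop("mixing matrix has non-finite entries")
  recording(mixing %*% rec$signals, rec$sampling_rate, rec$channel_labels)
}

#' Group template: a simulation config plus its couplings
#'
#' @param label group name.
#' @param base_config a [simulation_config()].
#' @param couplings list of [coupling_spec()].
#' @return List of class `"group_template"`.
#' @export
group_template <- function(label, base_config = simulation_config(),
                           couplings = list()) {
  stopifnot(inherits(base_config, "simulation_config"))
  if (inherits(couplings, "coupling_spec")) couplings <- list(couplings)
  for (cs in couplings)
    if (!all(cs$pair %in% base_config$channel_labels))
      stop("coupling references labels absent from the montage: ",
           paste(setdiff(cs$pair, base_config$channel_labels), collapse = ", "))
  structure(list(label = as.character(label),
                 base_config = base_config,
                 couplings = couplings),
            class = "group_template")
}

# shared coupling structure; the two templates differ only in strengths.
# Each band couples a hub leader to several followers with distinct lags:
# every pair inside the block then holds a constant nonzero phase
# difference, so the realized PLI matrix carries a dense synchronized
# block (hub + followers) rather than scattered strong edges. Lags are
# spaced so no pairwise difference sits near 0 or pi.
template_hubs <- function() {
  list(theta = list(leader = "Fz",
                    followers = c("P3", "Pz", "P4", "O1", "O2"),
                    lags = c(0.9, -0.9, 1.8, -1.8, 2.7)),
       alpha_high = list(leader = "Oz",
                         followers = c("O1", "O2", "Pz", "P3", "P4"),
                         lags = c(0.9, -0.9, 1.8, -1.8, 2.7)),
       beta = list(leader = "Cz",
                   followers = c("Fz", "C3", "C4", "Pz", "CP1"),
                   lags = c(0.9, -0.9, 1.8, -1.8, 2.7)))
}

#' Couplings for the built-in hub structure at chosen strengths
#'
#' Builds the [coupling_spec()] list of the built-in per-band hub-star
#' coupling structure (see [fxs_like_template()]) with the given per-band
#' strengths, e.g. `list(theta = 0.6, beta = 0.2)`. Bands not named get no
#' couplings.
#'
#' @param strengths named list or vector of coupling strengths in \[0, 1\].
#' @return List of [coupling_spec()].
#' @export
template_couplings <- function(strengths) {
  hubs <- template_hubs()
  out <- list()
  for (band in intersect(names(hubs), names(strengths))) {
    h <- hubs[[band]]
    for (k in seq_along(h$followers))
      out[[length(out) + 1]] <-
        coupling_spec(c(h$leader, h$followers[k]), band,
                      strengths[[band]], h$lags[k])
  }
  out
}

#' Built-in cohort templates
#'
#' Two group templates over identical coupling pair sets that differ only in
#' coupling strength, emulating the contrast between a fragile-X-like group
#' (elevated theta fronto-posterior and posterior coupling; reduced
#' upper-alpha and beta coupling) and a control-like group (the reverse).
#'
#' @param base_config a [simulation_config()] (default montage).
#' @return A [group_template()].
#' @export
fxs_like_template <- function(base_config = simulation_config()) {
  group_template("fxs_like", base_config,
                 template_couplings(list(theta = 0.6, alpha_high = 0.15,
                                         beta = 0.15)))
}

#' @rdname fxs_like_template
#' @export
control_like_template <- function(base_config = simulation_config()) {
  group_template("control_like", base_config,
                 template_couplings(list(theta = 0.15, alpha_high = 0.5,
                                         beta = 0.5)))
}

#' Generate a two-group synthetic cohort
#'
#' Per-subject seeds are derived deterministically from the master seed and
#' the subject index, so cohorts are reproducible and subjects independent.
#'
#' @param template_a,template_b [group_template()] objects.
#' @param n_per_group subjects per group: a single count used for both
#'   groups, or a length-2 vector `c(n_a, n_b)`.
#' @param seed master integer seed.
#' @return List of class `"eeg_cohort"` with element `subjects`, each a list
#'   `id`, `group`, `seed`, `recording`.
#' @export
generate_cohort <- function(template_a, template_b, n_per_group, seed) {
  stopifnot(inherits(template_a, "group_template"),
            inherits(template_b, "group_template"))
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  if (any(n_per_group < 0)) stop("n_per_group must be >= 0")
  subjects <- list()
  idx <- 0
  for (g in 1:2) {
    tpl <- if (g == 1) template_a else template_b
    for (k in seq_len(n_per_group[g])) {
      idx <- idx + 1
      sseed <- subject_seed(seed, idx)
      subjects[[idx]] <- list(
        id = sprintf("S%02d", idx),
        group = tpl$label,
        seed = sseed,
        recording = generate_recording(tpl$base_config, tpl$couplings, sseed))
    }
  }
  structure(list(subjects = subjects,
                 groups = c(template_a$label, template_b$label),
                 seed = as.integer(seed)),
            class = "eeg_cohort")
}
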
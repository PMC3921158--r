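#' Phase lag index of two phase series
#'
#' PLI = | mean over t of sign(dphi_t) | where dphi is the phase difference
#' wrapped to (-pi, pi] and sign(0) = 0. Values range from 0 (no coupling,
#' or coupling centered on zero / pi lag) to 1 (perfect nonzero-lag phase
#' locking). Symmetric in its arguments.
#'
#' @param phase_a,phase_b numeric vectors of wrapped phases, equal length
#'   >= 2.
#' @return Scalar in \[0, 1\].
#' @export
pli <- function(phase_a, phase_b) {
  check_phase_pair(phase_a, phase_b)
  abs(mean(sign(wrap_phase(phase_a - phase_b))))
}

#' Directed phase lag index
#'
#' dPLI = mean over t of H(dphi_t) with the Heaviside step H(0) = 0.5.
#' Values above 0.5 mean the first channel is phase leading; below 0.5,
#' lagging. Satisfies `dpli(a, b) + dpli(b, a) = 1` and
#' `|2 * dpli - 1| == pli` exactly.
#'
#' @inheritParams pli
#' @return Scalar in \[0, 1\].
#' @export
dpli <- function(phase_a, phase_b) {
  check_phase_pair(phase_a, phase_b)
  d <- wrap_phase(phase_a - phase_b)
  mean((d > 0) + 0.5 * (d == 0))
}

check_phase_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("phase series lengths differ: ", length(a), " vs ", length(b))
  if (length(a) < 2) stop("phase series must have length >= 2")
  invisible(TRUE)
}

# all-pairs PLI or dPLI for one phase epoch (channels x samples).
# The compiled kernel uses sign(wrapped(a - b)) == sign(sin(a - b)), which
# avoids explicit rewrapping in the pair loop; sign(0) = 0 / H(0) = 0.5
# conventions match pli() and dpli() exactly.
epoch_connectivity <- function(phases, measure = c("pli", "dpli")) {
  measure <- match.arg(measure)
  m <- phase_pair_matrix(unclass(phases), if (measure == "pli") 0L else 1L)
  dimnames(m) <- list(rownames(phases), rownames(phases))
  m
}

#' Subject-level connectivity matrix
#'
#' Computes an N x N PLI (or dPLI) matrix for each epoch and averages them
#' entrywise. The diagonal is zero.
#'
#' @param phases a `phase_epoch` matrix or a list of them (consistent
#'   channel sets).
#' @param measure `"pli"` (default) or `"dpli"`.
#' @param band optional [band_def()] recorded as an attribute.
#' @return N x N numeric matrix of class `"conn_matrix"` with attributes
#'   `measure`, `band` and `n_epochs`.
#' @export
connectivity_matrix <- function(phases, measure = c("pli", "dpli"), band = NULL) {
  measure <- match.arg(measure)
  if (is.matrix(phases)) phases <- list(phases)
  if (length(phases) == 0) stop("at least one phase epoch is required")
  labs <- rownames(phases[[1]])
  dims <- dim(phases[[1]])
  for (p in phases) {
    if (!identical(dim(p), dims) || !identical(rownames(p), labs))
      stop("inconsistent channel sets across epochs")
  }
  mats <- lapply(phases, epoch_connectivity, measure = measure)
  m <- Reduce(`+`, mats) / length(mats)
  structure(m, class = c("conn_matrix", "matrix", "array"),
            measure = measure, band = band, n_epochs = length(mats))
}

#' Global mean PLI
#'
#' Arithmetic mean of the upper-triangle off-diagonal entries of a
#' symmetric PLI matrix ("averaged over all pairs of EEG channels").
#' Defined for PLI only; a dPLI matrix is rejected.
#'
#' @param m a symmetric connectivity matrix (class `conn_matrix` or plain).
#' @return Scalar mean PLI.
#' @export
global_mean_pli <- function(m) {
  if (identical(attr(m, "measure"), "dpli"))
    stop("global mean is defined for PLI matrices, not dPLI")
  m <- unclass(m)
  if (!isSymmetric(unname(m), tol = 1e-12))
    stop("global mean requires a symmetric PLI matrix")
  mean(m[upper.tri(m)])
}

#' Frontal/posterior cluster connectivity summaries
#'
#' Short-range connectivity is the mean PLI over all within-cluster pairs;
#' long-range connectivity the mean over all frontal x posterior pairs.
#' With the default clusters the pair counts are 21 (frontal), 15
#' (posterior) and 42 (long-range).
#'
#' @param m connectivity matrix with channel labels as dimnames.
#' @param frontal,posterior character vectors of electrode labels; defaults
#'   from [default_clusters()]. Must not overlap.
#' @return List with `frontal_short`, `posterior_short`, `long_range` and
#'   `n_pairs` (named count vector).
#' @export
cluster_means <- function(m, frontal = default_clusters()$frontal,
                          posterior = default_clusters()$posterior) {
  labs <- rownames(m)
  if (is.null(labs)) stop("connectivity matrix must carry channel labels")
  missing <- setdiff(c(frontal, posterior), labs)
  if (length(missing) > 0)
    stop("unknown cluster label(s): ", paste(missing, collapse = ", "))
  if (length(intersect(frontal, posterior)) > 0)
    stop("clusters overlap: ",
         paste(intersect(frontal, posterior), collapse = ", "))
  m <- unclass(m)
  within_mean <- function(cl) {
    sub <- m[cl, cl, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  list(frontal_short = within_mean(frontal),
       posterior_short = within_mean(posterior),
       long_range = mean(m[frontal, posterior]),
       n_pairs = c(frontal_short = choose(length(frontal), 2),
                   posterior_short = choose(length(posterior), 2),
                   long_range = length(frontal) * length(posterior)))
}

#' Band connectivity for one recording
#'
#' Convenience chain: zero-phase band-pass, epoching, analytic-signal
#' phases, per-epoch PLI/dPLI matrices and their epoch mean.
#'
#' @param rec an [recording()].
#' @param band a [band_def()].
#' @param measure `"pli"` or `"dpli"`.
#' @param n_epochs,epoch_length epoching geometry.
#' @return List with `matrix` (epoch-mean `conn_matrix`) and
#'   `epoch_matrices` (list of per-epoch matrices).
#' @export
subject_connectivity <- function(rec, band, measure = "pli",
                                 n_epochs = 6, epoch_length = 4096) {
  ep <- make_epochs(bandpass(rec, band), n_epochs, epoch_length)
  phases <- lapply(ep$epochs, instantaneous_phase)
  mats <- lapply(phases, epoch_connectivity, measure = measure)
  m <- Reduce(`+`, mats) / length(mats)
  m <- structure(m, class = c("conn_matrix", "matrix", "array"),
                 measure = measure, band = band, n_epochs = length(mats))
  list(matrix = m, epoch_matrices = mats)
}
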
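# independent reference implementations used to cross-check the package

wrap_ref <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

pli_ref <- function(a, b) abs(mean(sign(wrap_ref(a - b))))

# naive triple-loop weighted clustering coefficient
clustering_oracle <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    num <- 0; den <- 0
    for (k in seq_len(n)) for (l in seq_len(n)) {
      if (k == l || k == i || l == i) next
      num <- num + w[i, k] * w[k, l] * w[l, i]
      den <- den + w[i, k] * w[i, l]
    }
    if (den > 0) num / den else 0
  })
}

# exhaustive shortest-path oracle: minimum of 1/w sums over all simple
# paths between every pair (feasible for n <= 7)
path_length_oracle <- function(w) {
  n <- nrow(w)
  len <- 1 / w
  best <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    others <- setdiff(seq_len(n), c(i, j))
    d <- if (is.finite(len[i, j])) len[i, j] else Inf
    for (k in 0:length(others)) {
      combos <- if (k == 0) list(integer(0)) else combn(others, k, simplify = FALSE)
      for (mid in combos) {
        perms <- if (k <= 1) list(mid) else perms_of(mid)
        for (p in perms) {
          nodes <- c(i, p, j)
          cost <- sum(len[cbind(nodes[-length(nodes)], nodes[-1])])
          if (cost < d) d <- cost
        }
      }
    }
    best[i, j] <- best[j, i] <- d
  }
  diag(best) <- 0
  mean(rowSums(best) / (n - 1))
}

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# random symmetric weight matrix with zero diagonal
random_weight_matrix <- function(n, lo = 0.05, hi = 1) {
  w <- matrix(stats::runif(n * n, lo, hi), n, n)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 0
  w
}

# mean magnitude-squared coherence of a two-channel recording within a band
band_coherence <- function(rec, band) {
  sp <- stats::spec.pgram(stats::ts(t(rec$signals), frequency = rec$sampling_rate),
                          spans = c(31, 31), taper = 0, plot = FALSE)
  keep <- sp$freq >= band$low & sp$freq <= band$high
  mean(sp$coh[keep])
}

# tiny test montage/config helpers
two_channel_config <- function(duration = 4096 / 500, ...) {
  simulation_config(n_channels = 2, channel_labels = c("A", "B"),
                    duration = duration, ...)
}
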
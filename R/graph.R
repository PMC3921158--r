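validate_weight_matrix <- function(w) {
  w <- unclass(as.matrix(w))
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (!isSymmetric(unname(w), tol = 1e-12)) stop("weight matrix must be symmetric")
  if (any(diag(w) != 0)) stop("weight matrix must have a zero diagonal")
  if (any(w < 0) || any(w > 1)) stop("weights must lie in [0, 1]")
  w
}

# clustering without validation; numerator diag(W^3) = rowSums((WW) * W)
# because W is symmetric with zero diagonal (terms k = l, k = i, l = i
# vanish); denominator (sum_k w_ik)^2 - sum_k w_ik^2
clustering_fast <- function(w) {
  num <- rowSums((w %*% w) * w)
  s <- rowSums(w)
  den <- s^2 - rowSums(w^2)
  ifelse(den > 0, num / den, 0)
}

path_length_fast <- function(w) {
  len <- 1 / w
  diag(len) <- 0
  d <- all_pairs_dijkstra(len)
  n <- nrow(w)
  mean(rowSums(d) / (n - 1))
}

#' Weighted clustering coefficient of a node
#'
#' For node i with symmetric weights w in \[0, 1\]:
#' \deqn{C_i = \frac{\sum_{k \ne l} w_{ik} w_{kl} w_{li}}{\sum_{k \ne l} w_{ik} w_{il}}}
#' (terms with k = i or l = i excluded). For isolated vertices
#' (zero denominator) the coefficient is defined as 0.
#'
#' @param w symmetric N x N weight matrix, zero diagonal, entries in \[0, 1\]
#'   (a PLI matrix qualifies).
#' @param node node index or label.
#' @return Clustering coefficient in \[0, 1\].
#' @export
node_clustering <- function(w, node) {
  cc <- clustering_coefficients(w)
  if (is.character(node)) {
    if (!node %in% names(cc)) stop("unknown node: ", node)
    cc[[node]]
  } else {
    if (node < 1 || node > length(cc)) stop("unknown node: ", node)
    cc[[node]]
  }
}

#' @rdname node_clustering
#' @return `clustering_coefficients()`: named vector of all N coefficients.
#' @export
clustering_coefficients <- function(w) {
  w <- validate_weight_matrix(w)
  cc <- clustering_fast(w)
  names(cc) <- rownames(w)
  cc
}

#' Mean weighted clustering coefficient
#'
#' Arithmetic mean of [clustering_coefficients()] over all N nodes.
#'
#' @inheritParams node_clustering
#' @return Scalar in \[0, 1\].
#' @export
mean_clustering <- function(w) {
  if (length(w) == 0 || nrow(as.matrix(w)) == 0) stop("empty graph")
  mean(clustering_coefficients(w))
}

#' Mean weighted path length
#'
#' Edge lengths are the inverse of the weights; the distance between two
#' nodes is the minimal sum of edge lengths over connecting paths
#' (Dijkstra's algorithm). The per-node path length L_i is the arithmetic
#' mean of distances from i to all other nodes (self-distances excluded),
#' and L is the mean of L_i over nodes. Zero-weight edges are treated as
#' absent; if this disconnects the graph an error names an unreachable
#' pair.
#'
#' @inheritParams node_clustering
#' @return Scalar mean shortest path length.
#' @export
mean_path_length <- function(w) {
  w <- validate_weight_matrix(w)
  n <- nrow(w)
  if (n < 2) stop("path length requires at least two nodes")
  len <- 1 / w
  diag(len) <- 0
  d <- all_pairs_dijkstra(len)
  if (any(is.infinite(d))) {
    bad <- which(is.infinite(d), arr.ind = TRUE)[1, ]
    labs <- rownames(w)
    nm <- if (is.null(labs)) paste(bad, collapse = ", ")
          else paste(labs[bad], collapse = ", ")
    stop("graph is disconnected: no path between nodes ", nm)
  }
  mean(rowSums(d) / (n - 1))
}

#' Edge-shuffled surrogate network
#'
#' Uniformly permutes the upper-triangle edge weights and mirrors them to
#' the lower triangle, preserving the weight multiset exactly (the null
#' model used for normalizing graph metrics).
#'
#' @inheritParams node_clustering
#' @return Weight matrix of the same size, symmetric, zero diagonal.
#' @export
shuffle_surrogate <- function(w) {
  w <- validate_weight_matrix(w)
  n <- nrow(w)
  up <- upper.tri(w)
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[up] <- sample(w[up])
  out + t(out)
}

#' Graph metrics normalized against edge-shuffled surrogates
#'
#' Computes the mean weighted clustering coefficient Cw and mean weighted
#' path length Lw of the graph, then divides each by its mean over
#' `n_surrogates` edge-shuffled surrogate networks. The small-world index
#' is S = (Cw / Cw_surr) / (Lw / Lw_surr); values above 1 together with
#' normalized clustering above 1 indicate small-world organization. A
#' surrogate that happens to be disconnected (possible only when zero
#' weights are present) is resampled and counted in `n_resampled`.
#'
#' @inheritParams node_clustering
#' @param n_surrogates number of surrogate networks (default 50).
#' @param seed optional integer seed for the surrogate stream; when given,
#'   the caller's RNG state is untouched.
#' @return List of class `"graph_metrics"`: `clustering`, `path_length`,
#'   `clustering_norm`, `path_length_norm`, `small_world`, `n_surrogates`,
#'   `n_resampled`.
#' @export
normalize_metrics <- function(w, n_surrogates = 50, seed = NULL) {
  w <- validate_weight_matrix(w)
  n <- nrow(w)
  if (n < 2) stop("graph metrics require at least two nodes")
  cw <- mean(clustering_fast(w))
  lw <- path_length_fast(w)
  if (!is.finite(lw)) return(mean_path_length(w))  # raises the naming error
  up <- upper.tri(w)
  weights_up <- w[up]
  all_positive <- all(weights_up > 0)
  run <- function() {
    cs <- numeric(n_surrogates)
    ls <- numeric(n_surrogates)
    resampled <- 0L
    tmpl <- matrix(0, n, n)
    for (k in seq_len(n_surrogates)) {
      repeat {
        s <- tmpl
        s[up] <- sample(weights_up)
        s <- s + t(s)
        l <- path_length_fast(s)
        if (is.finite(l)) break
        resampled <- resampled + 1L
        if (resampled > 100 * n_surrogates)
          stop("could not draw a connected surrogate network")
      }
      cs[k] <- mean(clustering_fast(s))
      ls[k] <- l
    }
    if (resampled > 0)
      message(resampled, " disconnected surrogate(s) resampled")
    list(cs = mean(cs), ls = mean(ls), resampled = resampled)
  }
  sur <- if (is.null(seed)) run() else with_preserved_rng({
    set.seed(as.integer(seed))
    run()
  })
  cn <- cw / sur$cs
  ln <- lw / sur$ls
  structure(list(clustering = cw,
                 path_length = lw,
                 clustering_norm = cn,
                 path_length_norm = ln,
                 small_world = cn / ln,
                 n_surrogates = n_surrogates,
                 n_resampled = sur$resampled),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(paste0("<graph_metrics> Cw = %.4f  Lw = %.4f  ",
                     "Cw/Cw_s = %.4f  Lw/Lw_s = %.4f  S = %.4f  (%d surrogates)\n"),
              x$clustering, x$path_length, x$clustering_norm,
              x$path_length_norm, x$small_world, x$n_surrogates))
  invisible(x)
}

#' Export / import a weighted graph as an edge list
#'
#' Tab-delimited table with columns `node_i`, `node_j`, `weight`, one row
#' per unordered pair (upper triangle).
#'
#' @param w symmetric weight matrix with node labels as dimnames.
#' @param path file path.
#' @return `write_edge_list()` returns `path` invisibly; `read_edge_list()`
#'   the reconstructed symmetric matrix.
#' @export
write_edge_list <- function(w, path) {
  w <- validate_weight_matrix(w)
  labs <- rownames(w)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(w)))
  ij <- which(upper.tri(w), arr.ind = TRUE)
  df <- data.frame(node_i = labs[ij[, 1]], node_j = labs[ij[, 2]],
                   weight = sprintf("%.17g", w[ij]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  labs <- unique(c(df$node_i, df$node_j))
  n <- length(labs)
  w <- matrix(0, n, n, dimnames = list(labs, labs))
  for (r in seq_len(nrow(df)))
    w[df$node_i[r], df$node_j[r]] <- w[df$node_j[r], df$node_i[r]] <- df$weight[r]
  w
}
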
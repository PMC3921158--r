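test_that("weighted clustering matches hand calculations", {
  # uniform complete graph: every node's coefficient equals the weight
  w <- matrix(0.5, 6, 6); diag(w) <- 0
  expect_equal(unname(clustering_coefficients(w)), rep(0.5, 6), tolerance = 1e-12)
  expect_equal(mean_clustering(w), 0.5, tolerance = 1e-12)
  # star: hub triangles all contain a zero leaf-leaf weight
  s <- matrix(0, 5, 5); s[1, 2:5] <- 1; s <- s + t(s)
  expect_equal(unname(clustering_coefficients(s)), rep(0, 5))
  # triangle, Eq-by-hand: C_A = (2*0.9*0.6*0.3)/(2*0.9*0.6) = 0.3
  tr <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr["A", "B"] <- tr["B", "A"] <- 0.9
  tr["A", "C"] <- tr["C", "A"] <- 0.6
  tr["B", "C"] <- tr["C", "B"] <- 0.3
  expect_equal(node_clustering(tr, "A"), 0.3, tolerance = 1e-12)
  expect_error(node_clustering(tr, "Z"), "unknown node")
  # graph with no edges
  expect_equal(mean_clustering(matrix(0, 4, 4)), 0)
})

test_that("mean path length uses inverse-weight Dijkstra distances", {
  expect_equal(mean_path_length(matrix(c(0, 0.5, 0.5, 0), 2, 2)), 2)
  w <- matrix(0.25, 7, 7); diag(w) <- 0
  expect_equal(mean_path_length(w), 4, tolerance = 1e-12)  # direct edge wins
  # indirect route shorter than weak direct edge
  tr <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr["A", "B"] <- tr["B", "A"] <- 0.2
  tr["A", "C"] <- tr["C", "A"] <- 0.9
  tr["C", "B"] <- tr["B", "C"] <- 0.9
  expect_equal(mean_path_length(tr), path_length_oracle(tr), tolerance = 1e-12)
  d_ab <- 1 / 0.9 + 1 / 0.9
  expect_lt(d_ab, 1 / 0.2)
  # disconnection names the unreachable pair
  z <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  z["A", "B"] <- z["B", "A"] <- 0.5
  expect_error(mean_path_length(z), "disconnected.*C")
})

test_that("surrogate shuffling conserves the weight multiset and symmetry", {
  u <- matrix(0.4, 5, 5); diag(u) <- 0
  set.seed(2)
  expect_identical(shuffle_surrogate(u), u)   # permuting equal weights
  set.seed(3)
  for (i in 1:20) {
    w <- random_weight_matrix(8)
    s <- shuffle_surrogate(w)
    expect_identical(sort(s[upper.tri(s)]), sort(w[upper.tri(w)]))
    expect_identical(s, t(s))
    expect_identical(diag(s), numeric(8))
  }
})

test_that("normalized metrics are exact for uniform graphs and reproducible", {
  w <- matrix(0.6, 8, 8); diag(w) <- 0
  gm <- normalize_metrics(w, n_surrogates = 10, seed = 1)
  expect_equal(gm$clustering_norm, 1)
  expect_equal(gm$path_length_norm, 1)
  expect_equal(gm$small_world, 1)
  set.seed(4)
  w2 <- random_weight_matrix(10)
  a <- normalize_metrics(w2, n_surrogates = 25, seed = 9)
  b <- normalize_metrics(w2, n_surrogates = 25, seed = 9)
  expect_identical(a, b)
  expect_equal(a$small_world, a$clustering_norm / a$path_length_norm)
  expect_equal(a$clustering, mean_clustering(w2), tolerance = 1e-12)
  expect_equal(a$path_length, mean_path_length(w2), tolerance = 1e-12)
})

test_that("weight matrices are validated", {
  w <- random_weight_matrix(4)
  w[1, 2] <- w[2, 1] <- 2
  expect_error(mean_clustering(w), "\\[0, 1\\]")
  w2 <- random_weight_matrix(4); w2[1, 2] <- w2[1, 2] + 0.1
  expect_error(mean_clustering(w2), "symmetric")
  w3 <- random_weight_matrix(4); diag(w3) <- 1
  expect_error(mean_path_length(w3), "diagonal")
})

test_that("edge lists round-trip weighted graphs", {
  set.seed(6)
  w <- random_weight_matrix(6)
  dimnames(w) <- list(letters[1:6], letters[1:6])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(w, path)
  expect_equal(read_edge_list(path)[letters[1:6], letters[1:6]], w,
               tolerance = 1e-15)
})
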
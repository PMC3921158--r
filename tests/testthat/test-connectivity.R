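test_that("PLI matches its defining formula on hand-checked series", {
  z <- numeric(4096)
  expect_identical(pli(rep(pi / 4, 4096), z), 1)
  expect_identical(pli(z, z), 0)
  expect_identical(pli(c(0.1, -0.1, 0.2, -0.2), numeric(4)), 0)
  expect_equal(pli(c(0.1, 0.2, -0.3), numeric(3)), 1 / 3)
  # symmetry and errors
  a <- runif(64, -pi, pi); b <- runif(64, -pi, pi)
  expect_identical(pli(a, b), pli(b, a))
  expect_error(pli(a, b[-1]), "lengths differ")
  expect_error(pli(1, 2), "length >= 2")
})

test_that("dPLI encodes lead/lag and ties to PLI through |2 dPLI - 1|", {
  z <- numeric(4096)
  expect_identical(dpli(rep(pi / 4, 4096), z), 1)   # first channel leading
  expect_identical(dpli(z, z), 0.5)                 # H(0) = 0.5 everywhere
  set.seed(11)
  for (i in 1:20) {
    a <- runif(256, -pi, pi); b <- runif(256, -pi, pi)
    expect_equal(abs(2 * dpli(a, b) - 1), pli(a, b), tolerance = 1e-12)
    expect_equal(dpli(a, b) + dpli(b, a), 1, tolerance = 1e-15)
  }
})

test_that("connectivity matrices average epochs entrywise with matching conventions", {
  set.seed(5)
  ph1 <- matrix(runif(4 * 512, -pi, pi), 4, 512,
                dimnames = list(letters[1:4], NULL))
  ph2 <- matrix(runif(4 * 512, -pi, pi), 4, 512,
                dimnames = list(letters[1:4], NULL))
  m1 <- connectivity_matrix(ph1)
  # single epoch: subject mean equals the epoch matrix, built from pli()
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(m1[i, j], pli(ph1[i, ], ph1[j, ]), tolerance = 1e-12)
  expect_identical(diag(unclass(m1)), setNames(numeric(4), letters[1:4]))
  # two epochs: entrywise mean
  m12 <- connectivity_matrix(list(ph1, ph2))
  e2 <- connectivity_matrix(ph2)
  expect_equal(unclass(m12), (unclass(m1) + unclass(e2)) / 2,
               ignore_attr = TRUE, tolerance = 1e-12)
  # dPLI conventions: antisymmetric around 0.5, |2d - 1| = PLI
  d1 <- connectivity_matrix(ph1, measure = "dpli")
  expect_equal(unclass(d1) + t(unclass(d1)) - diag(4) * 0,
               matrix(1, 4, 4) - diag(1, 4), ignore_attr = TRUE,
               tolerance = 1e-15)
  expect_equal(abs(2 * unclass(d1) - 1) * (1 - diag(4)), unclass(m1),
               ignore_attr = TRUE, tolerance = 1e-12)
  # inconsistent channel sets
  bad <- ph2[1:3, ]
  expect_error(connectivity_matrix(list(ph1, bad)), "inconsistent")
})

test_that("26-channel matrices have 325 distinct pairs", {
  set.seed(1)
  ph <- matrix(runif(26 * 128, -pi, pi), 26, 128,
               dimnames = list(default_montage()$labels, NULL))
  m <- connectivity_matrix(ph)
  expect_identical(sum(upper.tri(m)), 325L)
})

test_that("global mean PLI averages the upper triangle and rejects dPLI", {
  w <- matrix(0.3, 3, 3); diag(w) <- 0
  expect_equal(global_mean_pli(w), 0.3)
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- c(0.2, 0.4, 0.6)
  m <- m + t(m)
  expect_equal(global_mean_pli(m), 0.4)
  expect_identical(global_mean_pli(matrix(0, 4, 4)), 0)
  ph <- matrix(runif(3 * 64, -pi, pi), 3, 64, dimnames = list(letters[1:3], NULL))
  expect_error(global_mean_pli(connectivity_matrix(ph, measure = "dpli")),
               "dPLI")
})

test_that("cluster summaries pool the correct electrode pairs", {
  labs <- default_montage()$labels
  w <- matrix(0.25, 26, 26, dimnames = list(labs, labs)); diag(w) <- 0
  cl <- cluster_means(w)
  expect_equal(cl$frontal_short, 0.25)
  expect_equal(cl$posterior_short, 0.25)
  expect_equal(cl$long_range, 0.25)
  expect_identical(unname(cl$n_pairs), c(21, 15, 42))
  # construction: cross-cluster 1, within-cluster 0
  cl0 <- default_clusters()
  w2 <- matrix(0, 26, 26, dimnames = list(labs, labs))
  w2[cl0$frontal, cl0$posterior] <- 1
  w2[cl0$posterior, cl0$frontal] <- 1
  cl2 <- cluster_means(w2)
  expect_identical(c(cl2$frontal_short, cl2$posterior_short, cl2$long_range),
                   c(0, 0, 1))
  expect_error(cluster_means(w, frontal = c("Fp1", "XX")), "unknown")
  expect_error(cluster_means(w, frontal = c("Fp1", "P3"),
                             posterior = c("P3", "Pz")), "overlap")
})

test_that("cluster averaging commutes with epoch averaging", {
  set.seed(9)
  labs <- default_montage()$labels
  phs <- lapply(1:3, function(e)
    matrix(runif(26 * 256, -pi, pi), 26, 256, dimnames = list(labs, NULL)))
  mean_then_cluster <- cluster_means(connectivity_matrix(phs))
  per_epoch <- lapply(phs, function(p) cluster_means(connectivity_matrix(p)))
  for (f in c("frontal_short", "posterior_short", "long_range"))
    expect_equal(mean_then_cluster[[f]],
                 mean(vapply(per_epoch, `[[`, 0, f)), tolerance = 1e-12)
})

test_that("a fully coupled pair saturates while uncoupled pairs stay near the floor", {
  bc <- data.frame(band = "theta", freq = 6, amplitude = 1, sigma = 0.05,
                   freq_jitter = 1.5)
  cfg <- simulation_config(n_channels = 4, channel_labels = c("A", "B", "C", "D"),
                           duration = 6 * 4096 / 500, band_components = bc,
                           noise_amplitude = 0.01)
  vals <- sapply(1:20, function(sd) {
    r <- generate_recording(cfg, list(coupling_spec(c("A", "B"), "theta", 1, pi / 4)),
                            seed = sd)
    m <- subject_connectivity(r, eeg_bands()$theta)$matrix
    c(coupled = m["A", "B"],
      uncoupled = mean(m[cbind(c("A", "A", "B", "B", "C"),
                               c("C", "D", "C", "D", "D"))]))
  })
  expect_gt(min(vals["coupled", ]), 0.95)
  expect_lt(mean(vals["uncoupled", ]), 0.1)
})
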
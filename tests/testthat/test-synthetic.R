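test_that("same config, couplings and seed give bit-identical recordings and cohorts", {
  cfg <- two_channel_config()
  cp <- list(coupling_spec(c("A", "B"), "theta", 0.5))
  r1 <- generate_recording(cfg, cp, seed = 7)
  r2 <- generate_recording(cfg, cp, seed = 7)
  expect_identical(r1$signals, r2$signals)
  expect_false(identical(r1$signals,
                         generate_recording(cfg, cp, seed = 8)$signals))

  tpl <- group_template("g", cfg, cp)
  c1 <- generate_cohort(tpl, tpl, c(2, 2), seed = 3)
  c2 <- generate_cohort(tpl, tpl, c(2, 2), seed = 3)
  expect_identical(lapply(c1$subjects, function(s) s$recording$signals),
                   lapply(c2$subjects, function(s) s$recording$signals))
  # per-subject seeds depend only on (master, index)
  expect_identical(sapply(c1$subjects, `[[`, "seed"),
                   sapply(c2$subjects, `[[`, "seed"))
})

test_that("caller RNG state is untouched by seeded generation", {
  set.seed(99)
  expected <- c(runif(1), runif(1))
  set.seed(99)
  x1 <- runif(1)
  invisible(generate_recording(two_channel_config(), seed = 5))
  x2 <- runif(1)
  expect_identical(c(x1, x2), expected)
})

test_that("full-strength zero-diffusion coupling gives a constant lag and PLI 1", {
  bc <- data.frame(band = "theta", freq = 6, amplitude = 1, sigma = 0,
                   freq_jitter = 0)
  cfg <- simulation_config(n_channels = 2, channel_labels = c("A", "B"),
                           duration = 4096 / 500, band_components = bc,
                           noise_amplitude = 0)
  r <- generate_recording(cfg, list(coupling_spec(c("A", "B"), "theta", 1, pi / 4)),
                          seed = 1, keep_phases = TRUE)
  # phase level: exactly constant nonzero lag, every sign identical
  expect_identical(pli(r$phases$theta["A", ], r$phases$theta["B", ]), 1)
  # through filtering + Hilbert: only a handful of edge samples may flip
  m <- subject_connectivity(r, eeg_bands()$theta, n_epochs = 1)$matrix
  expect_gt(m["A", "B"], 0.99)
})

test_that("uncoupled channels have near-zero phase-level PLI (mean over 100 seeds)", {
  cfg <- two_channel_config()
  floor_vals <- sapply(1:100, function(sd) {
    r <- generate_recording(cfg, seed = sd, keep_phases = TRUE)
    pli(r$phases$theta["A", ], r$phases$theta["B", ])
  })
  expect_lt(mean(floor_vals), 0.1)
})

test_that("realized pair PLI is non-decreasing in coupling strength", {
  cfg <- two_channel_config(duration = 3 * 4096 / 500)
  strengths <- c(0, 0.25, 0.5, 0.75, 1)
  curve <- sapply(strengths, function(s) {
    mean(sapply(1:20, function(sd) {
      r <- generate_recording(cfg,
                              list(coupling_spec(c("A", "B"), "theta", s, pi / 3)),
                              seed = sd)
      subject_connectivity(r, eeg_bands()$theta, n_epochs = 3)$matrix["A", "B"]
    }))
  })
  expect_true(all(diff(curve) >= 0))
  expect_gt(curve[5], curve[1] + 0.3)   # strong coupling clearly separated
})

test_that("generator rejects invalid inputs", {
  cfg <- two_channel_config()
  expect_error(generate_recording(cfg, list(coupling_spec(c("A", "Z"), "theta", 1)),
                                  seed = 1), "unknown channel label")
  expect_error(generate_recording(cfg, list(coupling_spec(c("A", "B"), "sigma_band", 1)),
                                  seed = 1), "absent from band_components")
  expect_error(generate_recording(cfg), "seed")
  expect_error(coupling_spec(c("A", "A"), "theta", 1), "distinct")
  expect_error(coupling_spec(c("A", "B"), "theta", 1.5), "strength")
  expect_error(simulation_config(n_channels = 3,
                                 channel_labels = c("A", "B")), "n_channels")
  expect_error(simulation_config(sampling_rate = 0), "sampling_rate")
})

test_that("identity mixing is exact and mixing composes linearly", {
  rec <- generate_recording(two_channel_config(), seed = 2)
  expect_identical(apply_mixing(rec, diag(2))$signals, rec$signals)
  A <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2)
  B <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  expect_equal(apply_mixing(apply_mixing(rec, A), B)$signals,
               apply_mixing(rec, B %*% A)$signals, tolerance = 1e-12)
  expect_error(apply_mixing(rec, diag(3)), "channels")
})

test_that("duplicated channels have zero PLI; zero-lag mixtures stay near zero while amplitudes correlate", {
  cfg <- two_channel_config(duration = 6 * 4096 / 500)
  rec <- generate_recording(cfg, seed = 4)
  # duplicate-row mixing: identical outputs, phase difference identically 0
  dup <- apply_mixing(rec, matrix(c(1, 1, 0, 0), 2, 2))
  m <- subject_connectivity(dup, eeg_bands()$beta)$matrix
  expect_identical(m["A", "B"], 0)
  # 0.7/0.3 zero-lag mixing of independent channels (beta band: widest
  # epoch-bandwidth product, so the PLI noise floor is lowest there)
  stats <- sapply(1:10, function(sd) {
    r <- apply_mixing(generate_recording(cfg, seed = sd),
                      matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2))
    c(subject_connectivity(r, eeg_bands()$beta)$matrix["A", "B"],
      cor(r$signals[1, ], r$signals[2, ]))
  })
  expect_lt(mean(stats[1, ]), 0.1)
  expect_gt(mean(stats[2, ]), 0.5)
})

test_that("cohort generation labels groups and recovers the built-in direction", {
  cfg <- two_channel_config()
  tpl <- group_template("g", cfg)
  expect_length(generate_cohort(tpl, tpl, 0, seed = 1)$subjects, 0)

  # higher theta coupling strength in one template shows up as higher
  # group-mean long-range theta PLI in >= 90% of replicate cohorts
  mont <- c("Fz", "F3", "F4", "P3", "Pz", "P4", "O1", "O2", "Oz", "Cz")
  base <- simulation_config(n_channels = 10, channel_labels = mont,
                            duration = 2 * 4096 / 500)
  hi <- group_template("hi", base, template_couplings(list(theta = 0.6)))
  lo <- group_template("lo", base, template_couplings(list(theta = 0.15)))
  frontal <- c("Fz", "F3", "F4")
  posterior <- c("P3", "Pz", "P4", "O1", "O2")
  hits <- sapply(1:50, function(rep) {
    co <- generate_cohort(hi, lo, c(3, 3), seed = rep)
    lr <- sapply(co$subjects, function(s) {
      m <- subject_connectivity(s$recording, eeg_bands()$theta, n_epochs = 2)$matrix
      cluster_means(m, frontal, posterior)$long_range
    })
    g <- sapply(co$subjects, `[[`, "group")
    mean(lr[g == "hi"]) > mean(lr[g == "lo"])
  })
  expect_gte(mean(hits), 0.9)
})
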
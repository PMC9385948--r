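test_that("archetype catalog covers the four firing types with the stated semantics", {
  arcs <- archetype_catalog()
  expect_length(arcs, 4)
  expect_setequal(vapply(arcs, `[[`, "", "firing_type"),
                  c("tonic", "initial_doublet", "initial_burst", "delayed"))
  db <- arcs$initial_doublet
  expect_lt(db$initial_isi, 40)
  expect_equal(db$steady_rate, 3.9)
  expect_gte(arcs$initial_burst$n_initial_spikes, 3)
  expect_gt(1000 / arcs$initial_burst$initial_isi, 25)
  # all catalog archetypes satisfy the QC-passing invariants
  for (a in arcs) {
    expect_gte(a$ap_peak, 0)
    expect_lte(a$resting_potential, -40)
    expect_gt(a$time_constant, 0)
    expect_gt(a$input_resistance, 0)
  }
})

test_that("feature sampling honors spec moments, determinism and degenerate SDs", {
  spec <- cluster_spec("a", "Shox2", n = 5,
                       mean = c(em_mv = -50, cm_pf = 60),
                       sd = c(em_mv = 4, cm_pf = 20))
  # sd_scale = 0 collapses onto the means
  t0 <- sample_feature_table(spec, generator_config(seed = 1, sd_scale = 0))
  expect_equal(t0$em_mv, rep(-50, 5))
  expect_equal(t0$cm_pf, rep(60, 5))
  # identical seed + config is bit-identical
  cfg <- generator_config(seed = 9)
  expect_identical(sample_feature_table(spec, cfg),
                   sample_feature_table(spec, cfg))
  # SD = 0 allowed (delta); negative counts rejected
  d0 <- cluster_spec("d", "Chx10", n = 3,
                     mean = c(em_mv = -45), sd = c(em_mv = 0))
  expect_equal(sample_feature_table(d0, cfg)$em_mv, rep(-45, 3))
  expect_error(cluster_spec("bad", "Shox2", n = -1,
                            mean = c(em_mv = -45), sd = c(em_mv = 1)))
  expect_error(cluster_spec("bad", "Shox2", n = 2,
                            mean = c(em_mv = -45), sd = c(em_mv = -1)),
               "SD")
})

test_that("sample moments converge to spec moments at large n", {
  spec <- pooled_cohort_spec(n = 10000)
  tab <- sample_feature_table(spec, generator_config(seed = 4))
  for (f in c("em_mv", "cm_pf", "fahp_duration_ms", "pic_on_mv")) {
    expect_lt(abs(mean(tab[[f]]) - spec$mean[[f]]),
              0.05 * spec$sd[[f]])
    expect_lt(abs(sd(tab[[f]]) / spec$sd[[f]] - 1), 0.05)
  }
  # lognormal positive model matches the first two moments too
  tl <- sample_feature_table(spec, generator_config(seed = 4,
                                                    positive_model = "lognormal"))
  expect_true(all(tl$cm_pf > 0))
  expect_lt(abs(mean(tl$cm_pf) / spec$mean[["cm_pf"]] - 1), 0.05)
  expect_lt(abs(sd(tl$cm_pf) / spec$sd[["cm_pf"]] - 1), 0.05)
  # truncated Gaussians respect physical bounds
  tt <- sample_feature_table(
    cluster_spec("t", "Shox2", n = 2000,
                 mean = c(sahp_duration_ms = 30, fahp_amplitude_norm = 0.9),
                 sd = c(sahp_duration_ms = 40, fahp_amplitude_norm = 0.2)),
    generator_config(seed = 2, truncate = TRUE))
  expect_true(all(tt$sahp_duration_ms > 0))
  expect_true(all(tt$fahp_amplitude_norm >= 0 & tt$fahp_amplitude_norm <= 1))
})

test_that("reference-composition cohort reproduces the published counts", {
  tab <- simulate_reference_cohort(generator_config(seed = 11))
  expect_equal(nrow(tab), 171)
  expect_equal(sum(tab$population == "Shox2"), 143)
  expect_equal(sum(tab$population == "Chx10"), 28)
  counts <- table(tab$cluster, tab$population)
  expect_equal(unname(counts[, "Shox2"]), c(23, 7, 56, 57))
  expect_equal(unname(counts[, "Chx10"]), c(0, 4, 12, 12))
  # k1 is exclusively Shox2
  expect_equal(sum(tab$population[tab$cluster == "k1"] == "Chx10"), 0)
})

test_that("k-means recovers generative labels of well-separated specs", {
  specs <- list(
    cluster_spec("left", "Shox2", n = 5,
                 mean = c(em_mv = -60, cm_pf = 40),
                 sd = c(em_mv = 0.5, cm_pf = 2)),
    cluster_spec("right", "Chx10", n = 5,
                 mean = c(em_mv = -40, cm_pf = 120),
                 sd = c(em_mv = 0.5, cm_pf = 2))
  )
  tab <- sample_feature_table(specs, generator_config(seed = 5))
  X <- scale(feature_matrix(tab))
  km <- kmeans_best_of_restarts(X, k = 2, restarts = 10, seed = 5)
  expect_true(same_partition(km$labels, tab$cluster))
  expect_equal(mclust::adjustedRandIndex(km$labels, tab$cluster), 1)
  # matches the exhaustive-enumeration optimum on this 10-neuron instance
  brute <- brute_best_2partition(X)
  expect_true(same_partition(km$labels, brute$labels))
})

test_that("trace synthesis obeys its construction contracts", {
  arcs <- archetype_catalog()
  tonic <- arcs$tonic
  tonic$noise_sd <- 0
  rec <- synthesize_recording(tonic, protocol_spec(include = "supra"),
                              seed = 1)
  sw <- rec$sweeps$suprathreshold
  spikes <- attr(sw, "spike_times_ms")
  expect_gt(length(spikes), 3)
  # regular spacing spanning the bulk of the 1 s step
  expect_lt(sd(diff(spikes)), 1e-9)
  expect_gt(max(spikes) - sw$epoch_ms[1], 900)
  # noise-free passive cell: hyperpolarizing deflection is I x Rin exactly
  passive <- archetype_params("tonic", resting_potential = -50,
                              input_resistance = 500, time_constant = 40,
                              rheobase = 1e6, ap_threshold = -36,
                              ap_peak = 20, ap_halfwidth = 1,
                              fahp_depth = 22, fahp_latency = 4,
                              sahp_depth = 2, sahp_latency = 60,
                              steady_rate = 3, noise_sd = 0)
  prec <- synthesize_recording(passive,
                               protocol_spec(include = "hyper",
                                             hyper_steps_pa = -10), seed = 1)
  hy <- prec$sweeps[["hyper_-10"]]
  e <- hy$epoch_ms
  steady <- mean(hy$response[hy$time_ms >= e[2] - 50 & hy$time_ms < e[2]])
  expect_equal(steady - (-70), -10 * 500 / 1000, tolerance = 1e-6)
  # delayed archetype: silent before its first-spike latency
  del <- arcs$delayed
  del$noise_sd <- 0
  drec <- synthesize_recording(del, protocol_spec(include = "supra"),
                               seed = 1)
  ds <- drec$sweeps$suprathreshold
  first <- min(attr(ds, "spike_times_ms")) - ds$epoch_ms[1]
  expect_gte(first, 400)
  expect_equal(nrow(detect_spikes(list(
    clamp_mode = "current",
    time_ms = ds$time_ms[ds$time_ms < ds$epoch_ms[1] + 395],
    response = ds$response[ds$time_ms < ds$epoch_ms[1] + 395]
  ) |> structure(class = "sweep"))), 0)
})
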
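test_that("generator config validates its invariants", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(compensation_strength = 1.2),
               class = "microstab_config_error")
  expect_error(generator_config(fluctuation_sd = -1),
               class = "microstab_config_error")
  expect_error(generator_config(breadth_range = c(10, 99)),
               class = "microstab_config_error")
  expect_error(generator_config(duration = 3600),
               class = "microstab_config_error")
})

test_that("affinity generation is seeded and honors forced saturation", {
  cfg <- quick_config(seed = 42)
  m1 <- generate_affinity_matrix(cfg)
  m2 <- generate_affinity_matrix(quick_config(seed = 42))
  expect_identical(unclass(m1)[, ], unclass(m2)[, ])
  m3 <- generate_affinity_matrix(quick_config(seed = 43))
  expect_false(identical(unclass(m1)[, ], unclass(m3)[, ]))

  # breadth_range [95, 95]: every species uses everything, CMD flat at 95
  sat <- generate_affinity_matrix(quick_config(breadth_range = c(95L, 95L)))
  expect_true(all(sat == 1L))
  cc <- cmd_richness_curve(sat, build_design(rownames(sat)))
  expect_true(all(cc$cmd == 95L))

  # breadths land in the configured range
  expect_true(all(rowSums(m1) >= 40 & rowSums(m1) <= 55))
})

test_that("uniform-weight limit gives near-hypergeometric pairwise overlap", {
  # with a huge concentration the popularity weights are ~uniform, so the
  # expected Jaccard of two random b-subsets follows the hypergeometric
  # baseline; Monte-Carlo oracle on independently drawn uniform subsets
  b <- 47L
  set.seed(99)
  mc <- replicate(1000, {
    s1 <- sample.int(95, b); s2 <- sample.int(95, b)
    length(intersect(s1, s2)) / length(union(s1, s2))
  })
  gen <- numeric(0)
  for (s in 1:12) {
    m <- generate_affinity_matrix(
      quick_config(seed = 600 + s, breadth_range = c(b, b),
                   substrate_popularity_concentration = 1e6))
    o <- microstab:::overlap_matrix(m, rownames(m))
    gen <- c(gen, o[upper.tri(o)])
  }
  expect_lt(abs(mean(gen) - mean(mc)), 0.02)
})

test_that("abundance paths conserve shares and respond to compensation", {
  mat <- twin_matrix(seed = 2)
  pool <- rownames(mat)
  cfg <- quick_config(seed = 5)
  co <- consortium(pool[1:5], "A", level = 5)
  sh <- simulate_abundances(co, mat, cfg)
  expect_equal(dim(sh), c(5, 96))
  expect_true(all(abs(colSums(sh) - 1) < 1e-9))   # conservation per step
  expect_true(all(sh >= 0))

  # no fluctuation: constant equal shares
  sh0 <- simulate_abundances(co, mat, quick_config(fluctuation_sd = 0))
  expect_true(all(sh0 == 1 / 5))

  # compensation off: latent deviations of distinct species are uncorrelated
  cfg0 <- quick_config(seed = 7, compensation_strength = 0)
  cors <- numeric(0)
  for (s in 1:4) {
    co12 <- consortium(pool, "single", level = 12)
    lat <- attr(simulate_abundances(co12, mat, quick_config(
      seed = 70 + s, compensation_strength = 0)), "latent")
    cm <- cor(t(lat))
    cors <- c(cors, cm[upper.tri(cm)])
  }
  expect_gte(length(cors), 200)
  expect_lt(abs(mean(cors)), 0.05)

  # full compensation, identical twin pair: latent anti-correlation
  rtwin <- numeric(0)
  for (s in 1:10) {
    twin <- consortium(pool[1:2], "A", level = 2)
    lat <- attr(simulate_abundances(twin, mat, quick_config(
      seed = 100 + s, compensation_strength = 1)), "latent")
    rtwin <- c(rtwin, cor(lat[1, ], lat[2, ]))
  }
  expect_lt(mean(rtwin), -0.3)
})

test_that("composite Eh behaves as a setpoint mixture with compensation", {
  mat <- twin_matrix(seed = 3)
  pool <- rownames(mat)
  # one species, no noise, no drift: constant at its setpoint
  cfg <- quick_config(fluctuation_sd = 0, observation_noise_sd = 0,
                      probe_perturbation_sd = 0, drift_amplitude = 0)
  co1 <- consortium(pool[3], "single", level = 1)
  sh <- simulate_abundances(co1, mat, cfg)
  eh <- simulate_eh(co1, sh, cfg)
  expect_length(eh, 8)
  sp <- attr(sh, "setpoints")
  expect_true(all(abs(eh[[1]]$values - sp[[1]]) < 1e-9))

  # same seed: bit-identical series
  cfg2 <- quick_config(seed = 31)
  co <- consortium(pool[1:2], "A", level = 2)
  shA <- simulate_abundances(co, mat, cfg2, seed = 77)
  e1 <- simulate_eh(co, shA, cfg2, seed = 88)
  e2 <- simulate_eh(co, shA, cfg2, seed = 88)
  expect_identical(e1[[4]]$values, e2[[4]]$values)

  # Eh variance of a fully redundant (identical-profile) pair decreases as
  # compensation rises from 0 to 1 (median over seeds)
  vr <- sapply(c(0, 0.5, 1), function(cs) {
    med <- sapply(1:20, function(s) {
      cfgc <- quick_config(seed = 300 + s, compensation_strength = cs,
                           observation_noise_sd = 0,
                           probe_perturbation_sd = 0, drift_amplitude = 0)
      twin <- consortium(pool[1:2], "A", level = 2)
      shc <- simulate_abundances(twin, mat, cfgc)
      var(simulate_eh(twin, shc, cfgc)[[1]]$values)
    })
    median(med)
  })
  expect_true(vr[2] < vr[1] && vr[3] < vr[2])
})

test_that("endpoints are linear in CMD with clipped Gaussian noise", {
  cfg <- quick_config(seed = 8, endpoint_noise_sd = 0)
  m <- generate_affinity_matrix(cfg)
  d <- build_design(rownames(m))
  ep <- simulate_endpoints(d, m, cfg)
  expect_equal(ep$doc, cfg$doc_slope * ep$cmd)      # noiseless: exactly linear
  expect_equal(ep$etsa, cfg$etsa_slope * ep$cmd)
  expect_equal(nrow(ep), 51)

  # zero slope: r(DOC, CMD) centred on 0 across seeds
  rs <- sapply(1:40, function(s) {
    cfg0 <- quick_config(seed = 500 + s, doc_slope = 0)
    m0 <- generate_affinity_matrix(cfg0)
    ep0 <- simulate_endpoints(build_design(rownames(m0)), m0, cfg0)
    suppressWarnings(cor(ep0$doc, ep0$cmd))
  })
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.1)

  # clipping: never negative even with huge noise
  cfgn <- quick_config(seed = 9, endpoint_noise_sd = 50)
  mn <- generate_affinity_matrix(cfgn)
  epn <- simulate_endpoints(build_design(rownames(mn)), mn, cfgn)
  expect_true(all(epn$etsa >= 0) && all(epn$doc >= 0))
})

test_that("generate_experiment has the documented shape and is reproducible", {
  cfg <- quick_config(seed = 12)
  exp1 <- generate_experiment(cfg)
  expect_length(exp1$eh, 51)
  expect_length(exp1$eh[[1]], 8)
  expect_length(exp1$eh[[1]][[1]]$values, 96)
  expect_equal(nrow(exp1$endpoints), 51)

  # truth CMD agrees with the niche module on the generated matrix
  for (i in seq_len(nrow(exp1$truth))) {
    co <- Filter(function(x) x$label == exp1$truth$consortium[i],
                 exp1$design$consortia)[[1]]
    expect_identical(exp1$truth$cmd[i],
                     community_metabolic_diversity(exp1$matrix, co))
  }

  exp2 <- generate_experiment(quick_config(seed = 12))
  expect_identical(exp1$eh[["r05B_rep2"]][[3]]$values,
                   exp2$eh[["r05B_rep2"]][[3]]$values)
  exp3 <- generate_experiment(quick_config(seed = 13))
  expect_false(identical(exp1$eh[["r05B_rep2"]][[3]]$values,
                         exp3$eh[["r05B_rep2"]][[3]]$values))
  expect_identical(dim(exp3$endpoints), dim(exp1$endpoints))
})

test_that("high-overlap consortia are more stable than disjoint ones", {
  # same richness (4), same machinery; only the overlap structure differs
  pool <- sprintf("sp%02d", 1:12)
  set.seed(14)
  prof <- as.integer(seq_len(95) %in% sample.int(95, 44))
  ident <- affinity_matrix(matrix(rep(prof, 12), 12, byrow = TRUE),
                           species_ids = pool,
                           substrate_ids = sprintf("sub%02d", 1:95))
  disj <- affinity_matrix(
    t(sapply(0:11, function(i) as.integer(seq_len(95) %in% (i * 7 + 1:7)))),
    species_ids = pool, substrate_ids = sprintf("sub%02d", 1:95))
  st <- sapply(list(high = ident, low = disj), function(mat) {
    median(sapply(1:10, function(s) {
      cfg <- quick_config(seed = 800 + s)
      co <- consortium(pool[1:4], "A", level = 4)
      sh <- simulate_abundances(co, mat, cfg)
      treatment_stability(simulate_eh(co, sh, cfg), n_voices = 4)$stability
    }))
  })
  expect_gt(st[["high"]], st[["low"]])
})
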
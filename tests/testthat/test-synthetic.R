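test_that("attention envelope has 4 bouts with long silent gaps (no jitter)", {
  set.seed(1)
  env <- build_envelope(expression_profiles()$attention,
                        timing_jitter_sd_ms = 0)
  active <- env$vertical > 0
  # bouts = groups of active samples separated by >= 0.9 s of silence
  on_idx <- which(active)
  splits <- which(diff(on_idx) > 900)
  expect_equal(length(splits) + 1L, 4L)
  expect_true(all(diff(on_idx)[splits] >= 900))
})

test_that("sadness is a single contiguous hold covering >= 90% of the trial", {
  set.seed(2)
  for (i in 1:5) {
    env <- build_envelope(expression_profiles()$sadness,
                          timing_jitter_sd_ms = 100)
    r <- rle(env$static > 0)
    expect_equal(sum(r$values), 1L)       # one contiguous span
    expect_gte(sum(env$static > 0), 0.9 * 10000)
  }
})

test_that("attention active-contact time stays under 70% of the trial", {
  set.seed(3)
  for (i in 1:5) {
    env <- build_envelope(expression_profiles()$attention,
                          timing_jitter_sd_ms = 100)
    active <- env$vertical + env$tangential + env$static > 0
    expect_lte(mean(active), 0.7)
  }
})

test_that("calming bout durations average to ~2 s over many draws", {
  set.seed(4)
  durs <- replicate(100, {
    env <- build_envelope(expression_profiles()$calming,
                          timing_jitter_sd_ms = 100)
    r <- rle(env$tangential > 0)
    mean(r$lengths[r$values])
  })
  expect_lt(abs(mean(durs) - 2000) / 2000, 0.1)
})

test_that("transient-tuned models respond only to onset/offset of a hold", {
  env <- list(vertical = numeric(10000), tangential = numeric(10000),
              static = c(numeric(2000), rep(1, 6000), numeric(2000)))
  hfa <- subtype_models()$HFA
  lam <- rate_transform(env, hfa)
  # silent during the hold interior and before/after the bout
  expect_equal(max(lam[3000:7000]), hfa$baseline_hz)
  expect_equal(max(lam[1:1500]), hfa$baseline_hz)
  # transient pulses at the boundaries
  expect_gt(max(lam[1950:2100]), 10)
  expect_gt(max(lam[7950:8100]), 10)
})

test_that("zero driver with zero baseline gives zero rate", {
  env <- list(vertical = numeric(1000), tangential = numeric(1000),
              static = numeric(1000))
  m <- subtype_models()$HFA
  m$baseline_hz <- 0
  expect_equal(rate_transform(env, m), numeric(1000))
})

test_that("SA-II-like rate decays within a hold with the model tau", {
  env <- list(vertical = numeric(10000), tangential = numeric(10000),
              static = c(numeric(100), rep(1, 9900)))
  m <- subtype_models()$`SA-II`
  m$baseline_hz <- 0
  m$rate_cap_hz <- 1e6   # avoid clipping for the tau recovery
  lam <- rate_transform(env, m)
  tt <- 0:9899
  y <- lam[101:10000]
  fit <- lm(log(y) ~ tt)
  tau_hat <- -1 / coef(fit)[[2]]
  expect_lt(abs(tau_hat - m$decay_tau_ms) / m$decay_tau_ms, 0.05)
  expect_true(all(diff(y) <= 1e-9))   # monotone decay
})

test_that("thinning sampler honors rate zero, dead time and determinism", {
  set.seed(5)
  expect_length(sample_spikes(numeric(10000))$spike_times_ms, 0)

  # dead-time-corrected expectation: T*lambda/(1 + lambda*tau)
  lam <- rep(100, 10000)
  set.seed(6)
  counts <- replicate(500, length(sample_spikes(lam, refractory_ms = 1)$spike_times_ms))
  expected <- 10 * 100 / (1 + 100 * 0.001)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)

  set.seed(77); a <- sample_spikes(lam, refractory_ms = 2)
  set.seed(77); b <- sample_spikes(lam, refractory_ms = 2)
  expect_identical(a$spike_times_ms, b$spike_times_ms)
})

test_that("generate_dataset is balanced, deterministic and seed-sensitive", {
  cfg <- generator_config(n_units_per_subtype = 1L,
                          n_trials_per_unit_per_expression = 1L, seed = 21L)
  ds <- generate_dataset(cfg)
  expect_length(ds, 36L)   # 6 subtypes x 6 expressions
  info <- dataset_info(ds)
  expect_true(all(table(info$subtype, info$expression) == 1L))

  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  p3 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(p1, p2, p3, paste0(c(p1, p2, p3), ".meta.json"))))
  write_dataset(generate_dataset(cfg), p1)
  write_dataset(generate_dataset(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))   # byte-identical

  cfg2 <- generator_config(n_units_per_subtype = 1L,
                           n_trials_per_unit_per_expression = 1L, seed = 22L)
  write_dataset(generate_dataset(cfg2), p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("synthetic firing reproduces the qualitative subtype contrasts", {
  ds <- fixture_dataset()
  ft <- feature_table(ds)

  # SA-II: tapping expressions drive higher mean IFF than the hold
  sa <- ft[ft$subtype == "SA-II", ]
  expect_gt(mean(sa$mean_iff_hz[sa$expression %in% c("attention", "happiness")]),
            mean(sa$mean_iff_hz[sa$expression == "sadness"]))

  # SA-II fires throughout the sadness hold; HFA is silent in its interior
  sa_sad <- filter_dataset(ds, subtype = "SA-II", expression = "sadness")
  mid_counts <- vapply(sa_sad$trials, function(tr)
    sum(tr$spike_times_ms > 3000 & tr$spike_times_ms < 7000), 0L)
  expect_true(all(mid_counts > 20))
  hfa_sad <- filter_dataset(ds, subtype = "HFA", expression = "sadness")
  hfa_mid <- vapply(hfa_sad$trials, function(tr)
    sum(tr$spike_times_ms > 3000 & tr$spike_times_ms < 7000), 0L)
  expect_true(mean(hfa_mid) < mean(mid_counts) / 10)

  # low-rate subtypes stay under the 50 Hz IFF ceiling; Abeta exceed 100 Hz
  low <- ft[ft$subtype %in% c("CT", "MS"), ]
  expect_true(all(low$peak_iff_hz <= 50 + 1e-9))
  expect_gt(max(ft$mean_iff_hz[ft$subtype %in% c("SA-II", "HFA")]), 100)
})
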
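test_that("IFF follows the backward-difference definition", {
  tr <- spike_train(c(1000L, 1500L, 2000L))
  iff <- compute_iff(tr)
  expect_equal(iff$iff_hz, c(2, 2))
  expect_equal(iff$times_ms, c(1500L, 2000L))

  expect_length(compute_iff(spike_train(0L))$iff_hz, 0)
  expect_length(compute_iff(spike_train())$iff_hz, 0)
})

test_that("IFF matches the brute-force oracle on random trains", {
  set.seed(42)
  for (i in 1:1000) {
    tr <- random_train(duration_ms = 2000)
    got <- compute_iff(tr)
    want <- oracle_iff(tr$spike_times_ms)
    expect_identical(as.integer(got$times_ms), as.integer(want$times_ms))
    expect_equal(got$iff_hz, want$iff_hz)
  }
})

test_that("step interpolation uses the hold-forward convention", {
  expect_equal(step_interpolate(compute_iff(spike_train()), 100),
               numeric(100))

  tr <- spike_train(c(1000L, 2000L))
  trace <- step_interpolate(compute_iff(tr), 10000L)
  expect_equal(trace[1:1000], numeric(1000))
  expect_equal(trace[2001:10000], rep(1, 8000))
  expect_equal(trace[2001], 1)

  # sampling at each spike time >= 2nd reproduces the IFF values
  set.seed(7)
  for (i in 1:50) {
    tr <- random_train(duration_ms = 5000)
    iff <- compute_iff(tr)
    if (!length(iff$times_ms)) next
    trace <- step_interpolate(iff, 5000L)
    expect_equal(trace[iff$times_ms + 1L], iff$iff_hz)
  }
})

test_that("step-IFF integral counts the spikes for uniform-ISI trains", {
  # under the hold-forward convention the integral over [t_2, t_n)
  # recovers n-1 spikes exactly when ISIs are constant (each held value
  # 1/isi integrates over one isi); for irregular trains the held value
  # integrates over the *next* interval, so the identity is approximate
  # and is not asserted -- the sampling identity below is the exact
  # contract
  for (isi in c(20L, 125L, 500L)) {
    t <- seq(100L, 4500L, by = isi)
    tr <- spike_train(t, duration_ms = 5000L)
    trace <- step_interpolate(compute_iff(tr), 5000L)
    n <- length(t)
    # [t_2, t_n): n-2 whole intervals; adding the last held interval
    # recovers all n-1 IFF contributions
    expect_equal(sum(trace[(t[2] + 1L):tail(t, 1)]) / 1000, n - 2,
                 tolerance = 1e-9)
    expect_equal(sum(trace[(t[2] + 1L):(tail(t, 1) + isi)]) / 1000, n - 1,
                 tolerance = 1e-9)
  }
})

test_that("binarization marks exactly the occupied bins", {
  expect_equal(binarize(spike_train()), integer(10000))
  v <- binarize(spike_train(c(0L, 9999L)))
  expect_equal(which(v == 1L), c(1L, 10000L))
  expect_equal(sum(v), 2L)

  set.seed(9)
  for (i in 1:100) {
    tr <- random_train()
    v <- binarize(tr)
    expect_identical(which(v == 1L) - 1L, unique(tr$spike_times_ms))
    expect_equal(sum(v), length(unique(tr$spike_times_ms)))
  }
})

test_that("spike_train validates its invariants", {
  expect_error(spike_train(c(0L, 10000L), trial_id = "t1"),
               "out of range.*t1")
  expect_error(spike_train(c(5L, 5L), trial_id = "t2"),
               "strictly increasing.*t2")
  expect_error(spike_train(c(10L, 5L)), "strictly increasing")
  expect_error(spike_train(0L, subtype = "SA-I"), "unknown subtype")
  expect_error(spike_train(0L, expression = "anger"), "unknown expression")
})

test_that("collision resolution keeps counts and prefers near bins", {
  expect_equal(resolve_collisions(c(5L, 5L), 100L), c(4L, 5L))
  expect_equal(resolve_collisions(c(0L, 0L), 100L), c(0L, 1L))
  set.seed(10)
  for (i in 1:50) {
    t <- sort(sample.int(50L, 30, replace = TRUE) - 1L)
    out <- resolve_collisions(t, 50L)
    expect_length(out, length(t))
    expect_false(is.unsorted(out, strictly = TRUE))
    expect_true(all(out >= 0 & out < 50))
  }
})

test_that("dataset CSV round-trips losslessly", {
  ds <- fixture_dataset(subtypes = "SA-II")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".meta.json"))))
  write_dataset(ds, path)
  ds2 <- read_dataset(path)
  expect_identical(names(ds2$trials), names(ds$trials))
  for (id in names(ds$trials)) {
    expect_identical(ds2$trials[[id]]$spike_times_ms,
                     ds$trials[[id]]$spike_times_ms)
    expect_identical(ds2$trials[[id]]$expression, ds$trials[[id]]$expression)
    expect_identical(ds2$trials[[id]]$subtype, ds$trials[[id]]$subtype)
    expect_identical(ds2$trials[[id]]$unit_id, ds$trials[[id]]$unit_id)
  }
  expect_identical(ds2$duration_ms, ds$duration_ms)

  # zero-spike trials survive the round trip
  ds3 <- spike_dataset(list(
    spike_train(integer(), trial_id = "empty", subtype = "MS",
                expression = "sadness", unit_id = "u1"),
    spike_train(c(3L, 9L), trial_id = "two", subtype = "MS",
                expression = "love", unit_id = "u1")))
  p3 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(p3, paste0(p3, ".meta.json"))), add = TRUE)
  write_dataset(ds3, p3)
  back <- read_dataset(p3)
  expect_length(back$trials[["empty"]]$spike_times_ms, 0)
  expect_identical(back$trials[["two"]]$spike_times_ms, c(3L, 9L))
})

test_that("reading rejects out-of-range spikes and unknown labels", {
  p <- tempfile(fileext = ".csv")
  on.exit(unlink(p))
  writeLines(c("trial_id,unit_id,subtype,expression,spike_time_ms",
               "t1,u1,SA-II,love,10000"), p)
  expect_error(read_dataset(p), "out of range.*t1")
  writeLines(c("trial_id,unit_id,subtype,expression,spike_time_ms",
               "t1,u1,SA-III,love,5"), p)
  expect_error(read_dataset(p), "unknown subtype")
  writeLines(c("trial_id,unit_id,subtype,expression",
               "t1,u1,SA-II,love"), p)
  expect_error(read_dataset(p), "columns")
})
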
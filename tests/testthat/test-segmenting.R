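test_that("window length grid endpoints and split match the sampling scheme", {
  g <- window_length_grid()
  expect_equal(min(g), 100L)
  expect_equal(max(g), 10000L)
  expect_equal(sum(g <= 4000L), 40L)
  expect_equal(sum(g > 4000L), 24L)
  expect_false(anyDuplicated(g) > 0)
})

test_that("select_segment honors the metric definitions", {
  set.seed(22)
  tr <- random_train()
  expect_equal(select_segment(tr, 2500L, "first")$start_ms, 0L)

  # unique cluster is found by max_n_spikes
  tr2 <- spike_train(sort(sample(6000:6499, 80)), duration_ms = 10000L)
  seg <- select_segment(tr2, 1000L, "max_n_spikes")
  expect_lte(seg$start_ms, min(tr2$spike_times_ms))
  expect_gt(seg$start_ms + 1000L, max(tr2$spike_times_ms))

  # full-length window always starts at 0 for every metric
  for (m in POSITION_METRICS)
    expect_equal(select_segment(tr, 10000L, m)$start_ms, 0L)

  # empty train: earliest start by tie-breaking
  for (m in POSITION_METRICS)
    expect_equal(select_segment(spike_train(), 500L, m)$start_ms, 0L)
})

test_that("argmax segment selection matches the exhaustive scan oracle", {
  set.seed(23)
  for (i in 1:50) {
    tr <- random_train(duration_ms = 800, max_rate_hz = 30)
    for (L in c(100L, 250L)) {
      for (m in c("max_n_spikes", "max_mean_iff", "max_iff_variation",
                  "max_iff_entropy")) {
        got <- select_segment(tr, L, m)$start_ms
        want <- oracle_argmax_start(tr, L, m)
        expect_equal(got, want,
                     label = sprintf("train %d metric %s L=%d", i, m, L))
      }
    }
  }
})

test_that("windowed metric values agree with first-principles evaluation", {
  set.seed(24)
  for (i in 1:20) {
    tr <- random_train(duration_ms = 600, max_rate_hz = 40)
    L <- 200L
    starts <- c(0L, 123L, 400L)
    cnt <- touchcode:::window_metric_scan(tr, L, "max_n_spikes")
    cv_ <- touchcode:::window_metric_scan(tr, L, "max_iff_variation")
    ent <- touchcode:::window_metric_scan(tr, L, "max_iff_entropy")
    mif <- if (length(tr$spike_times_ms) >= 2)
      touchcode:::window_metric_scan(tr, L, "max_mean_iff") else NULL
    for (s in starts) {
      expect_equal(cnt[s + 1], oracle_window_metric(tr, s, L, "max_n_spikes"))
      cv_want <- oracle_window_metric(tr, s, L, "max_iff_variation")
      expect_lt(abs(cv_[s + 1] - cv_want), 1e-6 * max(1, cv_want))
      expect_equal(ent[s + 1],
                   oracle_window_metric(tr, s, L, "max_iff_entropy"),
                   tolerance = 1e-8)
      if (!is.null(mif))
        expect_equal(mif[s + 1], oracle_window_metric(tr, s, L, "max_mean_iff"),
                     tolerance = 1e-8)
    }
  }
})

test_that("iff_entropy has the closed-form values", {
  expect_equal(iff_entropy(rep(7, 100)), 0)
  expect_equal(iff_entropy(numeric(0)), 0)
  # k bins uniformly occupied -> ln(k)
  vals <- rep(c(2, 7, 12, 17), each = 25)   # 4 bins at width 5
  expect_equal(iff_entropy(vals), log(4))
  set.seed(25)
  v <- runif(500, 0, 60)
  p <- as.numeric(table(floor(v / 5))) / 500
  expect_equal(iff_entropy(v), -sum(p * log(p)))
})

test_that("segment extraction ignores spikes outside the window", {
  tr1 <- spike_train(c(100L, 200L, 300L), duration_ms = 1000L)
  tr2 <- spike_train(c(100L, 200L, 300L, 900L), duration_ms = 1000L)
  seg <- list(start_ms = 50L, length_ms = 400L)
  class(seg) <- "segment"
  expect_identical(segment_binary(tr1, seg), segment_binary(tr2, seg))
})

test_that("segment_dataset enumerates the full variant grid", {
  ds <- spike_dataset(list(
    spike_train(c(10L, 600L, 1200L), duration_ms = 10000L, trial_id = "a"),
    spike_train(c(5000L, 5001L), duration_ms = 10000L, trial_id = "b")))
  full <- segment_dataset(ds)
  expect_equal(nrow(full), 2L * 64L * 5L)   # 320 options per trial
  one <- segment_dataset(ds, lengths_ms = 1000L, metrics = "first")
  expect_equal(nrow(one), 2L)
  expect_true(all(one$start_ms == 0L))
})

test_that("BH adjustment reproduces the reference step-up procedure", {
  set.seed(26)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))^2
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
})

test_that("window metric comparison emits all pairs with BH correction", {
  set.seed(27)
  tab <- expand.grid(metric = POSITION_METRICS, length_ms = c(100, 200, 400),
                     repeat_ = 1:2, stringsAsFactors = FALSE)
  tab$accuracy <- runif(nrow(tab), 0.2, 0.9)
  cmp <- compare_window_metrics(tab)
  expect_length(cmp$metric_means, 5L)
  expect_equal(nrow(cmp$pairs), choose(5, 2))
  expect_true(all(cmp$pairs$p_adj >= cmp$pairs$p_value - 1e-12))
  expect_true(all(cmp$pairs$p_adj <= 1))
})
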
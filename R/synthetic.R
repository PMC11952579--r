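# Synthetic spike-train generator.
#
# Contact mechanics are abstracted into three channels (vertical impact,
# tangential motion, static pressure) on the 1 ms grid; each expression is a
# rhythm of contact bouts driving those channels, each afferent subtype a
# rate transform from the channels to an instantaneous firing rate, and
# spikes are drawn by thinning an inhomogeneous Bernoulli process with an
# absolute refractory period. The generator is calibrated only to the
# qualitative firing contrasts between subtypes and gestures, not to
# physical units.

#' Expression rhythm profiles
#'
#' Returns the contact-rhythm parameters of the six standardized touch
#' expressions. Bout and gap durations are in ms; taps are brief
#' vertical-impact pulses, strokes smooth tangential bumps, holds sustained
#' static pressure.
#'
#' @return named list of profiles, one per expression.
#' @export
expression_profiles <- function() {
  list(
    # 4 bursts of 4-5 taps, each burst ~1.5 s, ~1 s gaps
    attention = list(kind = "tap_bursts", n_bouts = 4L, bout_ms = 1500,
                     gap_ms = 1000, taps_per_bout = c(4L, 5L)),
    # continuous random playful tapping over the whole trial
    happiness = list(kind = "random_taps", iti_range_ms = c(150, 350)),
    # 4 repeated slow strokes, ~2 s each, ~0.5 s gaps
    calming   = list(kind = "stroke_bouts", n_bouts = 4L, bout_ms = 2000,
                     gap_ms = 500),
    # continuous back-and-forth light stroking
    love      = list(kind = "continuous_stroke", cycle_ms = 2000),
    # pats (~2 s bouts of 3-4 pats) alternated with holds (~2 s)
    gratitude = list(kind = "pat_hold", bout_ms = 2000,
                     pats_per_bout = c(3L, 4L)),
    # one sustained hold spanning the trial
    sadness   = list(kind = "hold", onset_ms = 200, offset_ms = 9900)
  )
}

#' Afferent subtype response models
#'
#' Gains are in Hz per channel unit; `adaptation` selects the per-channel
#' transform used by [rate_transform()]. Parameters are chosen to reproduce
#' the qualitative subtype contrasts: slowly adapting type II (SA-II) fires
#' throughout holds with slow decay; hair-follicle afferents (HFA) respond
#' only to onsets/offsets of sustained contact; Pacinian (FA-II) afferents
#' are transient-tuned; Field afferents fire during movement but not static
#' contact; C-tactile (CT) afferents are slow-stroking tuned with a ~50 Hz
#' ceiling; muscle spindles (MS) are weakly coupled with baseline firing.
#'
#' @return named list of models, one per subtype.
#' @export
subtype_models <- function() {
  list(
    `SA-II` = list(adaptation = "sustained_decay",
                   gain_vertical = 140, gain_tangential = 70,
                   gain_static = 90, gain_transient = 0,
                   decay_tau_ms = 2500, baseline_hz = 0.5,
                   refractory_ms = 2, rate_cap_hz = 400),
    HFA     = list(adaptation = "onset_offset_transient",
                   gain_vertical = 180, gain_tangential = 90,
                   gain_static = 60, gain_transient = 1,
                   decay_tau_ms = NA, baseline_hz = 0,
                   refractory_ms = 2, rate_cap_hz = 400),
    `FA-II` = list(adaptation = "transient_only",
                   gain_vertical = 220, gain_tangential = 30,
                   gain_static = 40, gain_transient = 1,
                   decay_tau_ms = NA, baseline_hz = 0,
                   refractory_ms = 2, rate_cap_hz = 400),
    Field   = list(adaptation = "sustained_irregular",
                   gain_vertical = 120, gain_tangential = 80,
                   gain_static = 0, gain_transient = 0,
                   decay_tau_ms = NA, baseline_hz = 0,
                   refractory_ms = 2, rate_cap_hz = 300),
    CT      = list(adaptation = "sustained_irregular",
                   gain_vertical = 5, gain_tangential = 12,
                   gain_static = 4, gain_transient = 0,
                   decay_tau_ms = NA, baseline_hz = 3,
                   refractory_ms = 20, rate_cap_hz = 50),
    MS      = list(adaptation = "low_rate",
                   gain_vertical = 6, gain_tangential = 6,
                   gain_static = 6, gain_transient = 0,
                   decay_tau_ms = NA, baseline_hz = 10,
                   refractory_ms = 20, rate_cap_hz = 50)
  )
}

#' Generator configuration
#'
#' @param n_units_per_subtype units simulated per subtype (study scale is
#'   4-12 units per subtype).
#' @param n_trials_per_unit_per_expression repeated trials per unit and
#'   expression (study mean ~19 trials per unit over six expressions, i.e.
#'   ~3 per cell).
#' @param seed integer seed; a fixed seed gives a bit-identical dataset.
#' @param unit_level_gain_sd log-normal SD of the per-unit gain multiplier
#'   (between-unit sensitivity variability).
#' @param timing_jitter_sd_ms Gaussian SD of bout-boundary timing jitter
#'   between trials.
#' @param duration_ms trial duration.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_units_per_subtype = 4L,
                             n_trials_per_unit_per_expression = 3L,
                             seed = 1L,
                             unit_level_gain_sd = 0.25,
                             timing_jitter_sd_ms = 100,
                             duration_ms = 10000L) {
  stopifnot(n_units_per_subtype >= 1L,
            n_trials_per_unit_per_expression >= 1L,
            unit_level_gain_sd >= 0, timing_jitter_sd_ms >= 0)
  structure(list(n_units_per_subtype = as.integer(n_units_per_subtype),
                 n_trials_per_unit_per_expression =
                   as.integer(n_trials_per_unit_per_expression),
                 seed = as.integer(seed),
                 unit_level_gain_sd = unit_level_gain_sd,
                 timing_jitter_sd_ms = timing_jitter_sd_ms,
                 duration_ms = as.integer(duration_ms)),
            class = "generator_config")
}

# Half-sine pulse helper: adds amplitude*sin(pi*s) over [start, start+len)
# into channel vector x (1-based grid), clipped to the grid.
add_pulse <- function(x, start_ms, len_ms, amplitude) {
  n <- length(x)
  lo <- max(0, floor(start_ms))
  hi <- min(n - 1, ceiling(start_ms + len_ms) - 1)
  if (hi < lo) return(x)
  idx <- seq.int(lo, hi)
  s <- (idx - start_ms) / len_ms
  s <- pmin(pmax(s, 0), 1)
  x[idx + 1L] <- x[idx + 1L] + amplitude * sin(pi * s)
  x
}

#' Build a contact-envelope driver for one expression
#'
#' Realizes one trial's contact rhythm on the 1 ms grid as three
#' non-negative channels: `vertical` (impact), `tangential` (motion) and
#' `static` (pressure), in arbitrary units. Bout boundaries and tap times
#' receive Gaussian jitter of SD `timing_jitter_sd_ms`.
#'
#' @param profile one element of [expression_profiles()].
#' @param duration_ms trial duration.
#' @param timing_jitter_sd_ms timing jitter SD in ms (0 gives the nominal
#'   rhythm).
#' @return list with numeric vectors `vertical`, `tangential`, `static` of
#'   length `duration_ms`. Uses the current R RNG stream.
#' @export
build_envelope <- function(profile, duration_ms = 10000L,
                           timing_jitter_sd_ms = 0) {
  D <- as.integer(duration_ms)
  vert <- numeric(D); tang <- numeric(D); stat_ <- numeric(D)
  jit <- function(x) x + rnorm(length(x), 0, timing_jitter_sd_ms)
  tap_width <- 60    # ms of skin contact per tap
  switch(profile$kind,
    tap_bursts = {
      period <- profile$bout_ms + profile$gap_ms
      for (b in seq_len(profile$n_bouts)) {
        b0 <- jit((b - 1L) * period)
        ntap <- sample(profile$taps_per_bout[1L]:profile$taps_per_bout[2L], 1L)
        tap_times <- b0 + (seq_len(ntap) - 1L) * profile$bout_ms / ntap +
          rnorm(ntap, 0, timing_jitter_sd_ms / 4)
        for (tt in tap_times) {
          vert <- add_pulse(vert, tt, tap_width, 1)
          stat_ <- add_pulse(stat_, tt, tap_width, 0.2)
        }
      }
    },
    random_taps = {
      tt <- runif(1, 0, profile$iti_range_ms[2L])
      while (tt < D) {
        vert <- add_pulse(vert, tt, tap_width, 1)
        stat_ <- add_pulse(stat_, tt, tap_width, 0.2)
        tt <- tt + runif(1, profile$iti_range_ms[1L], profile$iti_range_ms[2L])
      }
    },
    stroke_bouts = {
      period <- profile$bout_ms + profile$gap_ms
      for (b in seq_len(profile$n_bouts)) {
        b0 <- jit((b - 1L) * period)
        blen <- profile$bout_ms * exp(rnorm(1, 0, timing_jitter_sd_ms / 2000))
        tang <- add_pulse(tang, b0, blen, 1)
        stat_ <- add_pulse(stat_, b0, blen, 0.3)
      }
    },
    continuous_stroke = {
      phase <- runif(1, 0, 2 * pi)
      t <- seq_len(D) - 1L
      cyc <- profile$cycle_ms * exp(rnorm(1, 0, timing_jitter_sd_ms / 2000))
      # back-and-forth: tangential speed peaks twice per cycle
      tang <- 0.5 + 0.5 * abs(sin(2 * pi * t / cyc + phase))
      stat_ <- stat_ + 0.2
    },
    pat_hold = {
      # alternating 2 s pat bouts and 2 s hold bouts across the trial
      nb <- max(1L, floor(D / profile$bout_ms))
      for (b in seq_len(nb)) {
        b0 <- jit((b - 1L) * profile$bout_ms)
        if (b %% 2L == 1L) {
          npat <- sample(profile$pats_per_bout[1L]:profile$pats_per_bout[2L], 1L)
          pat_times <- b0 + (seq_len(npat) - 1L) * profile$bout_ms / npat
          for (tt in pat_times) {
            vert <- add_pulse(vert, tt, 120, 0.8)
            stat_ <- add_pulse(stat_, tt, 120, 0.3)
          }
        } else {
          stat_ <- add_pulse(stat_, b0, profile$bout_ms, 1)
        }
      }
    },
    hold = {
      on <- max(0, jit(profile$onset_ms))
      off <- min(D, jit(profile$offset_ms))
      if (off <= on) off <- on + 1000
      idx <- seq.int(floor(on), ceiling(off) - 1L)
      idx <- idx[idx >= 0L & idx < D]
      ramp <- 150  # ms on/off ramp
      prof <- pmin(1, (idx - on) / ramp, (off - idx) / ramp)
      stat_[idx + 1L] <- stat_[idx + 1L] + pmax(prof, 0)
      # slight hand micro-motion during the squeeze
      tang[idx + 1L] <- tang[idx + 1L] + 0.05
    },
    stop("unknown profile kind: ", profile$kind)
  )
  list(vertical = pmax(vert, 0), tangential = pmax(tang, 0),
       static = pmax(stat_, 0))
}

# Smoothed rectified derivative of a channel, for transient-tuned
# transforms; boxcar width trades off transient duration vs sharpness.
transient_drive <- function(x, threshold = 1e-3, width_ms = 30L) {
  d <- abs(diff(c(x[1L], x)))
  d[d < threshold] <- 0
  k <- rep(1, width_ms)
  as.numeric(stats::filter(d, k, sides = 2L, circular = FALSE)) -> sm
  sm[is.na(sm)] <- 0
  sm
}

# Exponential within-bout decay of a sustained drive: inside each
# contiguous active span of x, multiply by exp(-t'/tau) with t' time since
# span onset.
apply_bout_decay <- function(x, tau_ms) {
  active <- x > 1e-9
  if (!any(active)) return(x)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    x[idx] <- x[idx] * exp(-(seq_along(idx) - 1L) / tau_ms)
  }
  x
}

#' Transform a contact envelope into an instantaneous firing rate
#'
#' Applies the subtype's adaptation transform per channel, sums with the
#' channel gains, adds the baseline and clips to `[0, rate_cap_hz]`:
#' `sustained_decay` multiplies the static drive by `exp(-t'/decay_tau_ms)`
#' within each static bout; `onset_offset_transient` and `transient_only`
#' replace every channel by its smoothed rectified derivative scaled by
#' `gain_transient` (so sustained contact itself elicits nothing);
#' `sustained_irregular` and `low_rate` pass channels through unchanged.
#'
#' @param envelope output of [build_envelope()].
#' @param model one element of [subtype_models()].
#' @return numeric rate vector lambda(t) in Hz on the 1 ms grid.
#' @export
rate_transform <- function(envelope, model) {
  g <- function(x) switch(model$adaptation,
    sustained_decay = x,   # static-channel decay applied below
    onset_offset_transient = ,
    transient_only = model$gain_transient * transient_drive(x),
    sustained_irregular = ,
    low_rate = x,
    stop("unknown adaptation: ", model$adaptation))
  st <- envelope$static
  if (model$adaptation == "sustained_decay")
    st <- apply_bout_decay(st, model$decay_tau_ms)
  lambda <- model$baseline_hz +
    model$gain_vertical * g(envelope$vertical) +
    model$gain_tangential * g(envelope$tangential) +
    model$gain_static * g(st)
  pmin(pmax(lambda, 0), model$rate_cap_hz)
}

#' Sample a spike train from an instantaneous rate
#'
#' Bernoulli thinning on the 1 ms grid with an absolute refractory period:
#' bin `t` fires with probability `lambda(t)/1000` provided
#' `t - last_spike > refractory_ms`. For constant `lambda` the expected
#' count over `T` seconds is `T*lambda/(1 + lambda*refractory/1000)`
#' (dead-time-corrected renewal rate).
#'
#' @param lambda_hz rate vector on the 1 ms grid, Hz.
#' @param refractory_ms absolute refractory period, ms.
#' @param ... label fields passed to [spike_train()].
#' @return a [spike_train()]. Uses the current R RNG stream.
#' @export
sample_spikes <- function(lambda_hz, refractory_ms = 1, ...) {
  D <- length(lambda_hz)
  p <- pmin(pmax(lambda_hz, 0) / 1000, 1)
  cand <- which(runif(D) < p) - 1L
  if (length(cand)) {
    keep <- logical(length(cand))
    last <- -Inf
    for (i in seq_along(cand)) {
      if (cand[i] - last > refractory_ms) {
        keep[i] <- TRUE
        last <- cand[i]
      }
    }
    cand <- cand[keep]
  }
  spike_train(cand, duration_ms = D, ...)
}

#' Generate a balanced labeled synthetic dataset
#'
#' Draws `n_units_per_subtype` units per subtype, each with a log-normal
#' gain multiplier (units differ in sensitivity, making repeated trials
#' from one unit correlated), then
#' `n_trials_per_unit_per_expression` trials per unit and expression:
#' envelope realization -> subtype rate transform -> thinned sampling.
#'
#' @param config a [generator_config()].
#' @param subtypes,expressions optional subsets to generate.
#' @return a [spike_dataset()]; bit-identical for a fixed config.
#' @export
generate_dataset <- function(config = generator_config(),
                             subtypes = AFFERENT_SUBTYPES,
                             expressions = EXPRESSIONS) {
  stopifnot(inherits(config, "generator_config"))
  profiles <- expression_profiles()[expressions]
  models <- subtype_models()[subtypes]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  trials <- list()
  k <- 0L
  for (s in subtypes) {
    model <- models[[s]]
    for (u in seq_len(config$n_units_per_subtype)) {
      unit_id <- sprintf("%s_u%02d", s, u)
      gain_mult <- exp(rnorm(1, 0, config$unit_level_gain_sd))
      m <- model
      for (gn in c("gain_vertical", "gain_tangential", "gain_static"))
        m[[gn]] <- model[[gn]] * gain_mult
      for (e in expressions) {
        for (r in seq_len(config$n_trials_per_unit_per_expression)) {
          env <- build_envelope(profiles[[e]], config$duration_ms,
                                config$timing_jitter_sd_ms)
          lambda <- rate_transform(env, m)
          k <- k + 1L
          trials[[k]] <- sample_spikes(
            lambda, refractory_ms = m$refractory_ms,
            unit_id = unit_id, subtype = s, expression = e,
            trial_id = sprintf("%s_%s_t%02d", unit_id, e, r))
        }
      }
    }
  }
  spike_dataset(trials,
                provenance = sprintf("synthetic seed=%d units=%d trials=%d",
                                     config$seed, config$n_units_per_subtype,
                                     config$n_trials_per_unit_per_expression))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
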
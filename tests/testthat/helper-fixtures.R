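# Shared synthetic fixtures, generated once per test run and memoized.
# Scales are kept small (2 units x 3 trials per cell = 36 trials/subtype,
# the minimum that supports 5-fold stratification with per-class n = 6)
# so the whole suite stays within its time budget.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

fixture_dataset <- function(subtypes = c("SA-II", "HFA", "CT", "MS"),
                            seed = 11L) {
  fixture(paste0("ds_", paste(subtypes, collapse = "_"), "_", seed),
          function() generate_dataset(
            generator_config(n_units_per_subtype = 2L,
                             n_trials_per_unit_per_expression = 3L,
                             seed = seed),
            subtypes = subtypes))
}

# quick CNN settings for contract tests where full training is not the
# point (chance-level and protocol-identity checks)
fast_cnn <- function(input_len = 10000L) {
  cnn_spec(input_len = input_len, max_epochs = 30L, patience = 8L)
}
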
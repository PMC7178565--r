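# Shared trained models, built once per test session and cached.
# Problem sizes are the package's desk-scale study conditions (see the
# methods vignette): ~2,000 default-regime training windows for the
# architecture comparison, and an easy-regime set (low noise,
# deterministic dwell) for end-to-end pipeline checks.

.model_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.model_cache[[key]])) .model_cache[[key]] <- build()
  .model_cache[[key]]
}

easy_pore <- function() pore_model(k = 1, noise_sd = 0.05)
easy_dwell <- function() dwell_params(9, "fixed", drift_amplitude = 0)

bench_train_set <- function() {
  cache_get("bench_train", function() {
    make_dataset(170, 400, window_length = 300, seed = 101)
  })
}

bench_heldout_set <- function() {
  cache_get("bench_heldout", function() {
    make_dataset(20, 400, window_length = 300, seed = 9901)
  })
}

# one trained variant per (variant, seed) on the shared benchmark data
bench_fit <- function(variant, seed) {
  cache_get(paste0("bench_", variant, "_", seed), function() {
    m <- build_model(urnet_config(variant, preset = "tiny"), 300, seed = seed)
    train_model(m, bench_train_set(), epochs = 3, batch_size = 64, seed = seed)
  })
}

easy_train_set <- function() {
  cache_get("easy_train", function() {
    make_dataset(60, 400, pore = easy_pore(), dwell = easy_dwell(),
                 window_length = 300, seed = 301)
  })
}

easy_fit <- function() {
  cache_get("easy_fit", function() {
    m <- build_model(urnet_config("urnet", preset = "tiny"), 300, seed = 1)
    train_model(m, easy_train_set(), epochs = 8, batch_size = 32,
                learning_rate = 2e-3, seed = 1)
  })
}

easy_reads <- function(n = 20, seed = 777) {
  simulate_read_set(n, 400, pore = easy_pore(), dwell = easy_dwell(), seed = seed)
}
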
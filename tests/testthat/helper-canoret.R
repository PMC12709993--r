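# Shared fixtures, built once per test run.

.canoret_test_env <- new.env(parent = emptyenv())

# Small look-up table reused across test files.
test_lut <- function(n = 300L, seed = 42L) {
  key <- sprintf("lut_%d_%d", n, seed)
  if (is.null(.canoret_test_env[[key]])) {
    .canoret_test_env[[key]] <- build_lut(n = n, seed = seed)
  }
  .canoret_test_env[[key]]
}

# A typical mid-season rice parameter record.
typical_params <- function() {
  tibble::tibble(
    N = 1.5, Cab = 45, Car = 10, Cw = 0.015, Cm = 0.006,
    LAI = 3.5, Cam_alpha = 55, Hspot = 0.05, Psoil = 0.5
  )
}

# Fast training configuration for unit tests.
fast_cfg <- function(seed = 1L, epochs = 60L) {
  training_config(epochs = epochs, batch_size = 64L, patience = 60L,
                  seed = seed)
}

# 7000-record LUT + pre-trained model per seed, cached for the
# acceptance blocks. Test runs cap training at 120 epochs to stay within
# the suite's runtime envelope; the acceptance script trains with the
# full default budget.
acceptance_pretrained <- function(seed, epochs = 120L) {
  key <- sprintf("pre_%d", seed)
  if (is.null(.canoret_test_env[[key]])) {
    lut <- test_lut(n = 7000L, seed = seed)
    model <- pretrain(lut, cfg = training_config(seed = seed, epochs = epochs))
    .canoret_test_env[[key]] <- list(lut = lut, model = model)
  }
  .canoret_test_env[[key]]
}
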
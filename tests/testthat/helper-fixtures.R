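# Expensive fixtures (pretrained toy models and their training sets) are
# built once per test session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# Desk-scale carton study conditions: 64 procedural cartons, desk preset,
# pretraining seed 0.
carton_training_set <- function() {
  fixture("carton_train", carton_population(64, seed = 101))
}

carton_model <- function() {
  fixture("carton_model", pretrain_gan(carton_training_set(), desk_config(seed = 0)))
}

# Tiny throwaway model for mechanics-level tests (seconds, not minutes).
tiny_model <- function() {
  fixture("tiny_model", pretrain_gan(
    carton_population(16, seed = 3),
    desk_config(seed = 0, epochs = 5)
  ))
}

# Plant study conditions: per-complexity models on 16 plants each.
plant_model <- function(level) {
  fixture(paste0("plant_model_", level), pretrain_gan(
    plant_population(16, level = level, seed = 300 + level),
    desk_config(seed = 0, epochs = 120)
  ))
}
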
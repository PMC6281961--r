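# Shared fixtures: deterministic configs and scaled-down schedules used
# across test files.  All scaled schedules keep the printed block
# structure (4 sessions x 4 blocks for the predictability design, 4
# blocks for the motivation design) and shrink only the repetition
# counts.

quiet_effects <- function(...) {
  # noise-free generator: planted values propagate exactly
  effect_config(sd_participant = 0, sd_trial = 0, sd_noise = 0,
                shaking_amplitude = 0, ...)
}

small_exp1_schedule <- function(participant = 1L, seed = 1L) {
  build_exp1_schedule(participant, "blocked", seed = seed,
                      blocked_reps = 2L, random_reps = 1L)
}

small_exp1_design <- function(n = 4L, seed = 1L) {
  build_exp1_design(n, seed = seed, blocked_reps = 2L, random_reps = 1L)
}

small_exp2_design <- function(n = 4L, seed = 1L) {
  build_exp2_design(n, seed = seed, reps = 2L)
}

# toy per-trial feature table with known cell means
toy_features <- function() {
  grid <- expand.grid(participant = 1:3,
                      category = softness_categories(1),
                      presentation_order = c("blocked", "random"),
                      rep = 1:2, stringsAsFactors = FALSE)
  grid$category <- category_factor(grid$category)
  grid$first_peak <- with(grid, participant + as.integer(category) / 10 +
                            ifelse(presentation_order == "blocked", 0.5, 0) +
                            ifelse(rep == 2, 0.2, 0))
  grid$last_peak <- grid$first_peak + 1
  tibble::as_tibble(grid)
}

category_factor <- hapticforce:::category_factor
derive_seed <- hapticforce:::derive_seed
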
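# Shared fixtures. Everything is generated in code at test time; the heavier
# artifacts (a trained toy generative model) are built once per test run and
# memoized so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

toy_grid <- function() grid_spec(4, 6, 2, 4)

# A tiny hand-buildable cohort of n patients with D features.
toy_cohort <- function(n = 3, D = 2, Tn = grid_obs_length(toy_grid()),
                       seed = 42) {
  healthgen:::with_seed(seed, {
    records <- lapply(seq_len(n), function(i) {
      m <- matrix(rbinom(Tn * D, 1, 0.6), Tn, D)
      x <- matrix(rnorm(Tn * D), Tn, D) * m
      patient_record(x, m, s = c(sample(2, 1), sample(3, 1)),
                     y = rbinom(1, 1, 0.5), patient_id = paste0("p", i))
    })
    # guarantee both classes
    records[[1]]$y <- 0L
    records[[n]]$y <- 1L
    cohort(records, feature_names = paste0("f", seq_len(D)),
           static_vocab = list(sex = c("female", "male"),
                               insurance = c("a", "b", "c")),
           label_names = "vent",
           standardizer = list(mean = rep(0, D), sd = rep(1, D)),
           grid = toy_grid())
  })
}

# Simulator settings used as the study conditions of the TSTR experiments:
# a strong, recoverable label effect on feature 1 plus label-dependent
# missingness (MNAR), small subgroup structure.
tstr_sim_config <- function(n_patients = 600) {
  sim_config(n_patients = n_patients, n_features = 4,
             label_effect = c(3, 0, 0, 0))
}

toy_arch <- function() {
  healthgen_arch(dim_v = 8, dim_z = 8, dim_h = 16, dim_g = 16,
                 decoder_hidden = 32)
}

# Preprocessed simulated cohort + split, memoized.
get_sim_split <- function() {
  if (!is.null(.fixtures$split)) return(.fixtures$split)
  cfg <- tstr_sim_config()
  sim <- simulate_cohort(cfg, toy_grid(), seed = 11)
  co <- preprocess_cohort(sim$streams, toy_grid(),
                          feature_names = paste0("f", 1:cfg$n_features),
                          static_vocab = sim_static_vocab(cfg),
                          label_names = "task")
  .fixtures$split <- split_cohort(co, c(0.7, 0.15, 0.15), 1, seed = 7)
  .fixtures$split
}

# Trained toy generative model on the simulated training split, memoized.
get_trained_model <- function() {
  if (!is.null(.fixtures$model)) return(.fixtures$model)
  sp <- get_sim_split()
  .fixtures$model <- healthgen(sp$train, val = NULL, arch = toy_arch(),
                               epochs = 80, batch_size = 64,
                               learning_rate = 2e-3, seed = 0)
  .fixtures$model
}
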
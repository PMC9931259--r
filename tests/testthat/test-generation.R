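test_that("sampled patients have the right shape and satisfy record invariants", {
  co <- toy_cohort(n = 10, D = 3)
  mod <- healthgen(co, arch = toy_arch(), epochs = 1, batch_size = 10,
                   learning_rate = 0, seed = 0)
  rec <- sample_patient(mod, s = c(1L, 2L), y = 1L, seed = 3)
  expect_equal(dim(rec$x), c(25, 3))
  expect_equal(dim(rec$m), c(25, 3))
  expect_silent(healthgen:::validate_record(rec))   # zeros where m = 0 etc.

  rec2 <- sample_patient(mod, s = c(1L, 2L), y = 1L, seed = 3)
  expect_identical(rec$x, rec2$x)
  expect_identical(rec$m, rec2$m)
  rec3 <- sample_patient(mod, s = c(1L, 2L), y = 1L, seed = 4)
  expect_false(identical(rec$x, rec3$x))
})

test_that("generate_cohort returns the exact requested (s, y) contingency", {
  co <- toy_cohort(n = 12, D = 2)
  mod <- healthgen(co, arch = toy_arch(), epochs = 1, batch_size = 12,
                   learning_rate = 0, seed = 0)
  spec <- data.frame(sex = c("female", "male"), insurance = c("a", "b"),
                     y = c(1L, 0L), n = c(10L, 5L))
  synth <- generate_cohort(mod, spec, template = co, seed = 1)
  expect_equal(length(synth), 15L)
  expect_identical(synth$provenance, "synthetic")
  s <- healthgen:::cohort_statics(synth)
  y <- healthgen:::cohort_labels(synth, 1)
  expect_equal(sum(s[, 1] == 1 & s[, 2] == 1 & y == 1), 10)
  expect_equal(sum(s[, 1] == 2 & s[, 2] == 2 & y == 0), 5)
  expect_error(generate_cohort(mod, data.frame(sex = "none", insurance = "a",
                                               y = 1L, n = 1L), co, 1),
               "unknown category")
})

test_that("mirror mode reproduces the template's (s, y) contingency table", {
  co <- toy_cohort(n = 30, D = 2)
  mod <- healthgen(co, arch = toy_arch(), epochs = 1, batch_size = 30,
                   learning_rate = 0, seed = 0)
  synth <- simulate(mod, seed = 2, template = co)
  expect_equal(length(synth), length(co))
  tab_real <- table(healthgen:::cohort_statics(co)[, 1],
                    healthgen:::cohort_statics(co)[, 2],
                    healthgen:::cohort_labels(co, 1))
  tab_synth <- table(healthgen:::cohort_statics(synth)[, 1],
                     healthgen:::cohort_statics(synth)[, 2],
                     healthgen:::cohort_labels(synth, 1))
  expect_equal(as.numeric(tab_synth), as.numeric(tab_real))
})

test_that("unconditional-in-s models still generate exact label counts", {
  co <- toy_cohort(n = 10, D = 2)
  arch <- healthgen_arch(dim_v = 4, dim_z = 4, dim_h = 8, dim_g = 8,
                         decoder_hidden = 16, condition_on_static = FALSE)
  mod <- healthgen(co, arch = arch, epochs = 1, batch_size = 10,
                   learning_rate = 0, seed = 0)
  spec <- data.frame(y = c(1L, 0L), n = c(4L, 6L))
  synth <- generate_cohort(mod, spec, template = co, seed = 5)
  expect_equal(sum(healthgen:::cohort_labels(synth, 1)), 4)
  expect_equal(length(synth), 10L)
})

test_that("augmentation balances category counts to the majority", {
  healthgen:::with_seed(31, {
    records <- lapply(1:100, function(i) {
      m <- matrix(rbinom(50, 1, 0.5), 25, 2)
      patient_record(matrix(rnorm(50), 25, 2) * m, m,
                     s = c(if (i <= 90) 1L else 2L, sample(3, 1)),
                     y = rbinom(1, 1, 0.4), patient_id = paste0("p", i))
    })
  })
  co <- cohort(records, c("f1", "f2"),
               list(sex = c("female", "male"), insurance = c("a", "b", "c")),
               "vent", list(mean = c(0, 0), sd = c(1, 1)), toy_grid())
  mod <- healthgen(co, arch = toy_arch(), epochs = 1, batch_size = 100,
                   learning_rate = 0, seed = 0)
  aug <- augment_cohort(co, mod, static_var_index = 1, task_index = 1, seed = 2)
  s_aug <- healthgen:::cohort_statics(aug)[, 1]
  expect_equal(as.numeric(table(s_aug)), c(90, 90))
  expect_identical(aug$provenance, "augmented")
  # real records pass through bit-identically, in order
  for (i in 1:100) {
    expect_identical(aug$records[[i]], co$records[[i]])
  }
  # synthetic complement preserves the minority's label balance (rounded)
  added <- aug$records[101:180]
  y_added <- vapply(added, function(r) r$y[1], integer(1))
  y_real_min <- vapply(records[91:100], function(r) r$y[1], integer(1))
  expect_equal(sum(y_added), round(80 * mean(y_real_min)))

  # already balanced: fixed point
  co_bal <- co
  co_bal$records <- co$records[c(1:10, 91:100)]
  aug2 <- augment_cohort(co_bal, mod, 1, 1, seed = 3)
  expect_identical(aug2, co_bal)
})

test_that("three-way augmentation arithmetic fills every deficit", {
  healthgen:::with_seed(32, {
    cats <- rep(1:3, c(60, 30, 10))
    records <- lapply(seq_along(cats), function(i) {
      m <- matrix(rbinom(25, 1, 0.5), 25, 1)
      patient_record(matrix(rnorm(25), 25, 1) * m, m,
                     s = cats[i], y = rbinom(1, 1, 0.5),
                     patient_id = paste0("p", i))
    })
  })
  co <- cohort(records, "f1", list(grp = c("a", "b", "c")), "vent",
               list(mean = 0, sd = 1), toy_grid())
  mod <- healthgen(co, arch = healthgen_arch(4, 4, 8, 8, 16), epochs = 1,
                   batch_size = 100, learning_rate = 0, seed = 0)
  aug <- augment_cohort(co, mod, 1, 1, seed = 1)
  expect_equal(as.numeric(table(healthgen:::cohort_statics(aug)[, 1])),
               c(60, 60, 60))
  expect_equal(length(aug), 180L)
})

test_that("generated missingness rates track the training cohort after fitting", {
  sp <- get_sim_split()
  mod <- get_trained_model()
  train_rate <- colMeans(do.call(rbind, lapply(sp$train$records,
                                               function(r) colMeans(r$m))))
  devs <- sapply(1:3, function(k) {
    synth <- simulate(mod, seed = 100 + k, template = sp$train)
    synth_rate <- colMeans(do.call(rbind, lapply(synth$records,
                                                 function(r) colMeans(r$m))))
    abs(synth_rate - train_rate)
  })
  expect_lt(max(rowMeans(devs)), 0.05)
})
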
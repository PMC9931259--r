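mk_stream <- function(events = data.frame(feature = integer(0),
                                          time = numeric(0),
                                          value = numeric(0)),
                      interventions = data.frame(label = integer(0),
                                                 start = numeric(0),
                                                 end = numeric(0)),
                      statics = c(1L, 1L), id = "p1") {
  event_stream(events, interventions, statics, id)
}

test_that("events land on their nearest grid point, later event wins ties", {
  g <- toy_grid()
  st <- mk_stream(events = data.frame(feature = c(1, 1),
                                      time = c(0.10, 0.22),
                                      value = c(5, 7)))
  raw <- resample_to_grid(st, g, n_features = 2)
  expect_equal(raw[1, 1], 5)   # 0.10 h -> grid point at 0.00 h
  expect_equal(raw[2, 1], 7)   # 0.22 h -> grid point at 0.25 h
  expect_true(all(is.na(raw[-(1:2), 1])))
  expect_true(all(is.na(raw[, 2])))

  # within one window the event closest in time wins ...
  st2 <- mk_stream(events = data.frame(feature = c(1, 1),
                                       time = c(0.26, 0.30),
                                       value = c(1, 2)))
  expect_equal(resample_to_grid(st2, g, 1)[2, 1], 1)
  # ... and the later one wins an exact distance tie
  st3 <- mk_stream(events = data.frame(feature = c(1, 1),
                                       time = c(0.20, 0.30),
                                       value = c(1, 2)))
  expect_equal(resample_to_grid(st3, g, 1)[2, 1], 2)
})

test_that("empty streams give an all-missing grid; out-of-span events warn", {
  g <- toy_grid()
  raw <- resample_to_grid(mk_stream(), g, n_features = 3)
  expect_equal(dim(raw), c(healthgen:::grid_total_length(g), 3))
  expect_true(all(is.na(raw)))
  st <- mk_stream(events = data.frame(feature = 1, time = 50, value = 1))
  expect_warning(raw2 <- resample_to_grid(st, g, 1), "dropped")
  expect_true(all(is.na(raw2)))
})

test_that("observation block has 25 rows at the default clinical grid", {
  g <- toy_grid()
  expect_identical(grid_obs_length(g), 25L)
  expect_identical(healthgen:::grid_total_length(g), 49L)
  raw <- resample_to_grid(mk_stream(), g, 1)
  expect_equal(nrow(truncate_to_observation(raw, g)), 25)
  # degenerate grid: no gap/prediction beyond the observation block
  g0 <- grid_spec(4, 6, 0, 1e-9)
  expect_error(truncate_to_observation(matrix(0, 10, 1), toy_grid()),
               "observation block")
})

test_that("grid length follows T = obs_hours * steps_per_hour + 1", {
  for (f in c(1, 2, 4)) for (obs in c(1, 6, 9.5)) {
    if (abs(obs * f - round(obs * f)) > 1e-9) next
    expect_identical(grid_obs_length(grid_spec(f, obs, 1, 1)),
                     as.integer(obs * f) + 1L)
  }
})

test_that("mask extraction mirrors missingness exactly", {
  raw <- matrix(c(1.2, NA, NA, 0.0), 2, 2, byrow = TRUE)
  expect_equal(extract_mask(raw), matrix(c(1L, 0L, 0L, 1L), 2, 2, byrow = TRUE))
  expect_true(all(extract_mask(matrix(NA_real_, 3, 2)) == 0))
  expect_true(all(extract_mask(matrix(1, 3, 2)) == 1))
  # duality: count of ones equals count of observed cells
  healthgen:::with_seed(5, {
    raw2 <- matrix(rnorm(40), 8, 5)
    raw2[sample(40, 15)] <- NA
  })
  expect_equal(sum(extract_mask(raw2)), 25)
})

test_that("standardizer uses observed cells only, population sd, sd floor", {
  raw <- matrix(c(1, NA, 3, NA, NA, NA), 3, 2)
  std <- fit_standardizer(list(raw))
  expect_equal(std$mean[1], 2)
  expect_equal(std$sd[1], 1)          # population convention: sqrt(((1)^2+(1)^2)/2)
  expect_equal(std$mean[2], 0)        # never observed: fallback
  expect_equal(std$sd[2], 1)

  const <- matrix(c(5, 5, 5), 3, 1)
  stdc <- fit_standardizer(list(const))
  expect_equal(stdc$mean[1], 5)
  expect_equal(stdc$sd[1], 1e-6)

  # missing cells do not move the moments
  raw_b <- rbind(raw, matrix(NA, 10, 2))
  expect_equal(fit_standardizer(list(raw_b))$mean[1], 2)
})

test_that("standardization centers observed cells and zeroes missing ones", {
  std <- list(mean = c(2), sd = c(1))
  expect_equal(apply_standardizer(matrix(c(2, NA), 1), list(mean = 2, sd = 1)),
               matrix(c(0, 0), 1))
  expect_equal(apply_standardizer(matrix(4, 1, 1), std), matrix(2, 1, 1))
  # refit on own output: mean ~ 0, sd ~ 1 over observed cells
  healthgen:::with_seed(6, raw <- matrix(rnorm(200, 5, 3), 40, 5))
  raw[sample(200, 60)] <- NA
  std2 <- fit_standardizer(list(raw))
  zed <- apply_standardizer(raw, std2)
  zed[is.na(raw)] <- NA
  refit <- fit_standardizer(list(zed))
  expect_lt(max(abs(refit$mean)), 1e-9)
  expect_lt(max(abs(refit$sd - 1)), 1e-9)
})

test_that("labels read the open-start prediction window only", {
  g <- toy_grid()  # windows: obs (0,6], gap (6,8], prediction (8,12]
  st <- mk_stream(interventions = data.frame(label = 1, start = 9, end = 9.5))
  expect_equal(extract_labels(st, g, 2), c(1L, 0L))
  st2 <- mk_stream(interventions = data.frame(label = 1, start = 6.5, end = 7.5))
  expect_equal(extract_labels(st2, g, 1), 0L)
  expect_equal(extract_labels(mk_stream(), g, 3), c(0L, 0L, 0L))
  # boundary: ending exactly at the window's open start does not count
  st3 <- mk_stream(interventions = data.frame(label = 1, start = 7, end = 8))
  expect_equal(extract_labels(st3, g, 1), 0L)
  # label monotonicity: adding an interval can only flip 0 -> 1
  st4 <- mk_stream(interventions = data.frame(label = c(1, 1),
                                              start = c(6.5, 9),
                                              end = c(7.5, 9.5)))
  expect_equal(extract_labels(st4, g, 1), 1L)
})

test_that("delta recurrence counts hours since the last observation", {
  g <- toy_grid()
  m <- matrix(c(1L, 0L, 0L, 1L), 4, 1)
  expect_equal(compute_deltas(m, g), matrix(c(0, 0.25, 0.5, 0.75), 4, 1))
  expect_equal(compute_deltas(matrix(1L, 4, 1), g),
               matrix(c(0, 0.25, 0.25, 0.25), 4, 1))
  expect_equal(compute_deltas(matrix(0L, 4, 1), g),
               matrix(0.25 * (0:3), 4, 1))
})

test_that("preprocess_cohort composes the stages", {
  g <- toy_grid()
  streams <- list(
    mk_stream(events = data.frame(feature = 1, time = 0.1, value = 10),
              interventions = data.frame(label = 1, start = 9, end = 10),
              id = "a"),
    mk_stream(events = data.frame(feature = 2, time = 1.0, value = -4),
              id = "b"),
    mk_stream(id = "c"))   # zero events: retained, all-zero x and m
  co <- preprocess_cohort(streams, g, feature_names = c("hr", "bp"),
                          static_vocab = list(sex = c("f", "m"),
                                              ins = c("a", "b", "c")),
                          label_names = "vent")
  expect_equal(length(co), 3L)
  expect_equal(nrow(co$records[[1]]$x), 25)
  expect_equal(co$records[[1]]$y, 1L)
  expect_equal(co$records[[2]]$y, 0L)
  expect_equal(co$records[[1]]$m[1, 1], 1L)
  expect_true(all(co$records[[3]]$m == 0))
  expect_true(all(co$records[[3]]$x == 0))
  # two observations total, one per feature: each standardizes to (v - v)/sd = 0
  expect_equal(co$records[[1]]$x[1, 1], 0)

  # passing the fitted standardizer back in reproduces the cohort
  co2 <- preprocess_cohort(streams, g, c("hr", "bp"),
                           list(sex = c("f", "m"), ins = c("a", "b", "c")),
                           "vent", std = co$standardizer)
  expect_identical(co2$records[[1]]$x, co$records[[1]]$x)
})

test_that("stream filter applies the cohort-selection metadata checks", {
  s1 <- mk_stream(id = "keep")
  attr(s1, "age") <- 40; attr(s1, "stay_hours") <- 48; attr(s1, "stay_ordinal") <- 1
  s2 <- mk_stream(id = "tooyoung")
  attr(s2, "age") <- 12
  s3 <- mk_stream(id = "short")
  attr(s3, "stay_hours") <- 6
  s4 <- mk_stream(id = "second-stay")
  attr(s4, "stay_ordinal") <- 2
  kept <- filter_streams(list(s1, s2, s3, s4))
  expect_equal(vapply(kept, `[[`, character(1), "patient_id"), "keep")
})
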
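# Conversion of irregular per-patient event streams into the fixed-grid
# (x, m, s, y) representation: nearest-grid-point resampling, mask extraction,
# per-feature standardization with zero-imputation of missing cells, label
# extraction from the prediction window, and time-since-last-observation
# series for the downstream classifier.

#' Construct an event stream
#'
#' The raw interchange format for one patient: irregularly timed measurement
#' events, intervention intervals, and static category codes.
#'
#' @param events data.frame with columns `feature` (1-based index),
#'   `time` (hours) and `value`; may have zero rows.
#' @param interventions data.frame with columns `label` (1-based index),
#'   `start` and `end` (hours); may have zero rows.
#' @param statics integer vector of 1-based static category codes.
#' @param patient_id character id.
#' @export
event_stream <- function(events, interventions, statics, patient_id) {
  if (nrow(interventions) && any(interventions$start > interventions$end)) {
    stop("patient ", patient_id, ": intervention interval with start > end")
  }
  structure(list(events = events, interventions = interventions,
                 statics = as.integer(statics),
                 patient_id = as.character(patient_id)),
            class = "event_stream")
}

#' Resample an event stream onto the regular grid
#'
#' Grid point k sits at time `k / steps_per_hour`; its assignment window is
#' half a step on either side, left-closed/right-open. When several events of
#' the same feature fall into one window the one closest in time wins, the
#' later one on a tie. Events outside the grid span are dropped with a
#' warning. Unassigned cells carry `NA`.
#'
#' @param stream an [event_stream()].
#' @param grid a [grid_spec()].
#' @param n_features number of feature columns D.
#' @return A `T_total x D` numeric matrix with `NA` at missing cells.
#' @export
resample_to_grid <- function(stream, grid, n_features) {
  T_total <- grid_total_length(grid)
  f <- grid$steps_per_hour
  vals <- matrix(NA_real_, T_total, n_features)
  ev <- stream$events
  if (is.null(ev) || nrow(ev) == 0) return(vals)
  span <- grid_span_hours(grid)
  outside <- ev$time < 0 | ev$time >= span + 0.5 / f
  if (any(outside)) {
    warning(sum(outside), " event(s) outside the grid span dropped for patient ",
            stream$patient_id)
    ev <- ev[!outside, , drop = FALSE]
  }
  if (nrow(ev) == 0) return(vals)
  k <- floor(ev$time * f + 0.5)            # left-closed/right-open window
  k <- pmin(k, T_total - 1L)
  dist <- abs(ev$time - k / f)
  # order so that for each (feature, grid point) the winning event is last:
  # larger distance first, earlier time first on equal distance (the later
  # event wins ties), then overwrite in order.
  ord <- order(ev$feature, k, -dist, ev$time)
  for (i in ord) vals[k[i] + 1L, ev$feature[i]] <- ev$value[i]
  vals
}

#' Extract the binary missingness mask
#'
#' `m[t, d] = 1` exactly where the resampled grid holds an observed value.
#'
#' @param raw matrix with `NA` at missing cells.
#' @return Binary matrix of the same shape.
#' @export
extract_mask <- function(raw) {
  m <- matrix(0L, nrow(raw), ncol(raw))
  m[!is.na(raw)] <- 1L
  m
}

#' Fit a per-feature standardizer on observed cells
#'
#' Means and population (divide-by-n) standard deviations are pooled over all
#' patients and time steps, using observed cells only. Features with no
#' observations fall back to mean 0, sd 1; sds are floored at `sd_floor`.
#'
#' @param raws list of raw grids (matrices with `NA` at missing cells).
#' @param sd_floor minimum allowed sd (default 1e-6).
#' @return List with numeric vectors `mean` and `sd`.
#' @export
fit_standardizer <- function(raws, sd_floor = 1e-6) {
  D <- ncol(raws[[1]])
  mean_d <- numeric(D)
  sd_d <- numeric(D)
  for (d in seq_len(D)) {
    v <- unlist(lapply(raws, function(r) r[, d]))
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      mean_d[d] <- 0; sd_d[d] <- 1
    } else {
      mean_d[d] <- mean(v)
      sd_d[d] <- max(sqrt(mean((v - mean_d[d])^2)), sd_floor)
    }
  }
  list(mean = mean_d, sd = sd_d)
}

#' Apply a standardizer and impute missing cells with zero
#'
#' Observed cells become `(value - mean_d) / sd_d`; missing cells become
#' exactly 0.
#'
#' @param raw matrix with `NA` at missing cells.
#' @param std list with `mean` and `sd` as from [fit_standardizer()].
#' @export
apply_standardizer <- function(raw, std) {
  out <- sweep(sweep(raw, 2L, std$mean, "-"), 2L, std$sd, "/")
  out[is.na(out)] <- 0
  out
}

#' Extract intervention labels from the prediction window
#'
#' A label is positive iff one of its intervals intersects the open-start
#' prediction window `(obs_hours + gap_hours, total span]`. Activity confined
#' to the observation or gap windows does not count.
#'
#' @param stream an [event_stream()].
#' @param grid a [grid_spec()].
#' @param n_labels number of intervention labels L.
#' @return Integer 0/1 vector of length `n_labels`.
#' @export
extract_labels <- function(stream, grid, n_labels) {
  y <- integer(n_labels)
  iv <- stream$interventions
  if (is.null(iv) || nrow(iv) == 0) return(y)
  w0 <- grid$obs_hours + grid$gap_hours
  w1 <- grid_span_hours(grid)
  hit <- iv$end > w0 & iv$start <= w1
  y[unique(iv$label[hit])] <- 1L
  y
}

#' Truncate grid matrices to the observation block
#'
#' Keeps the first `T = obs_hours * steps_per_hour + 1` rows; the gap and
#' prediction rows are consumed only by [extract_labels()].
#'
#' @param mat `T_total x D` matrix.
#' @param grid a [grid_spec()].
#' @export
truncate_to_observation <- function(mat, grid) {
  Tn <- grid_obs_length(grid)
  if (nrow(mat) < Tn) {
    stop("matrix has ", nrow(mat), " rows but the observation block needs ", Tn)
  }
  mat[seq_len(Tn), , drop = FALSE]
}

#' Time since last observation per feature
#'
#' The decay input of the downstream classifier: with grid step
#' `delta = 1 / steps_per_hour` hours, `d[1, ] = 0` and for t > 1
#' `d[t, j] = delta + d[t-1, j] * (1 - m[t-1, j])` (the counter resets on an
#' observation and grows by one step otherwise).
#'
#' @param m binary T x D mask.
#' @param grid a [grid_spec()].
#' @return Nonnegative T x D matrix of hours.
#' @export
compute_deltas <- function(m, grid) {
  step <- 1 / grid$steps_per_hour
  Tn <- nrow(m); D <- ncol(m)
  delta <- matrix(0, Tn, D)
  if (Tn > 1) {
    for (t in 2:Tn) {
      delta[t, ] <- step + delta[t - 1, ] * (m[t - 1, ] == 0)
    }
  }
  delta
}

#' Preprocess event streams into a cohort
#'
#' Composes grid resampling, mask extraction, standardization (fitted on
#' these streams unless a training standardizer is supplied), truncation to
#' the observation block and label extraction.
#'
#' @param streams list of [event_stream()] objects.
#' @param grid a [grid_spec()].
#' @param feature_names character vector (defines D).
#' @param static_vocab named list of category-name vectors (defines M).
#' @param label_names character vector (defines L).
#' @param std optional standardizer from the training pass; when `NULL` one is
#'   fitted on `streams`.
#' @param provenance cohort provenance tag.
#' @return An [cohort()].
#' @export
preprocess_cohort <- function(streams, grid, feature_names, static_vocab,
                              label_names, std = NULL, provenance = "real") {
  D <- length(feature_names)
  L <- length(label_names)
  raws <- lapply(streams, resample_to_grid, grid = grid, n_features = D)
  if (is.null(std)) std <- fit_standardizer(raws)
  records <- vector("list", length(streams))
  for (i in seq_along(streams)) {
    m_full <- extract_mask(raws[[i]])
    x_full <- apply_standardizer(raws[[i]], std)
    records[[i]] <- patient_record(
      x = truncate_to_observation(x_full, grid),
      m = truncate_to_observation(m_full, grid),
      s = streams[[i]]$statics,
      y = extract_labels(streams[[i]], grid, L),
      patient_id = streams[[i]]$patient_id)
  }
  cohort(records, feature_names, static_vocab, label_names, std, grid,
         provenance)
}

#' Filter streams on cohort-selection metadata
#'
#' Standard ICU cohort selection expressed as a metadata check: keep the
#' first ICU stay of adult patients with a minimum stay length. Streams
#' lacking the attributes are kept.
#'
#' @param streams list of [event_stream()] objects, optionally carrying
#'   `age`, `stay_hours` and `stay_ordinal` attributes.
#' @param min_age minimum age in years (default 15).
#' @param min_stay_hours minimum stay length (default 12).
#' @export
filter_streams <- function(streams, min_age = 15, min_stay_hours = 12) {
  keep <- vapply(streams, function(s) {
    age <- attr(s, "age"); stay <- attr(s, "stay_hours")
    ord <- attr(s, "stay_ordinal")
    (is.null(age) || age >= min_age) &&
      (is.null(stay) || stay >= min_stay_hours) &&
      (is.null(ord) || ord == 1)
  }, logical(1))
  streams[keep]
}
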
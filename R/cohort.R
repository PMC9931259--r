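# Data model for fixed-grid ICU-style cohorts: per patient a standardized
# feature matrix x (T x D, zeros at missing cells), a binary missingness mask
# m (T x D), integer static-category codes s (length M, 1-based into the
# cohort's static_vocab), and binary intervention labels y (length L).

#' Time-grid specification
#'
#' Defines the regular sampling grid: `steps_per_hour` grid points per hour
#' with an inclusive endpoint, a leading observation window, a hold-out gap
#' and a final prediction window. The observation block has
#' `T = obs_hours * steps_per_hour + 1` rows (25 at the defaults: 4 steps/hour
#' over 6 hours).
#'
#' @param steps_per_hour positive integer sampling frequency (default 4).
#' @param obs_hours length of the observation window in hours (default 6).
#' @param gap_hours length of the hold-out gap in hours (default 2).
#' @param pred_hours length of the prediction window in hours (default 4).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(steps_per_hour = 4, obs_hours = 6, gap_hours = 2,
                      pred_hours = 4) {
  stopifnot(steps_per_hour >= 1, obs_hours > 0, gap_hours >= 0, pred_hours > 0)
  g <- list(steps_per_hour = as.integer(steps_per_hour),
            obs_hours = obs_hours, gap_hours = gap_hours,
            pred_hours = pred_hours)
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d steps/hour, %g h obs + %g h gap + %g h prediction (T = %d)\n",
              x$steps_per_hour, x$obs_hours, x$gap_hours, x$pred_hours,
              grid_obs_length(x)))
  invisible(x)
}

#' Observation-sequence length for a grid
#'
#' @param grid a [grid_spec()].
#' @return Integer `T = obs_hours * steps_per_hour + 1`.
#' @export
grid_obs_length <- function(grid) {
  as.integer(round(grid$obs_hours * grid$steps_per_hour)) + 1L
}

grid_total_length <- function(grid) {
  span <- grid$obs_hours + grid$gap_hours + grid$pred_hours
  as.integer(round(span * grid$steps_per_hour)) + 1L
}

grid_span_hours <- function(grid) {
  grid$obs_hours + grid$gap_hours + grid$pred_hours
}

#' One patient's preprocessed record
#'
#' @param x numeric T x D matrix of standardized feature values, 0 at cells
#'   where `m` is 0.
#' @param m binary T x D missingness mask (1 = observed).
#' @param s integer vector of length M: 1-based category codes per static
#'   variable.
#' @param y binary vector of length L: intervention labels.
#' @param patient_id character id.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(x, m, s, y, patient_id) {
  r <- list(x = x, m = m, s = as.integer(s), y = as.integer(y),
            patient_id = as.character(patient_id))
  class(r) <- "patient_record"
  validate_record(r)
  r
}

validate_record <- function(r) {
  if (!identical(dim(r$x), dim(r$m))) {
    stop("patient ", r$patient_id, ": x and m must have identical shape")
  }
  if (any(!is.finite(r$x)) || any(!is.finite(r$m))) {
    stop("patient ", r$patient_id, ": non-finite values in x or m")
  }
  if (!all(r$m %in% c(0, 1))) {
    stop("patient ", r$patient_id, ": mask entries must be 0 or 1")
  }
  if (any(r$x[r$m == 0] != 0)) {
    stop("patient ", r$patient_id, ": x must be 0 wherever m is 0")
  }
  if (anyNA(r$s) || anyNA(r$y) || !all(r$y %in% c(0L, 1L))) {
    stop("patient ", r$patient_id, ": invalid s or y")
  }
  invisible(r)
}

#' Assemble a cohort
#'
#' A cohort bundles an ordered collection of patient records with the shared
#' vocabularies, the standardization statistics used at preprocessing and the
#' sampling grid.
#'
#' @param records list of [patient_record()] objects sharing T, D, M, L.
#' @param feature_names character vector of length D.
#' @param static_vocab named list: per static variable an ordered character
#'   vector of category names.
#' @param label_names character vector of length L.
#' @param standardizer list with numeric `mean` and strictly positive `sd`,
#'   both of length D.
#' @param grid a [grid_spec()].
#' @param provenance one of "real", "synthetic", "augmented".
#' @return An object of class `hg_cohort`.
#' @export
cohort <- function(records, feature_names, static_vocab, label_names,
                   standardizer, grid, provenance = "real") {
  provenance <- match.arg(provenance, c("real", "synthetic", "augmented"))
  co <- structure(
    list(records = records, feature_names = feature_names,
         static_vocab = static_vocab, label_names = label_names,
         standardizer = standardizer, grid = grid, provenance = provenance),
    class = "hg_cohort")
  validate_cohort(co)
  co
}

validate_cohort <- function(co) {
  D <- length(co$feature_names)
  M <- length(co$static_vocab)
  L <- length(co$label_names)
  Tn <- grid_obs_length(co$grid)
  if (length(co$standardizer$mean) != D || length(co$standardizer$sd) != D) {
    stop("standardizer length must equal number of features")
  }
  if (any(co$standardizer$sd <= 0)) stop("standardizer sds must be strictly positive")
  vocab_sizes <- vapply(co$static_vocab, length, integer(1))
  for (r in co$records) {
    validate_record(r)
    if (!identical(dim(r$x), c(Tn, D))) {
      stop("patient ", r$patient_id, ": x must be ", Tn, " x ", D)
    }
    if (length(r$s) != M || length(r$y) != L) {
      stop("patient ", r$patient_id, ": s or y has wrong length")
    }
    if (M > 0 && (any(r$s < 1L) || any(r$s > vocab_sizes))) {
      stop("patient ", r$patient_id, ": static code outside vocabulary")
    }
  }
  ids <- vapply(co$records, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids in cohort")
  invisible(co)
}

#' @export
print.hg_cohort <- function(x, ...) {
  cat(sprintf("<hg_cohort> %d patients, D = %d features, M = %d statics, L = %d labels (%s)\n",
              length(x$records), length(x$feature_names),
              length(x$static_vocab), length(x$label_names), x$provenance))
  print(x$grid)
  invisible(x)
}

#' @export
length.hg_cohort <- function(x) length(x$records)

cohort_ids <- function(co) vapply(co$records, `[[`, character(1), "patient_id")

cohort_labels <- function(co, task_index) {
  vapply(co$records, function(r) r$y[task_index], integer(1))
}

cohort_statics <- function(co) {
  M <- length(co$static_vocab)
  out <- matrix(0L, length(co$records), M)
  for (i in seq_along(co$records)) out[i, ] <- co$records[[i]]$s
  out
}

cohort_subset <- function(co, idx) {
  co$records <- co$records[idx]
  co
}

## ---- serialization --------------------------------------------------------

# On-disk layout: one directory per cohort holding little-endian binary array
# payloads (doubles for x and the standardizer, integers for m, s, y) plus a
# meta.json sidecar with names, vocabularies, grid, provenance and ids.
# Floating point never passes through decimal text, so round trips are
# bit-exact.

write_doubles <- function(v, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(v), con, size = 8, endian = "little")
}

read_doubles <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "numeric", n = n, size = 8, endian = "little")
}

write_ints <- function(v, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(v), con, size = 4, endian = "little")
}

read_ints <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "integer", n = n, size = 4, endian = "little")
}

#' Save a cohort to a directory
#'
#' Writes binary array payloads plus a `meta.json` sidecar. The invariants are
#' validated before writing; [load_cohort()] reproduces the cohort bit-exactly.
#'
#' @param co an [cohort()] object.
#' @param path directory to create/overwrite.
#' @export
save_cohort <- function(co, path) {
  validate_cohort(co)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  N <- length(co$records)
  Tn <- grid_obs_length(co$grid)
  D <- length(co$feature_names)
  M <- length(co$static_vocab)
  L <- length(co$label_names)
  x_all <- vapply(co$records, function(r) as.numeric(r$x), numeric(Tn * D))
  m_all <- vapply(co$records, function(r) as.integer(r$m), integer(Tn * D))
  s_all <- vapply(co$records, function(r) r$s, integer(M))
  y_all <- vapply(co$records, function(r) r$y, integer(L))
  write_doubles(x_all, file.path(path, "x.bin"))
  write_ints(m_all, file.path(path, "m.bin"))
  write_ints(s_all, file.path(path, "s.bin"))
  write_ints(y_all, file.path(path, "y.bin"))
  write_doubles(c(co$standardizer$mean, co$standardizer$sd,
                  co$grid$obs_hours, co$grid$gap_hours, co$grid$pred_hours),
                file.path(path, "std.bin"))
  meta <- list(
    format = "healthgen-cohort-v1",
    n = N, T = Tn, D = D, M = M, L = L,
    feature_names = co$feature_names,
    static_vocab = co$static_vocab,
    label_names = co$label_names,
    steps_per_hour = co$grid$steps_per_hour,
    provenance = co$provenance,
    patient_ids = if (N > 0) cohort_ids(co) else character(0)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a cohort from a directory
#'
#' @param path directory written by [save_cohort()].
#' @return The reconstructed [cohort()] (invariants re-validated).
#' @export
load_cohort <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json under ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("format", "n", "T", "D", "M", "L", "feature_names",
                "static_vocab", "label_names", "steps_per_hour", "provenance")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("cohort metadata missing keys: ", paste(missing, collapse = ", "))
  }
  N <- meta$n; Tn <- meta$T; D <- meta$D; M <- meta$M; L <- meta$L
  std <- read_doubles(file.path(path, "std.bin"), 2 * D + 3)
  grid <- grid_spec(meta$steps_per_hour, std[2 * D + 1], std[2 * D + 2],
                    std[2 * D + 3])
  x_all <- read_doubles(file.path(path, "x.bin"), N * Tn * D)
  m_all <- read_ints(file.path(path, "m.bin"), N * Tn * D)
  s_all <- read_ints(file.path(path, "s.bin"), N * M)
  y_all <- read_ints(file.path(path, "y.bin"), N * L)
  if (!all(m_all %in% c(0L, 1L))) stop("mask payload contains non-binary values")
  ids <- as.character(meta$patient_ids)
  records <- vector("list", N)
  for (i in seq_len(N)) {
    off <- (i - 1L) * Tn * D
    records[[i]] <- structure(
      list(x = matrix(x_all[off + seq_len(Tn * D)], Tn, D),
           m = matrix(m_all[off + seq_len(Tn * D)], Tn, D),
           s = s_all[(i - 1L) * M + seq_len(M)],
           y = y_all[(i - 1L) * L + seq_len(L)],
           patient_id = ids[i]),
      class = "patient_record")
  }
  vocab <- meta$static_vocab
  if (M > 0) vocab <- lapply(vocab, as.character) else vocab <- list()
  cohort(records,
         feature_names = as.character(meta$feature_names),
         static_vocab = vocab,
         label_names = as.character(meta$label_names),
         standardizer = list(mean = std[seq_len(D)], sd = std[D + seq_len(D)]),
         grid = grid, provenance = meta$provenance)
}

## ---- stratified split -----------------------------------------------------

#' Stratified train/validation/test split
#'
#' Splits a cohort into disjoint train/validation/test cohorts, stratified on
#' one designated task label so the positive rate differs between splits by at
#' most one record's worth. Deterministic given `seed`.
#'
#' @param co a [cohort()].
#' @param fractions numeric triple summing to 1 (default `c(0.7, 0.15, 0.15)`).
#' @param task_index which label column to stratify on (default 1).
#' @param seed integer RNG seed.
#' @return List of class `cohort_split` with elements `train`, `val`, `test`
#'   and `fractions`.
#' @export
split_cohort <- function(co, fractions = c(0.7, 0.15, 0.15), task_index = 1L,
                         seed = 0L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3)
  y <- cohort_labels(co, task_index)
  if (length(unique(y)) < 2 && length(y) > 1 && all(fractions > 0)) {
    stop("cannot stratify: all records share the same label for task ",
         task_index)
  }
  assign_class <- function(idx) {
    # largest-remainder allocation of one stratum across the three splits
    n <- length(idx)
    raw <- fractions * n
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      order_rem <- order(raw - base, decreasing = TRUE)
      base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
    }
    shuffled <- idx[sample.int(n)]
    list(train = shuffled[seq_len(base[1])],
         val = shuffled[base[1] + seq_len(base[2])],
         test = shuffled[base[1] + base[2] + seq_len(base[3])])
  }
  parts <- with_seed(seed, {
    pos <- assign_class(which(y == 1L))
    neg <- assign_class(which(y == 0L))
    list(train = sort(c(pos$train, neg$train)),
         val = sort(c(pos$val, neg$val)),
         test = sort(c(pos$test, neg$test)))
  })
  out <- list(train = cohort_subset(co, parts$train),
              val = cohort_subset(co, parts$val),
              test = cohort_subset(co, parts$test),
              fractions = fractions)
  class(out) <- "cohort_split"
  out
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> train %d / val %d / test %d\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}
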
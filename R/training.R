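#' Active-learning training pipeline
#'
#' Mirrors the automated model-building loop used with per-system GP force
#' fields: a pool of sampled geometries is split into a small initial
#' training set chosen from feature extremes, a fixed validation set and a
#' large sample pool; models are fitted, validated, and grown by moving the
#' sample-pool points with the highest summed posterior variance of the
#' atomic-energy models into the training set.
#'
#' @name training_pipeline
NULL

#' Select the initial training set from feature extremes
#'
#' For each feature of a designated reference atom, the pool points
#' attaining the minimum, the maximum and the value nearest the mean are
#' selected (duplicates collapsed), then padded with seeded random picks up
#' to `target_size`. With 12 features this yields at most 36 points before
#' padding and exactly `target_size` after.
#'
#' @param features_pool numeric matrix (pool x features) for the reference
#'   atom.
#' @param target_size final set size (default 36).
#' @param seed RNG seed for the padding draw.
#' @return integer vector of pool indices, length `target_size`.
#' @export
select_initial_training <- function(features_pool, target_size = 36,
                                    seed = 1) {
  n <- nrow(features_pool)
  if (n < target_size) stop("pool smaller than the requested training size")
  if (sum(!duplicated(round(features_pool, 12))) < target_size) {
    stop("pool is degenerate: fewer distinct geometries than training size")
  }
  picks <- unique(unlist(lapply(seq_len(ncol(features_pool)), function(k) {
    x <- features_pool[, k]
    c(which.min(x), which.max(x), which.min(abs(x - mean(x))))
  })))
  if (length(picks) > target_size) picks <- picks[seq_len(target_size)]
  set.seed(seed)
  pad <- setdiff(seq_len(n), picks)
  c(picks, sample(pad, target_size - length(picks)))
}

#' Split a geometry pool into training / validation / sample sets
#'
#' The initial training set comes from [select_initial_training()] on the
#' reference atom's features; the validation set is drawn randomly from the
#' remainder and never mutated; everything else is the sample pool that
#' adaptive sampling draws from. Deterministic for a fixed seed.
#'
#' @param features_pool reference-atom feature matrix (pool x features).
#' @param n_valid validation-set size (default 500).
#' @param seed RNG seed.
#' @param n_init initial training-set size (default 36).
#' @return list of class `dataset_split` with `train`, `valid`, `sample`
#'   index vectors and the `seed`.
#' @export
split_dataset <- function(features_pool, n_valid = 500, seed = 1,
                          n_init = 36) {
  n <- nrow(features_pool)
  if (n < n_valid) stop("pool smaller than the validation set")
  if (n < n_valid + n_init) stop("pool cannot hold validation + training")
  train <- select_initial_training(features_pool, n_init, seed = seed)
  set.seed(seed)
  rest <- setdiff(seq_len(n), train)
  valid <- sort(sample(rest, n_valid))
  pool <- setdiff(rest, valid)
  if (length(pool) == 0L) {
    warning("sample pool is empty: no room for adaptive sampling")
  }
  structure(list(train = train, valid = valid, sample = pool, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split: %d train / %d valid / %d sample (seed %d)\n",
              length(x$train), length(x$valid), length(x$sample), x$seed))
  invisible(x)
}

#' One adaptive-sampling step
#'
#' Moves the `batch` sample-pool points with the highest total posterior
#' predictive variance (summed over the atomic-energy models) into the
#' training set.
#'
#' @param models list of fitted energy `gpr_model`s, one per atom.
#' @param features_by_atom list (one entry per atom) of pool-sized feature
#'   matrices aligned with the pool indexing.
#' @param split a `dataset_split`.
#' @param batch number of points to move (default 1).
#' @param verbose log the selected indices and variances.
#' @return the updated `dataset_split` with an attribute `selected`.
#' @export
adaptive_sampling_step <- function(models, features_by_atom, split,
                                   batch = 1, verbose = FALSE) {
  if (length(split$sample) == 0L) stop("sample pool is empty")
  batch <- min(batch, length(split$sample))
  v <- rowSums(vapply(seq_along(models), function(a) {
    gpr_variance(models[[a]], features_by_atom[[a]][split$sample, ,
                                                    drop = FALSE])
  }, numeric(length(split$sample))))
  sel <- split$sample[order(-v)[seq_len(batch)]]
  if (verbose) {
    message("adaptive step: adding ", paste(sel, collapse = ", "),
            " (variance ", paste(signif(sort(v, decreasing = TRUE)[
              seq_len(batch)], 3), collapse = ", "), ")")
  }
  split$train <- c(split$train, sel)
  split$sample <- setdiff(split$sample, sel)
  attr(split, "selected") <- sel
  split
}

## fit per-atom models for one property column extractor
fit_atom_models <- function(features_by_atom, target_by_atom, idx, cyclic,
                            property, n_starts, seed, theta_list = NULL) {
  lapply(seq_along(features_by_atom), function(a) {
    gpr_fit(features_by_atom[[a]][idx, , drop = FALSE],
            target_by_atom[[a]][idx], cyclic, property = property,
            n_starts = n_starts, seed = seed + a,
            theta = if (is.null(theta_list)) NULL else theta_list[[a]])
  })
}

#' Run the full training loop on a geometry/property source
#'
#' Iterates fit -> validate -> adaptive sampling until the training set
#' reaches `n_final` (or the validation maximum absolute energy error drops
#' below `target_max_error`, if given). Per-atom energy models are always
#' built; models for moment components listed in `moment_columns` are
#' fitted at the final training size.
#'
#' @param geoms list of pool geometries (shared topology).
#' @param properties per-atom property table (see [read_property_table()])
#'   with `frame` indexing `geoms`.
#' @param config list: `n_final` (default 200), `n_valid` (default 500),
#'   `n_init` (36), `batch` (default 20), `n_starts` (4), `seed` (1),
#'   `refit_every` (1: refit hyperparameters each iteration; larger values
#'   refresh only the weights in between), `target_max_error` (optional,
#'   kJ/mol), `moment_columns` (character, default none),
#'   `reference_atom` (default: first heavy atom).
#' @return list with `energy_models`, `moment_models` (per atom, by
#'   column), `split`, `alfs`, `features_by_atom`, and a per-iteration
#'   `log` data.frame (iteration, n_train, median and max validation
#'   error).
#' @export
run_training <- function(geoms, properties, config = list()) {
  cfg <- utils::modifyList(
    list(n_final = 200, n_valid = 500, n_init = 36, batch = 20,
         n_starts = 4, seed = 1, refit_every = 1,
         target_max_error = NULL, moment_columns = character()),
    config)
  if (cfg$n_final < cfg$n_init) {
    stop("n_final must be at least the initial training size")
  }
  g1 <- geoms[[1]]
  n_at <- n_atoms(g1)
  alfs <- alf_list(g1)
  cyclic <- feature_cyclic_mask(n_at)
  features_by_atom <- lapply(seq_len(n_at), function(a) {
    feature_matrix(geoms, a, alfs)
  })
  ## energy targets per atom, aligned with the pool frames
  energy_by_atom <- lapply(seq_len(n_at), function(a) {
    rec <- properties[properties$atom == a, ]
    if (nrow(rec) == 0L) stop("property table has no records for atom ", a)
    rec <- rec[order(rec$frame), ]
    if (nrow(rec) != length(geoms)) {
      stop("property table does not cover every frame for atom ", a)
    }
    rec$energy
  })
  ref_atom <- cfg$reference_atom
  if (is.null(ref_atom)) ref_atom <- which(g1$number > 1)[1]
  split <- split_dataset(features_by_atom[[ref_atom]], cfg$n_valid,
                         cfg$seed, cfg$n_init)
  log <- NULL
  models <- NULL
  theta_list <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    refit <- is.null(models) || (iter - 1L) %% cfg$refit_every == 0L
    models <- fit_atom_models(
      features_by_atom, energy_by_atom, split$train, cyclic, "iqa-energy",
      cfg$n_starts, cfg$seed + iter,
      theta_list = if (refit) NULL else theta_list)
    theta_list <- lapply(models, `[[`, "theta")
    ## validation: cancellation-mode molecular energy error
    pred <- rowSums(vapply(seq_len(n_at), function(a) {
      gpr_predict(models[[a]],
                  features_by_atom[[a]][split$valid, , drop = FALSE])
    }, numeric(length(split$valid))))
    true <- rowSums(vapply(seq_len(n_at), function(a) {
      energy_by_atom[[a]][split$valid]
    }, numeric(length(split$valid))))
    err <- abs(pred - true)
    log <- rbind(log, data.frame(iteration = iter,
                                 n_train = length(split$train),
                                 median_error = stats::median(err),
                                 max_error = max(err)))
    done <- length(split$train) >= cfg$n_final ||
      (!is.null(cfg$target_max_error) &&
         max(err) <= cfg$target_max_error) ||
      length(split$sample) == 0L
    if (done) break
    split <- adaptive_sampling_step(
      models, features_by_atom, split,
      batch = min(cfg$batch, cfg$n_final - length(split$train)))
  }
  ## refit hyperparameters at the final size, plus any moment models
  models <- fit_atom_models(features_by_atom, energy_by_atom, split$train,
                            cyclic, "iqa-energy", cfg$n_starts, cfg$seed)
  moment_models <- list()
  for (col in cfg$moment_columns) {
    target <- lapply(seq_len(n_at), function(a) {
      rec <- properties[properties$atom == a, ]
      rec[order(rec$frame), ][[col]]
    })
    moment_models[[col]] <- fit_atom_models(
      features_by_atom, target, split$train, cyclic, col, cfg$n_starts,
      cfg$seed)
  }
  list(energy_models = models, moment_models = moment_models,
       split = split, alfs = alfs, features_by_atom = features_by_atom,
       log = log)
}

#' Write the per-iteration training log as CSV
#' @param log data.frame from [run_training()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
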
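#' Per-assay mean-predictor baseline
#'
#' The naive imputation baseline: predict a missing track of assay `a` with
#' the per-bin mean of all observed tracks of that assay (arcsinh scale).
#'
#' @param ts a [track_set()] of observed tracks.
#' @param assay assay identifier.
#' @param exclude_cell optional cell type whose track is excluded from the
#'   mean (e.g. the held-out cell).
#' @return Named list of per-chromosome mean signal vectors.
#' @export
assay_mean_baseline <- function(ts, assay, exclude_cell = NULL) {
  obs <- observed_tracks(ts)
  obs <- obs[obs$assay == assay, , drop = FALSE]
  if (!is.null(exclude_cell)) obs <- obs[obs$cell != exclude_cell, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observed tracks for assay ", assay)
  acc <- NULL
  for (i in seq_len(nrow(obs))) {
    tr <- get_track(ts, obs$cell[i], obs$assay[i])
    acc <- if (is.null(acc)) tr else Map(`+`, acc, tr)
  }
  lapply(acc, function(v) v / nrow(obs))
}

#' Desk-scale structure-recovery benchmark
#'
#' Runs the full pipeline on a synthetic compendium: initialize a model,
#' two-stage training (pilot subset then per-chromosome genome factors) on
#' the observed tracks, then impute every track the generator masked as
#' missing and compare, on the arcsinh scale, against (a) the generator's
#' ground truth and (b) the per-assay mean-predictor baseline.  The model
#' widths default to a reduced desk-scale architecture (the published
#' widths are sized for a 115-million-bin genome compendium); the training
#' protocol keeps the published optimizer settings and epoch counts.
#'
#' @param spec a [synthetic_spec()].
#' @param config a [model_config()]; default reduced desk-scale widths.
#' @param tconfig a [training_config()].
#' @param pilot_fraction fraction of each chromosome used as the stage-1
#'   pilot subset (default 0.1; taken from the chromosome start).
#' @return list with `mse` (mean held-out imputation MSE), `baseline_mse`
#'   (per-assay mean predictor), `ratio` (`mse / baseline_mse`), per-track
#'   details in `tracks`, and the trained `model`.
#' @export
structure_recovery_benchmark <- function(spec = synthetic_spec(),
                                         config = model_config(
                                           n_cell_factors = 8L,
                                           n_assay_factors = 8L,
                                           n_g25 = 16L, n_g250 = 8L, n_g5k = 4L,
                                           n_hidden_layers = 2L,
                                           n_hidden_units = 128L),
                                         tconfig = training_config(
                                           batch_size = 1000L, dropout = 0.2,
                                           seed = spec$seed),
                                         pilot_fraction = 0.3) {
  comp <- make_compendium(spec)
  grid <- comp$grid
  regions <- do.call(rbind, lapply(grid$chrom_names, function(ch) {
    data.frame(chrom = ch, start_bin = 0L,
               end_bin = max(1L, round(pilot_fraction * grid$n_bins_25[ch])),
               stringsAsFactors = FALSE)
  }))
  model <- initialize_model(new_epi_model(config, grid, comp$observed$cells,
                                          comp$observed$assays),
                            seed = tconfig$seed)
  model <- fit_model(comp$observed, regions, model, tconfig)

  held_out <- which(!comp$observed_mask, arr.ind = TRUE)
  if (nrow(held_out) == 0L) stop("compendium has no held-out tracks to score")
  rows <- lapply(seq_len(nrow(held_out)), function(i) {
    cell <- rownames(comp$observed_mask)[held_out[i, 1L]]
    assay <- colnames(comp$observed_mask)[held_out[i, 2L]]
    truth <- get_track(comp$truth, cell, assay)
    imp <- impute_track(model, cell, assay)
    base <- assay_mean_baseline(comp$observed, assay)
    data.frame(cell = cell, assay = assay,
               mse = mse_global(unlist(truth), unlist(imp)),
               baseline_mse = mse_global(unlist(truth), unlist(base)))
  })
  tracks <- do.call(rbind, rows)
  mse <- mean(tracks$mse)
  baseline <- mean(tracks$baseline_mse)
  list(mse = mse, baseline_mse = baseline, ratio = mse / baseline,
       tracks = tracks, model = model, compendium = comp)
}
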
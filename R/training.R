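#' Training configuration
#'
#' Optimizer and protocol settings.  Defaults are the published ones: ADAM
#' with initial learning rate 0.01, beta1 0.9, beta2 0.999, epsilon 1e-8 and
#' a learning-rate decay of 1e-8 per step (`lr_t = lr / (1 + decay * t)`);
#' 800 epochs for the pilot-region stage and 200 epochs per chromosome for
#' the second stage; no early stopping.  An epoch is one pass over the
#' genomic axis: every 25-bp bin of the training subset is seen exactly
#' once, paired with a (cell, assay) drawn uniformly from the observed
#' tracks.  Batch size is not part of the epoch definition and defaults to
#' 40,000 samples.
#'
#' @param learning_rate,beta1,beta2,epsilon,decay ADAM settings.
#' @param epochs_stage1,epochs_stage2 epoch counts for the two stages.
#' @param batch_size samples per gradient step.
#' @param dropout hidden-layer dropout rate in `[0, 1)` applied during
#'   training only (inverted dropout; 0 disables it).  Dropout
#'   regularization was reported to improve the model's imputations.
#' @param seed integer seed for sampling and initialization of new factors.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.01, beta1 = 0.9, beta2 = 0.999,
                            epsilon = 1e-8, decay = 1e-8,
                            epochs_stage1 = 800L, epochs_stage2 = 200L,
                            batch_size = 40000L, dropout = 0, seed = 1L) {
  stopifnot(learning_rate >= 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0, decay >= 0, epochs_stage1 >= 1L, epochs_stage2 >= 1L,
            batch_size >= 1L, dropout >= 0, dropout < 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, decay = decay,
                 epochs_stage1 = as.integer(epochs_stage1),
                 epochs_stage2 = as.integer(epochs_stage2),
                 batch_size = as.integer(batch_size),
                 dropout = dropout,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Sample one training epoch
#'
#' Every 25-bp bin of the training subset appears exactly once, in a fresh
#' seeded permutation; each bin is paired with one (cell, assay) drawn
#' uniformly from the observed tracks.  Missing tensor entries are never
#' sampled.
#'
#' @param bins data.frame with columns `chrom`, `bin` (0-based) listing the
#'   training subset.
#' @param tracks data.frame of observed tracks (`cell`, `assay`).
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @return data.frame with columns `chrom`, `bin`, `cell`, `assay`, one row
#'   per training sample, in visit order.
#' @export
sample_epoch <- function(bins, tracks, seed = NULL) {
  if (nrow(tracks) == 0L) stop("no observed tracks to sample from")
  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  n <- nrow(bins)
  ord <- sample.int(n)
  ti <- sample.int(nrow(tracks), n, replace = TRUE)
  data.frame(chrom = bins$chrom[ord], bin = bins$bin[ord],
             cell = tracks$cell[ti], assay = tracks$assay[ti],
             stringsAsFactors = FALSE)
}

# expand a TrainingRegion data.frame (chrom, start_bin, end_bin; half-open
# bin coordinates) into a bins data.frame
.region_bins_df <- function(regions, grid) {
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    .grid_check_chrom(grid, ch)
    s <- regions$start_bin[i]; e <- regions$end_bin[i]
    if (s < 0 || e > grid$n_bins_25[ch] || s >= e) {
      stop("training region [", s, ",", e, ") outside grid bounds for ", ch)
    }
    out[[i]] <- data.frame(chrom = ch, bin = seq.int(s, e - 1L),
                           stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, out)
  if (anyDuplicated(bins)) stop("training regions overlap")
  bins
}

# ---- ADAM optimizer state ----------------------------------------------------

# one (m, v) pair per parameter tensor, addressed by the same tree shape as
# the model; t is the global step counter
.adam_init <- function(model) {
  zeros <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  mk <- function(x) list(m = zeros(x), v = zeros(x))
  list(
    t = 0L,
    cell = mk(model$factors$cell),
    assay = mk(model$factors$assay),
    genome = lapply(model$factors$genome, function(g) lapply(g, mk)),
    layers = lapply(model$dnn$layers, function(l) list(W = mk(l$W), b = mk(l$b))),
    out = list(w = mk(model$dnn$out$w), b = mk(model$dnn$out$b))
  )
}

# ADAM update of one tensor; returns list(param, m, v)
.adam_step <- function(param, grad, st, lr_t, beta1, beta2, epsilon, t) {
  m <- beta1 * st$m + (1 - beta1) * grad
  v <- beta2 * st$v + (1 - beta2) * grad * grad
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(param = param - lr_t * mhat / (sqrt(vhat) + epsilon), m = m, v = v)
}

#' Default trainable-parameter mask
#'
#' @param model an `epi_model`.
#' @param cell,assay,dnn logical: train the cell embedding, assay embedding,
#'   dense network.
#' @param genome logical scalar or named logical vector per chromosome.
#' @return A mask list for [train_step()]; parameter groups with `FALSE` are
#'   frozen bit-exactly.
#' @export
trainable_mask <- function(model, cell = TRUE, assay = TRUE, genome = TRUE,
                           dnn = TRUE) {
  chroms <- names(model$factors$genome)
  g <- if (length(genome) == 1L && is.null(names(genome))) {
    stats::setNames(rep(genome, length(chroms)), chroms)
  } else {
    gg <- stats::setNames(rep(FALSE, length(chroms)), chroms)
    gg[names(genome)] <- genome
    gg
  }
  list(cell = cell, assay = assay, genome = g, dnn = dnn)
}

#' One ADAM step on a training batch
#'
#' Computes the batch mean-squared-error loss between predictions and
#' observed arcsinh values, backpropagates through the dense network into
#' the touched embedding rows, and applies one ADAM update to every
#' parameter group enabled in `mask`.  Frozen groups are returned
#' bit-identical.  Embedding gradients are dense (untouched rows have zero
#' gradient but still undergo moment decay), matching the reference deep
#' learning toolkit's ADAM semantics.
#'
#' @param model an `epi_model`.
#' @param batch data.frame with columns `chrom`, `bin`, `cell`, `assay`,
#'   `value` (observed arcsinh signal).
#' @param state optimizer state from a previous call, or `NULL` to start.
#' @param mask a [trainable_mask()]; default trains everything.
#' @param config a [training_config()].
#' @return list(model, state, loss).
#' @export
train_step <- function(model, batch, state = NULL, mask = NULL,
                       config = training_config()) {
  if (is.null(state)) state <- .adam_init(model)
  if (is.null(mask)) mask <- trainable_mask(model)
  t <- state$t + 1L
  lr_t <- config$learning_rate / (1 + config$decay * (t - 1))
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$epsilon

  n <- nrow(batch)
  ci <- .entity_index(model$cells, batch$cell, "cell type")
  ai <- .entity_index(model$assays, batch$assay, "assay")

  # gather inputs chromosome by chromosome, preserving batch order
  X <- matrix(0, n, input_width(model$config))
  gather <- list()
  for (ch in unique(batch$chrom)) {
    rows <- which(batch$chrom == ch)
    idx <- multiscale_indices(batch$bin[rows], model$grid$n_bins_25[ch])
    g <- model$factors$genome[[ch]]
    X[rows, ] <- cbind(model$factors$cell[ci[rows], , drop = FALSE],
                       model$factors$assay[ai[rows], , drop = FALSE],
                       g$g25[idx$i25 + 1L, , drop = FALSE],
                       g$g250[idx$i250 + 1L, , drop = FALSE],
                       g$g5k[idx$i5k + 1L, , drop = FALSE])
    gather[[ch]] <- list(rows = rows, idx = idx)
  }

  p_drop <- if (is.null(config$dropout)) 0 else config$dropout
  fw <- .dnn_forward(model$dnn, X, keep = TRUE, dropout = p_drop)
  resid <- fw$y - batch$value
  loss <- mean(resid^2)
  if (!is.finite(loss)) stop("non-finite training loss (", loss, ") at step ", t)

  # backward pass (post-dropout activations: zeroed units pass no gradient,
  # surviving units carry the inverted-dropout 1/(1-p) scale)
  relu_scale <- if (p_drop > 0) 1 / (1 - p_drop) else 1
  dY <- matrix(2 * resid / n, ncol = 1L)
  L <- length(model$dnn$layers)
  HL <- fw$H[[L]]
  g_out_w <- crossprod(HL, dY)
  g_out_b <- sum(dY)
  dA <- dY %*% t(model$dnn$out$w)
  g_layers <- vector("list", L)
  for (l in seq.int(L, 1L)) {
    dZ <- dA * (fw$H[[l]] > 0) * relu_scale
    A_prev <- if (l == 1L) X else fw$H[[l - 1L]]
    g_layers[[l]] <- list(W = crossprod(A_prev, dZ), b = colSums(dZ))
    dA <- dZ %*% t(model$dnn$layers[[l]]$W)
  }
  dX <- dA
  sl <- .input_slices(model$config)

  # scatter-add input gradients into dense embedding gradients
  scatter <- function(d_slice, index1, n_rows, ncol_) {
    G <- matrix(0, n_rows, ncol_)
    agg <- rowsum(d_slice, index1)
    G[as.integer(rownames(agg)), ] <- agg
    G
  }

  if (isTRUE(mask$cell)) {
    G <- scatter(dX[, sl$cell, drop = FALSE], ci, nrow(model$factors$cell),
                 model$config$n_cell_factors)
    up <- .adam_step(model$factors$cell, G, state$cell, lr_t, b1, b2, eps, t)
    model$factors$cell <- up$param; state$cell <- list(m = up$m, v = up$v)
  }
  if (isTRUE(mask$assay)) {
    G <- scatter(dX[, sl$assay, drop = FALSE], ai, nrow(model$factors$assay),
                 model$config$n_assay_factors)
    up <- .adam_step(model$factors$assay, G, state$assay, lr_t, b1, b2, eps, t)
    model$factors$assay <- up$param; state$assay <- list(m = up$m, v = up$v)
  }
  for (ch in names(gather)) {
    if (!isTRUE(mask$genome[[ch]])) next
    rows <- gather[[ch]]$rows; idx <- gather[[ch]]$idx
    g <- model$factors$genome[[ch]]
    for (res in c("g25", "g250", "g5k")) {
      index1 <- switch(res, g25 = idx$i25, g250 = idx$i250, g5k = idx$i5k) + 1L
      G <- scatter(dX[rows, sl[[res]], drop = FALSE], index1,
                   nrow(g[[res]]), ncol(g[[res]]))
      up <- .adam_step(g[[res]], G, state$genome[[ch]][[res]], lr_t, b1, b2, eps, t)
      model$factors$genome[[ch]][[res]] <- up$param
      state$genome[[ch]][[res]] <- list(m = up$m, v = up$v)
    }
  }
  if (isTRUE(mask$dnn)) {
    for (l in seq_len(L)) {
      upW <- .adam_step(model$dnn$layers[[l]]$W, g_layers[[l]]$W,
                        state$layers[[l]]$W, lr_t, b1, b2, eps, t)
      upb <- .adam_step(model$dnn$layers[[l]]$b, g_layers[[l]]$b,
                        state$layers[[l]]$b, lr_t, b1, b2, eps, t)
      model$dnn$layers[[l]] <- list(W = upW$param, b = upb$param)
      state$layers[[l]] <- list(W = list(m = upW$m, v = upW$v),
                                b = list(m = upb$m, v = upb$v))
    }
    upw <- .adam_step(model$dnn$out$w, g_out_w, state$out$w, lr_t, b1, b2, eps, t)
    upb <- .adam_step(model$dnn$out$b, g_out_b, state$out$b, lr_t, b1, b2, eps, t)
    model$dnn$out <- list(w = upw$param, b = upb$param)
    state$out <- list(w = list(m = upw$m, v = upw$v), b = list(m = upb$m, v = upb$v))
  }
  state$t <- t
  list(model = model, state = state, loss = loss)
}

# look up observed values for an epoch sample
.sample_values <- function(ts, samples) {
  vals <- numeric(nrow(samples))
  key <- .track_key(samples$cell, samples$assay)
  for (k in unique(key)) {
    rows <- which(key == k)
    track <- ts$signal[[k]]
    for (ch in unique(samples$chrom[rows])) {
      r2 <- rows[samples$chrom[rows] == ch]
      vals[r2] <- track[[ch]][samples$bin[r2] + 1L]
    }
  }
  vals
}

# run `epochs` epochs over `bins` with a given mask; returns model + loss log
.fit_epochs <- function(ts, bins, model, config, mask, epochs, state = NULL,
                        stage = "stage") {
  tracks <- observed_tracks(ts)
  if (nrow(tracks) == 0L) stop("track set has no observed tracks")
  if (is.null(state)) state <- .adam_init(model)
  losses <- numeric(epochs)
  old <- .Random.seed_exists()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(config$seed)
  for (ep in seq_len(epochs)) {
    samples <- sample_epoch(bins, tracks, seed = NULL)
    samples$value <- .sample_values(ts, samples)
    n <- nrow(samples)
    starts <- seq.int(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      e <- min(s + config$batch_size - 1L, n)
      step <- train_step(model, samples[s:e, , drop = FALSE], state, mask, config)
      model <- step$model; state <- step$state
      ep_loss <- ep_loss + step$loss * (e - s + 1L)
    }
    losses[ep] <- ep_loss / n
  }
  attr(model, "loss_log") <- c(attr(model, "loss_log"),
                               stats::setNames(losses, paste0(stage, "_", seq_len(epochs))))
  attr(model, "opt_state") <- state
  model
}

#' Stage-1 training on pilot regions
#'
#' Jointly optimizes the cell, assay and (region-restricted) genome factors
#' together with the dense network for `epochs_stage1` epochs on the bins of
#' `regions` (the pilot subset, ~1% of the genome in real runs).  A fixed
#' epoch count is used; there is no early stopping.
#'
#' @param ts a [track_set()] holding only the training tracks (held-out
#'   folds excluded by the caller).
#' @param regions data.frame with columns `chrom`, `start_bin`, `end_bin`
#'   (half-open bin coordinates) defining the pilot subset.
#' @param model an initialized `epi_model`.
#' @param config a [training_config()].
#' @return The trained model; per-epoch losses in `attr(model, "loss_log")`.
#' @export
fit_stage1 <- function(ts, regions, model, config = training_config()) {
  if (nrow(regions) == 0L) stop("stage-1 region set is empty")
  bins <- .region_bins_df(regions, model$grid)
  mask <- trainable_mask(model)
  model <- .fit_epochs(ts, bins, model, config, mask, config$epochs_stage1,
                       stage = "stage1")
  attr(model, "pilot_bins") <- bins
  model
}

#' Stage-2 per-chromosome genome-factor training
#'
#' Freezes the cell factors, assay factors and dense network from stage 1
#' (bit-exactly) and trains only the three genome-factor matrices of one
#' chromosome for `epochs_stage2` epochs over all of its bins.  Genome
#' factor rows not covered by the stage-1 pilot regions are re-initialized
#' with fresh U(-0.5, 0.5) draws before training.  The optimizer state is
#' reset at the start of the stage.  Chromosomes are independent: training
#' order does not affect results.
#'
#' @param ts a [track_set()] of training tracks.
#' @param chrom chromosome to train.
#' @param model the stage-1 model.
#' @param config a [training_config()].
#' @return The model with updated genome factors for `chrom`.
#' @export
fit_stage2 <- function(ts, chrom, model, config = training_config()) {
  .grid_check_chrom(model$grid, chrom)
  n_bins <- as.integer(model$grid$n_bins_25[chrom])

  # fresh draws for rows the pilot stage never visited
  pilot <- attr(model, "pilot_bins")
  old <- .Random.seed_exists()
  set.seed(config$seed + 1L)
  g <- model$factors$genome[[chrom]]
  seen25 <- logical(n_bins)
  if (!is.null(pilot)) {
    pb <- pilot$bin[pilot$chrom == chrom]
    seen25[pb + 1L] <- TRUE
  }
  grp250 <- (seq_len(n_bins) - 1L) %/% 10L
  grp5k <- (seq_len(n_bins) - 1L) %/% 200L
  seen250 <- as.logical(rowsum(as.numeric(seen25), grp250) > 0)
  seen5k <- as.logical(rowsum(as.numeric(seen25), grp5k) > 0)
  redraw <- function(m, seen) {
    miss <- which(!seen)
    if (length(miss)) {
      m[miss, ] <- matrix(stats::runif(length(miss) * ncol(m), -0.5, 0.5),
                          length(miss), ncol(m))
    }
    m
  }
  g$g25 <- redraw(g$g25, seen25)
  g$g250 <- redraw(g$g250, seen250)
  g$g5k <- redraw(g$g5k, seen5k)
  model$factors$genome[[chrom]] <- g
  .restore_rng(old)

  bins <- data.frame(chrom = chrom, bin = seq.int(0L, n_bins - 1L),
                     stringsAsFactors = FALSE)
  mask <- trainable_mask(model, cell = FALSE, assay = FALSE, dnn = FALSE,
                         genome = stats::setNames(TRUE, chrom))
  cfg2 <- config
  cfg2$seed <- config$seed + match(chrom, model$grid$chrom_names)
  .fit_epochs(ts, bins, model, cfg2, mask, config$epochs_stage2,
              stage = paste0("stage2_", chrom))
}

#' Full two-stage training
#'
#' Convenience wrapper: [fit_stage1()] on the pilot regions, then
#' [fit_stage2()] on every chromosome of the grid.
#'
#' @inheritParams fit_stage1
#' @return The fully trained model.
#' @export
fit_model <- function(ts, regions, model, config = training_config()) {
  model <- fit_stage1(ts, regions, model, config)
  for (ch in model$grid$chrom_names) {
    model <- fit_stage2(ts, ch, model, config)
  }
  model
}

#' Extend a trained model with a new cell type or assay
#'
#' Transfer learning for unseen entities: all existing parameters are frozen
#' bit-exactly and a single new embedding row is fitted to the new entity's
#' observed track(s) (as little as one track suffices).  Existing
#' predictions are unchanged.
#'
#' @param model a trained `epi_model`.
#' @param ts a [track_set()] containing the new entity's track(s); its
#'   registries must include `name`.
#' @param name identifier of the new entity.
#' @param kind `"cell"` or `"assay"`.
#' @param config a [training_config()]; `epochs_stage2` epochs are run.
#' @return The extended model.
#' @export
fit_new_entity <- function(model, ts, name, kind = c("cell", "assay"),
                           config = training_config()) {
  kind <- match.arg(kind)
  registry <- if (kind == "cell") model$cells else model$assays
  if (name %in% registry) stop(kind, " '", name, "' is already registered")
  tracks <- observed_tracks(ts)
  tracks <- tracks[if (kind == "cell") tracks$cell == name else tracks$assay == name, ,
                   drop = FALSE]
  if (nrow(tracks) == 0L) stop("no observed tracks for new ", kind, " '", name, "'")
  # sample only the new entity's tracks during extension
  ts$signal <- ts$signal[.track_key(tracks$cell, tracks$assay)]

  old <- .Random.seed_exists()
  set.seed(config$seed + 7L)
  width <- if (kind == "cell") model$config$n_cell_factors else model$config$n_assay_factors
  new_row <- matrix(stats::runif(width, -0.5, 0.5), 1L, width)
  .restore_rng(old)

  if (kind == "cell") {
    model$cells <- c(model$cells, name)
    model$factors$cell <- rbind(model$factors$cell, new_row)
    mask <- trainable_mask(model, cell = TRUE, assay = FALSE, genome = FALSE,
                           dnn = FALSE)
  } else {
    model$assays <- c(model$assays, name)
    model$factors$assay <- rbind(model$factors$assay, new_row)
    mask <- trainable_mask(model, cell = FALSE, assay = TRUE, genome = FALSE,
                           dnn = FALSE)
  }
  frozen_rows <- seq_len(length(registry))

  # train over the union of bins covered by the new entity's tracks
  chroms <- unique(unlist(lapply(seq_len(nrow(tracks)), function(i) {
    names(get_track(ts, tracks$cell[i], tracks$assay[i]))
  })))
  bins <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch, bin = seq.int(0L, model$grid$n_bins_25[ch] - 1L),
               stringsAsFactors = FALSE)
  }))
  before <- if (kind == "cell") model$factors$cell else model$factors$assay
  model <- .fit_epochs(ts, bins, model, config, mask, config$epochs_stage2,
                       stage = paste0("extend_", name))
  # the mask trains the whole embedding matrix; restore pre-existing rows so
  # the freeze contract on registered entities is byte-exact
  if (kind == "cell") {
    model$factors$cell[frozen_rows, ] <- before[frozen_rows, ]
  } else {
    model$factors$assay[frozen_rows, ] <- before[frozen_rows, ]
  }
  model
}
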
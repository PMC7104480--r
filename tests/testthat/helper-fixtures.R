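# shared fixtures: everything is generated in code at test time

tiny_grid <- function(len = 25000, name = "chrT") {
  genomic_grid(stats::setNames(len, name))
}

# a small randomly initialized model over a tiny grid
toy_model <- function(grid = tiny_grid(), cells = c("c1", "c2"),
                      assays = c("a1", "a2"),
                      config = model_config(n_cell_factors = 4L,
                                            n_assay_factors = 4L,
                                            n_g25 = 4L, n_g250 = 3L, n_g5k = 2L,
                                            n_hidden_layers = 2L,
                                            n_hidden_units = 8L),
                      seed = 1L) {
  initialize_model(new_epi_model(config, grid, cells, assays), seed = seed)
}

# a model whose network is affine over the tested input range: identity
# hidden maps with a large positive bias keep every ReLU active, so
# f(x) = sum(w)-weighted affine function of x
affine_model <- function(grid = tiny_grid(), seed = 2L) {
  cfg <- model_config(n_cell_factors = 2L, n_assay_factors = 2L,
                      n_g25 = 2L, n_g250 = 2L, n_g5k = 2L,
                      n_hidden_layers = 2L, n_hidden_units = 10L)
  m <- toy_model(grid, config = cfg, seed = seed)
  d <- input_width(cfg)
  I <- diag(1, d, 10L)
  m$dnn$layers[[1L]] <- list(W = I, b = rep(50, 10L))
  m$dnn$layers[[2L]] <- list(W = diag(1, 10L, 10L), b = rep(0, 10L))
  set.seed(seed)
  m$dnn$out$w <- matrix(stats::runif(10L, -1, 1), 10L, 1L)
  m$dnn$out$b <- 0.25
  m
}

# tiny observed compendium for fast training tests
tiny_compendium <- function(n_bins = 400L, seed = 5L) {
  make_compendium(synthetic_spec(chrom_lengths = c(chrT = n_bins * 25),
                                 seed = seed))
}

fast_tconfig <- function(e1 = 15L, e2 = 10L, seed = 5L, batch_size = 1000L, ...) {
  training_config(epochs_stage1 = e1, epochs_stage2 = e2,
                  batch_size = batch_size, seed = seed, ...)
}

# brute-force average precision: enumerate every distinct score as a
# threshold (descending), compute precision/recall from the confusion
# matrix, apply the step-sum formula
ap_bruteforce <- function(labels, scores) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  prev_recall <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    precision <- tp / sum(pred)
    recall <- tp / P
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# brute-force top-1% selection: full sort with explicit index tie-break
top1_bruteforce <- function(observed, imputed, key) {
  n <- length(observed)
  ord <- order(-key, seq_len(n))
  sel <- ord[seq_len(n %/% 100L)]
  mean((observed[sel] - imputed[sel])^2)
}

# brute-force stratified confusion matrices, one loop per bin and cell
prf_bruteforce <- function(observed, imputed, calls, threshold) {
  counts <- Reduce(`+`, lapply(calls, as.integer))
  res <- list()
  for (cv in sort(unique(counts[counts > 0L]))) {
    tp <- fp <- fn <- 0L; se <- 0; n <- 0L
    for (b in which(counts == cv)) {
      for (cl in names(calls)) {
        pred <- imputed[[cl]][b] >= threshold
        truth <- calls[[cl]][b]
        if (pred && truth) tp <- tp + 1L
        if (pred && !truth) fp <- fp + 1L
        if (!pred && truth) fn <- fn + 1L
        se <- se + (observed[[cl]][b] - imputed[[cl]][b])^2
        n <- n + 1L
      }
    }
    res[[as.character(cv)]] <- data.frame(
      count = cv, n_bins = sum(counts == cv), mse = se / n,
      precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
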
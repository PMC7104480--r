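#' Concatenated per-bin genomic factors
#'
#' Internal helper: for fine bins `bins` of `chrom`, returns the matrix of
#' concatenated genomic factors g25 | g250 | g5k (mid/coarse rows repeat
#' across the fine bins they cover), with 25+40+45 = 110 columns at default
#' widths.
#'
#' @noRd
.genome_factor_rows <- function(model, chrom, bins) {
  g <- model$factors$genome[[chrom]]
  if (is.null(g)) stop("no genome factors for chromosome ", chrom)
  idx <- multiscale_indices(bins, model$grid$n_bins_25[chrom])
  cbind(g$g25[idx$i25 + 1L, , drop = FALSE],
        g$g250[idx$i250 + 1L, , drop = FALSE],
        g$g5k[idx$i5k + 1L, , drop = FALSE])
}

#' Latent feature width per genomic locus
#'
#' @param config a [model_config()].
#' @return `n_g25 + n_g250 + n_g5k` (110 at defaults).
#' @export
genome_feature_width <- function(config = model_config()) {
  config$n_g25 + config$n_g250 + config$n_g5k
}

#' Windowed mean of genomic latent factors
#'
#' Averages the concatenated per-bin genomic factors (g25 | g250 | g5k) over
#' the 25-bp bins covered by a window of `+/- half_width` bp around
#' `center_bp`, yielding one vector of [genome_feature_width()] features
#' (110 at defaults).  With `half_width = 250` exactly 20 bins are averaged.
#' Windows extending past the chromosome are clipped with a warning.
#'
#' @param model a trained `epi_model`.
#' @param chrom chromosome name.
#' @param center_bp window center in basepairs (0-based).
#' @param half_width half window width in basepairs (default 250).
#' @return Named numeric feature vector.
#' @export
window_factor_mean <- function(model, chrom, center_bp, half_width = 250L) {
  .grid_check_chrom(model$grid, chrom)
  bs <- model$grid$bin_size
  n_bins <- as.integer(model$grid$n_bins_25[chrom])
  start <- center_bp - half_width
  end <- center_bp + half_width
  if (start < 0 || end > model$grid$chrom_lengths[chrom]) {
    warning("window [", start, ",", end, ") clipped to chromosome ", chrom)
    start <- max(start, 0)
    end <- min(end, model$grid$chrom_lengths[chrom])
  }
  fb <- as.integer(start %/% bs)
  lb <- as.integer(min((end - 1) %/% bs, n_bins - 1L))
  M <- .genome_factor_rows(model, chrom, fb:lb)
  v <- colMeans(M)
  names(v) <- .genome_feature_names(model$config)
  v
}

.genome_feature_names <- function(config) {
  c(paste0("g25_", seq_len(config$n_g25)),
    paste0("g250_", seq_len(config$n_g250)),
    paste0("g5k_", seq_len(config$n_g5k)))
}

#' Multi-window promoter feature vector
#'
#' Describes a promoter as eight adjacent 250-bp windows covering its 2-kbp
#' span upstream of the transcription start site (downstream on the -
#' strand), aligned to the 250-bp factor grid.  Each window contributes the
#' mean of its ten 25-bp factor rows (`n_g25` features) concatenated with
#' its single 250-bp factor row (`n_g250` features); the 5-kbp factor row
#' of the block containing the TSS is appended once.  At default widths
#' this is 8 x (25 + 40) + 45 = 565 features; the equivalent raw-track
#' representation of the same eight windows over the full 1014-track
#' compendium would need 8112 columns (see [raw_track_feature_count()]).
#'
#' @param model a trained `epi_model`.
#' @param chrom chromosome name.
#' @param tss transcription start site (0-based bp); the 2-kbp promoter
#'   span must lie within the chromosome.
#' @param strand `"+"` or `"-"`; windows are ordered upstream to downstream.
#' @return Named numeric vector of `8 * (n_g25 + n_g250) + n_g5k` features.
#' @export
promoter_multiwindow_features <- function(model, chrom, tss, strand = "+") {
  .grid_check_chrom(model$grid, chrom)
  cfg <- model$config
  bs <- model$grid$bin_size
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  span_start <- if (strand == "+") tss - 2000L else tss
  span_end <- span_start + 2000L
  if (span_start < 0 || span_end > model$grid$chrom_lengths[chrom]) {
    stop("2-kbp promoter span around TSS ", tss, " leaves chromosome ", chrom)
  }
  # eight 250-bp factor blocks covering the span, ordered upstream->downstream
  first_block <- as.integer(span_start %/% 250L)
  blocks <- first_block + 0:7
  if (strand == "-") blocks <- rev(blocks)
  n250 <- as.integer(model$grid$n_bins_250[chrom])
  if (any(blocks < 0L) || any(blocks >= n250)) {
    stop("promoter windows fall outside the 250-bp factor grid of ", chrom)
  }
  g <- model$factors$genome[[chrom]]
  feats <- unlist(lapply(seq_along(blocks), function(w) {
    blk <- blocks[w]
    bins25 <- (blk * 10L):(blk * 10L + 9L)    # ten fine bins per block
    bins25 <- bins25[bins25 < model$grid$n_bins_25[chrom]]
    m25 <- colMeans(g$g25[bins25 + 1L, , drop = FALSE])
    stats::setNames(c(m25, g$g250[blk + 1L, ]),
                    c(paste0("w", w, "_g25_", seq_len(cfg$n_g25)),
                      paste0("w", w, "_g250_", seq_len(cfg$n_g250))))
  }))
  i5k <- (as.integer(tss %/% bs)) %/% 200L
  i5k <- min(i5k, as.integer(model$grid$n_bins_5k[chrom]) - 1L)
  g5k <- stats::setNames(g$g5k[i5k + 1L, ], paste0("g5k_", seq_len(cfg$n_g5k)))
  c(feats, g5k)
}

#' Column count of the raw-track window representation
#'
#' A multi-window representation built directly from signal tracks needs
#' `n_windows * n_tracks` columns (one value per track per window); for the
#' eight-window promoter over the full 1014-track compendium that is 8112,
#' against 565 latent features.
#'
#' @param n_tracks number of signal tracks (default 1014).
#' @param n_windows number of windows (default 8).
#' @return `n_windows * n_tracks`.
#' @export
raw_track_feature_count <- function(n_tracks = 1014L, n_windows = 8L) {
  as.integer(n_windows) * as.integer(n_tracks)
}

#' Aggregate genomic factors to a coarse resolution
#'
#' Averages the concatenated per-bin genomic factors over consecutive
#' fixed-width loci (default 40 kbp = 1600 fine bins, the resolution used
#' for replication-timing and chromatin-interaction tasks).  The terminal
#' partial locus is averaged over its actual bins.
#'
#' @param model a trained `epi_model`.
#' @param chrom chromosome name.
#' @param resolution locus width in bp; must be a multiple of the bin size.
#' @return Matrix of loci x [genome_feature_width()] features.
#' @export
aggregate_factors <- function(model, chrom, resolution = 40000L) {
  .grid_check_chrom(model$grid, chrom)
  bs <- model$grid$bin_size
  if (resolution %% bs != 0L) stop("resolution must be a multiple of ", bs, " bp")
  bins_per_locus <- resolution %/% bs
  n_bins <- as.integer(model$grid$n_bins_25[chrom])
  M <- .genome_factor_rows(model, chrom, seq.int(0L, n_bins - 1L))
  locus <- (seq_len(n_bins) - 1L) %/% bins_per_locus
  agg <- rowsum(M, locus) / as.vector(table(locus))
  colnames(agg) <- .genome_feature_names(model$config)
  rownames(agg) <- NULL
  agg
}

#' Binary expression labels from an RNA-seq coverage track
#'
#' A gene is labelled active iff the mean normalized read-count value over
#' its gene-body bins is strictly greater than `threshold` (default 0.5; a
#' mean of exactly 0.5 is inactive).
#'
#' @param rna_track named per-chromosome coverage list (or vector for a
#'   single-chromosome grid).
#' @param gene_bodies region data.frame of gene bodies.
#' @param grid a [genomic_grid()].
#' @param threshold activity threshold (strict inequality).
#' @return Logical vector, one label per gene-body row.
#' @export
expression_labels <- function(rna_track, gene_bodies, grid, threshold = 0.5) {
  if (nrow(gene_bodies) == 0L) stop("no gene bodies")
  if (any(gene_bodies$end <= gene_bodies$start)) stop("zero-length gene body")
  m <- region_means(rna_track, gene_bodies, grid)
  m > threshold
}

# ---- cross-validation harnesses ---------------------------------------------

#' Learner contracts for the cross-validation harnesses
#'
#' A learner is a list with two functions: `fit(X, y, X_val, y_val)`
#' returning an opaque fitted object, and `score(fit, X)` returning a
#' numeric ranking score per row.  `xgboost_learner()` is the
#' gradient-boosted-trees default used for the classification tasks (up to
#' 5000 trees, maximum depth 6, early stopping after 20 rounds without
#' validation improvement, other settings default);
#' `logistic_learner(strength)` is an L2-regularized logistic regression
#' with inverse-regularization strength `C` (glmnet backend) used for the
#' promoter-enhancer-interaction task; `glm_learner()` is a dependency-free
#' plain logistic regression useful for testing the harnesses.
#'
#' @param nrounds,max_depth,early_stopping_rounds gradient-boosting
#'   settings.
#' @return A learner list with elements `fit` and `score`.
#' @export
xgboost_learner <- function(nrounds = 5000L, max_depth = 6L,
                            early_stopping_rounds = 20L) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("xgboost_learner requires the xgboost package")
  }
  list(
    fit = function(X, y, X_val, y_val) {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = as.numeric(y))
      dval <- xgboost::xgb.DMatrix(as.matrix(X_val), label = as.numeric(y_val))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eval_metric = "logloss", nthread = 1L),
        data = dtrain, nrounds = nrounds,
        evals = list(validation = dval),
        early_stopping_rounds = early_stopping_rounds, verbose = 0L)
    },
    score = function(fit, X) {
      stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(X)))
    })
}

#' @rdname xgboost_learner
#' @param strength inverse regularization strength `C` (larger = weaker
#'   penalty); the glmnet lambda is `1 / (C * n)`.
#' @export
logistic_learner <- function(strength = 1) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    stop("logistic_learner requires the glmnet package")
  }
  list(
    fit = function(X, y, X_val, y_val) {
      glmnet::glmnet(as.matrix(X), as.numeric(y), family = "binomial",
                     alpha = 0, lambda = 1 / (strength * length(y)),
                     standardize = TRUE)
    },
    score = function(fit, X) {
      drop(stats::predict(fit, as.matrix(X), type = "response"))
    })
}

#' @rdname xgboost_learner
#' @export
glm_learner <- function() {
  canon <- function(X) {
    X <- as.data.frame(X)
    names(X) <- paste0("x", seq_along(X))
    X
  }
  list(
    fit = function(X, y, X_val, y_val) {
      df <- data.frame(y = as.numeric(y), canon(X))
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    },
    score = function(fit, X) {
      suppressWarnings(stats::predict(fit, canon(X), type = "response"))
    })
}

#' k-fold cross-validated classification with a validation fold
#'
#' The harness used for the gene-expression, replication-timing and FIRE
#' tasks: instances are split into `k` folds (default 20, uniform random,
#' unstratified); for each evaluation one fold is the test set, one of the
#' remaining folds is the early-stopping validation set, and the other
#' `k - 2` folds train the learner.  Average precision is computed per test
#' fold and averaged into the MAP.  Folds without a positive test label are
#' skipped with a warning and recorded.
#'
#' @param X feature matrix or data.frame (rows = instances).
#' @param y logical labels.
#' @param learner a learner contract (see [xgboost_learner()]).
#' @param k number of folds.
#' @param seed integer seed controlling the fold assignment.
#' @return list with `ap` (per-fold AP, NA for skipped folds), `map`
#'   (mean over scored folds), `fold` (per-instance assignment), and
#'   `skipped` (fold indices without positives).
#' @export
cv_classify <- function(X, y, learner = xgboost_learner(), k = 20L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.logical(y)
  n <- nrow(X)
  if (k < 3L) stop("k must be at least 3 (train/validation/test folds)")
  old <- .Random.seed_exists()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  ap <- rep(NA_real_, k)
  skipped <- integer(0)
  for (f in seq_len(k)) {
    test <- fold == f
    vfold <- if (f == k) 1L else f + 1L
    val <- fold == vfold
    train <- !(test | val)
    if (!any(y[test])) {
      warning("fold ", f, " has no positive labels; skipped")
      skipped <- c(skipped, f)
      next
    }
    fit <- learner$fit(X[train, , drop = FALSE], y[train],
                       X[val, , drop = FALSE], y[val])
    scores <- learner$score(fit, X[test, , drop = FALSE])
    ap[f] <- average_precision(y[test], scores)
  }
  list(ap = ap, map = mean(ap, na.rm = TRUE), fold = fold, skipped = skipped)
}

#' Repeated 5-fold logistic-regression harness
#'
#' The promoter-enhancer-interaction harness: 5-fold cross-validation
#' repeated `n_repeats` times (default 20), reshuffling instances before
#' each repeat.  Within each training split the inverse regularization
#' strength is chosen from 10 values evenly log-spaced between 1e-4 and 1e4
#' by an internal 3-fold cross-validation (mean AP); the selected strength
#' is refitted on the full training split and scored on the outer test
#' fold.  Average precision is averaged over all `n_repeats * k`
#' evaluations.
#'
#' @param X feature matrix (rows = instances).
#' @param y logical labels; at least 15 positives recommended so each outer
#'   fold keeps positives.
#' @param seed integer seed.
#' @param n_repeats outer repeats (default 20).
#' @param k outer folds per repeat (default 5).
#' @param strengths inverse-regularization grid (default
#'   `10^seq(-4, 4, length.out = 10)`).
#' @param learner_factory function(strength) returning a learner contract;
#'   defaults to [logistic_learner()].
#' @return list with `ap` (vector of per-evaluation APs), `mean_ap`, and
#'   `strengths`.
#' @export
cv_pei <- function(X, y, seed = 1L, n_repeats = 20L, k = 5L,
                   strengths = 10^seq(-4, 4, length.out = 10),
                   learner_factory = logistic_learner) {
  X <- as.matrix(X)
  y <- as.logical(y)
  n <- nrow(X)
  old <- .Random.seed_exists()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  aps <- numeric(0)
  for (rep_i in seq_len(n_repeats)) {
    fold <- sample(rep_len(seq_len(k), n))
    for (f in seq_len(k)) {
      test <- fold == f
      train <- !test
      if (!any(y[test]) || !any(y[train]) || all(y[train])) next
      best <- .select_strength(X[train, , drop = FALSE], y[train], strengths,
                               learner_factory)
      lr <- learner_factory(best)
      fit <- lr$fit(X[train, , drop = FALSE], y[train], NULL, NULL)
      aps <- c(aps, average_precision(y[test], lr$score(fit, X[test, , drop = FALSE])))
    }
  }
  list(ap = aps, mean_ap = mean(aps), strengths = strengths)
}

# internal 3-fold CV over the strength grid; single-class inner folds are
# skipped in the mean
.select_strength <- function(X, y, strengths, learner_factory) {
  n <- nrow(X)
  fold <- sample(rep_len(1:3, n))
  mean_ap <- vapply(strengths, function(s) {
    lr <- learner_factory(s)
    vals <- c()
    for (f in 1:3) {
      tr <- fold != f
      te <- fold == f
      if (!any(y[te]) || !any(y[tr]) || all(y[tr])) next
      fit <- lr$fit(X[tr, , drop = FALSE], y[tr], NULL, NULL)
      vals <- c(vals, average_precision(y[te], lr$score(fit, X[te, , drop = FALSE])))
    }
    if (length(vals)) mean(vals) else -Inf
  }, numeric(1))
  strengths[which.max(mean_ap)]
}
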
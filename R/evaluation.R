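#' Global mean squared error
#'
#' MSE over the full set of positions, on the arcsinh scale.
#'
#' @param observed,imputed equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse_global <- function(observed, imputed) {
  if (length(observed) != length(imputed)) {
    stop("observed (", length(observed), ") and imputed (", length(imputed),
         ") differ in length")
  }
  mean((observed - imputed)^2)
}

#' MSE on the top 1 percent of positions
#'
#' Selects the `floor(N/100)` positions with the highest values of the
#' ranking track (the observed signal for MSE1obs, the imputed signal for
#' MSE1imp; ties at the cutoff are broken by ascending position index) and
#' returns the MSE over them.
#'
#' @inheritParams mse_global
#' @param rank_by `"observed"` or `"imputed"`.
#' @return MSE over the selected positions.
#' @export
mse_top1 <- function(observed, imputed, rank_by = c("observed", "imputed")) {
  rank_by <- match.arg(rank_by)
  n <- length(observed)
  if (length(imputed) != n) stop("observed and imputed differ in length")
  if (n < 100L) stop("need at least 100 positions for a top-1% metric (have ", n, ")")
  key <- if (rank_by == "observed") observed else imputed
  n_top <- n %/% 100L
  sel <- order(-key, seq_len(n))[seq_len(n_top)]
  mean((observed[sel] - imputed[sel])^2)
}

#' MSE over region-covered positions
#'
#' MSE restricted to the union of 25-bp bins covered by the regions (bins
#' shared by overlapping regions are counted once).
#'
#' @param observed,imputed named lists of per-chromosome signal vectors, or
#'   plain vectors for a single-chromosome grid.
#' @param regions region data.frame (`chrom`, `start`, `end`).
#' @param grid a [genomic_grid()].
#' @return MSE over the covered bins.
#' @export
mse_regions <- function(observed, imputed, regions, grid) {
  if (nrow(regions) == 0L) stop("empty region set")
  if (is.numeric(observed)) {
    observed <- stats::setNames(list(observed), grid$chrom_names[1L])
  }
  if (is.numeric(imputed)) {
    imputed <- stats::setNames(list(imputed), grid$chrom_names[1L])
  }
  se <- 0; n <- 0L
  for (ch in unique(regions$chrom)) {
    bins <- region_bins(regions, grid, ch, unique_bins = TRUE)
    if (!length(bins)) next
    d <- observed[[ch]][bins + 1L] - imputed[[ch]][bins + 1L]
    se <- se + sum(d^2)
    n <- n + length(d)
  }
  if (n == 0L) stop("regions cover no bins")
  se / n
}

#' Six-metric evaluation report
#'
#' Computes the standard metric suite for one imputed track against its
#' observed counterpart (both arcsinh scale): MSEglobal over all positions,
#' MSE1obs / MSE1imp over the top 1% of positions ranked by observed /
#' imputed signal, and MSEProm / MSEGene / MSEEnh over promoter, gene-body
#' and enhancer regions.
#'
#' @param observed,imputed named per-chromosome signal lists.
#' @param grid a [genomic_grid()].
#' @param promoters,genes,enhancers region data.frames (any may be `NULL`
#'   to omit that metric).
#' @return An `evaluation_report`: named list of metric values plus a
#'   `meta` attribute.
#' @export
evaluate_imputation <- function(observed, imputed, grid, promoters = NULL,
                                genes = NULL, enhancers = NULL) {
  obs <- unlist(observed, use.names = FALSE)
  imp <- unlist(imputed, use.names = FALSE)
  report <- list(
    MSEglobal = mse_global(obs, imp),
    MSE1obs = mse_top1(obs, imp, "observed"),
    MSE1imp = mse_top1(obs, imp, "imputed")
  )
  if (!is.null(promoters)) report$MSEProm <- mse_regions(observed, imputed, promoters, grid)
  if (!is.null(genes)) report$MSEGene <- mse_regions(observed, imputed, genes, grid)
  if (!is.null(enhancers)) report$MSEEnh <- mse_regions(observed, imputed, enhancers, grid)
  structure(report, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-10s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Stratify bins by cross-cell-type peak count
#'
#' Sums per-cell-type peak indicators at each 25-bp bin of one chromosome;
#' bins where no cell type has a peak are flagged as excluded from the
#' stratified evaluation.
#'
#' @param peak_calls named list (one element per cell type) of logical
#'   per-bin indicators, all the same length.
#' @return list with integer `count` per bin and logical `excluded`
#'   (`count == 0`).
#' @export
stratify_by_peak_count <- function(peak_calls) {
  if (length(peak_calls) == 0L) stop("need peak calls for at least one cell type")
  lens <- lengths(peak_calls)
  if (length(unique(lens)) != 1L) {
    stop("peak-call vectors have inconsistent lengths: ",
         paste(unique(lens), collapse = ", "))
  }
  count <- Reduce(`+`, lapply(peak_calls, as.integer))
  list(count = count, excluded = count == 0L)
}

#' Peak-count-stratified MSE, precision and recall
#'
#' For each peak count `c >= 1`, restricts to bins where exactly `c` cell
#' types have a MACS2 peak, thresholds each cell type's signal at
#' `threshold` (inclusive; the default 1.44 is `arcsinh(2)`, a signal
#' p value of 0.01) and scores the recovery of the peak calls pooled across
#' cell types: precision = TP/(TP+FP), recall = TP/(TP+FN), plus the MSE
#' between `observed` and `imputed` over those bins and cell types.
#' Precision is omitted (`NA`) in strata with no predicted peaks; strata
#' with no bins are omitted entirely.
#'
#' @param observed named list per cell type of observed arcsinh signal (used
#'   for the MSE column; pass the imputed list to score imputations against
#'   themselves).
#' @param imputed named list per cell type of the signal being thresholded
#'   and scored.
#' @param peak_calls named list per cell type of logical peak indicators.
#' @param stratification result of [stratify_by_peak_count()]; computed from
#'   `peak_calls` when `NULL`.
#' @param threshold arcsinh peak threshold (default `asinh(2)`, ~1.44).
#' @return data.frame with columns `count`, `n_bins`, `mse`, `precision`,
#'   `recall`.
#' @export
stratified_prf <- function(observed, imputed, peak_calls,
                           stratification = NULL, threshold = asinh(2)) {
  cells <- names(peak_calls)
  if (is.null(stratification)) stratification <- stratify_by_peak_count(peak_calls)
  count <- stratification$count
  rows <- list()
  for (cval in sort(unique(count[count > 0L]))) {
    bins <- which(count == cval)
    tp <- fp <- fn <- 0L
    se <- 0; n <- 0L
    for (cl in cells) {
      pred <- imputed[[cl]][bins] >= threshold
      call <- peak_calls[[cl]][bins]
      tp <- tp + sum(pred & call)
      fp <- fp + sum(pred & !call)
      fn <- fn + sum(!pred & call)
      d <- observed[[cl]][bins] - imputed[[cl]][bins]
      se <- se + sum(d^2)
      n <- n + length(bins)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      count = cval, n_bins = length(bins), mse = se / n,
      precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_)
  }
  if (!length(rows)) {
    return(data.frame(count = integer(), n_bins = integer(), mse = numeric(),
                      precision = numeric(), recall = numeric()))
  }
  do.call(rbind, rows)
}

#' Pairwise mark-relationship correlation
#'
#' Correlation of per-region mean signal between two tracks, used to check
#' that imputations preserve known relationships between marks (e.g. the
#' negative H3K4me3 / H3K27me3 correlation in promoters, or the positive
#' H3K36me3 / RNA-seq correlation in gene bodies).  Positive values mean the
#' two tracks co-vary across regions.  With `regions_b`, region `i` of
#' `regions` is paired with region `i` of `regions_b` (e.g. a promoter with
#' its gene body).
#'
#' @param track_a,track_b named per-chromosome signal lists (arcsinh scale).
#' @param regions region data.frame; per-region means of `track_a` (and of
#'   `track_b` unless `regions_b` is given) are correlated.
#' @param grid a [genomic_grid()].
#' @param regions_b optional second region set, row-paired with `regions`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient.
#' @export
pairwise_relationship <- function(track_a, track_b, regions, grid,
                                  regions_b = NULL,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(regions) < 3L) stop("need at least 3 regions to correlate")
  a <- region_means(track_a, regions, grid)
  b <- region_means(track_b, if (is.null(regions_b)) regions else regions_b, grid)
  stats::cor(a, b, method = method)
}

#' Per-region mean signal
#'
#' @param track named per-chromosome signal list (or a vector for a
#'   single-chromosome grid).
#' @param regions region data.frame.
#' @param grid a [genomic_grid()].
#' @return Numeric vector, one mean per region row.
#' @export
region_means <- function(track, regions, grid) {
  if (is.numeric(track)) track <- stats::setNames(list(track), grid$chrom_names[1L])
  vapply(seq_len(nrow(regions)), function(i) {
    bins <- region_bins(regions[i, , drop = FALSE], grid, regions$chrom[i])
    if (!length(bins)) return(NA_real_)
    mean(track[[regions$chrom[i]]][bins + 1L])
  }, numeric(1))
}

#' Average precision
#'
#' Summarizes a precision-recall curve with the step formula
#' `AP = sum_n (Recall_n - Recall_{n-1}) * Precision_n`, with one threshold
#' per distinct score value, in descending order (tied scores form a single
#' threshold).
#'
#' @param labels logical (or 0/1) vector; at least one positive required.
#' @param scores numeric ranking scores, higher = more confidently positive.
#' @return AP in (0, 1].
#' @export
average_precision <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  P <- sum(labels)
  if (P == 0L) stop("average precision undefined without positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # last index of each distinct-score block = one threshold
  block_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[block_end]
  np <- block_end                    # predicted positives at each threshold
  precision <- tp / np
  recall <- tp / P
  sum((recall - c(0, recall[-length(recall)])) * precision)
}
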
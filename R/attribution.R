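# gradient of the scalar network output with respect to its input, for a
# batch of inputs; analytic backprop through the ReLU layers (subgradient 0
# at exact zeros)
.dnn_input_grad <- function(dnn, X) {
  fw <- .dnn_forward(dnn, X, keep = TRUE)
  L <- length(dnn$layers)
  dA <- matrix(1, nrow(X), 1L) %*% t(dnn$out$w)
  for (l in seq.int(L, 1L)) {
    dZ <- dA * (fw$H[[l]] > 0)
    dA <- dZ %*% t(dnn$layers[[l]]$W)
  }
  dA
}

#' Integrated-gradients attribution of one imputed value
#'
#' Attributes a prediction to its input features by integrating the
#' gradient of the network output along the straight path from a reference
#' input `x'` to the actual input `x`:
#' `a_i = (x_i - x'_i) * (1/m) * sum_{k=1..m} df/dx_i` evaluated at
#' `x' + (k/m)(x - x')` (right-Riemann approximation).  Attributions sum to
#' `f(x) - f(x')` up to the Riemann discretization error, which is reported
#' as `completeness_error`; for a linear model the formula is exact at any
#' `m`.  The five model components (cell, assay, and the three genomic
#' scales) partition the features via the fixed concatenation order.
#'
#' @param model a trained `epi_model`.
#' @param cell,assay,chrom,bin the tensor index to explain (`bin` 0-based).
#' @param reference `"zero"` (all-zero input, default) or `"mean"` (mean
#'   factor rows), or a numeric vector of [input_width()] values.
#' @param steps number of Riemann steps `m` (default 128).
#' @return An `attribution_result`: list with `features` (length-398
#'   attribution vector at defaults), `components` (five sums),
#'   `prediction`, `reference_prediction`, `completeness_error`, `steps`.
#' @export
integrated_gradients <- function(model, cell, assay, chrom, bin,
                                 reference = "zero", steps = 128L) {
  if (steps < 1L) stop("steps must be >= 1")
  x <- drop(assemble_input(model, cell, assay, chrom, bin))
  x0 <- .reference_input(model, reference, chrom)
  if (length(x0) != length(x)) stop("reference width ", length(x0),
                                    " does not match input width ", length(x))
  ks <- seq_len(steps) / steps
  path <- matrix(rep(x0, each = steps), steps) +
    outer(ks, x - x0)
  grads <- .dnn_input_grad(model$dnn, path)
  avg_grad <- colMeans(grads)
  features <- (x - x0) * avg_grad
  pred <- forward(model, x)
  ref_pred <- forward(model, x0)
  res <- list(features = features,
              components = .component_sums(features, model$config),
              prediction = pred, reference_prediction = ref_pred,
              completeness_error = abs(sum(features) - (pred - ref_pred)),
              steps = as.integer(steps))
  class(res) <- "attribution_result"
  res
}

.reference_input <- function(model, reference, chrom) {
  if (is.numeric(reference)) return(reference)
  if (identical(reference, "zero")) return(numeric(input_width(model$config)))
  if (identical(reference, "mean")) {
    g <- model$factors$genome[[chrom]]
    return(c(colMeans(model$factors$cell), colMeans(model$factors$assay),
             colMeans(g$g25), colMeans(g$g250), colMeans(g$g5k)))
  }
  stop("reference must be 'zero', 'mean', or a numeric vector")
}

.component_sums <- function(features, config) {
  sl <- .input_slices(config)
  vapply(sl, function(ix) sum(features[ix]), numeric(1))
}

#' Component sums of an attribution
#'
#' Sums the per-feature attributions over the five model components (cell,
#' assay, 25-bp, 250-bp, 5-kbp genomic factors) using the fixed
#' concatenation slices; the five sums add up to
#' `prediction - reference_prediction` within the completeness error.
#'
#' @param result an `attribution_result` from [integrated_gradients()].
#' @return Named numeric vector `c(cell, assay, g25, g250, g5k)`.
#' @export
component_attributions <- function(result) {
  stopifnot(inherits(result, "attribution_result"))
  result$components
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("attribution: prediction", format(x$prediction, digits = 4),
      "reference", format(x$reference_prediction, digits = 4),
      "(m =", x$steps, ", completeness error",
      format(x$completeness_error, digits = 3), ")\n")
  print(round(x$components, 4))
  invisible(x)
}

#' Per-bin component attribution tracks
#'
#' Runs integrated gradients at every bin of a range and returns one value
#' per component per bin, alongside the prediction and reference
#' prediction; component columns sum to `prediction - reference` within the
#' completeness tolerance.  Deterministic given the model and reference
#' policy.  The component columns can be exported as bedGraph tracks with
#' [export_imputed()].
#'
#' @param model a trained `epi_model`.
#' @param cell,assay,chrom track to explain.
#' @param bins integer vector of 0-based fine bins (default: whole
#'   chromosome).
#' @param reference reference policy as in [integrated_gradients()].
#' @param steps Riemann steps per bin.
#' @return data.frame with columns `bin`, `prediction`, `reference`,
#'   `cell`, `assay`, `g25`, `g250`, `g5k`, `completeness_error`.
#' @export
attribution_profile <- function(model, cell, assay, chrom,
                                bins = NULL, reference = "zero", steps = 128L) {
  if (is.null(bins)) bins <- seq.int(0L, model$grid$n_bins_25[chrom] - 1L)
  X <- assemble_input(model, cell, assay, chrom, bins)
  x0 <- .reference_input(model, reference, chrom)
  n <- nrow(X)
  d <- ncol(X)
  preds <- .dnn_forward(model$dnn, X)
  ref_pred <- forward(model, x0)
  ks <- seq_len(steps) / steps
  # accumulate the path-average gradient over steps (keeps memory at n x d)
  avg <- matrix(0, n, d)
  X0 <- matrix(rep(x0, each = n), n)
  D <- X - X0
  for (k in ks) {
    avg <- avg + .dnn_input_grad(model$dnn, X0 + k * D)
  }
  A <- D * (avg / steps)
  sl <- .input_slices(model$config)
  comp <- vapply(sl, function(ix) rowSums(A[, ix, drop = FALSE]), numeric(n))
  if (n == 1L) comp <- matrix(comp, nrow = 1L, dimnames = list(NULL, names(sl)))
  data.frame(bin = bins, prediction = preds, reference = ref_pred,
             cell = comp[, "cell"], assay = comp[, "assay"],
             g25 = comp[, "g25"], g250 = comp[, "g250"], g5k = comp[, "g5k"],
             completeness_error = abs(rowSums(A) - (preds - ref_pred)))
}

#' Stratified mean component attributions
#'
#' Aggregates attribution profiles for several cell types into mean
#' component attributions per (cross-cell-type peak count, peak status)
#' stratum: positions are grouped by the number of cell types with a peak
#' (count 0 strata are omitted), and within each group the mean attribution
#' of each component is computed separately over the cell types in which a
#' peak does or does not occur.  Peak status comes from thresholding the
#' observed -log10 p signal at `binarize_threshold` (default 2) when
#' `signals` are given, otherwise from the peak calls themselves.
#'
#' @param profiles named list (per cell type) of data.frames from
#'   [attribution_profile()], all over the same bins.
#' @param peak_calls named list (per cell type) of logical indicators over
#'   the same bins.
#' @param signals optional named list (per cell type) of raw -log10 p
#'   signal over the same bins, binarized at `binarize_threshold` for peak
#'   status.
#' @param binarize_threshold -log10 p threshold for peak status (default 2,
#'   i.e. p = 0.01).
#' @return data.frame with columns `count`, `peak` (logical), `component`,
#'   `mean_attribution`, `n`; empty strata are omitted.
#' @export
stratified_attribution_summary <- function(profiles, peak_calls,
                                           signals = NULL,
                                           binarize_threshold = 2) {
  cells <- names(profiles)
  if (!setequal(cells, names(peak_calls))) {
    stop("profiles and peak_calls must cover the same cell types")
  }
  strat <- stratify_by_peak_count(peak_calls[cells])
  components <- c("cell", "assay", "g25", "g250", "g5k")
  rows <- list()
  for (cval in sort(unique(strat$count[strat$count > 0L]))) {
    sel <- strat$count == cval
    for (status in c(TRUE, FALSE)) {
      acc <- stats::setNames(numeric(length(components)), components)
      n <- 0L
      for (cl in cells) {
        st <- if (is.null(signals)) peak_calls[[cl]][sel] else
          signals[[cl]][sel] >= binarize_threshold
        pick <- which(st == status)
        if (!length(pick)) next
        prof <- profiles[[cl]][sel, , drop = FALSE]
        for (comp in components) acc[comp] <- acc[comp] + sum(prof[[comp]][pick])
        n <- n + length(pick)
      }
      if (n == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        count = cval, peak = status, component = components,
        mean_attribution = as.numeric(acc) / n, n = n)
    }
  }
  if (!length(rows)) {
    return(data.frame(count = integer(), peak = logical(),
                      component = character(), mean_attribution = numeric(),
                      n = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
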
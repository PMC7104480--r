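#' Impute a genome-wide signal track
#'
#' Predicts the arcsinh-scale signal of any (cell type, assay) pair at every
#' 25-bp bin of the requested chromosomes by evaluating the trained model.
#' Imputation is a pure function of the model and indices; predictions are
#' not clipped to be non-negative unless `clip = TRUE` (true arcsinh signal
#' is >= 0, but evaluation uses raw predictions by default).
#'
#' @param model a trained `epi_model`.
#' @param cell,assay registered identifiers.
#' @param chroms chromosome names (default: all in the grid).
#' @param clip clamp negative predictions to 0 (default `FALSE`).
#' @param batch_size bins evaluated per forward pass.
#' @return Named list of per-chromosome numeric vectors of predicted arcsinh
#'   signal, with attributes `cell` and `assay`.
#' @export
impute_track <- function(model, cell, assay, chroms = model$grid$chrom_names,
                         clip = FALSE, batch_size = 100000L) {
  missing_ch <- setdiff(chroms, names(model$factors$genome))
  if (length(missing_ch)) {
    stop("no trained genome factors for chromosome(s): ",
         paste(missing_ch, collapse = ", "))
  }
  out <- lapply(stats::setNames(chroms, chroms), function(ch) {
    n_bins <- as.integer(model$grid$n_bins_25[ch])
    vals <- numeric(n_bins)
    for (s in seq.int(0L, n_bins - 1L, by = batch_size)) {
      e <- min(s + batch_size - 1L, n_bins - 1L)
      vals[(s + 1L):(e + 1L)] <- predict_signal(model, cell, assay, ch, s:e)
    }
    if (clip) vals <- pmax(vals, 0)
    vals
  })
  attr(out, "cell") <- cell
  attr(out, "assay") <- assay
  out
}

#' Export an imputed track as bedGraph
#'
#' Values are written at 4 decimal places by default (file size vs
#' fidelity); `inverse_transform = TRUE` converts arcsinh predictions back
#' to the raw -log10 p scale with `sinh`.  Negative predictions are exported
#' unchanged.
#'
#' @param track named list of per-chromosome value vectors (e.g. from
#'   [impute_track()]).
#' @param grid a [genomic_grid()].
#' @param path output bedGraph path.
#' @param inverse_transform write `sinh(values)` (raw -log10 p scale).
#' @param digits decimal places (default 4; `NA` = full precision).
#' @return `path`, invisibly.
#' @export
export_imputed <- function(track, grid, path, inverse_transform = FALSE,
                           digits = 4L) {
  lines <- unlist(lapply(names(track), function(ch) {
    vals <- track[[ch]]
    if (inverse_transform) vals <- sinh(vals)
    .signal_lines(vals, grid, ch, digits)
  }))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot open ", path, " for writing"))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
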
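#' Genomic binning grid
#'
#' A `genomic_grid` records chromosome names and lengths together with the
#' fixed 25-bp binning they induce, plus the derived bin counts at the two
#' coarser genomic resolutions used by the model (250 bp = 10 fine bins,
#' 5 kbp = 200 fine bins).  All coordinates in this package are 0-based
#' half-open (BED/bedGraph convention); fine bin `i` covers
#' `[25*i, 25*i + 25)`.  Partial terminal bins are kept, so bin counts are
#' ceilings.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in
#'   basepairs; names are the chromosome identifiers.
#' @param bin_size fine bin width in basepairs (default 25).
#'
#' @return An object of class `genomic_grid` with fields `chrom_names`,
#'   `chrom_lengths`, `bin_size`, and per-chromosome bin counts `n_bins_25`,
#'   `n_bins_250`, `n_bins_5k`.
#' @examples
#' grid <- genomic_grid(c(chrT = 1000))
#' grid$n_bins_25   # 40 bins of 25 bp
#' @export
genomic_grid <- function(chrom_lengths, bin_size = 25L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector of chromosome lengths")
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop("duplicate chromosome names in chrom_lengths")
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("all chromosome lengths must be positive and finite")
  }
  lens <- as.numeric(chrom_lengths)
  names(lens) <- names(chrom_lengths)
  n25 <- ceiling(lens / bin_size)
  structure(list(
    chrom_names   = names(lens),
    chrom_lengths = lens,
    bin_size      = as.integer(bin_size),
    n_bins_25     = n25,
    n_bins_250    = ceiling(n25 / 10),
    n_bins_5k     = ceiling(n25 / 200)
  ), class = "genomic_grid")
}

#' Read a chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length in basepairs.
#'
#' @param path path to the chrom.sizes file.
#' @param bin_size fine bin width passed to [genomic_grid()].
#' @return A [genomic_grid()].
#' @export
read_chrom_sizes <- function(path, bin_size = 25L) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1, numeric = 2))
  if (ncol(dt) < 2L) stop("chrom.sizes file must have two tab-separated columns: ", path)
  lens <- dt[[2L]]
  names(lens) <- dt[[1L]]
  genomic_grid(lens, bin_size = bin_size)
}

#' @export
print.genomic_grid <- function(x, ...) {
  cat("genomic_grid:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp,",
      format(sum(x$n_bins_25), big.mark = ","), "bins of", x$bin_size, "bp\n")
  invisible(x)
}

.grid_check_chrom <- function(grid, chrom) {
  if (!chrom %in% grid$chrom_names) {
    stop("unknown chromosome '", chrom, "'; grid has: ",
         paste(grid$chrom_names, collapse = ", "))
  }
  invisible(chrom)
}

#' Map fine bins to the three genomic resolutions
#'
#' The model keeps one latent factor row per 25-bp bin, one per 250-bp bin,
#' and one per 5-kbp bin.  A fine bin `b` (0-based, per chromosome) uses the
#' mid-resolution row `floor(b/10)` and the coarse row `floor(b/200)`.
#'
#' @param bin25 integer vector of 0-based fine bin indices.
#' @param n_bins_25 number of fine bins on the chromosome (for range checks).
#' @return A list with integer vectors `i25`, `i250`, `i5k` (0-based).
#' @examples
#' multiscale_indices(c(0, 199, 4000), 5000)
#' @export
multiscale_indices <- function(bin25, n_bins_25) {
  bin25 <- as.integer(bin25)
  if (any(bin25 < 0L) || any(bin25 >= n_bins_25)) {
    bad <- bin25[bin25 < 0L | bin25 >= n_bins_25][1L]
    stop("bin index ", bad, " out of range [0, ", n_bins_25, ")")
  }
  list(i25 = bin25, i250 = bin25 %/% 10L, i5k = bin25 %/% 200L)
}
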
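#' Arcsinh transform of enrichment signal
#'
#' Signal tracks are -log10 p enrichment values; training and evaluation use
#' the variance-stabilizing arcsinh transform
#' \eqn{\sinh^{-1}(x) = \ln(x + \sqrt{1 + x^2})}, which compresses outliers
#' while keeping small values nearly unchanged.  The evaluation peak
#' threshold 1.44 is `arcsinh_transform(2)`, i.e. a signal p value of 0.01.
#'
#' @param x numeric vector of raw -log10 p values (finite).
#' @return `asinh(x)`.
#' @seealso [arcsinh_inverse()]
#' @examples
#' arcsinh_transform(2)          # 1.4436; rounds to the 1.44 peak threshold
#' arcsinh_inverse(arcsinh_transform(5))
#' @export
arcsinh_transform <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) stop("x must be finite numeric")
  asinh(x)
}

#' Inverse arcsinh transform
#'
#' @param y numeric vector on the arcsinh scale.
#' @return `sinh(y)`, the raw -log10 p scale.
#' @export
arcsinh_inverse <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y))) stop("y must be finite numeric")
  sinh(y)
}

#' Bin interval signal onto the 25-bp grid
#'
#' Converts bedGraph-style `(start, end, value)` intervals for one chromosome
#' into one value per 25-bp bin.  Each bin holds the coverage-weighted mean of
#' the interval values overlapping it (weights are covered basepairs, so a
#' partially covered bin averages over its actually covered width);
#' uncovered bins are 0.  With `aggregator = "max"` the bin takes the maximum
#' overlapping value instead.
#'
#' @param intervals data.frame with numeric columns `start`, `end` (0-based
#'   half-open) and `value`; sorted, non-overlapping within the chromosome.
#' @param grid a [genomic_grid()].
#' @param chrom chromosome name.
#' @param aggregator `"mean"` (coverage-weighted, default) or `"max"`.
#' @return numeric vector of length `grid$n_bins_25[chrom]`.
#' @examples
#' g <- genomic_grid(c(chrT = 100))
#' bin_track(data.frame(start = c(0, 10), end = c(10, 25), value = c(1, 4)),
#'           g, "chrT")[1]   # (10*1 + 15*4)/25 = 2.8
#' @export
bin_track <- function(intervals, grid, chrom, aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  .grid_check_chrom(grid, chrom)
  n_bins <- as.integer(grid$n_bins_25[chrom])
  bs <- grid$bin_size
  out <- numeric(n_bins)
  if (nrow(intervals) == 0L) return(out)

  start <- as.numeric(intervals$start)
  end   <- as.numeric(intervals$end)
  value <- as.numeric(intervals$value)
  if (any(start < 0) || any(end <= start)) stop("intervals must satisfy 0 <= start < end")
  chrom_len <- grid$chrom_lengths[chrom]
  if (any(end > chrom_len)) {
    i <- which(end > chrom_len)[1L]
    stop(sprintf("interval [%d,%d) extends beyond chromosome %s (length %d)",
                 as.integer(start[i]), as.integer(end[i]), chrom, as.integer(chrom_len)))
  }
  if (is.unsorted(start, strictly = FALSE)) stop("intervals must be sorted by start")
  if (any(start[-1L] < end[-length(end)])) stop("intervals must be non-overlapping")

  # expand each interval into the fine bins it touches
  first_bin <- start %/% bs
  last_bin  <- (end - 1) %/% bs
  n_touch   <- as.integer(last_bin - first_bin + 1L)
  iv_id <- rep.int(seq_along(start), n_touch)
  bin   <- as.integer(first_bin[iv_id] + sequence(n_touch) - 1L)
  w <- pmin(end[iv_id], (bin + 1) * bs) - pmax(start[iv_id], bin * bs)

  if (aggregator == "mean") {
    num <- rowsum(w * value[iv_id], bin)
    den <- rowsum(w, bin)
    cnt <- rowsum(rep(1L, length(bin)), bin)
    vals <- num[, 1L] / den[, 1L]
    # bins covered by a single interval take its value exactly (keeps the
    # write -> read round trip bit-identical)
    single <- cnt[, 1L] == 1L
    first <- match(as.integer(rownames(num)), bin)
    vals[single] <- value[iv_id[first]][single]
    idx <- as.integer(rownames(num)) + 1L
    out[idx] <- vals
  } else {
    mx <- vapply(split(value[iv_id], bin), max, numeric(1))
    idx <- as.integer(names(mx)) + 1L
    out[idx] <- mx
  }
  out
}

.read_tsv_checked <- function(path, n_min_cols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  if (file.size(path) == 0L) return(data.table::data.table())
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stop("failed to read ", what, " file ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) > 0L && ncol(dt) < n_min_cols) {
    stop(what, " file ", path, " has ", ncol(dt), " columns; expected >= ", n_min_cols)
  }
  dt
}

#' Read a bedGraph signal file
#'
#' Four tab-separated columns: chrom, start, end, value (0-based half-open).
#' Lines are validated; a malformed line raises an error naming its number.
#'
#' @param path bedGraph file path.
#' @param grid a [genomic_grid()]; intervals on chromosomes absent from the
#'   grid are an error.
#' @param transform `"none"` (default) or `"arcsinh"` to transform values on
#'   load (raw tracks are -log10 p; the model works on the arcsinh scale).
#' @param aggregator passed to [bin_track()].
#' @return Named list of per-chromosome binned signal vectors (one entry per
#'   grid chromosome; chromosomes with no intervals are all-zero).
#' @export
read_bedgraph <- function(path, grid, transform = c("none", "arcsinh"),
                          aggregator = "mean") {
  transform <- match.arg(transform)
  dt <- .read_tsv_checked(path, 4L, "bedGraph")
  out <- lapply(grid$chrom_names, function(ch) numeric(grid$n_bins_25[ch]))
  names(out) <- grid$chrom_names
  if (nrow(dt) > 0L) {
    bad <- which(is.na(suppressWarnings(as.numeric(dt[[2L]]))) |
                 is.na(suppressWarnings(as.numeric(dt[[3L]]))) |
                 is.na(suppressWarnings(as.numeric(dt[[4L]]))))
    if (length(bad)) stop("malformed bedGraph line ", bad[1L], " in ", path)
    unknown <- setdiff(unique(dt[[1L]]), grid$chrom_names)
    if (length(unknown)) stop("bedGraph ", path, " has unknown chromosome(s): ",
                              paste(unknown, collapse = ", "))
    for (ch in intersect(grid$chrom_names, unique(dt[[1L]]))) {
      sub <- dt[dt[[1L]] == ch, ]
      iv <- data.frame(start = as.numeric(sub[[2L]]), end = as.numeric(sub[[3L]]),
                       value = as.numeric(sub[[4L]]))
      iv <- iv[order(iv$start), , drop = FALSE]
      out[[ch]] <- bin_track(iv, grid, ch, aggregator = aggregator)
    }
  }
  if (transform == "arcsinh") out <- lapply(out, arcsinh_transform)
  out
}

#' Write a binned signal vector as bedGraph
#'
#' Adjacent equal-valued bins are run-length merged into single lines; the
#' terminal interval is clipped to the chromosome length.  With the default
#' full-precision formatting, `write_signal` followed by [bin_track()] (via
#' [read_bedgraph()]) reproduces the input exactly.
#'
#' @param values numeric vector, one value per 25-bp bin of `chrom`.
#' @param grid a [genomic_grid()].
#' @param chrom chromosome name.
#' @param path output path.
#' @param digits decimal places for values, or `NA` (default) for full
#'   precision (`%.17g`).
#' @return `path`, invisibly.
#' @export
write_signal <- function(values, grid, chrom, path, digits = NA) {
  lines <- .signal_lines(values, grid, chrom, digits)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot open ", path, " for writing"))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.signal_lines <- function(values, grid, chrom, digits = NA) {
  .grid_check_chrom(grid, chrom)
  n_bins <- as.integer(grid$n_bins_25[chrom])
  if (length(values) != n_bins) {
    stop("values has length ", length(values), " but ", chrom, " has ", n_bins, " bins")
  }
  if (is.na(digits)) {
    vchr <- sprintf("%.17g", values)
  } else {
    vchr <- sprintf(paste0("%.", digits, "f"), values)
  }
  r <- rle(vchr)
  ends25 <- cumsum(r$lengths)
  starts <- c(0, ends25[-length(ends25)]) * grid$bin_size
  ends   <- pmin(ends25 * grid$bin_size, grid$chrom_lengths[chrom])
  sprintf("%s\t%d\t%d\t%s", chrom, as.integer(starts), as.integer(ends), r$values)
}

#' Read MACS2 narrowPeak calls as per-bin indicators
#'
#' narrowPeak is BED6+4 (10 columns).  A 25-bp bin is marked `TRUE` iff it
#' overlaps at least one basepair of any peak interval.
#'
#' @param path narrowPeak file path.
#' @param grid a [genomic_grid()].
#' @return Named list of per-chromosome logical vectors.
#' @export
read_narrowpeak <- function(path, grid) {
  dt <- .read_tsv_checked(path, 10L, "narrowPeak")
  out <- lapply(grid$chrom_names, function(ch) logical(grid$n_bins_25[ch]))
  names(out) <- grid$chrom_names
  if (nrow(dt) == 0L) return(out)
  starts <- suppressWarnings(as.numeric(dt[[2L]]))
  ends   <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(starts) | is.na(ends) | ends <= starts)
  if (length(bad)) stop("malformed narrowPeak line ", bad[1L], " in ", path)
  unknown <- setdiff(unique(dt[[1L]]), grid$chrom_names)
  if (length(unknown)) stop("narrowPeak ", path, " has unknown chromosome(s): ",
                            paste(unknown, collapse = ", "))
  bs <- grid$bin_size
  for (ch in intersect(grid$chrom_names, unique(dt[[1L]]))) {
    sel <- dt[[1L]] == ch
    n_bins <- as.integer(grid$n_bins_25[ch])
    ind <- logical(n_bins)
    fb <- pmax(starts[sel] %/% bs, 0)
    lb <- pmin((ends[sel] - 1) %/% bs, n_bins - 1L)
    keep <- fb <= lb
    fb <- fb[keep]; lb <- lb[keep]
    if (length(fb)) {
      n_touch <- as.integer(lb - fb + 1L)
      bins <- as.integer(rep.int(fb, n_touch) + sequence(n_touch) - 1L)
      ind[bins + 1L] <- TRUE
    }
    out[[ch]] <- ind
  }
  out
}

#' Build promoter regions from transcription start sites
#'
#' The promoter span is `span_bp` upstream of the TSS, respecting strand:
#' `[tss - span, tss)` on the + strand and `[tss, tss + span)` on the -
#' strand, clipped to the chromosome bounds.
#'
#' @param tss_records data.frame with columns `chrom`, `tss` (0-based bp),
#'   `strand` (`"+"` or `"-"`), and optionally `label`.
#' @param grid a [genomic_grid()].
#' @param span_bp promoter span in basepairs (default 2000).
#' @return A region data.frame (`chrom`, `start`, `end`, `strand`, `label`)
#'   with attribute `kind = "promoter"`; coordinates 0-based half-open.
#' @export
promoter_regions <- function(tss_records, grid, span_bp = 2000L) {
  if (span_bp <= 0) stop("span_bp must be positive")
  chrom <- as.character(tss_records$chrom)
  tss <- as.numeric(tss_records$tss)
  strand <- as.character(tss_records$strand)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  for (i in seq_along(chrom)) .grid_check_chrom(grid, chrom[i])
  lens <- grid$chrom_lengths[chrom]
  if (any(tss < 0) || any(tss > lens)) {
    i <- which(tss < 0 | tss > lens)[1L]
    stop("TSS at ", tss[i], " outside chromosome ", chrom[i])
  }
  start <- ifelse(strand == "+", pmax(tss - span_bp, 0), tss)
  end   <- ifelse(strand == "+", tss, pmin(tss + span_bp, lens))
  label <- if (!is.null(tss_records$label)) as.character(tss_records$label) else
    paste0("prom", seq_along(chrom))
  regions <- data.frame(chrom = chrom, start = start, end = end,
                        strand = strand, label = label,
                        stringsAsFactors = FALSE)
  attr(regions, "kind") <- "promoter"
  regions
}

#' Read a BED file of regions
#'
#' Accepts BED3 to BED6; missing name/strand columns are filled in.
#'
#' @param path BED file path.
#' @param grid a [genomic_grid()]; used to validate chromosomes.
#' @param kind region kind tag (`"promoter"`, `"gene_body"`, `"enhancer"`,
#'   or `"generic"`).
#' @return Region data.frame as in [promoter_regions()].
#' @export
read_bed_regions <- function(path, grid, kind = "generic") {
  dt <- .read_tsv_checked(path, 3L, "BED")
  if (nrow(dt) == 0L) {
    regions <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                          strand = character(), label = character())
    attr(regions, "kind") <- kind
    return(regions)
  }
  starts <- suppressWarnings(as.numeric(dt[[2L]]))
  ends   <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(starts) | is.na(ends) | ends <= starts)
  if (length(bad)) stop("malformed BED line ", bad[1L], " in ", path)
  unknown <- setdiff(unique(dt[[1L]]), grid$chrom_names)
  if (length(unknown)) stop("BED ", path, " has unknown chromosome(s): ",
                            paste(unknown, collapse = ", "))
  label  <- if (ncol(dt) >= 4L) as.character(dt[[4L]]) else paste0("region", seq_len(nrow(dt)))
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6L]]) else rep(".", nrow(dt))
  regions <- data.frame(chrom = as.character(dt[[1L]]), start = starts, end = ends,
                        strand = strand, label = label, stringsAsFactors = FALSE)
  attr(regions, "kind") <- kind
  regions
}

#' Map regions to the fine bins they cover
#'
#' @param regions region data.frame (`chrom`, `start`, `end`).
#' @param grid a [genomic_grid()].
#' @param chrom restrict to one chromosome.
#' @param unique_bins drop duplicate bins covered by overlapping regions
#'   (default `TRUE`).
#' @return Integer vector of 0-based fine bin indices on `chrom`.
#' @export
region_bins <- function(regions, grid, chrom, unique_bins = TRUE) {
  .grid_check_chrom(grid, chrom)
  sel <- regions$chrom == chrom
  if (!any(sel)) return(integer(0))
  bs <- grid$bin_size
  n_bins <- as.integer(grid$n_bins_25[chrom])
  fb <- pmax(regions$start[sel] %/% bs, 0)
  lb <- pmin((regions$end[sel] - 1) %/% bs, n_bins - 1L)
  keep <- fb <= lb
  fb <- fb[keep]; lb <- lb[keep]
  if (!length(fb)) return(integer(0))
  n_touch <- as.integer(lb - fb + 1L)
  bins <- as.integer(rep.int(fb, n_touch) + sequence(n_touch) - 1L)
  if (unique_bins) bins <- unique(bins)
  bins
}
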
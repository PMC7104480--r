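#' Observed signal-track collection
#'
#' A `track_set` is the sparse 3-D data tensor: a collection of
#' (cell type, assay) tracks, each a named list of per-chromosome 25-bp
#' signal vectors on the arcsinh scale.  Missing tensor entries are simply
#' absent tracks.
#'
#' @param grid a [genomic_grid()].
#' @param cells character vector of cell-type identifiers.
#' @param assays character vector of assay identifiers.
#' @return An empty `track_set`; add tracks with [add_track()].
#' @export
track_set <- function(grid, cells, assays) {
  stopifnot(length(cells) >= 1L, length(assays) >= 1L)
  if (anyDuplicated(cells)) stop("duplicate cell identifiers")
  if (anyDuplicated(assays)) stop("duplicate assay identifiers")
  structure(list(grid = grid, cells = as.character(cells),
                 assays = as.character(assays),
                 signal = list()),
            class = "track_set")
}

.track_key <- function(cell, assay) paste(cell, assay, sep = "\r")

#' Add one observed track
#'
#' @param ts a [track_set()].
#' @param cell,assay identifiers registered in `ts`.
#' @param values named list of per-chromosome numeric vectors (arcsinh
#'   scale), lengths matching the grid.
#' @return The updated `track_set`.
#' @export
add_track <- function(ts, cell, assay, values) {
  if (!cell %in% ts$cells) stop("unknown cell type '", cell, "'")
  if (!assay %in% ts$assays) stop("unknown assay '", assay, "'")
  if (is.numeric(values)) values <- stats::setNames(list(values), ts$grid$chrom_names[1L])
  for (ch in names(values)) {
    .grid_check_chrom(ts$grid, ch)
    if (length(values[[ch]]) != ts$grid$n_bins_25[ch]) {
      stop("track ", cell, "/", assay, " on ", ch, " has length ",
           length(values[[ch]]), "; expected ", ts$grid$n_bins_25[ch])
    }
    if (any(!is.finite(values[[ch]]))) stop("non-finite signal in ", cell, "/", assay)
  }
  ts$signal[[.track_key(cell, assay)]] <- values
  ts
}

#' Retrieve one track
#'
#' @inheritParams add_track
#' @return Named list of per-chromosome signal vectors, or error if absent.
#' @export
get_track <- function(ts, cell, assay) {
  key <- .track_key(cell, assay)
  if (is.null(ts$signal[[key]])) stop("track ", cell, "/", assay, " is not observed")
  ts$signal[[key]]
}

#' List the observed (cell, assay) pairs
#'
#' @param ts a [track_set()].
#' @return data.frame with columns `cell` and `assay`, one row per observed
#'   track, in insertion order.
#' @export
observed_tracks <- function(ts) {
  if (!length(ts$signal)) {
    return(data.frame(cell = character(), assay = character()))
  }
  parts <- strsplit(names(ts$signal), "\r", fixed = TRUE)
  data.frame(cell = vapply(parts, `[[`, "", 1L),
             assay = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' @export
print.track_set <- function(x, ...) {
  cat("track_set:", length(x$cells), "cell types x", length(x$assays),
      "assays;", length(x$signal), "of", length(x$cells) * length(x$assays),
      "tracks observed\n")
  invisible(x)
}

#' Split observed tracks into cross-validation folds
#'
#' Tracks (not positions) are the cross-validation unit: each observed
#' (cell, assay) pair is assigned to one of `k` folds by a seeded random
#' partition with fold sizes differing by at most one.
#'
#' @param tracks data.frame with columns `cell`, `assay` (e.g. from
#'   [observed_tracks()]).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return The input data.frame with an integer `fold` column in `1:k`.
#' @export
make_track_folds <- function(tracks, k = 5L, seed = 1L) {
  n <- nrow(tracks)
  if (k > n) stop("k = ", k, " exceeds number of observed tracks (", n, ")")
  old <- .Random.seed_exists()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  tracks$fold <- sample(rep_len(seq_len(k), n))
  tracks
}

# RNG bracketing: functions that take a seed leave the caller's RNG state
# untouched.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
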
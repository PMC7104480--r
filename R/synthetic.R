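#' Synthetic compendium specification
#'
#' Parameters of the seeded generator that emulates a small epigenomic
#' compendium with known latent structure: smooth enrichment peaks on the
#' -log10 p scale, shared across all cell types (constitutive) or a random
#' subset (facultative), modulated per assay through a low-rank affinity
#' matrix, plus truncated Gaussian noise and the arcsinh transform.  The
#' defaults describe the desk-scale benchmark used throughout the test
#' suite: 6 cell types x 5 assays on one 125-kbp chromosome (5000 bins of
#' 25 bp), with 80% of tracks observed.
#'
#' @param n_cells,n_assays compendium dimensions.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param peak_density expected peaks per fine bin (default 0.008: ~40
#'   peaks on the default chromosome).
#' @param facultative_fraction fraction of peaks present only in a cell
#'   subset (default 0.5).
#' @param silencing_prob probability a facultative peak is silenced in a
#'   given cell type (default 0.5).
#' @param amplitude_range -log10 p amplitude range of peak summits
#'   (default c(4, 8), well above the p = 0.01 call threshold).
#' @param affinity_rank rank of the assay x peak affinity structure
#'   (default 2).
#' @param noise_sd truncated-Gaussian noise sd on the -log10 p scale
#'   (default 0.25).
#' @param observed_fraction fraction of (cell, assay) tracks observed
#'   (default 0.8); every cell and assay keeps at least one observed track.
#' @param seed mandatory integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cells = 6L, n_assays = 5L,
                           chrom_lengths = c(chrS = 125000),
                           peak_density = 0.008,
                           facultative_fraction = 0.5,
                           silencing_prob = 0.5,
                           amplitude_range = c(4, 8),
                           affinity_rank = 2L,
                           noise_sd = 0.25,
                           observed_fraction = 0.8,
                           seed = 1L) {
  stopifnot(n_cells >= 1L, n_assays >= 1L,
            facultative_fraction >= 0, facultative_fraction <= 1,
            silencing_prob >= 0, silencing_prob <= 1,
            noise_sd >= 0, observed_fraction > 0, observed_fraction <= 1,
            length(amplitude_range) == 2L, amplitude_range[1] > 0)
  if (missing(seed) && is.null(seed)) stop("a seed is mandatory")
  structure(list(n_cells = as.integer(n_cells), n_assays = as.integer(n_assays),
                 chrom_lengths = chrom_lengths, peak_density = peak_density,
                 facultative_fraction = facultative_fraction,
                 silencing_prob = silencing_prob,
                 amplitude_range = amplitude_range,
                 affinity_rank = as.integer(affinity_rank),
                 noise_sd = noise_sd,
                 observed_fraction = observed_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic epigenome compendium
#'
#' Draws peak locations (Gaussian bumps 10-40 bins wide), assigns each peak
#' as constitutive (present in all cell types) or facultative (silenced per
#' cell with `silencing_prob`), modulates peak height per assay through a
#' rank-`affinity_rank` affinity matrix scaled to \[0.5, 1\], adds
#' zero-truncated Gaussian noise on the -log10 p scale, applies the arcsinh
#' transform, and masks `1 - observed_fraction` of the tracks as missing
#' (ground truth retained).  Peak calls per (cell, assay) are the bins
#' whose noiseless -log10 p signal reaches 2 (p = 0.01).  Fully
#' reproducible from the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `grid`, `truth` (complete [track_set()]), `observed`
#'   ([track_set()] with masked tracks removed), `observed_mask`
#'   (cells x assays logical matrix), `peaks` (per cell, per assay, per
#'   chromosome logical indicators), `peak_table` (data.frame of the
#'   planted peaks: chrom, center bin, width, amplitude, type, and the
#'   cell-membership matrix in `cell_membership`), and `spec`.
#' @export
make_compendium <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_exists()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(spec$seed)

  grid <- genomic_grid(spec$chrom_lengths)
  cells <- sprintf("C%02d", seq_len(spec$n_cells))
  assays <- sprintf("A%02d", seq_len(spec$n_assays))

  # plant peaks per chromosome
  peak_rows <- list()
  for (ch in grid$chrom_names) {
    n_bins <- as.integer(grid$n_bins_25[ch])
    n_peaks <- max(1L, stats::rbinom(1L, n_bins, spec$peak_density))
    center <- sort(sample.int(n_bins, n_peaks)) - 1L
    width <- stats::runif(n_peaks, 10, 40)          # bins (support half-width)
    amp <- stats::runif(n_peaks, spec$amplitude_range[1], spec$amplitude_range[2])
    fac <- stats::runif(n_peaks) < spec$facultative_fraction
    peak_rows[[ch]] <- data.frame(chrom = ch, center = center, width = width,
                                  amplitude = amp,
                                  type = ifelse(fac, "facultative", "constitutive"),
                                  stringsAsFactors = FALSE)
  }
  peak_table <- do.call(rbind, peak_rows)
  rownames(peak_table) <- NULL
  n_peaks <- nrow(peak_table)

  # cell membership: constitutive peaks in all cells; facultative peaks
  # silenced per cell with silencing_prob (at least one carrier retained)
  membership <- matrix(TRUE, spec$n_cells, n_peaks,
                       dimnames = list(cells, NULL))
  for (p in which(peak_table$type == "facultative")) {
    keep <- stats::runif(spec$n_cells) >= spec$silencing_prob
    if (!any(keep)) keep[sample.int(spec$n_cells, 1L)] <- TRUE
    membership[, p] <- keep
  }

  # low-rank assay affinities scaled into [0.5, 1] so peak summits stay at
  # or above the -log10 p = 2 call threshold for every assay
  U <- matrix(stats::runif(spec$n_assays * spec$affinity_rank), spec$n_assays)
  V <- matrix(stats::runif(n_peaks * spec$affinity_rank), n_peaks)
  raw_aff <- U %*% t(V)
  rng <- range(raw_aff)
  affinity <- if (diff(rng) > 0) {
    0.5 + 0.5 * (raw_aff - rng[1]) / diff(rng)
  } else matrix(0.75, spec$n_assays, n_peaks)
  dimnames(affinity) <- list(assays, NULL)

  # noiseless per-chromosome bump profiles: bins x peaks (sparse in effect)
  profiles <- lapply(grid$chrom_names, function(ch) {
    n_bins <- as.integer(grid$n_bins_25[ch])
    rows <- which(peak_table$chrom == ch)
    M <- matrix(0, n_bins, length(rows))
    for (j in seq_along(rows)) {
      p <- rows[j]
      sigma <- peak_table$width[p] / 2
      lo <- max(0L, as.integer(floor(peak_table$center[p] - 3 * sigma)))
      hi <- min(n_bins - 1L, as.integer(ceiling(peak_table$center[p] + 3 * sigma)))
      b <- lo:hi
      M[b + 1L, j] <- exp(-((b - peak_table$center[p])^2) / (2 * sigma^2))
    }
    list(rows = rows, M = M)
  })
  names(profiles) <- grid$chrom_names

  truth <- track_set(grid, cells, assays)
  peaks <- stats::setNames(vector("list", length(cells)), cells)
  for (ci in seq_along(cells)) {
    peaks[[ci]] <- stats::setNames(vector("list", length(assays)), assays)
    for (ai in seq_along(assays)) {
      values <- list()
      calls <- list()
      for (ch in grid$chrom_names) {
        pr <- profiles[[ch]]
        w <- peak_table$amplitude[pr$rows] * affinity[ai, pr$rows] *
          membership[ci, pr$rows]
        clean <- as.vector(pr$M %*% w)      # -log10 p scale, noiseless
        calls[[ch]] <- clean >= 2
        noisy <- clean + stats::rnorm(length(clean), 0, spec$noise_sd)
        values[[ch]] <- arcsinh_transform(pmax(noisy, 0))
      }
      truth <- add_track(truth, cells[ci], assays[ai], values)
      peaks[[ci]][[ai]] <- calls
    }
  }

  # mask tracks as missing, guaranteeing each cell and assay keeps one
  n_tracks <- spec$n_cells * spec$n_assays
  n_obs <- max(1L, round(spec$observed_fraction * n_tracks))
  if (n_obs < max(spec$n_cells, spec$n_assays)) {
    stop("observed_fraction too low to keep one track per cell and assay")
  }
  mask <- matrix(FALSE, spec$n_cells, spec$n_assays,
                 dimnames = list(cells, assays))
  # a transversal first (one per cell, spread over assays), then random fill
  for (ci in seq_len(spec$n_cells)) {
    mask[ci, ((ci - 1L) %% spec$n_assays) + 1L] <- TRUE
  }
  for (ai in seq_len(spec$n_assays)) {
    if (!any(mask[, ai])) mask[sample.int(spec$n_cells, 1L), ai] <- TRUE
  }
  remaining <- which(!mask)
  extra <- n_obs - sum(mask)
  if (extra > 0L) mask[sample(remaining, min(extra, length(remaining)))] <- TRUE

  observed <- track_set(grid, cells, assays)
  for (ci in seq_along(cells)) {
    for (ai in seq_along(assays)) {
      if (mask[ci, ai]) {
        observed <- add_track(observed, cells[ci], assays[ai],
                              get_track(truth, cells[ci], assays[ai]))
      }
    }
  }

  list(grid = grid, truth = truth, observed = observed, observed_mask = mask,
       peaks = peaks, peak_table = peak_table, cell_membership = membership,
       assay_affinity = affinity, spec = spec)
}

#' Task labels correlated with the planted structure
#'
#' Builds a labelled locus set for the downstream-prediction harnesses.
#' For the `"expression"` task, one locus (a gene-body-like region of 40
#' bins centred on the peak) is created per planted peak plus an equal
#' number of background loci away from peaks; loci at constitutive peaks
#' are labelled positive with probability `p_hi`, all others with `p_lo`.
#' The generative rule is recorded in the `meta` attribute.
#'
#' @param compendium output of [make_compendium()].
#' @param task `"expression"` (the only built-in task).
#' @param p_hi,p_lo positive-label probabilities for constitutive-peak and
#'   other loci.
#' @param seed integer seed.
#' @return list with `regions` (locus data.frame), `labels` (logical),
#'   `locus_class` (character), and `meta`.
#' @export
make_task_labels <- function(compendium, task = "expression",
                             p_hi = 0.9, p_lo = 0.1, seed = 1L) {
  if (!identical(task, "expression")) stop("unknown task: ", task)
  old <- .Random.seed_exists()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  grid <- compendium$grid
  pt <- compendium$peak_table
  bs <- grid$bin_size
  half <- 20L  # 40-bin locus

  peak_regions <- data.frame(
    chrom = pt$chrom,
    start = pmax((pt$center - half) * bs, 0),
    end = pmin((pt$center + half) * bs, grid$chrom_lengths[pt$chrom]),
    strand = "+",
    label = paste0("locus_peak_", seq_len(nrow(pt))),
    stringsAsFactors = FALSE)
  locus_class <- pt$type

  # background loci: sampled away from any peak center
  bg <- list()
  for (ch in grid$chrom_names) {
    n_bins <- as.integer(grid$n_bins_25[ch])
    centers <- pt$center[pt$chrom == ch]
    cand <- setdiff(seq.int(half, n_bins - half - 1L),
                    unlist(lapply(centers, function(c0) (c0 - 60L):(c0 + 60L))))
    n_bg <- sum(pt$chrom == ch)
    if (length(cand) && n_bg > 0L) {
      picks <- sample(cand, min(n_bg, length(cand)))
      bg[[ch]] <- data.frame(
        chrom = ch, start = (picks - half) * bs, end = (picks + half) * bs,
        strand = "+", label = paste0("locus_bg_", ch, "_", seq_along(picks)),
        stringsAsFactors = FALSE)
    }
  }
  bg <- do.call(rbind, bg)
  regions <- rbind(peak_regions, bg)
  locus_class <- c(locus_class, rep("background", if (is.null(bg)) 0L else nrow(bg)))
  rownames(regions) <- NULL

  p <- ifelse(locus_class == "constitutive", p_hi, p_lo)
  labels <- stats::runif(nrow(regions)) < p
  list(regions = regions, labels = labels, locus_class = locus_class,
       meta = list(task = task, p_hi = p_hi, p_lo = p_lo, seed = seed,
                   rule = "P(positive) = p_hi at constitutive-peak loci, p_lo elsewhere"))
}

#' Write a compendium to disk
#'
#' Emits the file layout consumed by the I/O layer: `chrom.sizes`,
#' `manifest.tsv` (columns cell, assay, path) listing one bedGraph per
#' observed track on the raw -log10 p scale, and one narrowPeak file per
#' (cell, assay).
#'
#' @param compendium output of [make_compendium()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_compendium <- function(compendium, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- compendium$grid
  writeLines(sprintf("%s\t%d", grid$chrom_names, as.integer(grid$chrom_lengths)),
             file.path(dir, "chrom.sizes"))
  obs <- observed_tracks(compendium$observed)
  manifest <- data.frame(cell = obs$cell, assay = obs$assay,
                         path = sprintf("%s_%s.bedgraph", obs$cell, obs$assay))
  for (i in seq_len(nrow(obs))) {
    track <- get_track(compendium$observed, obs$cell[i], obs$assay[i])
    raw <- lapply(track, arcsinh_inverse)
    export_imputed(raw, grid, file.path(dir, manifest$path[i]), digits = NA)
    # narrowPeak: BED6+4 from the call indicator runs
    calls <- compendium$peaks[[obs$cell[i]]][[obs$assay[i]]]
    lines <- character(0)
    for (ch in names(calls)) {
      r <- rle(calls[[ch]])
      ends <- cumsum(r$lengths)
      starts <- c(0L, ends[-length(ends)])
      on <- which(r$values)
      if (length(on)) {
        lines <- c(lines, sprintf(
          "%s\t%d\t%d\tpeak%d\t0\t.\t0\t-1\t-1\t-1",
          ch, as.integer(starts[on]) * grid$bin_size,
          pmin(as.integer(ends[on]) * grid$bin_size, grid$chrom_lengths[ch]),
          seq_along(on)))
      }
    }
    writeLines(lines, file.path(dir, sprintf("%s_%s.narrowPeak",
                                             obs$cell[i], obs$assay[i])))
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
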
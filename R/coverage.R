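# Coverage profiling: per-chromosome read densities, binned raw and
# normalized coverage tracks, relative depletion, and continuity-based
# segmentation of normalized tracks.

#' Per-chromosome read density table
#'
#' One row per chromosome of the genome map (zero-count chromosomes
#' included), with density in unique reads per megabase — the summary behind
#' per-chromosome density comparisons such as a depleted host chromosome
#' versus its euploid neighbours.
#'
#' @param placements placements with status `unique` only.
#' @param genome_map genome map data frame.
#' @return data frame: chrom, genome_class, subgenome, group, placed_reads,
#'   length_bp, density.
#' @export
chromosome_density <- function(placements, genome_map) {
  if (nrow(placements) && !all(placements$status == "unique")) {
    stop("chromosome_density expects unique placements only")
  }
  unknown <- setdiff(placements$chrom, genome_map$name)
  if (length(unknown)) {
    stop("placement on unknown chromosome: ", paste(unknown, collapse = ", "))
  }
  counts <- table(factor(placements$chrom, levels = genome_map$name))
  data.frame(chrom = genome_map$name,
             genome_class = genome_map$genome_class,
             subgenome = genome_map$subgenome,
             group = genome_map$group,
             placed_reads = as.integer(counts),
             length_bp = genome_map$length_bp,
             density = as.integer(counts) / (genome_map$length_bp / 1e6),
             stringsAsFactors = FALSE)
}

#' Bin unique placements into a raw coverage track
#'
#' Each read is assigned to the bin containing its start position. Bins tile
#' every chromosome; the last bin may be short and its density is later
#' scaled by its actual width. A chromosome shorter than one bin yields a
#' single short bin.
#'
#' @param placements unique placements.
#' @param genome_map genome map (provides chromosome lengths).
#' @param bin_size_bp bin width in bp (>= 1).
#' @return data frame of class `coverage_track`: chrom, bin (0-based index),
#'   start_bp, end_bp, width_bp, raw_count; attribute `bin_size_bp`.
#' @export
bin_coverage <- function(placements, genome_map, bin_size_bp) {
  stopifnot(bin_size_bp >= 1)
  if (nrow(placements) && !all(placements$status == "unique")) {
    stop("bin_coverage expects unique placements only")
  }
  unknown <- setdiff(placements$chrom, genome_map$name)
  if (length(unknown)) {
    stop("placement on unknown chromosome: ", paste(unknown, collapse = ", "))
  }
  track <- do.call(rbind, lapply(seq_len(nrow(genome_map)), function(i) {
    len <- genome_map$length_bp[i]
    nb <- max(1L, as.integer(ceiling(len / bin_size_bp)))
    start <- (seq_len(nb) - 1) * bin_size_bp
    end <- pmin(start + bin_size_bp, len)
    data.frame(chrom = genome_map$name[i], bin = seq_len(nb) - 1L,
               start_bp = start, end_bp = end, width_bp = end - start,
               stringsAsFactors = FALSE)
  }))
  idx <- match(paste(placements$chrom,
                     floor(placements$start_bp / bin_size_bp)),
               paste(track$chrom, track$bin))
  track$raw_count <- tabulate(idx, nbins = nrow(track))
  attr(track, "bin_size_bp") <- bin_size_bp
  class(track) <- c("coverage_track", "data.frame")
  track
}

#' Normalize a coverage track to a host-genome baseline
#'
#' Per-bin read density (reads per Mb of actual bin width) is divided by a
#' baseline density. The default policy takes the median density over all
#' wheat-genome bins: robust to one or two absent or aneuploid chromosomes,
#' which is precisely the use case. A disomic host bin then sits near 1, a
#' hemizygous bin near 0.5, an absent bin near 0.
#'
#' @param track a `coverage_track` with raw counts.
#' @param genome_map genome map.
#' @param baseline_policy `"wheat_median"` (default) or `"global_median"`.
#' @return the track with `density` and `normalized` columns and a
#'   `baseline` attribute (reads/Mb).
#' @export
normalize_track <- function(track, genome_map,
                            baseline_policy = c("wheat_median", "global_median")) {
  baseline_policy <- match.arg(baseline_policy)
  stopifnot(inherits(track, "coverage_track"))
  track$density <- track$raw_count / (track$width_bp / 1e6)
  wheat <- genome_map$name[genome_map$genome_class == "wheat"]
  base_bins <- if (baseline_policy == "wheat_median") {
    track$density[track$chrom %in% wheat]
  } else {
    track$density
  }
  baseline <- median(base_bins)
  if (!is.finite(baseline) || baseline <= 0) {
    stop("normalization baseline is zero: no reads on baseline bins")
  }
  track$normalized <- track$density / baseline
  attr(track, "baseline") <- baseline
  attr(track, "baseline_policy") <- baseline_policy
  track
}

#' Relative depletion of a chromosome's density
#'
#' Percentage decrease of a target density against the lowest and highest
#' reference densities, reported to one decimal: e.g. a residual 18.1
#' reads/Mb against a 429.1-582.4 reads/Mb euploid range is a 95.8-96.9%
#' decrease.
#'
#' @param d_target target density (reads/Mb, >= 0).
#' @param d_low,d_high reference densities (> 0).
#' @return named numeric vector `c(pct_vs_low, pct_vs_high)`.
#' @export
relative_depletion <- function(d_target, d_low, d_high) {
  if (d_low <= 0 || d_high <= 0) stop("reference densities must be positive")
  if (d_target < 0) stop("target density must be non-negative")
  round(c(pct_vs_low = 100 * (1 - d_target / d_low),
          pct_vs_high = 100 * (1 - d_target / d_high)), 1)
}

# dosage band of a normalized value (vectorised); see dosage_thresholds()
classify_band <- function(x, thresholds) {
  if (any(x < 0)) stop("normalized coverage must be non-negative")
  band <- rep("indeterminate", length(x))
  band[x < thresholds$absent_max] <- "absent"
  band[x >= thresholds$single_low & x <= thresholds$single_high] <- "single_copy"
  band[x >= thresholds$present_min] <- "present"
  band
}

# merge runs shorter than min_run into the larger neighbouring run
merge_short_runs <- function(band, min_run) {
  r <- rle(band)
  while (length(r$lengths) > 1L) {
    short <- which(r$lengths < min_run)
    if (!length(short)) break
    j <- short[which.min(r$lengths[short])]
    nl <- length(r$lengths)
    target <- if (j == 1L) 2L
      else if (j == nl) nl - 1L
      else if (r$lengths[j + 1L] > r$lengths[j - 1L]) j + 1L else j - 1L
    r$values[j] <- r$values[target]
    r <- rle(inverse.rle(r))
  }
  inverse.rle(r)
}

#' Segment a normalized track by coverage continuity
#'
#' Per chromosome, normalized values are median-smoothed (`smooth_window`
#' bins, odd), classified into dosage bands, and maximal single-band runs
#' shorter than `min_run` bins are merged into their dominant neighbour —
#' suppressing isolated mismapping spikes while preserving genuine
#' multi-bin gaps. Segments tile the binned extent of each chromosome.
#'
#' @param track normalized `coverage_track`.
#' @param thresholds a [dosage_thresholds()].
#' @param min_run minimum run length in bins (default 3).
#' @param smooth_window odd median-filter window in bins (default 3).
#' @return data frame: chrom, start_bp, end_bp, band, mean_normalized, n_bins.
#' @export
segment_track <- function(track, thresholds = dosage_thresholds(),
                          min_run = 3L, smooth_window = 3L) {
  stopifnot(inherits(track, "coverage_track"), "normalized" %in% names(track),
            smooth_window %% 2 == 1)
  out <- lapply(unique(track$chrom), function(nm) {
    tr <- track[track$chrom == nm, , drop = FALSE]
    x <- tr$normalized
    sm <- if (length(x) >= smooth_window && smooth_window > 1) {
      as.numeric(runmed(x, smooth_window))
    } else {
      x
    }
    band <- merge_short_runs(classify_band(sm, thresholds), min_run)
    r <- rle(band)
    stop_idx <- cumsum(r$lengths)
    start_idx <- c(1L, head(stop_idx, -1) + 1L)
    data.frame(chrom = nm,
               start_bp = tr$start_bp[start_idx],
               end_bp = tr$end_bp[stop_idx],
               band = r$values,
               mean_normalized = vapply(seq_along(start_idx), function(i) {
                 mean(x[start_idx[i]:stop_idx[i]])
               }, numeric(1)),
               n_bins = r$lengths,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write segments as BED
#'
#' 0-based half-open; name = band, score = mean normalized coverage x 1000,
#' rounded.
#'
#' @param segments segment data frame from [segment_track()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = format(segments$start_bp, scientific = FALSE, trim = TRUE),
                    end = format(segments$end_bp, scientific = FALSE, trim = TRUE),
                    name = segments$band,
                    score = round(segments$mean_normalized * 1000))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
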
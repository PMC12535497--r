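# End-to-end orchestration: simulate -> place -> profile -> call, plus the
# real-data (SAM/BAM) entry point. A single top-level seed fans out to
# per-stage seeds so every artifact is reproducible from (config, seed).

# enrichment needs >= 2 groups per alien subgenome; skip it otherwise
maybe_enrichment <- function(density) {
  alien <- density[density$genome_class == "alien", , drop = FALSE]
  if (!nrow(alien)) return(NULL)
  if (max(table(alien$subgenome)) < 2) return(NULL)
  group_enrichment(density)
}

#' Pipeline configuration
#'
#' Defaults are the toy-scale study conditions: a 7-group, 3+3-subgenome
#' reference of 1 Mb chromosomes, 200,000 read pairs of 2x150 bp at 1%
#' substitution error, 20 kb bins, k = 21 seeds with a 4-mismatch cap.
#'
#' @param karyotype karyotype string, see [parse_karyotype()].
#' @param genome a [genome_config()].
#' @param total_pairs number of simulated read pairs.
#' @param read_length mate length in bp.
#' @param error_rate per-base substitution error rate.
#' @param bin_size_bp coverage bin width.
#' @param k seed length for the built-in placer.
#' @param max_mismatch Hamming mismatch cap.
#' @param min_len,max_len size-selection window in bp.
#' @param require_mixed_ends require one MspI and one SphI end per locus.
#' @param thresholds a [dosage_thresholds()].
#' @param min_run minimum run length (bins) for segmentation and alien calls.
#' @param smooth_window odd median-smoothing window (bins).
#' @param seed top-level integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(karyotype = "euploid",
                            genome = genome_config(),
                            total_pairs = 2e5,
                            read_length = 150L,
                            error_rate = 0.01,
                            bin_size_bp = 20000,
                            k = 21L,
                            max_mismatch = 4L,
                            min_len = 350, max_len = 390,
                            require_mixed_ends = TRUE,
                            thresholds = dosage_thresholds(),
                            min_run = 3L,
                            smooth_window = 3L,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the simulation-mode pipeline
#'
#' Builds the synthetic reference, digests it, size-selects loci, simulates
#' reads under the configured karyotype, places mate-1 reads, discards
#' multi-mapped and unplaced reads, profiles coverage, segments the tracks
#' and calls the karyotype. Rerunning with an identical config reproduces
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, standard TSV/BED/
#'   JSON/FASTA/FASTQ outputs are written via [write_outputs()].
#' @param reference optionally, a prebuilt `reference_set` matching
#'   `config$genome` (skips genome construction).
#' @param index optionally, a prebuilt `seed_index` on `reference`.
#' @return object of class `karyoskim_run`: list with reference map, loci,
#'   density, track, segments, enrichment, karyotype estimate and a manifest
#'   of per-stage counts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         reference = NULL, index = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (is.null(reference)) {
    reference <- build_reference(config$genome, seed_child(seed, "genome"))
  }
  gm <- genome_map(reference)
  kar <- parse_karyotype(config$karyotype, gm)

  fragments <- digest_reference(reference)
  loci <- select_loci(fragments, config$min_len, config$max_len,
                      config$require_mixed_ends)
  reads <- simulate_reads(reference, loci, kar, config$total_pairs,
                          config$read_length, config$error_rate,
                          seed_child(seed, "reads"))
  if (is.null(index)) index <- build_index(reference, config$k)
  placements <- place_reads(setNames(reads$mate1, reads$id), index, reference,
                            config$max_mismatch)
  unique_pl <- placements[placements$status == "unique", , drop = FALSE]

  density <- chromosome_density(unique_pl, gm)
  track <- bin_coverage(unique_pl, gm, config$bin_size_bp)
  track <- normalize_track(track, gm)
  segments <- segment_track(track, config$thresholds, config$min_run,
                            config$smooth_window)
  calls <- call_dosage(track, gm, config$thresholds, config$min_run)
  enrichment <- maybe_enrichment(density)
  karyotype <- infer_karyotype(calls, enrichment, segments)

  manifest <- list(
    mode = "simulate",
    seed = seed,
    karyotype_spec = config$karyotype,
    n_chromosomes = nrow(gm),
    n_fragments = nrow(fragments),
    n_loci = nrow(loci),
    n_pairs_simulated = nrow(reads),
    n_placed_unique = sum(placements$status == "unique"),
    n_multi = sum(placements$status == "multi"),
    n_unplaced = sum(placements$status == "unplaced"),
    n_bins = nrow(track),
    baseline_reads_per_mb = attr(track, "baseline"),
    label = karyotype$label)
  stopifnot(manifest$n_placed_unique + manifest$n_multi +
              manifest$n_unplaced == manifest$n_pairs_simulated)

  run <- structure(list(config = config, reference = reference, loci = loci,
                        reads = reads, placements = placements,
                        density = density, track = track, segments = segments,
                        enrichment = enrichment, karyotype = karyotype,
                        manifest = manifest),
                   class = "karyoskim_run")
  if (!is.null(out_dir)) write_outputs(run, out_dir)
  run
}

#' Run the real-data pipeline on external alignments
#'
#' Imports SAM/BAM alignments against a concatenated host+alien reference,
#' removes unmapped/secondary/supplementary/low-MAPQ (multi-mapped) records,
#' and runs the coverage profiling and karyotype calling stages.
#'
#' @param alignment_path SAM or BAM file.
#' @param genome_map genome map data frame or path to its TSV.
#' @param bin_size_bp coverage bin width (default 1 Mb, the full-genome scale).
#' @param min_mapq minimum mapping quality (default 1).
#' @param both_mates count both mates (default TRUE).
#' @param thresholds a [dosage_thresholds()].
#' @param min_run,smooth_window segmentation parameters (bins).
#' @param out_dir optional output directory.
#' @return a `karyoskim_run` (no reads/loci components).
#' @export
run_real <- function(alignment_path, genome_map, bin_size_bp = 1e6,
                     min_mapq = 1L, both_mates = TRUE,
                     thresholds = dosage_thresholds(),
                     min_run = 3L, smooth_window = 3L, out_dir = NULL) {
  gm <- if (is.character(genome_map)) read_genome_map(genome_map) else genome_map
  imported <- import_alignments(alignment_path, gm, min_mapq, both_mates)
  pl <- imported$placements

  density <- chromosome_density(pl, gm)
  track <- bin_coverage(pl, gm, bin_size_bp)
  track <- normalize_track(track, gm)
  segments <- segment_track(track, thresholds, min_run, smooth_window)
  calls <- call_dosage(track, gm, thresholds, min_run)
  enrichment <- maybe_enrichment(density)
  karyotype <- infer_karyotype(calls, enrichment, segments)

  manifest <- list(
    mode = "real",
    alignment = alignment_path,
    n_chromosomes = nrow(gm),
    n_placed_unique = nrow(pl),
    rejections = imported$rejections,
    n_bins = nrow(track),
    baseline_reads_per_mb = attr(track, "baseline"),
    label = karyotype$label)

  run <- structure(list(config = NULL, reference = NULL, loci = NULL,
                        reads = NULL, placements = pl, density = density,
                        track = track, segments = segments,
                        enrichment = enrichment, karyotype = karyotype,
                        manifest = manifest),
                   class = "karyoskim_run")
  if (!is.null(out_dir)) write_outputs(run, out_dir)
  run
}

#' @export
print.karyoskim_run <- function(x, ...) {
  m <- x$manifest
  cat("karyoskim run (", m$mode, " mode)\n", sep = "")
  if (!is.null(m$n_pairs_simulated)) {
    cat(sprintf("  reads: %d simulated; %d unique, %d multi, %d unplaced\n",
                m$n_pairs_simulated, m$n_placed_unique, m$n_multi, m$n_unplaced))
  } else {
    cat(sprintf("  reads: %d unique placements imported\n", m$n_placed_unique))
  }
  cat(sprintf("  baseline: %.1f reads/Mb over %d bins\n",
              m$baseline_reads_per_mb, m$n_bins))
  print(x$karyotype)
  invisible(x)
}

#' Write the standard output file set of a run
#'
#' Writes `density.tsv`, `coverage_bins.tsv`, `segments.bed`,
#' `karyotype_calls.tsv`, `karyotype.json` (schema-versioned summary),
#' `manifest.json`, and for simulation runs `loci.bed`. All tables carry a
#' header row with fixed column order; BED is 0-based half-open. Outputs are
#' byte-identical across reruns of the same config+seed.
#'
#' @param run a `karyoskim_run`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, named vector of file paths.
#' @export
write_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "karyoskim_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", out_dir)
  }
  paths <- c(density = file.path(out_dir, "density.tsv"),
             bins = file.path(out_dir, "coverage_bins.tsv"),
             segments = file.path(out_dir, "segments.bed"),
             calls = file.path(out_dir, "karyotype_calls.tsv"),
             karyotype = file.path(out_dir, "karyotype.json"),
             manifest = file.path(out_dir, "manifest.json"))
  write.table(run$density, paths["density"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(run$track), paths["bins"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_segments_bed(run$segments, paths["segments"])
  write.table(run$karyotype$calls, paths["calls"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(schema = "karyoskim/karyotype/v1",
         label = run$karyotype$label,
         alien_group = run$karyotype$alien_group,
         notes = run$karyotype$notes,
         enrichment = run$enrichment$table),
    paths["karyotype"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- run$manifest
  manifest$checksums <- as.list(tools::md5sum(unname(
    paths[c("density", "bins", "segments", "calls", "karyotype")])))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  if (!is.null(run$loci)) {
    paths <- c(paths, loci = file.path(out_dir, "loci.bed"))
    write_loci_bed(run$loci, paths["loci"])
  }
  invisible(paths)
}

#' Read a BED file of intervals
#'
#' Minimal BED reader for the files this package writes (0-based half-open).
#'
#' @param path BED path.
#' @return data frame with chrom, start_bp, end_bp and any extra columns
#'   named name, score.
#' @export
read_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start_bp", "end_bp", "name", "score")[seq_len(ncol(bed))]
  bed
}
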
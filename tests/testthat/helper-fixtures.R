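# Shared fixtures. The default-scale reference and its seed index are
# expensive (42 x 1 Mb chromosomes), so they are built lazily once per test
# session and reused; read simulation varies by seed on top of them, the same
# way replicate libraries vary over a fixed reference genome.

.fixture_env <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_env$ref)) {
    cfg <- genome_config()
    ref <- build_reference(cfg, seed = 20260930)
    .fixture_env$cfg <- cfg
    .fixture_env$ref <- ref
    .fixture_env$gm <- genome_map(ref)
    .fixture_env$loci <- select_loci(digest_reference(ref))
    .fixture_env$index <- build_index(ref)
  }
  .fixture_env
}

# run the simulate-mode pipeline on the shared default reference, varying
# only the downstream (read-simulation) seed
run_on_default <- function(karyotype, seed, total_pairs = 2e5,
                           error_rate = 0.01) {
  fx <- default_fixture()
  cfg <- pipeline_config(karyotype = karyotype, genome = fx$cfg,
                         total_pairs = total_pairs, error_rate = error_rate,
                         seed = seed)
  run_pipeline(cfg, reference = fx$ref, index = fx$index)
}

# small two-group reference for cheap unit tests
small_reference <- function(seed = 42, chrom_length = 60000,
                            wheat_divergence = 0.02, alien_divergence = 0.05,
                            loci_per_mb = 2200, groups = 2L) {
  build_reference(genome_config(groups = groups,
                                wheat_subgenomes = c("A", "D"),
                                alien_subgenomes = "S",
                                chrom_length_bp = chrom_length,
                                wheat_divergence = wheat_divergence,
                                alien_divergence = alien_divergence,
                                loci_per_mb = loci_per_mb),
                  seed = seed)
}

fake_placements <- function(chrom, start) {
  data.frame(read_id = sprintf("r%d", seq_along(chrom)), chrom = chrom,
             start_bp = start, strand = "+", mismatches = 0L,
             status = "unique", stringsAsFactors = FALSE)
}

# hand-rolled coverage_track from normalized values (for segmentation tests)
synthetic_track <- function(normalized, chrom = "chrT", bin_size = 1000) {
  n <- length(normalized)
  track <- data.frame(chrom = chrom, bin = seq_len(n) - 1L,
                      start_bp = (seq_len(n) - 1) * bin_size,
                      end_bp = seq_len(n) * bin_size,
                      width_bp = bin_size,
                      raw_count = as.integer(round(normalized * 10)),
                      density = normalized * 10 / (bin_size / 1e6),
                      normalized = normalized,
                      stringsAsFactors = FALSE)
  attr(track, "bin_size_bp") <- bin_size
  attr(track, "baseline") <- 10 / (bin_size / 1e6)
  class(track) <- c("coverage_track", "data.frame")
  track
}

# positionwise mismatch fraction between two equal-length DNA strings
mismatch_fraction <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(charToRaw(a) != charToRaw(b))
}

# exhaustive Hamming-scan placement oracle over every position of every
# chromosome, both strands; independent of the seed-index code path
oracle_place <- function(read, reference, max_mismatch = 4L) {
  best <- max_mismatch + 1L
  hits <- list()
  for (nm in reference$records$name) {
    subj <- Biostrings::DNAString(reference$sequences[[nm]])
    L <- length(subj)
    if (L < nchar(read)) next
    starts <- seq_len(L - nchar(read) + 1L)
    for (st in c("+", "-")) {
      pat <- if (st == "+") read else revcomp(read)
      ed <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subj,
                                        starting.at = starts,
                                        with.indels = FALSE)
      hits[[paste(nm, st)]] <- data.frame(
        chrom = nm, start_bp = starts - 1L, strand = st, mismatches = ed,
        stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, hits)
  all <- all[all$mismatches <= max_mismatch, , drop = FALSE]
  if (!nrow(all)) {
    return(list(status = "unplaced", chrom = NA, start_bp = NA, mismatches = NA))
  }
  # a +/- tie at the same (chrom, start) is one location
  agg <- aggregate(mismatches ~ chrom + start_bp, data = all, FUN = min)
  best <- min(agg$mismatches)
  top <- agg[agg$mismatches == best, , drop = FALSE]
  list(status = if (nrow(top) >= 2) "multi" else "unique",
       chrom = top$chrom[1], start_bp = top$start_bp[1], mismatches = best)
}

# write a crafted 5-record SAM file: 1 unmapped, 1 secondary, 1 primary with
# MAPQ 0, 2 primary with MAPQ >= 1; returns the path
write_sam_fixture <- function(path, chrom = "1A", chrom_len = 60000,
                              shuffle_seed = NULL) {
  cigar <- "20M"
  seq20 <- "ACGTACGTACGTACGTACGT"
  qual <- strrep("I", 20)
  records <- c(
    paste("r_unmapped", 4, "*", 0, 0, "*", "*", 0, 0, seq20, qual, sep = "\t"),
    paste("r_secondary", 256, chrom, 101, 60, cigar, "*", 0, 0, "*", "*", sep = "\t"),
    paste("r_mapq0", 0, chrom, 201, 0, cigar, "*", 0, 0, seq20, qual, sep = "\t"),
    paste("r_good1", 0, chrom, 301, 37, cigar, "*", 0, 0, seq20, qual, sep = "\t"),
    paste("r_good2", 16, chrom, 401, 60, cigar, "*", 0, 0, seq20, qual, sep = "\t"))
  if (!is.null(shuffle_seed)) {
    records <- withr::with_seed(shuffle_seed, sample(records))
  }
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len),
               records), path)
  path
}

sam_fixture_genome_map <- function(chrom = "1A", chrom_len = 60000) {
  data.frame(name = chrom, genome_class = "wheat", subgenome = "A",
             group = 1L, length_bp = chrom_len, stringsAsFactors = FALSE)
}
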
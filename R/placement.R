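# Read placement against the concatenated host+alien reference, and import of
# external SAM/BAM alignments. Reads with several equally good locations
# ("multi-mapped") are flagged and discarded downstream, excluding
# homoeologous mis-assignments within and between the genomes.

#' Build a k-mer seed index over a reference set
#'
#' Enumerates every forward-strand k-mer occurrence of every chromosome into a
#' sorted lookup table. With the default `k = 21` and 150 bp reads, seven
#' disjoint seeds per strand guarantee (pigeonhole) that every location within
#' the default mismatch cap of 4 is recovered, making unique/multi calls exact.
#'
#' @param reference a `reference_set`.
#' @param k seed length in bp (>= 11, at most the shortest chromosome).
#' @return object of class `seed_index` with a `reference_digest` checksum.
#' @export
build_index <- function(reference, k = 21L) {
  stopifnot(inherits(reference, "reference_set"))
  if (k < 11L) stop("k must be at least 11")
  if (k > min(reference$records$length_bp)) {
    stop("k exceeds the shortest chromosome length")
  }
  idx <- cpp_build_index(unname(reference$sequences), as.integer(k))
  idx$chroms <- reference$records$name
  idx$reference_digest <- cpp_reference_digest(unname(reference$sequences))
  class(idx) <- "seed_index"
  idx
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: k=%d, %d chromosomes, %s k-mer positions, digest %s\n",
              x$k, length(x$chroms), format(length(x$kmers), big.mark = ","),
              x$reference_digest))
  invisible(x)
}

#' Place reads on the reference
#'
#' Candidate locations are gathered from exact seed hits of the read and of
#' its reverse complement, then verified by full-length Hamming distance.
#' A unique minimum within `max_mismatch` gives status `unique`; tied minima
#' at two or more distinct locations give `multi` (a +/− tie at the same
#' position counts as one location); otherwise `unplaced`.
#'
#' @param reads character vector of read sequences (each at least `k` long).
#' @param index a `seed_index` built on `reference`.
#' @param reference the same `reference_set`.
#' @param max_mismatch Hamming mismatch cap (default 4).
#' @return data frame: read_id, chrom, start_bp (0-based), strand, mismatches,
#'   status.
#' @export
place_reads <- function(reads, index, reference, max_mismatch = 4L) {
  stopifnot(inherits(index, "seed_index"), inherits(reference, "reference_set"))
  if (!identical(index$reference_digest,
                 cpp_reference_digest(unname(reference$sequences)))) {
    stop("seed index was built on a different reference")
  }
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
  res <- cpp_place_reads(unname(reads), unclass(index)[c("kmers", "gpos", "offsets", "k")],
                         unname(reference$sequences), as.integer(max_mismatch))
  data.frame(read_id = ids,
             chrom = index$chroms[res$chrom_idx],
             start_bp = res$start,
             strand = res$strand,
             mismatches = res$mismatches,
             status = res$status,
             stringsAsFactors = FALSE)
}

#' Place a single read
#'
#' @inheritParams place_reads
#' @param mate1 one read sequence.
#' @return one-row placement data frame (see [place_reads()]).
#' @export
place_read <- function(mate1, index, reference, max_mismatch = 4L) {
  place_reads(setNames(mate1, "read"), index, reference, max_mismatch)
}

#' Import and filter external alignments (SAM/BAM)
#'
#' Keeps primary, mapped records with mapping quality at least `min_mapq`
#' (BWA-MEM assigns MAPQ 0 to repeat-placed reads, so the default
#' `min_mapq = 1` operationalises multi-mapped-read removal). Secondary and
#' supplementary records are always dropped. Every kept record becomes a
#' `unique` placement at its leftmost aligned position (0-based); rejected
#' records are counted by reason.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param genome_map genome map; alignment header chromosomes must all be
#'   resolvable against it.
#' @param min_mapq minimum mapping quality (default 1).
#' @param both_mates if `FALSE`, keep only first-in-pair (or unpaired) records.
#' @return list with `placements` (data frame as in [place_reads()]) and
#'   `rejections` (data frame reason/count).
#' @export
import_alignments <- function(path, genome_map, min_mapq = 1L,
                              both_mates = TRUE) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  header <- Rsamtools::scanBamHeader(path)[[1]]$targets
  unmatched <- setdiff(names(header), genome_map$name)
  if (length(unmatched)) {
    stop("alignment chromosomes absent from the genome map: ",
         paste(unmatched, collapse = ", "))
  }
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq")))[[1]]
  flag <- b$flag
  n <- length(flag)
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  mate2 <- !both_mates & bitwAnd(flag, 128L) != 0L
  mapq <- b$mapq
  mapq[is.na(mapq)] <- 0L
  low_mapq <- !unmapped & !secondary & !supplementary & !mate2 & mapq < min_mapq
  keep <- !(unmapped | secondary | supplementary | mate2 | low_mapq)

  rejections <- data.frame(
    reason = c("unmapped", "secondary", "supplementary", "second_mate",
               "low_mapq_multi"),
    count = c(sum(unmapped), sum(secondary & !unmapped),
              sum(supplementary & !unmapped & !secondary),
              sum(mate2 & !unmapped & !secondary & !supplementary),
              sum(low_mapq)),
    stringsAsFactors = FALSE)

  placements <- data.frame(
    read_id = as.character(b$qname[keep]),
    chrom = as.character(b$rname[keep]),
    start_bp = as.integer(b$pos[keep]) - 1L,   # SAM is 1-based
    strand = as.character(b$strand[keep]),
    mismatches = rep(NA_integer_, sum(keep)),
    status = rep("unique", sum(keep)),
    stringsAsFactors = FALSE)

  list(placements = placements, rejections = rejections)
}

#' Write placements as TSV
#'
#' @param placements placement data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_placements <- function(placements, path) {
  write.table(placements, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
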
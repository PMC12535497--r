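# In-silico double-digest RAD protocol: recognition-site scanning, dual-cut
# fragment enumeration, size selection, and copy-number-weighted paired-end
# read simulation under a karyotype specification.

#' Built-in restriction enzymes
#'
#' `MspI` (C^CGG) and `SphI` (GCATG^C), the enzyme pair of the ddRAD protocol
#' modelled here. `cut_offset` is the number of recognition-site bases left of
#' the cut on the top strand; both recognition sequences are palindromic, so a
#' top-strand scan finds every site.
#'
#' @param name `"MspI"`, `"SphI"`, or supply `recognition`/`cut_offset` for a
#'   custom enzyme.
#' @param recognition recognition sequence (DNA string).
#' @param cut_offset integer in `[0, nchar(recognition)]`.
#' @return object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition = NULL, cut_offset = NULL) {
  builtins <- list(MspI = list(recognition = "CCGG", cut_offset = 1L),
                   SphI = list(recognition = "GCATGC", cut_offset = 5L))
  if (is.null(recognition)) {
    if (!name %in% names(builtins)) {
      stop("unknown enzyme '", name, "'; supply recognition and cut_offset")
    }
    recognition <- builtins[[name]]$recognition
    cut_offset <- builtins[[name]]$cut_offset
  }
  stopifnot(cut_offset >= 0, cut_offset <= nchar(recognition))
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' Find all recognition-site start positions
#'
#' Scans the top strand for every occurrence of the enzyme's recognition
#' sequence, overlapping occurrences included. Positions are 0-based.
#'
#' @param sequence DNA string (may be empty).
#' @param enzyme a [restriction_enzyme()].
#' @return sorted integer vector of 0-based site starts.
#' @export
find_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  scan_pattern(sequence, enzyme$recognition)
}

#' Double-digest one chromosome
#'
#' Cut positions are pooled over both enzymes (site start + cut offset) plus
#' the chromosome ends; fragments are the intervals between consecutive cuts,
#' labelled with the flanking enzyme on each side (`"chrom_end"` at the
#' termini). Zero-length fragments from coincident cuts are dropped; the
#' remaining fragments tile `[0, len)` exactly.
#'
#' @param sequence DNA string.
#' @param enzymes list of two distinct [restriction_enzyme()] objects.
#' @param chrom chromosome name recorded in the output.
#' @return data frame with columns chrom, start_bp, end_bp (0-based
#'   half-open), left_enzyme, right_enzyme, length_bp.
#' @export
digest_sequence <- function(sequence, enzymes = list(restriction_enzyme("MspI"),
                                                     restriction_enzyme("SphI")),
                            chrom = "chr") {
  stopifnot(length(enzymes) == 2)
  if (identical(enzymes[[1]]$name, enzymes[[2]]$name)) {
    stop("the two enzymes must be distinct")
  }
  L <- nchar(sequence)
  cuts <- data.frame(pos = numeric(0), enzyme = character(0))
  for (e in enzymes) {
    s <- find_sites(sequence, e)
    if (length(s)) {
      cuts <- rbind(cuts, data.frame(pos = s + e$cut_offset, enzyme = e$name,
                                     stringsAsFactors = FALSE))
    }
  }
  cuts <- cuts[order(cuts$pos), , drop = FALSE]
  cuts <- cuts[!duplicated(cuts$pos), , drop = FALSE]   # coincident cuts: keep first
  pos <- c(0, cuts$pos, L)
  lab <- c("chrom_end", cuts$enzyme, "chrom_end")
  keep <- which(diff(pos) > 0)
  data.frame(chrom = chrom,
             start_bp = pos[keep],
             end_bp = pos[keep + 1],
             left_enzyme = lab[keep],
             right_enzyme = lab[keep + 1],
             length_bp = pos[keep + 1] - pos[keep],
             stringsAsFactors = FALSE)
}

#' Double-digest every chromosome of a reference set
#'
#' @param reference a `reference_set`.
#' @param enzymes list of two [restriction_enzyme()] objects.
#' @return data frame of fragments (see [digest_sequence()]).
#' @export
digest_reference <- function(reference,
                             enzymes = list(restriction_enzyme("MspI"),
                                            restriction_enzyme("SphI"))) {
  stopifnot(inherits(reference, "reference_set"))
  do.call(rbind, lapply(reference$records$name, function(nm) {
    digest_sequence(reference$sequences[[nm]], enzymes, chrom = nm)
  }))
}

#' Size-select ddRAD loci
#'
#' Keeps fragments whose length lies in the closed window
#' `[min_len, max_len]` (defaults 350-390 bp) and, when
#' `require_mixed_ends`, whose two ends were cut by different enzymes
#' (one MspI + one SphI; chromosome-end fragments are excluded), matching
#' standard two-adapter ddRAD chemistry.
#'
#' @param fragments fragment data frame from [digest_sequence()].
#' @param min_len,max_len inclusive length bounds in bp.
#' @param require_mixed_ends logical.
#' @return the selected subset of `fragments`.
#' @export
select_loci <- function(fragments, min_len = 350, max_len = 390,
                        require_mixed_ends = TRUE) {
  stopifnot(min_len <= max_len)
  keep <- fragments$length_bp >= min_len & fragments$length_bp <= max_len
  if (require_mixed_ends) {
    keep <- keep &
      fragments$left_enzyme != "chrom_end" &
      fragments$right_enzyme != "chrom_end" &
      fragments$left_enzyme != fragments$right_enzyme
  }
  fragments[keep, , drop = FALSE]
}

# copy number of each locus under a karyotype (segment overrides win when the
# locus overlaps the override interval)
locus_copies <- function(loci, karyotype) {
  stopifnot(inherits(karyotype, "karyotype_spec"))
  cp <- unname(karyotype$copies[loci$chrom])
  if (anyNA(cp)) {
    stop("karyotype names chromosomes absent from the locus set: ",
         paste(unique(loci$chrom[is.na(cp)]), collapse = ", "))
  }
  ov <- karyotype$overrides
  if (nrow(ov)) {
    for (i in seq_len(nrow(ov))) {
      hit <- loci$chrom == ov$name[i] &
        loci$start_bp < ov$end_bp[i] & loci$end_bp > ov$start_bp[i]
      cp[hit] <- ov$copies[i]
    }
  }
  cp
}

#' Simulate paired-end ddRAD reads under a karyotype
#'
#' Each read pair picks a locus with probability proportional to its copy
#' number (0/1/2, honouring segment overrides) and a sequencing orientation at
#' random. Mate 1 is the first `read_length` bases from one fragment end,
#' mate 2 the reverse complement of the last `read_length` bases as seen from
#' mate 1's strand; for 350-390 bp loci and 150 bp reads the mates overlap in
#' the fragment middle. Per-base substitution errors are applied at
#' `error_rate`. Reads are emitted post-trimming (no adapters/barcodes) with
#' constant quality strings. The true origin of every pair is recorded.
#'
#' @param reference a `reference_set`.
#' @param loci selected loci ([select_loci()]).
#' @param karyotype a `karyotype_spec` over the same reference.
#' @param total_pairs number of read pairs (>= 0).
#' @param read_length mate length in bp (default 150).
#' @param error_rate per-base substitution error in `[0, 0.25]`.
#' @param seed integer seed.
#' @return data frame with id, mate1, mate2, and truth columns chrom,
#'   frag_start, frag_end, strand; attribute `read_length`.
#' @export
simulate_reads <- function(reference, loci, karyotype, total_pairs,
                           read_length = 150L, error_rate = 0.01, seed = 1L) {
  stopifnot(inherits(reference, "reference_set"),
            total_pairs >= 0, error_rate >= 0, error_rate <= 0.25,
            read_length >= 1)
  w <- locus_copies(loci, karyotype)
  empty <- data.frame(id = character(0), mate1 = character(0),
                      mate2 = character(0), chrom = character(0),
                      frag_start = numeric(0), frag_end = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)
  attr(empty, "read_length") <- as.integer(read_length)
  if (total_pairs == 0) return(empty)
  if (sum(w) == 0) stop("karyotype assigns zero copies to every locus")

  # per-locus mate templates, computed once
  frag_seq <- substring(reference$sequences[loci$chrom],
                        loci$start_bp + 1, loci$end_bp)
  first_rl <- substring(frag_seq, 1, read_length)
  last_rl_rc <- revcomp(substring(frag_seq,
                                  pmax(loci$length_bp - read_length + 1, 1),
                                  loci$length_bp))

  withr::with_seed(seed, {
    idx <- sample.int(nrow(loci), total_pairs, replace = TRUE, prob = w)
    strand <- sample(c("+", "-"), total_pairs, replace = TRUE)
    plus <- strand == "+"
    mate1 <- ifelse(plus, first_rl[idx], last_rl_rc[idx])
    mate2 <- ifelse(plus, last_rl_rc[idx], first_rl[idx])
    if (error_rate > 0) {
      n1 <- length(mate1)
      both <- cpp_add_errors(c(mate1, mate2), error_rate)
      mate1 <- both[seq_len(n1)]
      mate2 <- both[-seq_len(n1)]
    }
    out <- data.frame(id = sprintf("read%07d", seq_len(total_pairs)),
                      mate1 = mate1, mate2 = mate2,
                      chrom = loci$chrom[idx],
                      frag_start = loci$start_bp[idx],
                      frag_end = loci$end_bp[idx],
                      strand = strand, stringsAsFactors = FALSE)
    attr(out, "read_length") <- as.integer(read_length)
    out
  })
}

#' Write simulated read pairs as two FASTQ files
#'
#' @param reads data frame from [simulate_reads()].
#' @param mate1_path,mate2_path output FASTQ paths.
#' @param quality_char constant per-base quality symbol.
#' @return invisibly, the two paths.
#' @export
write_fastq <- function(reads, mate1_path, mate2_path, quality_char = "I") {
  fq <- function(ids, seqs, path) {
    qual <- vapply(nchar(seqs), function(n)
      paste(rep(quality_char, n), collapse = ""), character(1))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  }
  fq(reads$id, reads$mate1, mate1_path)
  fq(reads$id, reads$mate2, mate2_path)
  invisible(c(mate1_path, mate2_path))
}

#' Write selected loci as BED
#'
#' 0-based half-open intervals; the name field is
#' `<left_enzyme>/<right_enzyme>`.
#'
#' @param loci locus data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- data.frame(chrom = loci$chrom,
                    start = format(loci$start_bp, scientific = FALSE, trim = TRUE),
                    end = format(loci$end_bp, scientific = FALSE, trim = TRUE),
                    name = paste0(loci$left_enzyme, "/", loci$right_enzyme))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
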
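# brute-force k-mer scan oracle
kmer_scan_oracle <- function(sequence, k, kmer) {
  n <- nchar(sequence)
  which(vapply(seq_len(n - k + 1L), function(i) {
    substring(sequence, i, i + k - 1L) == kmer
  }, logical(1))) - 1L
}

# wrap plain sequences in a reference_set
as_refset <- function(sequences) {
  records <- data.frame(name = names(sequences), genome_class = "wheat",
                        subgenome = "A", group = seq_along(sequences),
                        length_bp = nchar(sequences), stringsAsFactors = FALSE)
  structure(list(records = records, sequences = sequences,
                 provenance = list()), class = "reference_set")
}

test_that("seed index enumerates every forward-strand k-mer occurrence", {
  ref <- as_refset(c(c1 = "ACGTACGTACGTACG", c2 = "TTTTTTTTTTTTTTTT"))
  idx <- build_index(ref, k = 12)
  # counting identity: total positions = sum(len - k + 1)
  expect_identical(length(idx$gpos), sum(nchar(ref$sequences) - 12L + 1L))

  # lookup positions of a known 12-mer against a brute-force scan
  key <- karyoskim:::cpp_build_index("ACGTACGTACGT", 12L)$kmers[1]
  hit <- idx$gpos[idx$kmers == key]
  expect_identical(as.integer(sort(hit)),
                   kmer_scan_oracle("ACGTACGTACGTACG", 12L, "ACGTACGTACGT"))

  # determinism: rebuilt index carries the identical checksum and table
  idx2 <- build_index(ref, k = 12)
  expect_identical(idx$reference_digest, idx2$reference_digest)
  expect_identical(idx$kmers, idx2$kmers)

  expect_error(build_index(ref, k = 5), "at least 11")
  expect_error(build_index(ref, k = 16), "shortest chromosome")
})

test_that("exact-copy, duplicated and alien reads get unique/multi/unplaced status", {
  a <- make_ancestor(30000, 0.5, 71)
  ref <- as_refset(c(chrA = a, chrB = derive_homoeolog(a, 0.05, 72)))
  idx <- build_index(ref, k = 21)

  # read copied verbatim from a diverged, locus-unique region
  read <- substring(a, 5001, 5150)
  pl <- place_read(read, idx, ref)
  expect_identical(pl$status, "unique")
  expect_identical(pl$chrom, "chrA")
  expect_identical(pl$start_bp, 5000L)
  expect_identical(pl$strand, "+")
  expect_identical(pl$mismatches, 0L)

  # reverse-complemented copy places at the same location on the minus strand
  pl_rc <- place_read(revcomp(read), idx, ref)
  expect_identical(pl_rc$status, "unique")
  expect_identical(pl_rc$start_bp, 5000L)
  expect_identical(pl_rc$strand, "-")

  # identical homoeologs (divergence 0) -> multi
  ref0 <- as_refset(c(chrA = a, chrB = a))
  idx0 <- build_index(ref0, k = 21)
  pl0 <- place_read(read, idx0, ref0)
  expect_identical(pl0$status, "multi")

  # read sharing no k-mer with the reference -> unplaced
  alien_read <- strrep("ACGGT", 30)
  pl_na <- place_read(alien_read, idx, ref)
  expect_identical(pl_na$status, "unplaced")
  expect_true(is.na(pl_na$chrom))
})

test_that("placement agrees with the exhaustive Hamming-scan oracle", {
  # two homoeologous chromosomes, 40 kb each, plus simulated reads with errors
  ref <- small_reference(seed = 55, chrom_length = 40000)
  idx <- build_index(ref)
  loci <- select_loci(digest_reference(ref))
  kar <- parse_karyotype("euploid", genome_map(ref))
  reads <- simulate_reads(ref, loci, kar, 40, error_rate = 0.02, seed = 56)
  # add a handful of unplaceable and duplicated-region reads
  probes <- c(reads$mate1,
              strrep("ACGGT", 30),
              substring(ref$sequences[["1A"]], 101, 250))
  got <- place_reads(probes, idx, ref, max_mismatch = 4)
  for (i in seq_along(probes)) {
    want <- oracle_place(probes[i], ref, max_mismatch = 4)
    expect_identical(got$status[i], want$status)
    if (want$status == "unique") {
      expect_identical(got$chrom[i], want$chrom)
      expect_identical(got$start_bp[i], as.integer(want$start_bp))
      expect_identical(got$mismatches[i], as.integer(want$mismatches))
    }
  }
})

test_that("unique placements of error-free reads land exactly on their origin", {
  ref <- small_reference(seed = 21)
  idx <- build_index(ref)
  loci <- select_loci(digest_reference(ref))
  kar <- parse_karyotype("euploid", genome_map(ref))
  reads <- simulate_reads(ref, loci, kar, 3000, error_rate = 0, seed = 22)
  pl <- place_reads(setNames(reads$mate1, reads$id), idx, ref,
                    max_mismatch = 0)
  uq <- pl$status == "unique"
  expect_gt(mean(uq), 0.8)
  truth_start <- ifelse(reads$strand == "+", reads$frag_start,
                        reads$frag_end - 150)
  expect_identical(pl$chrom[uq], reads$chrom[uq])
  expect_identical(pl$start_bp[uq], as.integer(truth_start[uq]))
  expect_identical(pl$strand[uq], reads$strand[uq])
  expect_true(all(pl$mismatches[uq] == 0L))
})

test_that("multi-map frequency decreases as alien divergence increases", {
  rate <- vapply(c(0.005, 0.02, 0.08), function(d) {
    ref <- build_reference(genome_config(groups = 1L,
                                         wheat_subgenomes = "A",
                                         alien_subgenomes = "S",
                                         chrom_length_bp = 50000,
                                         wheat_divergence = 0,
                                         alien_divergence = d), seed = 61)
    idx <- build_index(ref)
    gm <- genome_map(ref)
    loci <- select_loci(digest_reference(ref))
    kar <- parse_karyotype("SUB:1S(1A)", gm)
    # reads from the alien chromosome against its wheat homoeolog
    reads <- simulate_reads(ref, loci, kar, 2000, error_rate = 0, seed = 62)
    pl <- place_reads(reads$mate1, idx, ref)
    mean(pl$status == "multi")
  }, numeric(1))
  expect_true(all(diff(rate) < 0))
  expect_gt(rate[1], 0.2)
  expect_lt(rate[3], 0.05)
})

test_that("SAM import keeps primary mapped records above the MAPQ cut", {
  sam <- write_sam_fixture(tempfile(fileext = ".sam"))
  gm <- sam_fixture_genome_map()
  got <- import_alignments(sam, gm)
  # oracle (manual count): 1 unmapped, 1 secondary, 1 MAPQ 0, 2 kept
  expect_identical(nrow(got$placements), 2L)
  expect_setequal(got$placements$read_id, c("r_good1", "r_good2"))
  expect_identical(sort(got$placements$start_bp), c(300L, 400L))  # 0-based
  expect_setequal(got$placements$status, "unique")
  rej <- setNames(got$rejections$count, got$rejections$reason)
  expect_identical(rej[["unmapped"]], 1L)
  expect_identical(rej[["secondary"]], 1L)
  expect_identical(rej[["low_mapq_multi"]], 1L)
  expect_identical(sum(rej), 3L)

  # order independence: shuffled records yield the same placement multiset
  sam_sh <- write_sam_fixture(tempfile(fileext = ".sam"), shuffle_seed = 99)
  got_sh <- import_alignments(sam_sh, gm)
  o1 <- got$placements[order(got$placements$read_id), ]
  o2 <- got_sh$placements[order(got_sh$placements$read_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)

  # header chromosome missing from the genome map is an error naming it
  gm_bad <- gm; gm_bad$name <- "chr99"
  expect_error(import_alignments(sam, gm_bad), "1A")
})

test_that("empty alignment files give empty placements and zero-filled rejections", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:1A\tLN:60000"), sam)
  got <- import_alignments(sam, sam_fixture_genome_map())
  expect_identical(nrow(got$placements), 0L)
  expect_true(all(got$rejections$count == 0L))
})
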
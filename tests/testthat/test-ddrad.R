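# brute-force substring scan, independent of find_sites
scan_oracle <- function(sequence, pattern) {
  n <- nchar(sequence); w <- nchar(pattern)
  if (n < w) return(integer(0))
  starts <- which(vapply(seq_len(n - w + 1L), function(i) {
    substring(sequence, i, i + w - 1L) == pattern
  }, logical(1)))
  starts - 1L
}

# all-pairs locus enumeration oracle: every (MspI cut, SphI cut) pair with no
# intervening cut and a length inside the window, either orientation
locus_oracle <- function(sequence, min_len = 350, max_len = 390) {
  msp <- scan_oracle(sequence, "CCGG") + 1L
  sph <- scan_oracle(sequence, "GCATGC") + 5L
  all_cuts <- sort(c(msp, sph))
  out <- NULL
  for (m in msp) for (s in sph) {
    lo <- min(m, s); hi <- max(m, s)
    len <- hi - lo
    if (len < min_len || len > max_len) next
    if (any(all_cuts > lo & all_cuts < hi)) next
    out <- rbind(out, data.frame(start_bp = lo, end_bp = hi))
  }
  out[order(out$start_bp), , drop = FALSE]
}

MSP <- restriction_enzyme("MspI")
SPH <- restriction_enzyme("SphI")

test_that("recognition-site scan equals a brute-force substring scan", {
  expect_identical(find_sites("AAAA", MSP), integer(0))
  expect_identical(find_sites("", MSP), integer(0))
  expect_identical(find_sites("AAACCGGAAAGCATGCAAA", MSP), 3L)
  expect_identical(find_sites("AAACCGGAAAGCATGCAAA", SPH), 10L)
  expect_identical(find_sites("CCGGCCGG", MSP), c(0L, 4L))

  # both recognition sites are their own reverse complement
  expect_identical(revcomp(MSP$recognition), MSP$recognition)
  expect_identical(revcomp(SPH$recognition), SPH$recognition)

  s <- make_ancestor(20000, 0.5, 91)
  for (e in list(MSP, SPH)) {
    expect_identical(find_sites(s, e), scan_oracle(s, e$recognition))
  }
})

test_that("double digest fragments follow hand cut arithmetic and tile the chromosome", {
  # no sites: one fragment spanning the whole chromosome
  un <- digest_sequence("AAATTTAAA", chrom = "c")
  expect_identical(nrow(un), 1L)
  expect_identical(un$start_bp, 0)
  expect_identical(un$end_bp, 9)
  expect_identical(un$left_enzyme, "chrom_end")
  expect_identical(un$right_enzyme, "chrom_end")

  # manual cut arithmetic: MspI cut 3+1=4, SphI cut 10+5=15
  fr <- digest_sequence("AAACCGGAAAGCATGCAAA", chrom = "c")
  expect_identical(fr$start_bp, c(0, 4, 15))
  expect_identical(fr$end_bp, c(4, 15, 19))
  mid <- fr[2, ]
  expect_identical(mid$left_enzyme, "MspI")
  expect_identical(mid$right_enzyme, "SphI")

  # tiling property on random sequence
  s <- make_ancestor(50000, 0.5, 17)
  fr <- digest_sequence(s, chrom = "c")
  expect_identical(fr$start_bp[1], 0)
  expect_identical(fr$end_bp[nrow(fr)], 50000)
  expect_true(all(fr$start_bp[-1] == fr$end_bp[-nrow(fr)]))
  expect_true(all(fr$length_bp > 0))
  expect_error(digest_sequence(s, list(MSP, MSP)), "distinct")
})

test_that("size selection keeps the closed 350-390 window with mixed ends", {
  fr <- data.frame(chrom = "c", start_bp = c(0, 0, 0, 0, 0),
                   end_bp = c(370, 349, 350, 390, 391),
                   left_enzyme = c("MspI", "MspI", "MspI", "SphI", "MspI"),
                   right_enzyme = c("SphI", "SphI", "SphI", "MspI", "SphI"),
                   length_bp = c(370, 349, 350, 390, 391))
  kept <- select_loci(fr)
  expect_identical(kept$length_bp, c(370, 350, 390))

  # mixed-end chemistry: MspI/MspI, SphI/SphI and terminal fragments drop
  fr2 <- data.frame(chrom = "c", start_bp = 0, end_bp = 360,
                    left_enzyme = c("MspI", "SphI", "chrom_end"),
                    right_enzyme = c("MspI", "SphI", "SphI"),
                    length_bp = 360)
  expect_identical(nrow(select_loci(fr2)), 0L)
  expect_identical(nrow(select_loci(fr2, require_mixed_ends = FALSE)), 3L)
})

test_that("selected loci equal the exhaustive site-pair enumeration oracle", {
  s <- withr::with_seed(101, karyoskim:::plant_ddrad_loci(
    make_ancestor(200000, 0.46, 101), loci_per_mb = 2200))
  loci <- select_loci(digest_sequence(s, chrom = "c"))
  oracle <- locus_oracle(s)
  expect_identical(nrow(loci), nrow(oracle))
  expect_identical(loci$start_bp, as.numeric(oracle$start_bp))
  expect_identical(loci$end_bp, as.numeric(oracle$end_bp))
  expect_gt(nrow(loci), 100)

  # locus symmetry: reversing the enzyme order leaves the set unchanged
  swapped <- select_loci(digest_sequence(s, list(SPH, MSP), chrom = "c"))
  expect_identical(loci$start_bp, swapped$start_bp)
  expect_identical(loci$end_bp, swapped$end_bp)
})

test_that("read simulation honours copy weights, geometry and provenance", {
  ref <- small_reference(seed = 31)
  gm <- genome_map(ref)
  loci <- select_loci(digest_reference(ref))
  expect_gt(nrow(loci), 50)

  # absent chromosome contributes zero pairs
  kar <- parse_karyotype("NULLI:2A", gm)
  reads <- simulate_reads(ref, loci, kar, 2000, seed = 4)
  expect_identical(nrow(reads), 2000L)
  expect_false(any(reads$chrom == "2A"))

  # monosomic share matches the binomial expectation from locus weights
  kar_m <- parse_karyotype("MONO:2A", gm)
  w <- ifelse(loci$chrom == "2A", 1, ifelse(grepl("S$", loci$chrom), 0, 2))
  p <- sum(w[loci$chrom == "2A"]) / sum(w)
  n <- 40000
  reads_m <- simulate_reads(ref, loci, kar_m, n, seed = 5)
  obs <- sum(reads_m$chrom == "2A")
  bounds <- qbinom(c(0.0005, 0.9995), n, p)
  expect_gte(obs, bounds[1])
  expect_lte(obs, bounds[2])

  # geometry: 350-390 bp loci vs 150 bp mates -> both mates full length,
  # overlapping in the middle; with zero errors each mate is an exact
  # (reverse-complemented) substring of its truth fragment
  reads0 <- simulate_reads(ref, loci, kar, 500, error_rate = 0, seed = 6)
  expect_true(all(nchar(reads0$mate1) == 150L))
  expect_true(all(nchar(reads0$mate2) == 150L))
  frag <- unname(substring(ref$sequences[reads0$chrom], reads0$frag_start + 1,
                           reads0$frag_end))
  fwd_first <- substring(frag, 1, 150)
  rc_last <- revcomp(substring(frag, nchar(frag) - 149, nchar(frag)))
  plus <- reads0$strand == "+"
  expect_identical(reads0$mate1[plus], fwd_first[plus])
  expect_identical(reads0$mate1[!plus], rc_last[!plus])
  expect_identical(reads0$mate2[plus], rc_last[plus])
  expect_identical(reads0$mate2[!plus], fwd_first[!plus])

  # seeded determinism and error model sanity
  expect_identical(simulate_reads(ref, loci, kar, 200, seed = 9),
                   simulate_reads(ref, loci, kar, 200, seed = 9))
  reads_err <- simulate_reads(ref, loci, kar, 500, error_rate = 0.02, seed = 10)
  frag_e <- unname(substring(ref$sequences[reads_err$chrom],
                             reads_err$frag_start + 1, reads_err$frag_end))
  template <- ifelse(reads_err$strand == "+",
                     substring(frag_e, 1, 150),
                     revcomp(substring(frag_e, nchar(frag_e) - 149,
                                       nchar(frag_e))))
  frac <- mean(charToRaw(paste(reads_err$mate1, collapse = "")) !=
                 charToRaw(paste(template, collapse = "")))
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.04)

  expect_identical(nrow(simulate_reads(ref, loci, kar, 0, seed = 2)), 0L)
})

test_that("segment overrides reweight loci inside the interval", {
  ref <- small_reference(seed = 12)
  gm <- genome_map(ref)
  loci <- select_loci(digest_reference(ref))
  kar <- parse_karyotype("SEG:1A:0-30000:0", gm)
  reads <- simulate_reads(ref, loci, kar, 5000, seed = 3)
  in_seg <- reads$chrom == "1A" & reads$frag_start < 30000 &
    reads$frag_end > 0
  expect_identical(sum(in_seg), 0L)
  expect_gt(sum(reads$chrom == "1A" & reads$frag_start >= 30000), 0L)
})

test_that("FASTQ and locus BED writers round-trip", {
  ref <- small_reference(seed = 13, chrom_length = 30000)
  loci <- select_loci(digest_reference(ref))
  kar <- parse_karyotype("euploid", genome_map(ref))
  reads <- simulate_reads(ref, loci, kar, 50, seed = 1)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  write_fastq(reads, f1, f2)
  back1 <- Biostrings::readDNAStringSet(f1, format = "fastq")
  expect_identical(as.character(unname(back1)), reads$mate1)
  expect_identical(names(back1), reads$id)

  bed <- tempfile(fileext = ".bed")
  write_loci_bed(loci, bed)
  parsed <- read_bed(bed)
  expect_identical(parsed$start_bp, as.integer(loci$start_bp))
  expect_identical(parsed$end_bp, as.integer(loci$end_bp))
})
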
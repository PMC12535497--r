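# Synthetic allopolyploid genomes: toy wheat-like host subgenomes plus
# divergent alien subgenomes, organised in homoeologous groups. Chromosomes in
# a group are derived from a common ancestor by substitutions only, so
# homoeologous coordinates stay aligned and multi-mapping can be checked
# exactly against ground truth.

#' Configuration for a synthetic allopolyploid reference
#'
#' Describes a toy genome with `groups` homoeologous groups, each holding one
#' chromosome per host ("wheat") subgenome and one per alien subgenome. All
#' chromosomes in a group descend from a shared ancestor by point
#' substitutions at the stated divergence, which is what makes host homoeologs
#' multi-map against each other while sufficiently diverged alien chromosomes
#' attract unique reads.
#'
#' Restriction-locus planting: i.i.d. random sequence produces only ~15
#' MspI/SphI fragments per Mb inside a 350-390 bp window with mixed ends --
#' orders of magnitude sparser (relative to genome size) than a real
#' Triticeae genome yields in practice. To emulate a realistic density of
#' usable ddRAD loci the generator plants `loci_per_mb` dual-site loci
#' (a CCGG site, then a GCATGC site 346-386 bp downstream) into each group
#' ancestor and removes stray recognition sites from the planted fragment
#' interiors. Set `loci_per_mb = 0` for pure i.i.d. sequence.
#'
#' @param groups number of homoeologous groups (default 7, as in Triticeae).
#' @param wheat_subgenomes letters of the host subgenomes (default A, B, D).
#' @param alien_subgenomes letters of the alien subgenomes (default S, J, V,
#'   the *Thinopyrum intermedium* St/Jr/Jvs analogues).
#' @param chrom_length_bp length of every toy chromosome in bp.
#' @param gc_fraction GC content of the ancestral i.i.d. sequence.
#' @param wheat_divergence per-site substitution probability applied to each
#'   host copy relative to the group ancestor.
#' @param alien_divergence per-site substitution probability for alien copies;
#'   should exceed `wheat_divergence`.
#' @param loci_per_mb target density of planted ddRAD loci per Mb of ancestor.
#' @return a list of class `genome_config`.
#' @export
genome_config <- function(groups = 7L,
                          wheat_subgenomes = c("A", "B", "D"),
                          alien_subgenomes = c("S", "J", "V"),
                          chrom_length_bp = 1e6,
                          gc_fraction = 0.46,
                          wheat_divergence = 0.02,
                          alien_divergence = 0.05,
                          loci_per_mb = 2200) {
  subs <- c(wheat_subgenomes, alien_subgenomes)
  if (anyDuplicated(subs)) {
    stop("duplicate subgenome letters: ",
         paste(unique(subs[duplicated(subs)]), collapse = ", "))
  }
  stopifnot(groups >= 1L, chrom_length_bp >= 0,
            gc_fraction >= 0, gc_fraction <= 1,
            wheat_divergence >= 0, wheat_divergence <= 1,
            alien_divergence >= 0, alien_divergence <= 1,
            loci_per_mb >= 0)
  structure(list(groups = as.integer(groups),
                 wheat_subgenomes = wheat_subgenomes,
                 alien_subgenomes = alien_subgenomes,
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 gc_fraction = gc_fraction,
                 wheat_divergence = wheat_divergence,
                 alien_divergence = alien_divergence,
                 loci_per_mb = loci_per_mb),
            class = "genome_config")
}

#' Draw an ancestral chromosome sequence
#'
#' Uniform i.i.d. sequence: each site is drawn independently with
#' `P(G) = P(C) = gc_fraction/2` and `P(A) = P(T) = (1 - gc_fraction)/2`.
#' The same `(length_bp, gc_fraction, seed)` triple always reproduces the
#' identical sequence.
#'
#' @param length_bp sequence length (>= 0).
#' @param gc_fraction GC content in `[0, 1]`.
#' @param seed integer seed.
#' @return a DNA string.
#' @export
make_ancestor <- function(length_bp, gc_fraction = 0.5, seed = 1L) {
  if (length_bp < 0) stop("length_bp must be non-negative")
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  withr::with_seed(seed, random_dna(as.integer(length_bp), gc_fraction))
}

#' Derive a homoeologous copy from an ancestor
#'
#' Substitution-only divergence: every site is independently replaced by one
#' of the three other bases with probability `divergence`. No indels, so the
#' output has exactly the ancestor's length and homoeologous coordinates stay
#' comparable across a group.
#'
#' @param ancestor DNA string.
#' @param divergence per-site substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a DNA string of the same length as `ancestor`.
#' @export
derive_homoeolog <- function(ancestor, divergence, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 1)
  withr::with_seed(seed, mutate_dna(ancestor, divergence))
}

# Plant dual-enzyme ddRAD loci into an ancestor (draws from the current RNG).
# Each locus is a CCGG site followed, 346-386 bp downstream, by a GCATGC site,
# so the MspI/SphI cut positions delimit a mixed-end fragment of 350-390 bp.
# Stray recognition sites inside planted fragments are disrupted so the
# fragment is not split by background cuts. Returns the modified sequence.
plant_ddrad_loci <- function(sequence, loci_per_mb,
                             spacing_range = c(346L, 386L), min_gap = 20L) {
  L <- nchar(sequence)
  if (loci_per_mb <= 0 || L < 500L) return(sequence)
  r <- charToRaw(sequence)
  site_span <- mean(spacing_range) + 6      # MspI start .. SphI end
  period <- 1e6 / loci_per_mb
  gap_mean <- max(period - site_span - min_gap, 1)

  msp <- charToRaw("CCGG")
  sph <- charToRaw("GCATGC")
  msp_starts <- integer(0)
  sph_starts <- integer(0)
  p <- 1L + min_gap + as.integer(rexp(1L, 1 / gap_mean))   # 1-based MspI start
  while (p + max(spacing_range) + 6L <= L) {
    d <- sample(spacing_range[1]:spacing_range[2], 1L)
    r[p:(p + 3L)] <- msp
    r[(p + d):(p + d + 5L)] <- sph
    msp_starts <- c(msp_starts, p)
    sph_starts <- c(sph_starts, p + d)
    p <- p + d + 6L + min_gap + as.integer(rexp(1L, 1 / gap_mean))
  }

  # sanitize: disrupt recognition sites that would cut inside a planted
  # fragment (cut strictly between the two planted cut positions)
  frag_lo <- msp_starts + 1L   # 1-based first base after MspI cut
  frag_hi <- sph_starts + 4L   # 1-based last base before SphI cut
  planted <- c(msp_starts, sph_starts)
  planted_span_lo <- c(msp_starts, sph_starts)
  planted_span_hi <- c(msp_starts + 3L, sph_starts + 5L)
  for (iter in 1:6) {
    seqc <- rawToChar(r)
    dirty <- FALSE
    for (pat in list(c("CCGG", 1L), c("GCATGC", 5L))) {
      starts <- scan_pattern(seqc, pat[[1]]) + 1L          # 1-based
      cuts <- starts + as.integer(pat[[2]])                # 1-based base after cut
      idx <- findInterval(cuts, frag_lo)
      inside <- idx >= 1L & cuts <= frag_hi[pmax(idx, 1L)] & cuts > frag_lo[pmax(idx, 1L)]
      bad <- starts[inside & !(starts %in% planted)]
      for (s in bad) {
        span <- s:(s + nchar(pat[[1]]) - 1L)
        # flip the first base of the occurrence not owned by a planted site
        free <- span[!vapply(span, function(x)
          any(x >= planted_span_lo & x <= planted_span_hi), logical(1))]
        if (!length(free)) next
        x <- free[1]
        r[x] <- if (r[x] == charToRaw("A")) charToRaw("T") else charToRaw("A")
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  rawToChar(r)
}

#' Build a concatenated host+alien reference set
#'
#' For every homoeologous group one ancestor is drawn (with planted ddRAD
#' loci, see [genome_config()]), then each host subgenome copy is derived from
#' it at `wheat_divergence` and each alien copy at `alien_divergence`.
#' Chromosomes are named `<group><subgenome>` ("3D", "3S", ...). The default
#' configuration yields 21 host plus 21 alien chromosomes, mirroring a
#' concatenated bread-wheat + *Thinopyrum* reference.
#'
#' @param config a [genome_config()].
#' @param seed integer seed; identical config+seed reproduce identical output.
#' @return an object of class `reference_set`: list with `records` (data frame
#'   of name, genome_class, subgenome, group, length_bp), `sequences` (named
#'   character vector), and `provenance`.
#' @export
build_reference <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  subs <- data.frame(
    subgenome = c(config$wheat_subgenomes, config$alien_subgenomes),
    genome_class = rep(c("wheat", "alien"),
                       c(length(config$wheat_subgenomes),
                         length(config$alien_subgenomes))),
    stringsAsFactors = FALSE)
  records <- do.call(rbind, lapply(seq_len(config$groups), function(g) {
    data.frame(name = paste0(g, subs$subgenome),
               genome_class = subs$genome_class,
               subgenome = subs$subgenome,
               group = g,
               length_bp = config$chrom_length_bp,
               stringsAsFactors = FALSE)
  }))
  sequences <- character(nrow(records))
  names(sequences) <- records$name
  for (g in seq_len(config$groups)) {
    anc <- make_ancestor(config$chrom_length_bp, config$gc_fraction,
                         seed_child(seed, paste0("ancestor", g)))
    anc <- withr::with_seed(seed_child(seed, paste0("loci", g)),
                            plant_ddrad_loci(anc, config$loci_per_mb))
    for (i in which(records$group == g)) {
      div <- if (records$genome_class[i] == "wheat") {
        config$wheat_divergence
      } else {
        config$alien_divergence
      }
      sequences[records$name[i]] <-
        derive_homoeolog(anc, div, seed_child(seed, paste0("derive", records$name[i])))
    }
  }
  records$length_bp <- nchar(sequences[records$name])
  structure(list(records = records, sequences = sequences,
                 provenance = list(config = config, seed = seed)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d chromosomes (%d wheat, %d alien), %.3g Mb total\n",
              nrow(x$records), sum(x$records$genome_class == "wheat"),
              sum(x$records$genome_class == "alien"),
              sum(x$records$length_bp) / 1e6))
  invisible(x)
}

#' Genome map of a reference set
#'
#' The per-chromosome annotation table used throughout the pipeline:
#' name, genome_class (wheat/alien), subgenome letter, homoeologous group and
#' length. For real references the same table is supplied as a TSV.
#'
#' @param reference a `reference_set`.
#' @return data frame.
#' @export
genome_map <- function(reference) {
  stopifnot(inherits(reference, "reference_set"))
  reference$records
}

#' Write a reference set to FASTA plus genome-map TSV
#'
#' @param reference a `reference_set`.
#' @param fasta_path output FASTA path.
#' @param map_path output TSV path (columns name, genome_class, subgenome,
#'   group, length_bp).
#' @return invisibly, the two paths.
#' @export
write_reference <- function(reference, fasta_path, map_path) {
  stopifnot(inherits(reference, "reference_set"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference$sequences), fasta_path)
  write.table(reference$records, map_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, map = map_path))
}

#' Read a genome-map TSV
#'
#' @param path TSV with columns name, genome_class, subgenome, group, length_bp.
#' @return data frame.
#' @export
read_genome_map <- function(path) {
  gm <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "genome_class", "subgenome", "group", "length_bp")
  missing <- setdiff(need, names(gm))
  if (length(missing)) {
    stop("genome map is missing columns: ", paste(missing, collapse = ", "))
  }
  gm
}

#' Load a reference set from FASTA plus genome-map TSV
#'
#' @param fasta_path FASTA of all chromosomes (host and alien concatenated).
#' @param map_path genome-map TSV, see [read_genome_map()].
#' @return a `reference_set`.
#' @export
load_reference <- function(fasta_path, map_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gm <- read_genome_map(map_path)
  unmatched <- setdiff(gm$name, names(seqs))
  if (length(unmatched)) {
    stop("genome-map chromosomes absent from FASTA: ",
         paste(unmatched, collapse = ", "))
  }
  sequences <- setNames(as.character(seqs[gm$name]), gm$name)
  gm$length_bp <- nchar(sequences)
  structure(list(records = gm, sequences = sequences,
                 provenance = list(fasta = fasta_path, map = map_path)),
            class = "reference_set")
}
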
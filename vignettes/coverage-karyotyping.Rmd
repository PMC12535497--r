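---
title: "Read-coverage karyotyping of allopolyploid introgression lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-coverage karyotyping of allopolyploid introgression lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wheat pre-breeding programmes introgress chromatin from wild relatives such
as *Thinopyrum* into the hexaploid wheat background (subgenomes A, B, D;
seven homoeologous groups). Validating what a derived line actually carries —
a whole-chromosome disomic substitution, a monosomic, a segmental deletion or
introgression — traditionally requires cytogenetics (GISH/FISH). Low-pass
genotyping-by-sequencing of a ddRAD library offers a cheap molecular
complement: align a few million reads to a *concatenated* host+alien
reference, discard multi-mapped reads, and read the karyotype off binned
coverage. A chromosome present in two copies attracts its expected share of
reads; a missing chromosome shows near-zero density; an alien chromosome
present in the line shows coverage on its in-silico reference where a pure
wheat line shows almost none.

`karyoskim` implements this analysis as a reusable, tested pipeline, and
pairs it with a synthetic-data module so every stage — digestion, size
selection, read simulation, placement, normalization, segmentation, dosage
calling — is verifiable end to end without any external downloads.

## The model

Let $r_c$ be the number of uniquely placed reads on chromosome $c$ and
$L_c$ its length. The density $d_c = r_c / (L_c/10^6)$ (reads per Mb) is the
chromosome-level statistic; relative depletion of a target chromosome
against a reference density $d_\mathrm{ref}$ is
$100\,(1 - d_c/d_\mathrm{ref})$ percent.

For tracks, reads are counted into bins of fixed width (by start position),
converted to per-Mb density using each bin's actual width (the terminal bin
of a chromosome may be short), and divided by a baseline:

* **baseline** = median per-bin density over all *wheat* bins
  (`wheat_median` policy). The median is used rather than the mean because
  the analysis targets lines in which one or two chromosomes are missing or
  aneuploid — exactly the situation in which a mean would be biased by the
  aberration being measured.

Normalized coverage $x$ is interpreted through fixed bands: $x < 0.2$
absent (homozygous loss), $x \in [0.3, 0.7]$ single copy (hemizygous,
anchored at ~0.5), $x \ge 0.8$ present (disomic), and alien chromatin is
accepted when $x > 0.2$ *strictly*. The two gaps (0.2–0.3, 0.7–0.8) are
deliberate: a chromosome falling there is reported as `indeterminate`
rather than silently forced into a band. Alien presence additionally
requires at least `min_run` (default 3) consecutive bins above the
threshold — a coverage-continuity guard, since scattered single-bin spikes
are the signature of residual homoeologous mismapping, while genuine alien
chromatin is contiguous.

Group-level evidence comes from enrichment: for each alien subgenome and
homoeologous group, the fold of that chromosome's density over the mean of
the same subgenome's other groups. The maximal fold above a floor of 2
nominates the introgressed group. The floor sits below the weakest
chromosome-scale signal one would act on (about fourfold) with margin; it is
configurable. On clean simulations the non-introgressed alien groups often
receive exactly zero unique reads; the fold is then undefined (flagged, not
fabricated) and the caller falls back to matching presence calls by group,
which is sufficient for labelling.

The final estimate applies a decision table: exactly one wheat chromosome
absent plus an alien chromosome present in the same (or nominated) group
yields `disomic substitution <alien>(<wheat>)`; a single-copy wheat
chromosome with no alien yields `monosomic <chrom>`; an absent wheat
chromosome with no alien yields `nullisomic <chrom>`; segment-level losses
are reported as interval notes. Conflicts and ambiguities are always
reported in notes, never raised as errors.

## The synthetic-data generator

The generator emulates the statistical structure the coverage analysis
relies on, not wheat biology in detail:

* **Homoeologous similarity.** Per group, one ancestor sequence is drawn
  i.i.d. (default GC 0.46) and each subgenome copy is derived by point
  substitutions only — no indels — at 2% for wheat copies and 5% for alien
  copies by default. Substitution-only divergence keeps coordinates aligned
  across a group, which is what makes the exhaustive-scan placement oracle
  exact and lets tests assert that identical homoeologous regions multi-map.
  The true divergences among the S/J/V subgenomes of *Thinopyrum
  intermedium* are not well constrained; the defaults are exposed in
  `genome_config()` and chosen so that wheat homoeologs multi-map at a
  realistic low rate while alien chromosomes attract overwhelmingly unique
  reads.
* **ddRAD locus density.** An i.i.d. sequence yields only ~15 mixed-end
  MspI/SphI fragments per Mb in the 350–390 bp window — the rare cutter
  (GCATGC, ~1/4 kb) and the narrow window make such fragments intrinsically
  scarce in memoryless sequence, far too sparse for stable binned coverage
  at toy scale. Real genomes are much richer in usable ddRAD loci relative
  to their size. The generator therefore *plants* dual-site loci (a CCGG
  site followed 346–386 bp downstream by a GCATGC site) into each ancestor
  at a configurable rate (default 2,200/Mb) and removes stray recognition
  sites from planted fragment interiors. Divergence then erodes planted
  sites differentially per homoeolog (allele dropout), which is realistic.
  `make_ancestor()` itself stays purely i.i.d.; set `loci_per_mb = 0` for
  unplanted sequence.
* **Library protocol.** Double digestion uses MspI (C^CGG) and SphI
  (GCATG^C); size selection keeps the closed window 350–390 bp and, by
  default, only fragments with one MspI and one SphI end (two-adapter
  chemistry; the flag is exposed). Reads are 2×150 bp; mates are the two
  fragment ends (reverse-complemented as appropriate) and overlap in the
  middle for loci shorter than 300 bp — which the whole selection window is.
  Reads are emitted as if post-demultiplexing and post-trimming: no
  adapters or barcodes, constant quality strings, substitution errors only
  (default 1%). Quality plays no role in the coverage analysis, so
  modelling it would add nothing the tests could check.
* **Karyotypes.** Loci are sampled with probability proportional to copy
  number (0/1/2) with 0-based half-open segment overrides (a locus
  overlapping an override interval takes the override's copy number).
  The mini-grammar (`euploid`, `SUB:3S(3D)`, `MONO:3D`, `NULLI:3D`,
  `SEG:2D:574000000-621000000:0`) covers euploids, substitutions,
  monosomics, nullisomics and interstitial events such as a 2DL-type
  introgression gap.

What the generator does **not** emulate: repeats and transposons, GC
heterogeneity, indel divergence, PCR duplicates, insert-size noise beyond
the selection window, or quality-correlated errors. Passing tests therefore
demonstrate the *inference machinery* is correct under the stated model;
they do not certify performance on real libraries, where mappability and
repeat structure add noise the multi-map filter and continuity guard are
designed to absorb but which only real alignments can quantify.

## Read placement

Simulation mode uses a built-in seed-and-verify matcher: every
forward-strand 21-mer of the reference is indexed in a sorted table;
candidates are gathered from non-overlapping seeds of the read and of its
reverse complement and verified by full-length Hamming distance with a cap
of 4 mismatches. With seven disjoint 21-mers per strand on a 150 bp read and
a cap of 4, the pigeonhole principle guarantees every location within the
cap shares an exact seed, so unique/multi/unplaced status is *exact* with
respect to an exhaustive scan (the test suite asserts this against an
independent full-scan oracle). The cap of 4 tolerates the 1–2% simulated
error comfortably (a 150 bp read at 1% carries 1.5 errors on average);
k = 21 keeps candidate sets small at 2–5% homoeologous divergence. A
plus/minus tie at the same position counts as one location. Only mate 1 is
placed: dosage needs counts, not pairing, and this halves compute; the
SAM/BAM path exposes a flag to count both mates.

Real-data mode imports BWA-MEM-style alignments: primary, mapped records
with MAPQ ≥ 1 become unique placements; unmapped, secondary, supplementary
and MAPQ-0 records are counted by rejection reason. BWA-MEM reports
repeat-placed reads with MAPQ 0, so the MAPQ cut is the operational
definition of "multi-mapped" on that path; the two definitions (tied best
Hamming score vs MAPQ < 1) are documented separately and both surface in
the rejection log.

## Numerical and design choices

* **Bin size**: 1 Mb for real chromosome-scale references (the scale at
  which per-Mb densities are conventionally reported); 20 kb for the 1 Mb
  toy chromosomes. At the toy locus density (~1,600 wheat loci/Mb) a 20 kb
  bin holds ~30 loci and ~190 reads at default depth, giving a bin-level
  CV of about 0.2 — tight enough that, on euploid simulations, the wheat-bin
  median is exactly 1 and well over 95% of wheat bins fall inside
  [0.5, 1.5]. Halving the bin to 10 kb roughly doubles the bin-level
  variance (CV ≈ 0.27) and breaks that property; 20 kb still leaves 50 bins
  per chromosome, so a ≥10-bin segmental event occupies a fifth of a
  chromosome, comfortably interior.
* **Segmentation**: median smoothing (window 3 bins) then run-length
  merging of bands, absorbing runs shorter than 3 bins into the dominant
  neighbour. This suppresses isolated mismapping spikes, shifts clean
  change points by at most one bin, and is idempotent on piecewise-constant
  tracks. Statistical change-point models (CBS, HMM) are deliberately out
  of scope; run-length merging is transparent and sufficient for
  chromosome-arm-scale events.
* **Ties and degenerate inputs**: coincident cut positions from the two
  enzymes keep the first enzyme's label and produce no zero-length
  fragment; a chromosome with no cut sites is one terminal fragment; a
  chromosome shorter than one bin is a single short bin; an empty alignment
  file yields an empty placement set and a zero-filled rejection log.
  Normalization fails loudly when no wheat bin has reads.
* **Seeding**: one top-level seed fans out to per-stage seeds via a fixed
  label hash (all below $2^{31}$), so stages are independently rerunnable
  and every output file is byte-identical across reruns of the same
  config+seed.
* **Problem sizes**: the package's own verification runs use the default
  toy scale — 42 chromosomes of 1 Mb, 200,000 read pairs, ten replicate
  library seeds over a fixed reference — which recovers a 3S(3D)
  substitution with all 42 dosage states correct in ≥9/10 replicates.
  Oracle-equivalence checks run on 30–200 kb sequences where exhaustive
  enumeration is feasible.

## Known limitations and open points

* The expected normalized level of a disomic alien chromosome is not 1
  under wheat-median normalization: higher alien divergence erodes more
  ddRAD loci, so simulated alien chromosomes sit around 0.5–0.8. Published
  real-data analyses of this design report alien values up to ~1.5, which
  a genome-wide-baseline normalization does not explain either; the caller
  therefore requires only the conservative >0.2 continuity-backed
  threshold and reports the observed mean rather than asserting a level.
* Coverage cannot distinguish which alien subgenome (St vs J-type) donated
  a chromosome when subgenomes are closely related; the label reports the
  best-supported chromosome and lists competing present chromosomes in the
  notes. Resolving identity is cytogenetics' job.
* No GC-bias correction, mappability masking or variant calling; zero
  coverage bins are retained. Telosome/translocation breakpoint
  fine-mapping beyond bin resolution is out of scope.
* Real-data benchmarking against deposited sequencing runs requires the
  full wheat and *Thinopyrum* references and SRA downloads; the real-data
  code path is exercised in tests on crafted SAM fixtures instead.
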
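# Dosage calling: normalized-coverage thresholds, per-chromosome dosage
# states, alien-presence calls, homoeologous-group enrichment, and assembly
# of a named karyotype estimate.

#' Dosage-calling thresholds
#'
#' Band anchors follow the coverage interpretation of low-pass skimming data:
#' normalized values near 0 mean homozygous absence, values around 0.5 a
#' single (hemizygous) copy, values near 1 a disomic chromosome, and alien
#' chromatin is accepted when coverage exceeds 0.2 (strictly). The gaps
#' 0.2-0.3 and 0.7-0.8 are deliberately left indeterminate so ambiguous
#' chromosomes surface instead of being forced into a band.
#'
#' @param absent_max upper bound (exclusive) of the absent band.
#' @param single_low,single_high closed band for single-copy calls.
#' @param present_min lower bound (inclusive) of the present band.
#' @param alien_present_min alien chromatin accepted when mean normalized
#'   coverage is strictly greater than this.
#' @return list of class `dosage_thresholds`.
#' @export
dosage_thresholds <- function(absent_max = 0.2, single_low = 0.3,
                              single_high = 0.7, present_min = 0.8,
                              alien_present_min = 0.2) {
  if (!(absent_max <= single_low && single_low < single_high &&
        single_high <= present_min)) {
    stop("thresholds must satisfy absent_max <= single_low < single_high <= present_min")
  }
  structure(list(absent_max = absent_max, single_low = single_low,
                 single_high = single_high, present_min = present_min,
                 alien_present_min = alien_present_min),
            class = "dosage_thresholds")
}

#' Call the dosage state of a host chromosome
#'
#' @param mean_normalized mean normalized coverage (>= 0); vectorised.
#' @param thresholds a [dosage_thresholds()].
#' @return character: `"absent"`, `"single_copy"`, `"present"` or
#'   `"indeterminate"`.
#' @export
call_wheat_dosage <- function(mean_normalized, thresholds = dosage_thresholds()) {
  if (any(mean_normalized < 0)) stop("mean_normalized must be non-negative")
  classify_band(mean_normalized, thresholds)
}

#' Call alien-chromatin presence
#'
#' Present iff mean normalized coverage is strictly greater than
#' `alien_present_min` (default 0.2); a value of exactly 0.2 is absent.
#'
#' @inheritParams call_wheat_dosage
#' @return character: `"present"` or `"absent"`.
#' @export
call_alien_presence <- function(mean_normalized, thresholds = dosage_thresholds()) {
  if (any(mean_normalized < 0)) stop("mean_normalized must be non-negative")
  ifelse(mean_normalized > thresholds$alien_present_min, "present", "absent")
}

#' Homoeologous-group enrichment of alien read density
#'
#' For each (alien subgenome, group) pair: fold = density divided by the mean
#' density of that subgenome's other groups. The globally maximal finite fold
#' nominates the introgressed homoeologous group when it exceeds
#' `enrichment_floor`. A zero background leaves the fold undefined (NA) and
#' is flagged; a zero density over positive background gives fold 0.
#'
#' @param density_table a [chromosome_density()] table.
#' @param enrichment_floor minimum fold for a nomination (default 2).
#' @return list with `table` (subgenome, group, chrom, density, background,
#'   fold), `nominated_group` (integer or NA) and `notes`.
#' @export
group_enrichment <- function(density_table, enrichment_floor = 2) {
  alien <- density_table[density_table$genome_class == "alien", , drop = FALSE]
  if (!nrow(alien)) stop("density table contains no alien chromosomes")
  notes <- character(0)
  rows <- do.call(rbind, lapply(split(alien, alien$subgenome), function(a) {
    if (nrow(a) < 2) return(NULL)
    background <- vapply(seq_len(nrow(a)), function(i) mean(a$density[-i]),
                         numeric(1))
    data.frame(subgenome = a$subgenome, group = a$group, chrom = a$chrom,
               density = a$density, background = background,
               fold = ifelse(background > 0, a$density / background, NA_real_),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    stop("group enrichment needs densities for at least 2 groups per alien subgenome")
  }
  rownames(rows) <- NULL
  zero_bg <- rows$subgenome[is.na(rows$fold) & rows$density > 0]
  if (length(zero_bg)) {
    notes <- c(notes, paste0("zero background density for subgenome(s): ",
                             paste(unique(zero_bg), collapse = ", "),
                             "; fold undefined"))
  }
  nominated <- NA_integer_
  finite <- which(is.finite(rows$fold))
  if (length(finite)) {
    best <- finite[which.max(rows$fold[finite])]
    if (rows$fold[best] > enrichment_floor) nominated <- rows$group[best]
  }
  list(table = rows, nominated_group = nominated, notes = notes)
}

#' Call per-chromosome dosage states from a normalized track
#'
#' Host chromosomes get absent/single_copy/present/indeterminate states from
#' their chromosome-mean normalized coverage. Alien chromosomes are called
#' present only when the mean exceeds the alien threshold *and* the track
#' holds at least `min_run` consecutive bins above it — the coverage
#' continuity guard against scattered mismapping.
#'
#' @param track normalized `coverage_track`.
#' @param genome_map genome map.
#' @param thresholds a [dosage_thresholds()].
#' @param min_run minimum consecutive-bin run for alien presence.
#' @return data frame: chrom, genome_class, subgenome, group, mean_normalized,
#'   state.
#' @export
call_dosage <- function(track, genome_map, thresholds = dosage_thresholds(),
                        min_run = 3L) {
  stopifnot("normalized" %in% names(track))
  baseline <- attr(track, "baseline")
  per_chrom <- vapply(genome_map$name, function(nm) {
    tr <- track[track$chrom == nm, , drop = FALSE]
    # width-weighted mean = chromosome density / baseline
    sum(tr$raw_count) / (sum(tr$width_bp) / 1e6) / baseline
  }, numeric(1))
  state <- character(nrow(genome_map))
  for (i in seq_len(nrow(genome_map))) {
    nm <- genome_map$name[i]
    if (genome_map$genome_class[i] == "wheat") {
      state[i] <- call_wheat_dosage(per_chrom[[nm]], thresholds)
    } else {
      above <- track$normalized[track$chrom == nm] > thresholds$alien_present_min
      run_ok <- length(above) > 0 &&
        max(c(0, rle(above)$lengths[rle(above)$values])) >= min_run
      state[i] <- if (call_alien_presence(per_chrom[[nm]], thresholds) == "present" &&
                      run_ok) "present" else "absent"
    }
  }
  data.frame(chrom = genome_map$name, genome_class = genome_map$genome_class,
             subgenome = genome_map$subgenome, group = genome_map$group,
             mean_normalized = unname(per_chrom), state = state,
             stringsAsFactors = FALSE)
}

#' Infer a named karyotype estimate
#'
#' Decision rules on the dosage calls:
#' exactly one host chromosome absent and an alien chromosome present in the
#' same (or enrichment-nominated) homoeologous group gives a
#' `"disomic substitution <alien>(<wheat>)"` label; a single-copy host
#' chromosome with no alien gives `"monosomic <chrom>"`; an absent host
#' chromosome with no alien gives `"nullisomic <chrom>"`. Segment-level
#' losses on otherwise-present host chromosomes are reported in the notes.
#' Ambiguities are reported, never raised.
#'
#' @param calls dosage-call data frame from [call_dosage()].
#' @param enrichment optional result of [group_enrichment()].
#' @param segments optional segment calls from [segment_track()].
#' @return object of class `karyotype_estimate`: list with `label`, `calls`,
#'   `alien_group`, `notes`.
#' @export
infer_karyotype <- function(calls, enrichment = NULL, segments = NULL) {
  wheat <- calls[calls$genome_class == "wheat", , drop = FALSE]
  alien <- calls[calls$genome_class == "alien", , drop = FALSE]
  absent <- wheat$chrom[wheat$state == "absent"]
  single <- wheat$chrom[wheat$state == "single_copy"]
  indet <- wheat$chrom[wheat$state == "indeterminate"]
  alien_present <- alien[alien$state == "present", , drop = FALSE]
  notes <- character(0)
  if (length(indet)) {
    notes <- c(notes, paste0("indeterminate dosage: ",
                             paste(indet, collapse = ", ")))
  }
  label <- ""
  alien_group <- if (!is.null(enrichment)) enrichment$nominated_group else NA_integer_

  if (length(absent) == 1L && nrow(alien_present) >= 1L) {
    lost_group <- wheat$group[wheat$chrom == absent]
    cand <- alien_present[alien_present$group %in%
                            c(lost_group, alien_group), , drop = FALSE]
    if (nrow(cand)) {
      pick <- cand[which.max(cand$mean_normalized), , drop = FALSE]
      label <- sprintf("disomic substitution %s(%s)", pick$chrom, absent)
      alien_group <- pick$group
      extra <- setdiff(alien_present$chrom, pick$chrom)
      if (length(extra)) {
        notes <- c(notes, paste0("additional alien chromosomes present: ",
                                 paste(extra, collapse = ", ")))
      }
    } else {
      notes <- c(notes,
                 paste0("host chromosome ", absent, " absent but present alien ",
                        "chromosome(s) belong to other group(s): ",
                        paste(alien_present$chrom, collapse = ", ")))
    }
  } else if (length(absent) == 1L && !nrow(alien_present)) {
    label <- paste("nullisomic", absent)
  } else if (length(absent) == 0L && length(single) == 1L &&
             !nrow(alien_present)) {
    label <- paste("monosomic", single)
  } else if (length(absent) > 1L) {
    notes <- c(notes, paste0("multiple host chromosomes absent: ",
                             paste(absent, collapse = ", ")))
  } else if (length(absent) == 0L && nrow(alien_present)) {
    notes <- c(notes, paste0("alien chromatin present without host loss: ",
                             paste(alien_present$chrom, collapse = ", ")))
  }
  if (length(single) && nzchar(label) && !startsWith(label, "monosomic")) {
    notes <- c(notes, paste0("single-copy host chromosome(s): ",
                             paste(single, collapse = ", ")))
  }
  if (!is.null(segments)) {
    # interval losses also explain chromosomes whose overall mean fell
    # between bands (e.g. a present chromosome carrying a large deletion)
    wheat_scan <- wheat$chrom[wheat$state %in% c("present", "indeterminate")]
    seg_loss <- segments[segments$chrom %in% wheat_scan &
                           segments$band %in% c("absent", "single_copy"), ,
                         drop = FALSE]
    if (nrow(seg_loss)) {
      notes <- c(notes, sprintf(
        "segmental loss %s:%d-%d (%s, %d bins, mean %.2f)",
        seg_loss$chrom, seg_loss$start_bp, seg_loss$end_bp, seg_loss$band,
        seg_loss$n_bins, seg_loss$mean_normalized))
    }
  }
  structure(list(label = label, calls = calls, alien_group = alien_group,
                 notes = notes),
            class = "karyotype_estimate")
}

#' @export
print.karyotype_estimate <- function(x, ...) {
  cat("karyotype estimate:",
      if (nzchar(x$label)) x$label else "euploid (no aberration called)", "\n")
  tab <- table(x$calls$state[x$calls$genome_class == "wheat"])
  cat("  wheat states:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  alien_present <- x$calls$chrom[x$calls$genome_class == "alien" &
                                   x$calls$state == "present"]
  cat("  alien present:",
      if (length(alien_present)) paste(alien_present, collapse = ", ") else "none",
      "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
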
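# Karyotype specifications: per-chromosome copy number (0/1/2) plus optional
# per-segment copy overrides, parsed from a compact comma-separated grammar.

#' Construct a karyotype specification
#'
#' @param copies named integer vector, one entry per chromosome, values in
#'   `{0, 1, 2}`.
#' @param overrides data frame with columns `name`, `start_bp`, `end_bp`,
#'   `copies` (0-based half-open intervals), or `NULL`.
#' @param genome_map genome map used for validation.
#' @return object of class `karyotype_spec`.
#' @export
karyotype_spec <- function(copies, overrides = NULL, genome_map) {
  unknown <- setdiff(names(copies), genome_map$name)
  if (length(unknown)) {
    stop("unknown chromosome name(s): ", paste(unknown, collapse = ", "))
  }
  if (!all(copies %in% 0:2)) stop("chromosome copies must be 0, 1 or 2")
  full <- setNames(integer(nrow(genome_map)), genome_map$name)
  full[names(copies)] <- as.integer(copies)
  if (is.null(overrides)) {
    overrides <- data.frame(name = character(0), start_bp = numeric(0),
                            end_bp = numeric(0), copies = integer(0),
                            stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("name", "start_bp", "end_bp", "copies") %in% names(overrides)))
    bad <- setdiff(overrides$name, genome_map$name)
    if (length(bad)) stop("segment override on unknown chromosome: ",
                          paste(bad, collapse = ", "))
    len <- genome_map$length_bp[match(overrides$name, genome_map$name)]
    if (any(overrides$start_bp < 0 | overrides$end_bp > len |
            overrides$start_bp >= overrides$end_bp)) {
      stop("segment override interval out of chromosome bounds")
    }
    if (!all(overrides$copies %in% 0:2)) stop("segment copies must be 0, 1 or 2")
    for (nm in unique(overrides$name)) {
      o <- overrides[overrides$name == nm, , drop = FALSE]
      o <- o[order(o$start_bp), , drop = FALSE]
      if (nrow(o) > 1 && any(o$start_bp[-1] < o$end_bp[-nrow(o)])) {
        stop("overlapping segment overrides on chromosome ", nm)
      }
    }
  }
  structure(list(copies = full, overrides = overrides),
            class = "karyotype_spec")
}

#' Parse a karyotype mini-grammar
#'
#' Comma-separated clauses, applied left to right on an euploid baseline
#' (all host chromosomes 2 copies, all alien 0):
#' \describe{
#'   \item{`euploid`}{the baseline itself (no-op clause).}
#'   \item{`SUB:<alien>(<wheat>)`}{disomic substitution, e.g. `SUB:3S(3D)`
#'     sets 3D to 0 copies and 3S to 2.}
#'   \item{`MONO:<chrom>`}{one copy of the named chromosome.}
#'   \item{`NULLI:<chrom>`}{zero copies.}
#'   \item{`SEG:<chrom>:<start>-<end>:<copies>`}{segment copy override,
#'     0-based half-open bp interval.}
#' }
#'
#' @param spec_text karyotype string, e.g. `"SUB:3S(3D)"` or
#'   `"MONO:3D,SEG:2D:574000000-621000000:0"`.
#' @param genome_map genome map data frame (see [genome_map()]).
#' @return a `karyotype_spec`.
#' @export
parse_karyotype <- function(spec_text, genome_map) {
  copies <- setNames(ifelse(genome_map$genome_class == "wheat", 2L, 0L),
                     genome_map$name)
  overrides <- NULL
  clauses <- trimws(strsplit(spec_text, ",", fixed = TRUE)[[1]])
  clauses <- clauses[nzchar(clauses)]
  if (!length(clauses)) stop("empty karyotype specification")
  check_chrom <- function(nm, clause) {
    if (!nm %in% genome_map$name) {
      stop(sprintf("unknown chromosome '%s' in clause '%s'", nm, clause))
    }
    nm
  }
  for (cl in clauses) {
    if (identical(toupper(cl), "EUPLOID")) next
    if (grepl("^SUB:", cl)) {
      m <- regmatches(cl, regexec("^SUB:([^()]+)\\(([^()]+)\\)$", cl))[[1]]
      if (length(m) != 3) stop("malformed substitution clause: '", cl, "'")
      alien <- check_chrom(m[2], cl)
      wheat <- check_chrom(m[3], cl)
      copies[wheat] <- 0L
      copies[alien] <- 2L
    } else if (grepl("^MONO:", cl)) {
      copies[check_chrom(sub("^MONO:", "", cl), cl)] <- 1L
    } else if (grepl("^NULLI:", cl)) {
      copies[check_chrom(sub("^NULLI:", "", cl), cl)] <- 0L
    } else if (grepl("^SEG:", cl)) {
      m <- regmatches(cl, regexec("^SEG:([^:]+):([0-9]+)-([0-9]+):([0-9]+)$", cl))[[1]]
      if (length(m) != 5) stop("malformed segment clause: '", cl, "'")
      nm <- check_chrom(m[2], cl)
      start <- as.numeric(m[3]); end <- as.numeric(m[4])
      cp <- as.integer(m[5])
      if (!cp %in% 0:2) stop("segment copies outside {0,1,2} in clause '", cl, "'")
      if (start >= end) stop("malformed interval in clause '", cl, "'")
      overrides <- rbind(overrides,
                         data.frame(name = nm, start_bp = start, end_bp = end,
                                    copies = cp, stringsAsFactors = FALSE))
    } else {
      stop("unrecognised karyotype clause: '", cl, "'")
    }
  }
  karyotype_spec(copies, overrides, genome_map)
}

#' @export
print.karyotype_spec <- function(x, ...) {
  cat("karyotype_spec:", sum(x$copies == 2), "disomic chromosomes;",
      nrow(x$overrides), "segment override(s)\n")
  invisible(x)
}
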
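# Low-level DNA string helpers. Sequences are plain character scalars over
# {A,C,G,T}; raw-vector views are used for fast in-place edits.

.BASES <- c("A", "C", "G", "T")
.BASES_RAW <- charToRaw("ACGT")

# uniform random DNA with a given GC fraction (draws from the current RNG)
random_dna <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# substitute each position independently with probability `rate`, drawing the
# replacement uniformly from the three other bases (draws from current RNG)
mutate_dna <- function(sequence, rate) {
  if (rate == 0 || nchar(sequence) == 0L) return(sequence)
  r <- charToRaw(sequence)
  hit <- which(runif(length(r)) < rate)
  if (length(hit)) {
    cur <- match(r[hit], .BASES_RAW)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    r[hit] <- .BASES_RAW[(cur - 1L + shift) %% 4L + 1L]
  }
  rawToChar(r)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over `{A,C,G,T}`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# all start positions (0-based) of `pattern` in `sequence`, overlaps included
scan_pattern <- function(sequence, pattern) {
  if (nchar(sequence) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(sequence))
  as.integer(BiocGenerics::start(m)) - 1L
}
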
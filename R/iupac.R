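IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Test whether an IUPAC pattern is its own reverse complement
#'
#' Duplex-palindromic patterns (such as the CcrM methylation motif GANTC)
#' describe the same site on both strands, so a duplex site should be
#' counted once, not twice.
#'
#' @param pattern IUPAC nucleotide string.
#' @return Logical scalar.
#' @export
is_iupac_palindrome <- function(pattern) {
  pattern <- toupper(pattern)
  reverse_complement(pattern) == pattern
}

validate_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1]], names(IUPAC_CODES))
  if (length(bad)) stop("invalid IUPAC character(s): ",
                        paste(bad, collapse = ", "))
  pattern
}

#' Match a degenerate IUPAC motif in a genome
#'
#' Finds exact matches of an IUPAC pattern (e.g. `GANTC`), wrapping
#' across the origin for circular genomes. Matches whose window contains
#' `N` in the genome are not reported. When the pattern is duplex
#' palindromic each duplex site is reported once, on the plus strand.
#'
#' @param pattern IUPAC nucleotide string.
#' @param genome A `genome_seq`.
#' @param both_strands Also search the reverse strand (ignored for
#'   duplex-palindromic patterns, which need only one pass); default `TRUE`.
#' @return A `motif_hits` data.frame (as in [scan_genome()]) with
#'   `rel_score` fixed at 1 and `score` `NA`.
#' @export
match_degenerate <- function(pattern, genome, both_strands = TRUE) {
  pattern <- validate_iupac(pattern)
  L <- nchar(pattern)
  n <- genome_length(genome)
  padded <- genome$sequence
  if (genome$circular && L > 1L) {
    padded <- paste0(padded, substr(padded, 1L, L - 1L))
  }
  subject <- Biostrings::DNAString(padded)
  find <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  fixed = FALSE)
    starts <- BiocGenerics::start(m)
    starts <- starts[starts <= n]
    seqs <- as.character(m)[BiocGenerics::start(m) <= n]
    ok <- !grepl("N", seqs, fixed = TRUE)
    starts <- starts[ok]; seqs <- seqs[ok]
    if (!length(starts)) return(empty_hits())
    if (strand == "-") seqs <- vapply(seqs, reverse_complement, "",
                                      USE.NAMES = FALSE)
    data.frame(motif_id = pattern, start = starts,
               end = wrap1(starts - 1L + L - 1L, n), strand = strand,
               score = NA_real_, rel_score = 1, seq = seqs,
               stringsAsFactors = FALSE)
  }
  hits <- find(pattern, "+")
  if (both_strands && !is_iupac_palindrome(pattern)) {
    hits <- rbind(hits, find(reverse_complement(pattern), "-"))
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("motif_hits", "data.frame")
  hits
}
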
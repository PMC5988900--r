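#' Construct a genome sequence object
#'
#' Holds a single (by default circular) chromosome as an uppercase
#' character string over the alphabet A, C, G, T, N. Lowercase input is
#' folded to uppercase and `U` is mapped to `T` with a warning, so RNA-style
#' sequences can be supplied. Any other character is a hard error that
#' names the first offending position.
#'
#' @param sequence Character scalar, the nucleotide sequence.
#' @param name Sequence identifier (defaults to `"chr"`).
#' @param circular Logical; treat the chromosome as circular so that
#'   windows may wrap across the origin. Defaults to `TRUE`, as befits a
#'   bacterial chromosome.
#' @return An object of class `genome_seq` with fields `name`, `sequence`
#'   and `circular`.
#' @export
genome_seq <- function(sequence, name = "chr", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("U", sequence, fixed = TRUE)) {
    warning("sequence contains 'U'; folding to 'T'")
    sequence <- gsub("U", "T", sequence, fixed = TRUE)
  }
  if (nchar(sequence) < 1L) stop("empty sequence")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  }
  structure(list(name = name, sequence = sequence, circular = circular),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %d bp, %s\n", x$name, genome_length(x),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Genome length in nucleotides
#' @param genome A `genome_seq`.
#' @return Integer length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

# wrap 0-based offsets into 1-based positions on a circle of size n
wrap1 <- function(pos0, n) (pos0 %% n) + 1L

# positions covered by a (possibly origin-spanning) 1-based inclusive
# interval; start > end means the interval wraps
interval_positions <- function(start, end, n) {
  len <- ((end - start) %% n) + 1L
  wrap1(start - 1L + seq_len(len) - 1L, n)
}

# split a possibly wrapping 1-based inclusive interval into linear segments
interval_segments <- function(start, end, n) {
  if (start <= end) {
    list(c(start, end))
  } else {
    list(c(start, n), c(1L, end))
  }
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#' @param x Character scalar over A/C/G/T/N (IUPAC codes allowed).
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
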
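DNA_BASES <- c("A", "C", "G", "T")

new_pwm <- function(f, motif_id, pseudocount) {
  stopifnot(is.matrix(f), ncol(f) == 4L, nrow(f) >= 1L)
  colnames(f) <- DNA_BASES
  if (any(f < 0)) stop("PWM frequencies must be nonnegative")
  if (any(abs(rowSums(f) - 1) > 1e-9)) {
    stop("PWM frequencies must sum to 1 at every position")
  }
  # zero frequency scores -Inf: such a window can never pass a threshold
  contrib <- 2 + log2(f)       # per-position score contribution, bits
  structure(list(motif_id = motif_id, L = nrow(f), f = f,
                 contrib = contrib, pseudocount = pseudocount),
            class = "pwm")
}

#' Build a position weight matrix from aligned binding sites
#'
#' Per-position nucleotide frequencies are estimated with a pseudocount:
#' `f(n, x) = (count(n, x) + pseudocount) / (N + 4 * pseudocount)`.
#' With a zero pseudocount, bases unseen at a position get frequency 0
#' and a score contribution of `-Inf`: windows using them can never pass
#' a retention threshold. The positive default avoids this.
#'
#' @param sites Character vector of equal-length sequences over A/C/G/T.
#' @param pseudocount Nonnegative number added to every count; default 0.5.
#' @param motif_id Identifier stored in the PWM and in emitted hits.
#' @return An object of class `pwm` with fields `motif_id`, `L`, `f`
#'   (L x 4 frequency matrix), `contrib` (the `2 + log2 f` score terms)
#'   and `pseudocount`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5, motif_id = "motif") {
  stopifnot(length(sites) >= 1L)
  sites <- toupper(sites)
  lens <- unique(nchar(sites))
  if (length(lens) != 1L) stop("aligned sites must all have the same length")
  if (lens < 1L) stop("sites must be non-empty")
  chars <- do.call(rbind, strsplit(sites, ""))
  if (!all(chars %in% DNA_BASES)) stop("sites must contain only A, C, G, T")
  counts <- vapply(DNA_BASES,
                   function(b) colSums(matrix(chars == b, nrow = length(sites))),
                   numeric(lens))
  counts <- matrix(counts, nrow = lens, ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  f <- (counts + pseudocount) / (length(sites) + 4 * pseudocount)
  new_pwm(f, motif_id, pseudocount)
}

#' Build a PWM from a frequency or count matrix
#'
#' Rows are motif positions, columns A, C, G, T. Rows summing to about 1
#' are treated as frequencies (zero entries floored at `floor` and
#' renormalized); otherwise rows are treated as counts and `pseudocount`
#' is applied as in [build_pwm()].
#'
#' @param m Numeric matrix or data.frame with columns A, C, G, T.
#' @param pseudocount Pseudocount for count input; default 0.5.
#' @param floor Frequency floor for frequency input; default 1e-6.
#' @param motif_id Motif identifier.
#' @return A `pwm`.
#' @export
pwm_from_matrix <- function(m, pseudocount = 0.5, floor = 1e-6,
                            motif_id = "motif") {
  m <- as.matrix(m)
  if (!is.null(colnames(m))) {
    if (!all(DNA_BASES %in% toupper(colnames(m)))) {
      stop("matrix must have columns A, C, G, T")
    }
    colnames(m) <- toupper(colnames(m))
    m <- m[, DNA_BASES, drop = FALSE]
  }
  if (ncol(m) != 4L) stop("matrix must have 4 columns (A, C, G, T)")
  mode(m) <- "numeric"
  if (any(is.na(m))) stop("non-numeric entry in PWM matrix")
  if (any(m < 0)) stop("negative entry in PWM matrix")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop(sprintf("PWM matrix row %d sums to 0", which(rs == 0)[1]))
  }
  if (all(abs(rs - 1) < 1e-3)) {
    f <- pmax(m, floor)
    f <- f / rowSums(f)
  } else {
    n <- rs[1]
    f <- (m + pseudocount) / (rs + 4 * pseudocount)
  }
  new_pwm(f, motif_id, pseudocount)
}

#' Read a PWM from file
#'
#' Accepts either a FASTA of equal-length aligned binding sites or a TSV
#' with header columns A, C, G, T giving a per-position frequency or
#' count matrix.
#'
#' @param path Input path.
#' @param pseudocount Pseudocount, see [build_pwm()].
#' @param motif_id Motif identifier; defaults to the file base name.
#' @return A `pwm`.
#' @export
read_pwm <- function(path, pseudocount = 0.5, motif_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(motif_id)) {
    motif_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty PWM file: ", path)
  if (startsWith(trimws(first), ">")) {
    build_pwm(read_aligned_sites(path), pseudocount = pseudocount,
              motif_id = motif_id)
  } else {
    m <- utils::read.delim(path, stringsAsFactors = FALSE)
    pwm_from_matrix(m, pseudocount = pseudocount, motif_id = motif_id)
  }
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: %d positions, consensus %s, S_max = %.4f bits\n",
              x$motif_id, x$L, pwm_consensus(x), pwm_max_score(x)))
  invisible(x)
}

#' Maximum attainable PWM score
#'
#' The score of the consensus path: `S_max = (1/L) * sum_n max_x(2 + log2
#' f(n, x))`, in bits. Bounded above by 2.
#'
#' @param pwm A `pwm`.
#' @return Numeric scalar.
#' @export
pwm_max_score <- function(pwm) mean(apply(pwm$contrib, 1L, max))

#' Consensus sequence of a PWM
#' @param pwm A `pwm`.
#' @return Character scalar of length `L` (ties broken A < C < G < T).
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$f, 1L, which.max)], collapse = "")
}

#' Reverse complement a PWM
#'
#' Models the same sites read on the opposite strand: positions reversed,
#' A/T and C/G frequencies swapped.
#'
#' @param pwm A `pwm`.
#' @return A `pwm`.
#' @export
pwm_reverse_complement <- function(pwm) {
  f <- pwm$f[rev(seq_len(pwm$L)), rev(DNA_BASES), drop = FALSE]
  colnames(f) <- DNA_BASES
  new_pwm(f, paste0(pwm$motif_id, "_rc"), pwm$pseudocount)
}

#' Score one window with a PWM
#'
#' The information score `S = (1/L) * sum_{n=1..L} (2 + log2 f(n, x_n))`
#' in bits: 2 means a perfect match to a fully specific motif, 0 is the
#' expectation under a uniform model. Windows containing `N` are
#' unscoreable and return `NA`.
#'
#' @param pwm A `pwm`.
#' @param window Character scalar of length `L`.
#' @return Numeric scalar in `(-Inf, 2]`, or `NA` if the window contains N.
#' @export
score_window <- function(pwm, window) {
  window <- toupper(window)
  if (nchar(window) != pwm$L) {
    stop(sprintf("window length %d does not match motif length %d",
                 nchar(window), pwm$L))
  }
  idx <- match(strsplit(window, "")[[1]], DNA_BASES)
  if (anyNA(idx)) {
    if (grepl("N", window, fixed = TRUE)) return(NA_real_)
    stop("window contains a non-DNA character")
  }
  mean(pwm$contrib[cbind(seq_len(pwm$L), idx)])
}

# integer-encode a genome (A=1 C=2 G=3 T=4, N = NA), padded for circular
# scanning; returns list(code, starts)
encode_starts <- function(pwm, genome) {
  n <- genome_length(genome)
  if (n < pwm$L) stop("genome shorter than the motif")
  code <- match(strsplit(genome$sequence, "")[[1]], DNA_BASES)
  if (genome$circular) {
    if (pwm$L > 1L) code <- c(code, code[seq_len(pwm$L - 1L)])
    starts <- seq_len(n)
  } else {
    starts <- seq_len(n - pwm$L + 1L)
  }
  list(code = code, starts = starts)
}

# vectorized window scores for every start position on the encoded strand
strand_scores <- function(contrib, code, starts, L) {
  s <- numeric(length(starts))
  for (npos in seq_len(L)) {
    s <- s + contrib[npos, ][code[starts + npos - 1L]]
  }
  s / L
}

#' Scan a genome with a PWM
#'
#' Every window (both strands by default; wraparound windows included for
#' circular genomes) is scored with [score_window()]'s formula, scores
#' are normalized by the maximum attainable score, and windows at or
#' above the relative retention threshold (default 60%) are emitted.
#' Windows containing `N` are skipped. Minus-strand hits are reported in
#' plus-strand coordinates with strand `-` and the reverse-complemented
#' matched sequence.
#'
#' @param pwm A `pwm`; a degenerate PWM with `S_max <= 0` is rejected
#'   because the relative score is then undefined.
#' @param genome A `genome_seq`.
#' @param rel_threshold Retention threshold on `S / S_max`; default 0.6.
#' @param both_strands Scan the reverse strand too; default `TRUE`.
#' @return A `motif_hits` data.frame sorted by `start` with columns
#'   `motif_id`, `start`, `end` (1-based inclusive, `end < start` for
#'   origin-spanning hits), `strand`, `score` (bits), `rel_score` and
#'   `seq` (the matched sequence, motif-oriented).
#' @export
scan_genome <- function(pwm, genome, rel_threshold = 0.6,
                        both_strands = TRUE) {
  smax <- pwm_max_score(pwm)
  if (smax <= 0) stop("degenerate PWM, relative score undefined")
  es <- encode_starts(pwm, genome)
  n <- genome_length(genome)
  one_strand <- function(contrib, strand) {
    s <- strand_scores(contrib, es$code, es$starts, pwm$L)
    rel <- s / smax
    keep <- which(!is.na(rel) & rel >= rel_threshold - 1e-9)
    if (!length(keep)) return(empty_hits())
    starts <- es$starts[keep]
    ends <- wrap1(starts - 1L + pwm$L - 1L, n)
    seqs <- vapply(starts, function(st) {
      paste(DNA_BASES[es$code[st:(st + pwm$L - 1L)]], collapse = "")
    }, "")
    if (strand == "-") seqs <- vapply(seqs, reverse_complement, "",
                                      USE.NAMES = FALSE)
    data.frame(motif_id = pwm$motif_id, start = starts, end = ends,
               strand = strand, score = s[keep], rel_score = rel[keep],
               seq = seqs, stringsAsFactors = FALSE)
  }
  hits <- one_strand(pwm$contrib, "+")
  if (both_strands) {
    rc <- pwm_reverse_complement(pwm)$contrib
    hits <- rbind(hits, one_strand(rc, "-"))
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

empty_hits <- function() {
  data.frame(motif_id = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(), rel_score = numeric(),
             seq = character(), stringsAsFactors = FALSE)
}
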
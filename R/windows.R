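#' Promoter window around a TSS
#'
#' For a plus-strand gene the scanned regulatory region is
#' `[TSS - upstream, TSS + downstream]`; for a minus-strand gene the
#' layout is mirrored, `[TSS - downstream, TSS + upstream]`. With the
#' defaults (100 upstream, 50 downstream) the window is always 151 nt.
#' On a circular genome coordinates wrap across the origin; `start > end`
#' marks a wrapped window.
#'
#' @param tss 1-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param upstream,downstream Window extent in nt; defaults 100 and 50.
#' @param genome_length Chromosome length, required for wrapping (and for
#'   validating coordinates). `NULL` allows negative-coordinate-free
#'   windows only.
#' @param circular Wrap across the origin; default `TRUE`.
#' @param ncrna_id Optional identifier carried along.
#' @return A one-row data.frame of class `promoter_window` with columns
#'   `ncrna_id`, `tss`, `strand`, `start`, `end`, `width`.
#' @export
promoter_window <- function(tss, strand, upstream = 100, downstream = 50,
                            genome_length = NULL, circular = TRUE,
                            ncrna_id = NA_character_) {
  if (is.na(tss) || tss < 1L) stop("nonpositive TSS")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (strand == "+") {
    lo <- tss - upstream; hi <- tss + downstream
  } else {
    lo <- tss - downstream; hi <- tss + upstream
  }
  width <- upstream + downstream + 1L
  if (!is.null(genome_length)) {
    if (tss > genome_length) stop("TSS beyond genome length")
    if (width > genome_length) stop("window wider than the genome")
    if (circular) {
      lo <- wrap1(lo - 1L, genome_length)
      hi <- wrap1(hi - 1L, genome_length)
    } else {
      lo <- max(lo, 1L)
      hi <- min(hi, genome_length)
      width <- hi - lo + 1L
    }
  } else if (lo < 1L) {
    stop("window extends below position 1; supply genome_length for wrapping")
  }
  out <- data.frame(ncrna_id = ncrna_id, tss = as.integer(tss),
                    strand = strand, start = as.integer(lo),
                    end = as.integer(hi), width = as.integer(width),
                    stringsAsFactors = FALSE)
  class(out) <- c("promoter_window", "data.frame")
  out
}

#' Promoter windows for every catalog TSS
#'
#' @param catalog An `ncrna_catalog`.
#' @inheritParams promoter_window
#' @return A `promoter_window` data.frame, one row per TSS row.
#' @export
promoter_windows <- function(catalog, upstream = 100, downstream = 50,
                             genome_length = NULL, circular = TRUE) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    promoter_window(catalog$tss[i], catalog$strand[i], upstream, downstream,
                    genome_length, circular, ncrna_id = catalog$ccna[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# length of a (possibly wrapped) 1-based inclusive interval
interval_width <- function(start, end, n) {
  if (is.null(n)) return(end - start + 1L)
  ((end - start) %% n) + 1L
}

#' Count motif hits fully contained in a promoter window
#'
#' A binding site is counted only if its full extent lies within the
#' window (wrap-aware); sites straddling a window edge are not counted.
#' Overlapping hits are each counted.
#'
#' @param hits A `motif_hits` data.frame.
#' @param window A one-row `promoter_window`.
#' @param genome_length Chromosome length for wrap arithmetic; `NULL` for
#'   linear coordinates.
#' @return Integer count.
#' @export
count_sites_in_window <- function(hits, window, genome_length = NULL) {
  if (nrow(hits) == 0L) return(0L)
  wlen <- interval_width(window$start, window$end, genome_length)
  if (is.null(genome_length)) {
    off <- hits$start - window$start
  } else {
    off <- (hits$start - window$start) %% genome_length
  }
  hlen <- mapply(interval_width, hits$start, hits$end,
                 MoreArgs = list(n = genome_length))
  sum(off >= 0L & off + hlen <= wlen)
}

#' Count ChIP-seq peaks overlapping a promoter window
#'
#' Unlike motif sites, peaks are wide, so any overlap of at least one
#' position counts.
#'
#' @param peaks data.frame with `start`, `end` (1-based inclusive), as
#'   returned by [read_bed_peaks()].
#' @param window A one-row `promoter_window`.
#' @param genome_length Chromosome length for wrap arithmetic; `NULL` for
#'   linear coordinates.
#' @return Integer count of overlapping peaks.
#' @export
count_peak_overlaps <- function(peaks, window, genome_length = NULL) {
  if (nrow(peaks) == 0L) return(0L)
  n <- if (is.null(genome_length)) {
    max(window$end, peaks$end) + 1L
  } else {
    genome_length
  }
  wseg <- interval_segments(window$start, window$end, n)
  wr <- IRanges::IRanges(start = vapply(wseg, `[`, 0, 1L),
                         end = vapply(wseg, `[`, 0, 2L))
  overlaps <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    pseg <- interval_segments(peaks$start[i], peaks$end[i], n)
    pr <- IRanges::IRanges(start = vapply(pseg, `[`, 0, 1L),
                           end = vapply(pseg, `[`, 0, 2L))
    overlaps[i] <- length(IRanges::findOverlaps(pr, wr)) > 0L
  }
  sum(overlaps)
}

#' Per-TSS site and peak counts over promoter windows
#'
#' Builds the per-promoter count table that drives the network: one row
#' per catalog TSS, one column per motif hit set plus one for ChIP-seq
#' peaks.
#'
#' @param catalog An `ncrna_catalog`.
#' @param hit_sets Named list of `motif_hits` data.frames (e.g.
#'   `list(ctra_full = ..., ctra_half = ..., ccrm = ..., dnaa = ...)`).
#' @param peaks Optional peaks data.frame; adds a `gcra_peaks`-style
#'   column named by `peaks_name`.
#' @param peaks_name Column name for the peak counts.
#' @inheritParams promoter_windows
#' @return data.frame with `ccna`, `tss`, `strand` and one integer count
#'   column per hit set / peak set.
#' @export
site_count_table <- function(catalog, hit_sets, peaks = NULL,
                             peaks_name = "gcra_peaks", upstream = 100,
                             downstream = 50, genome_length = NULL,
                             circular = TRUE) {
  wins <- promoter_windows(catalog, upstream, downstream,
                           genome_length, circular)
  out <- data.frame(ccna = catalog$ccna, tss = catalog$tss,
                    strand = catalog$strand, stringsAsFactors = FALSE)
  for (nm in names(hit_sets)) {
    out[[nm]] <- vapply(seq_len(nrow(wins)), function(i) {
      count_sites_in_window(hit_sets[[nm]], wins[i, ], genome_length)
    }, integer(1))
  }
  if (!is.null(peaks)) {
    out[[peaks_name]] <- vapply(seq_len(nrow(wins)), function(i) {
      count_peak_overlaps(peaks, wins[i, ], genome_length)
    }, integer(1))
  }
  out
}

#' Fraction of unpaired positions in a dot-bracket interval
#'
#' sRNA seed regions must sit in accessible loops, not stems; this
#' measures the unpaired ('.') fraction of an interval of a dot-bracket
#' secondary structure.
#'
#' @param dot_bracket Dot-bracket string (characters `.`, `(`, `)`).
#' @param interval Integer vector `c(i, j)`, 1-based inclusive on the RNA.
#' @return Fraction in `[0, 1]`.
#' @export
loop_accessibility <- function(dot_bracket, interval) {
  chars <- strsplit(dot_bracket, "")[[1]]
  if (!all(chars %in% c(".", "(", ")"))) {
    stop("dot-bracket string may contain only '.', '(' and ')'")
  }
  depth <- cumsum(ifelse(chars == "(", 1L, ifelse(chars == ")", -1L, 0L)))
  if (any(depth < 0L) || depth[length(depth)] != 0L) {
    stop("unbalanced dot-bracket string")
  }
  i <- interval[1]; j <- interval[2]
  if (i < 1L || j > length(chars) || i > j) stop("interval out of range")
  mean(chars[i:j] == ".")
}
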
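#' Read a genome FASTA file
#'
#' Reads a single-record FASTA into a [genome_seq()]. Genome input must
#' contain exactly one record; multi-record files are rejected rather than
#' silently truncated.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, passed to [genome_seq()]. Default `TRUE`.
#' @return A `genome_seq`.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  if (length(recs) > 1L) {
    stop(sprintf("expected a single genome record, found %d in %s",
                 length(recs), path))
  }
  nm <- sub("\\s.*$", "", names(recs)[1])
  genome_seq(as.character(recs[[1]]), name = nm, circular = circular)
}

#' Read aligned binding sites from FASTA
#'
#' All records must have the same length; used as input to [build_pwm()].
#'
#' @param path FASTA of equal-length aligned binding sites.
#' @return Character vector of uppercase site sequences.
#' @export
read_aligned_sites <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no sites in ", path)
  sites <- toupper(as.character(recs))
  if (length(unique(nchar(sites))) != 1L) {
    stop("aligned sites have differing lengths in ", path)
  }
  unname(sites)
}

CATALOG_TIME_COLS <- paste0("t", seq(0, 140, by = 20))
PHASE_LEVELS <- c("G1", "G1-S", "S", "G2", "G1-G2")

#' Read an ncRNA catalog TSV
#'
#' One row per transcription start site (TSS). Expected header columns:
#' `ccna`, `multiple_tss`, `phase`, `tss`, `strand`, `t0` .. `t140` (eight
#' expression values from a 0-140 min synchrony time course) and
#' `annotation`. A `/` denotes an absent phase label or absent
#' multiple-TSS index. Unicode minus signs in the strand column are
#' normalized to `-`.
#'
#' @param path Path to the TSV.
#' @return A data.frame of class `ncrna_catalog` with columns `ccna`
#'   (character), `multiple_tss` (integer, `NA` when absent), `phase`
#'   (character, `NA` when absent), `tss` (integer), `strand` (`+`/`-`),
#'   the eight numeric time-course columns and `annotation`.
#' @export
read_ncrna_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  need <- c("ccna", "multiple_tss", "phase", "tss", "strand",
            CATALOG_TIME_COLS, "annotation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog missing column(s): ",
                         paste(miss, collapse = ", "))
  as_catalog(data.frame(
    ccna = df$ccna,
    multiple_tss = suppressWarnings(
      as.integer(ifelse(df$multiple_tss == "/", NA, df$multiple_tss))),
    phase = ifelse(df$phase == "/", NA_character_, df$phase),
    tss = as.integer(df$tss),
    strand = gsub("−", "-", df$strand),
    lapply(df[CATALOG_TIME_COLS], function(x) as.numeric(x)),
    annotation = df$annotation,
    stringsAsFactors = FALSE
  ))
}

# validate and class a catalog data.frame
as_catalog <- function(df) {
  if (any(is.na(df$tss)) || any(df$tss < 1L)) {
    stop("TSS positions must be positive integers")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'; found: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  }
  expr <- as.matrix(df[CATALOG_TIME_COLS])
  if (any(is.na(expr))) stop("non-numeric expression value in catalog")
  if (any(expr < 0)) stop("negative expression value in catalog")
  bad_phase <- setdiff(stats::na.omit(unique(df$phase)), PHASE_LEVELS)
  if (length(bad_phase)) stop("unknown phase label(s): ",
                              paste(bad_phase, collapse = ", "))
  key <- paste(df$ccna, df$tss)
  if (anyDuplicated(key)) {
    stop("duplicated (ccna, tss) pair: ", key[duplicated(key)][1])
  }
  class(df) <- c("ncrna_catalog", "data.frame")
  df
}

#' Extract the expression matrix from a catalog
#' @param catalog An `ncrna_catalog`.
#' @return Numeric matrix, rows = TSS rows, columns = the 8 time points.
#' @export
catalog_expression <- function(catalog) {
  m <- as.matrix(catalog[CATALOG_TIME_COLS])
  rownames(m) <- paste0(catalog$ccna, ifelse(is.na(catalog$multiple_tss), "",
                                             paste0(".", catalog$multiple_tss)))
  m
}

#' Read ChIP-seq peaks from a BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to the
#' package-internal 1-based inclusive convention on read.
#'
#' @param path Path to a BED3+ file.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and `label` (`NA` when the name field is absent).
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 which(nf < 3L)[1]))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (any(is.na(start0)) || any(is.na(end0))) {
    stop("malformed BED line: non-integer coordinate")
  }
  if (any(start0 >= end0)) {
    stop(sprintf("malformed BED line %d: start >= end",
                 which(start0 >= end0)[1]))
  }
  label <- vapply(fields, function(f) if (length(f) >= 4L) f[4L]
                  else NA_character_, "")
  data.frame(chrom = chrom, start = start0 + 1L, end = end0,
             label = label, stringsAsFactors = FALSE)
}

#' Write motif hits as BED6
#'
#' Converts internal 1-based inclusive coordinates back to 0-based
#' half-open BED. The score field is `round(1000 * relative_score)`.
#'
#' @param hits A `motif_hits` data.frame as returned by [scan_genome()].
#' @param path Output path.
#' @param chrom Chromosome name used in column 1.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path, chrom = "chr") {
  if (nrow(hits) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   chrom, hits$start - 1L, hits$end, hits$motif_id,
                   as.integer(round(1000 * hits$rel_score)), hits$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read motif hits from a BED6 file written by [write_hits_bed()]
#' @param path BED6 path.
#' @return data.frame with `motif_id`, `start`, `end`, `strand`,
#'   `rel_score` (score field / 1000).
#' @export
read_hits_bed <- function(path) {
  df <- read_bed_peaks(path)
  if (nrow(df) == 0L) {
    return(data.frame(motif_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      rel_score = numeric(), stringsAsFactors = FALSE))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L)) stop("expected BED6 input")
  data.frame(
    motif_id = vapply(fields, `[`, "", 4L),
    start = df$start, end = df$end,
    strand = vapply(fields, `[`, "", 6L),
    rel_score = as.numeric(vapply(fields, `[`, "", 5L)) / 1000,
    stringsAsFactors = FALSE
  )
}

# ---- packaged fixtures (transcribed from the published catalog tables) ----

fixture_path <- function(file) {
  system.file("extdata", file, package = "sRNAcycle", mustWork = TRUE)
}

#' Packaged ncRNA catalog with synchrony time courses
#'
#' The 46 TSS-level rows (44 distinct CCNA identifiers) of the published
#' *C. crescentus* ncRNA catalog: TSS position, strand, optional
#' multiple-TSS index, curated cell-cycle phase label and the 8-point
#' 0-140 min synchrony expression profile.
#'
#' @return An `ncrna_catalog` data.frame.
#' @export
caulo_catalog <- function() read_ncrna_catalog(fixture_path("ncrna_catalog.tsv"))

#' Packaged ncRNA target-function table
#'
#' Per ncRNA: its phase label (`NA` when not cell-cycle regulated), the
#' functional categories among its confirmed predicted targets, and the
#' significant target loci (flagellar genes are by convention not listed).
#'
#' @return data.frame with columns `ccna`, `phase`, `functions` and
#'   `significant_genes`; the latter two are list-columns of character
#'   vectors.
#' @export
caulo_target_functions <- function() {
  df <- utils::read.delim(fixture_path("target_functions.tsv"),
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  split_field <- function(x) {
    lapply(strsplit(x, ",", fixed = TRUE),
           function(v) trimws(v[nzchar(trimws(v))]))
  }
  data.frame(
    ccna = df$ccna,
    phase = ifelse(df$phase == "/", NA_character_, df$phase),
    functions = I(split_field(df$functions)),
    significant_genes = I(split_field(df$significant_genes)),
    stringsAsFactors = FALSE
  )
}

#' Packaged promoter site/peak count table
#'
#' Per TSS: counts of CtrA full sites, CtrA half sites, CcrM (GANTC)
#' methylation sites and DnaA boxes in the promoter region
#' (TSS - 100 to TSS + 50, strand-mirrored), plus the number of
#' overlapping GcrA ChIP-seq peaks.
#'
#' @return data.frame with columns `ccna`, `tss`, `strand`, `ctra_full`,
#'   `ctra_half`, `ccrm`, `dnaa`, `gcra_peaks`.
#' @export
caulo_site_counts <- function() {
  df <- utils::read.delim(fixture_path("promoter_site_counts.tsv"),
                          stringsAsFactors = FALSE)
  df$strand <- gsub("−", "-", df$strand)
  df
}
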
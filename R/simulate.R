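# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments plus the current RNG state; callers set the seed.

#' Sample a random background genome
#'
#' i.i.d. nucleotides at the given GC content.
#'
#' @param length Genome length in nt.
#' @param gc GC fraction; default 0.5.
#' @param circular Circular chromosome; default `TRUE`.
#' @param name Sequence name.
#' @return A `genome_seq`.
#' @export
sim_background <- function(length, gc = 0.5, circular = TRUE,
                           name = "synthetic_chr") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome_seq(paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
                   collapse = ""), name = name, circular = circular)
}

# sample one site from the PWM columns, rejection-sampled until its
# relative score falls in rel_range
sample_site <- function(pwm, rel_range, max_tries = 10000L) {
  smax <- pwm_max_score(pwm)
  for (i in seq_len(max_tries)) {
    site <- paste(vapply(seq_len(pwm$L), function(n) {
      sample(DNA_BASES, 1L, prob = pwm$f[n, ])
    }, ""), collapse = "")
    rel <- score_window(pwm, site) / smax
    if (rel >= rel_range[1] && rel <= rel_range[2]) {
      return(list(seq = site, rel = rel))
    }
  }
  stop(sprintf("could not sample a site with relative score in [%g, %g] ",
               rel_range[1], rel_range[2]), "after ", max_tries, " tries")
}

#' Generate a genome with motif instances planted at known scores
#'
#' Plants non-overlapping motif instances, sampled column-wise from each
#' PWM and rejection-sampled until their relative score falls in the
#' requested range, into an i.i.d. background. Placement leaves a gap of
#' at least the motif length around each site and avoids the origin, so
#' every planted site is recoverable without wrap arithmetic; strands are
#' drawn at random (minus-strand sites are inserted reverse-complemented).
#'
#' @param length,gc,circular Background parameters, see
#'   [sim_background()].
#' @param planted List of specs, each a list with elements `pwm` (a
#'   `pwm`), `n` (number of sites) and `rel_range` (length-2 numeric,
#'   target relative-score interval).
#' @param max_tries Rejection-sampling and placement retry cap.
#' @return List with `genome` (a `genome_seq`) and `truth` (data.frame
#'   `motif_id`, `start`, `end`, `strand`, `seq`, `rel_score`).
#' @export
sim_genome <- function(length, planted = list(), gc = 0.5, circular = TRUE,
                       max_tries = 10000L) {
  genome <- sim_background(length, gc, circular)
  chars <- strsplit(genome$sequence, "")[[1]]
  occupied <- integer(0)
  truth <- list()
  for (spec in planted) {
    pwm <- spec$pwm
    for (i in seq_len(spec$n)) {
      site <- sample_site(pwm, spec$rel_range, max_tries)
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        start <- sample.int(length - 2L * pwm$L, 1L) + pwm$L
        span <- (start - pwm$L):(start + 2L * pwm$L - 1L)
        if (any(span %in% occupied)) next
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") site$seq else reverse_complement(site$seq)
        chars[start:(start + pwm$L - 1L)] <- strsplit(ins, "")[[1]]
        occupied <- c(occupied, span)
        truth[[length(truth) + 1L]] <- data.frame(
          motif_id = pwm$motif_id, start = start,
          end = start + pwm$L - 1L, strand = strand, seq = site$seq,
          rel_score = site$rel, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place site without overlap")
    }
  }
  genome$sequence <- paste(chars, collapse = "")
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(motif_id = character(), start = integer(), end = integer(),
               strand = character(), seq = character(),
               rel_score = numeric(), stringsAsFactors = FALSE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

# phase -> template profile over the 0..140 min grid; peak value is
# `fold` times the baseline so the template passes the dynamic-range gate
phase_template <- function(phase, fold = 8, base = 10) {
  peak <- base * fold
  mid <- base * fold / 4
  switch(phase,
    "G1"    = c(peak, base, base, base, base, base, base, base),
    "G1-S"  = c(base, peak, mid, base, base, base, base, base),
    "S"     = c(base, base, mid, peak, mid, base, base, base),
    "G2"    = c(base, base, base, base, base, base, mid, peak),
    "G1-G2" = c(peak, mid, base, base, base, base, mid, peak),
    "none"  = rep(base, 8L),
    stop("unknown phase template: ", phase))
}

#' Generate synthetic synchrony time courses with known phases
#'
#' Each profile is a phase-specific template (expression peaking at the
#' phase's characteristic time; U-shaped for `G1-G2`; flat for `none`)
#' scaled by a log-uniform amplitude and perturbed by multiplicative
#' lognormal noise, emulating the heavy right tail of real synchrony
#' expression data.
#'
#' @param phase_mix Named integer vector, profiles per phase, e.g.
#'   `c(G1 = 10, S = 10, none = 10)` (names from G1, G1-S, S, G2, G1-G2,
#'   none).
#' @param noise_sigma sdlog of the lognormal noise; default 0.2.
#' @param fold Template peak-to-baseline fold change; default 8.
#' @param base Baseline expression; default 10.
#' @param amp_range Log-uniform amplitude range; default `c(1, 10)`.
#' @return An `ncrna_catalog` data.frame with synthetic ids and an extra
#'   `true_phase` column (`NA` for `none`).
#' @export
sim_timecourses <- function(phase_mix, noise_sigma = 0.2, fold = 8,
                            base = 10, amp_range = c(1, 10)) {
  phases <- rep(names(phase_mix), phase_mix)
  n <- length(phases)
  rows <- lapply(seq_len(n), function(i) {
    amp <- exp(stats::runif(1, log(amp_range[1]), log(amp_range[2])))
    noise <- stats::rlnorm(8L, meanlog = 0, sdlog = noise_sigma)
    vals <- phase_template(phases[i], fold, base) * amp * noise
    stats::setNames(as.list(round(vals, 1)), CATALOG_TIME_COLS)
  })
  vals <- do.call(rbind, lapply(rows, as.data.frame))
  df <- data.frame(
    ccna = sprintf("SYN_R%04d", seq_len(n)),
    multiple_tss = NA_integer_,
    phase = ifelse(phases == "none", NA_character_, phases),
    tss = sample.int(4e6, n),
    strand = sample(c("+", "-"), n, replace = TRUE),
    vals,
    annotation = "Small non-coding RNA",
    stringsAsFactors = FALSE)
  df <- as_catalog(df)
  df$true_phase <- ifelse(phases == "none", NA_character_, phases)
  df
}

#' Synthetic catalog records for the excluded annotation classes
#'
#' Clearly synthetic stand-ins for the translational-machinery RNAs
#' (tRNAs, ribosome-related) and the tmRNA that a full catalog contains
#' but the published study-set table does not print; used to exercise the
#' catalog filter chain end-to-end.
#'
#' @param n_translational Number of translational-machinery records;
#'   default 43.
#' @param n_tmrna Number of tmRNA records; default 1.
#' @return An `ncrna_catalog` data.frame (flat low expression profiles).
#' @export
sim_excluded_records <- function(n_translational = 43, n_tmrna = 1) {
  n <- n_translational + n_tmrna
  vals <- matrix(rep(10, 8L * n), nrow = n,
                 dimnames = list(NULL, CATALOG_TIME_COLS))
  as_catalog(data.frame(
    ccna = sprintf("SYNX_R%04d", seq_len(n)),
    multiple_tss = NA_integer_,
    phase = NA_character_,
    tss = 10000L + 500L * seq_len(n),
    strand = "+",
    as.data.frame(vals),
    annotation = c(rep("Translational machinery (tRNA/ribosome-related)",
                       n_translational), rep("tmRNA", n_tmrna)),
    stringsAsFactors = FALSE))
}

#' Generate three-tool target-prediction tables with known truth
#'
#' The primary ranked tool lists every true target near the top of its
#' list, padded with decoys; the two confirming tools each include a true
#' target independently with the given probability. Decoy pools are
#' disjoint between tools, so a decoy is never spuriously confirmed.
#' Seed-based p-values are drawn below `0.05` for included true targets
#' and uniform on `[0.05, 1]` for decoys.
#'
#' @param truth Named list: ncRNA id -> character vector of true target
#'   loci.
#' @param top_n Length of the primary tool's ranked list; default 100.
#' @param p_copra Probability a true target appears in the comparative
#'   tool's list; default 0.8.
#' @param p_targetrna2 Probability a true target appears (significantly)
#'   in the seed-based tool's list; default 0.8.
#' @param n_confirm_decoys Decoys per ncRNA in each confirming tool;
#'   default 20.
#' @return List of data.frames `predator` (`ncrna_id`, `gene_locus`,
#'   `rank`, `score`), `copra` (`ncrna_id`, `gene_locus`, `score`),
#'   `targetrna2` (`ncrna_id`, `gene_locus`, `p_value`).
#' @export
sim_prediction_tables <- function(truth, top_n = 100, p_copra = 0.8,
                                  p_targetrna2 = 0.8,
                                  n_confirm_decoys = 20) {
  predator <- list(); copra <- list(); targetrna2 <- list()
  for (id in names(truth)) {
    genes <- truth[[id]]
    stopifnot(length(genes) <= top_n)
    n_dec <- top_n - length(genes)
    pool <- c(genes, sprintf("decoyP_%s_%03d", id, seq_len(n_dec)))
    ranks <- sample.int(top_n)
    predator[[id]] <- data.frame(
      ncrna_id = id, gene_locus = pool[order(ranks)],
      rank = seq_len(top_n), score = -sort(stats::runif(top_n, 5, 25)),
      stringsAsFactors = FALSE)
    inc_c <- genes[stats::runif(length(genes)) < p_copra]
    copra[[id]] <- data.frame(
      ncrna_id = id,
      gene_locus = c(inc_c, sprintf("decoyC_%s_%03d", id,
                                    seq_len(n_confirm_decoys))),
      score = stats::runif(length(inc_c) + n_confirm_decoys),
      stringsAsFactors = FALSE)
    inc_t <- genes[stats::runif(length(genes)) < p_targetrna2]
    targetrna2[[id]] <- data.frame(
      ncrna_id = id,
      gene_locus = c(inc_t, sprintf("decoyT_%s_%03d", id,
                                    seq_len(n_confirm_decoys))),
      p_value = c(stats::runif(length(inc_t), 0, 0.049),
                  stats::runif(n_confirm_decoys, 0.05, 1)),
      stringsAsFactors = FALSE)
  }
  list(predator = do.call(rbind, c(predator, make.row.names = FALSE)),
       copra = do.call(rbind, c(copra, make.row.names = FALSE)),
       targetrna2 = do.call(rbind, c(targetrna2, make.row.names = FALSE)))
}

#' Generate random ChIP-seq-like peak intervals
#'
#' @param n Number of peaks.
#' @param genome_length Chromosome length.
#' @param width_range Peak width range in nt; default `c(50, 400)`.
#' @return data.frame `chrom`, `start`, `end`, `label` (1-based
#'   inclusive, no wrapping).
#' @export
sim_peaks <- function(n, genome_length, width_range = c(50, 400)) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  start <- vapply(w, function(wi) sample.int(genome_length - wi, 1L),
                  integer(1))
  data.frame(chrom = "synthetic_chr", start = start, end = start + w - 1L,
             label = sprintf("peak_%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}
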
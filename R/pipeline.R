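default_params <- function() {
  list(rel_threshold = 0.6, upstream = 100, downstream = 50,
       iupac = "GANTC", top_n = 100, p_max = 0.05,
       fold_threshold = 4, min_peak = 5, u_ratio = 3)
}

resolve_input <- function(x, reader, packaged) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    if (x == "packaged") return(packaged())
    return(reader(x))
  }
  x
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: catalog filtering, phase
#' classification and tallies, promoter scanning (when a genome and PWMs
#' are supplied) or ingestion of precomputed site counts, target-function
#' integration with the cell-cycle enrichment fractions, network assembly
#' and export, plus a reproducibility manifest with input checksums.
#'
#' @param config A list or path to a YAML file. Recognized keys:
#'   `seed` (integer); `inputs$catalog` (TSV path, `"packaged"`, or an
#'   `ncrna_catalog`); `inputs$functions_table` (path/`"packaged"`/
#'   data.frame as in [caulo_target_functions()]); `inputs$site_counts`
#'   (path/`"packaged"`/data.frame as in [caulo_site_counts()]);
#'   `inputs$genome` (FASTA path or `genome_seq`); `inputs$pwms`
#'   (named list of PWM file paths or `pwm` objects); `inputs$peaks`
#'   (BED path or data.frame); `params` overriding any analysis
#'   constant (relative threshold 0.6, window 100/50, IUPAC motif GANTC,
#'   top-100 primary list, p < 0.05, fold gate 4, minimum peak 5).
#' @param out_dir Output directory; created if needed.
#' @param force Overwrite an existing non-empty output directory.
#' @return Invisibly, a list with the stage summaries: `filter_counts`,
#'   `phase_tss`, `phase_ncrna`, `fractions`, `network`, `manifest_path`.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  params <- utils::modifyList(default_params(), config$params %||% list())
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop("output directory not empty (use force = TRUE): ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  inp <- config$inputs %||% list()

  ## --- catalog: filter chain + phase classification -------------------
  catalog <- resolve_input(inp$catalog, read_ncrna_catalog, caulo_catalog)
  if (is.null(catalog)) stop("stage catalog: no catalog input")
  study <- select_study_set(catalog)
  filter_counts <- attr(study, "filter_counts")
  study <- classify_catalog(study, params$fold_threshold, params$min_peak,
                            params$u_ratio)
  utils::write.table(study, file.path(out_dir, "study_catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  phase_col <- if (any(!is.na(study$phase))) "phase" else "phase_called"
  phase_tss <- count_by_phase(study, "tss", phase_col)
  phase_ncrna <- count_by_phase(study, "ncrna", phase_col)
  message(sprintf("[catalog] %d -> %d -> %d ncRNAs; %d phase-labelled TSS rows, %d distinct dynamic ncRNAs",
                  filter_counts["input"], filter_counts["after_machinery"],
                  filter_counts["final"], attr(phase_tss, "n_labelled"),
                  attr(phase_ncrna, "n_labelled")))
  message(sprintf("[phases] %s",
                  paste(names(phase_tss), phase_tss, sep = "=",
                        collapse = " ")))

  ## --- promoter scanning / site counts --------------------------------
  genome <- resolve_input(inp$genome, read_genome_fasta, function() NULL)
  site_counts <- NULL
  if (!is.null(genome)) {
    pwms <- lapply(inp$pwms, function(p) {
      if (inherits(p, "pwm")) p else read_pwm(p)
    })
    names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
    hit_sets <- lapply(pwms, function(p) {
      hits <- scan_genome(p, genome, params$rel_threshold)
      write_hits_bed(hits, file.path(out_dir,
                                     paste0("hits_", p$motif_id, ".bed")),
                     chrom = genome$name)
      hits
    })
    if (!is.null(params$iupac)) {
      hit_sets$ccrm <- match_degenerate(params$iupac, genome)
      write_hits_bed(hit_sets$ccrm, file.path(out_dir, "hits_ccrm.bed"),
                     chrom = genome$name)
    }
    peaks <- resolve_input(inp$peaks, read_bed_peaks, function() NULL)
    site_counts <- site_count_table(
      study, hit_sets, peaks, upstream = params$upstream,
      downstream = params$downstream, genome_length = genome_length(genome),
      circular = genome$circular)
    message(sprintf("[scan] %d promoter windows x %d motif/peak sets",
                    nrow(site_counts), length(hit_sets) +
                      as.integer(!is.null(peaks))))
  } else {
    site_counts <- resolve_input(inp$site_counts,
                                 function(p) utils::read.delim(p),
                                 caulo_site_counts)
  }
  if (!is.null(site_counts)) {
    utils::write.table(site_counts, file.path(out_dir, "site_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- target integration ---------------------------------------------
  fractions <- NULL
  functions_table <- resolve_input(
    inp$functions_table,
    function(p) stop("functions_table must be 'packaged' or a data.frame"),
    caulo_target_functions)
  target_pairs <- NULL
  if (!is.null(inp$predictions)) {
    pr <- inp$predictions
    target_pairs <- confirmed_targets(pr$predator, pr$copra, pr$targetrna2,
                                      top_n = params$top_n,
                                      p_max = params$p_max)
    utils::write.table(target_pairs,
                       file.path(out_dir, "confirmed_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("[targets] %d confirmed (ncRNA, locus) pairs",
                    nrow(target_pairs)))
  }
  if (!is.null(functions_table)) {
    fractions <- cellcycle_fraction(functions_table)
    message(sprintf("[enrichment] dynamic %d/%d (%.1f%%), static %d/%d (%.1f%%)",
                    fractions$dynamic[["k"]], fractions$dynamic[["n"]],
                    fractions$percent[["dynamic"]],
                    fractions$static[["k"]], fractions$static[["n"]],
                    fractions$percent[["static"]]))
    if (is.null(target_pairs)) {
      ft <- functions_table[lengths(functions_table$significant_genes) > 0,
                            , drop = FALSE]
      target_pairs <- unique(data.frame(
        ncrna_id = rep(ft$ccna, lengths(ft$significant_genes)),
        gene_locus = tolower(unlist(ft$significant_genes)),
        stringsAsFactors = FALSE))
    }
  }

  ## --- network ---------------------------------------------------------
  network <- NULL
  if (!is.null(site_counts)) {
    network <- suppressWarnings(build_network(site_counts, target_pairs))
    export_network(network, file.path(out_dir, "network.sif"), "sif")
    export_network(network, file.path(out_dir, "network_edges.tsv"), "tsv")
    export_network(network, file.path(out_dir, "network.graphml"),
                   "graphml")
    message(sprintf("[network] %d nodes, %d edges; %d multi-regulated ncRNAs",
                    nrow(network$nodes), nrow(network$edges),
                    nrow(multiregulated(network))))
  }

  ## --- manifest --------------------------------------------------------
  outputs <- sort(dir(out_dir, full.names = TRUE))
  manifest <- list(
    tool = paste0("sRNAcycle ",
                  as.character(utils::packageVersion("sRNAcycle"))),
    seed = config$seed,
    params = params,
    filter_counts = as.list(filter_counts),
    phase_tss = as.list(phase_tss),
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))
    }))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(filter_counts = filter_counts, phase_tss = phase_tss,
                 phase_ncrna = phase_ncrna, fractions = fractions,
                 site_counts = site_counts, network = network,
                 manifest_path = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
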
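#' Integrate three-tool target predictions under the confirmation rule
#'
#' An (ncRNA, gene) pair is retained iff the gene is within the primary
#' tool's top `top_n` ranked predictions for that ncRNA AND the gene is
#' confirmed, i.e. it appears in the comparative-genomics tool's list
#' for that ncRNA, or in the seed-based tool's list with
#' `p_value < p_max`. Records of the seed-based tool without a p-value
#' cannot confirm. Locus tags are matched case-insensitively.
#'
#' @param predator data.frame with `ncrna_id`, `gene_locus`, `rank`
#'   (primary ranked predictions).
#' @param copra data.frame with `ncrna_id`, `gene_locus` (comparative
#'   predictions; any listed gene confirms).
#' @param targetrna2 data.frame with `ncrna_id`, `gene_locus`, `p_value`.
#' @param top_n Primary-list depth; default 100.
#' @param p_max Significance cutoff for the seed-based tool; default 0.05.
#' @return data.frame `ncrna_id`, `gene_locus` (lowercase), deduplicated
#'   and sorted by (ncrna_id, gene_locus).
#' @export
confirmed_targets <- function(predator, copra, targetrna2,
                              top_n = 100, p_max = 0.05) {
  key <- function(id, locus) paste(id, tolower(locus), sep = "\r")
  pred <- predator[!is.na(predator$rank) & predator$rank <= top_n,
                   , drop = FALSE]
  pk <- key(pred$ncrna_id, pred$gene_locus)
  ck <- if (nrow(copra)) key(copra$ncrna_id, copra$gene_locus) else character()
  t2 <- targetrna2[!is.na(targetrna2$p_value) &
                     targetrna2$p_value < p_max, , drop = FALSE]
  tk <- if (nrow(t2)) key(t2$ncrna_id, t2$gene_locus) else character()
  keep <- pk %in% c(ck, tk)
  out <- unique(data.frame(ncrna_id = pred$ncrna_id[keep],
                           gene_locus = tolower(pred$gene_locus[keep]),
                           stringsAsFactors = FALSE))
  out <- out[order(out$ncrna_id, out$gene_locus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

TARGET_CATEGORIES <- c("Cell cycle", "Cell division", "Flagellum", "Pilus",
                       "Stalk", "Chromosome partitioning", "ppGpp")

#' Read a gene-function annotation table
#'
#' @param path TSV with columns `gene_locus` and `categories`
#'   (comma-separated, from the controlled vocabulary).
#' @return Named list mapping lowercase locus tag to a character vector
#'   of categories.
#' @export
read_function_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ann <- lapply(strsplit(df$categories, ",", fixed = TRUE), trimws)
  bad <- setdiff(unlist(ann), TARGET_CATEGORIES)
  if (length(bad)) stop("categories outside the controlled vocabulary: ",
                        paste(unique(bad), collapse = ", "))
  names(ann) <- tolower(df$gene_locus)
  ann
}

#' Packaged curated gene-function map
#'
#' A small curated mapping from *C. crescentus* cell-cycle-relevant locus
#' tags (and a few flagellar genes) to the controlled category
#' vocabulary, for use with [annotate_targets()].
#'
#' @return Named list, lowercase locus tag to category vector.
#' @export
caulo_gene_functions <- function() {
  read_function_annotation(fixture_path("gene_functions.tsv"))
}

#' Annotate confirmed targets with functional categories
#'
#' Per ncRNA, the union of its target genes' categories, plus the
#' significant loci. Following the reporting convention of the source
#' tables, loci whose only categories are `Flagellum` are not listed
#' (flagellar genes are numerous), though the category itself is kept.
#' Loci absent from the annotation contribute nothing (a warning names
#' them).
#'
#' @param pairs data.frame from [confirmed_targets()].
#' @param annotation Named list from [read_function_annotation()] (or an
#'   equivalent lowercase-locus to category-vector mapping).
#' @return data.frame with `ncrna_id`, list-columns `functions` and
#'   `significant_genes`.
#' @export
annotate_targets <- function(pairs, annotation) {
  ids <- unique(pairs$ncrna_id)
  unknown <- setdiff(unique(pairs$gene_locus), names(annotation))
  if (length(unknown)) {
    warning("loci absent from annotation: ", paste(unknown, collapse = ", "))
  }
  funs <- vector("list", length(ids))
  sig <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    loci <- sort(unique(pairs$gene_locus[pairs$ncrna_id == ids[i]]))
    cats <- annotation[intersect(loci, names(annotation))]
    funs[[i]] <- sort(unique(unlist(cats)))
    listed <- vapply(cats, function(v) any(v != "Flagellum"), TRUE)
    sig[[i]] <- if (length(cats)) names(cats)[listed] else character(0)
  }
  data.frame(ncrna_id = ids, functions = I(funs),
             significant_genes = I(sig), stringsAsFactors = FALSE)
}

#' Cell-cycle enrichment among dynamic vs static ncRNAs
#'
#' Among distinct ncRNAs with a cell-cycle phase label (dynamic), `k1`
#' have `"Cell cycle"` among their target-function categories, out of
#' `n1`; likewise `k2 / n2` for ncRNAs without a phase label (static).
#' Membership is the exact category `"Cell cycle"`, distinct from
#' `"Cell division"`. An ncRNA with both labelled and unlabelled TSS rows
#' is counted in both denominators, mirroring the source tables.
#'
#' @param functions_table data.frame with one row per (ncRNA, phase
#'   group) as in [caulo_target_functions()]: columns `ccna`, `phase`
#'   (`NA` for static rows) and list-column `functions`.
#' @param test Also run a two-sided Fisher exact test on the 2x2 table;
#'   off by default.
#' @return List with elements `dynamic` and `static`, each `c(k =, n =)`,
#'   `percent` (named numeric, one decimal), and `p_value` when
#'   `test = TRUE`.
#' @export
cellcycle_fraction <- function(functions_table, test = FALSE) {
  has_cc <- function(rows) {
    vapply(rows, function(v) "Cell cycle" %in% v, TRUE)
  }
  side <- function(dyn) {
    sel <- if (dyn) !is.na(functions_table$phase) else
      is.na(functions_table$phase)
    sub <- functions_table[sel, , drop = FALSE]
    ids <- unique(sub$ccna)
    k <- sum(vapply(ids, function(id) {
      any(has_cc(sub$functions[sub$ccna == id]))
    }, TRUE))
    c(k = k, n = length(ids))
  }
  dynamic <- side(TRUE)
  static <- side(FALSE)
  out <- list(dynamic = dynamic, static = static,
              percent = c(
                dynamic = round(100 * dynamic[["k"]] / dynamic[["n"]], 1),
                static = round(100 * static[["k"]] / static[["n"]], 1)
              ))
  if (test) {
    m <- matrix(c(dynamic["k"], dynamic["n"] - dynamic["k"],
                  static["k"], static["n"] - static["k"]), nrow = 2L)
    out$p_value <- stats::fisher.test(m)$p.value
  }
  out
}
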
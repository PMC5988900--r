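MASTER_REGULATORS <- c(ctra_full = "CtrA", ctra_half = "CtrA",
                       ccrm_site = "CcrM", dnaa_box = "DnaA",
                       gcra_peak = "GcrA")

#' Assemble the regulator / ncRNA / target network
#'
#' Integrates per-promoter motif and peak counts (regulator acting on
#' ncRNA) with confirmed target pairs (ncRNA acting on transcript). For
#' each ncRNA with a positive count for a motif class, one typed edge
#' regulator -> ncRNA is added with the count as weight. CtrA full and
#' half sites collapse: whenever a full site is present, half sites are
#' not indicated. Master proteins (upper case, e.g. `CtrA`) and targeted
#' transcripts (lower case, e.g. `dnaA`'s transcript `dnaa`) are distinct
#' nodes. Site counts with several TSS rows per ncRNA are summed per
#' ncRNA before edges are drawn.
#'
#' @param site_counts data.frame shaped like [caulo_site_counts()]:
#'   `ccna` plus count columns `ctra_full`, `ctra_half`, `ccrm`, `dnaa`,
#'   `gcra_peaks` (missing columns are treated as all-zero).
#' @param targets Optional data.frame from [confirmed_targets()] giving
#'   `ncrna_id`, `gene_locus` pairs; each becomes an `ncrna_target` edge.
#'   A target ncRNA absent from `site_counts` is added with a warning.
#' @return An object of class `regulatory_network`: list with `nodes`
#'   (data.frame `name`, `type`) and `edges` (data.frame `from`, `to`,
#'   `edge_type`, `weight`).
#' @export
build_network <- function(site_counts, targets = NULL) {
  count_cols <- c(ctra_full = "ctra_full", ctra_half = "ctra_half",
                  ccrm_site = "ccrm", dnaa_box = "dnaa",
                  gcra_peak = "gcra_peaks")
  ids <- unique(site_counts$ccna)
  agg <- vapply(count_cols, function(cl) {
    if (!cl %in% names(site_counts)) {
      return(stats::setNames(rep(0L, length(ids)), ids))
    }
    v <- tapply(site_counts[[cl]], site_counts$ccna, sum)
    stats::setNames(as.integer(v[ids]), ids)
  }, integer(length(ids)))
  agg <- matrix(agg, nrow = length(ids), ncol = length(count_cols),
                dimnames = list(ids, names(count_cols)))
  edges <- list()
  for (id in ids) {
    for (etype in names(count_cols)) {
      w <- agg[id, etype]
      if (w <= 0L) next
      if (etype == "ctra_half" && agg[id, "ctra_full"] > 0L) next
      edges[[length(edges) + 1L]] <- data.frame(
        from = MASTER_REGULATORS[[etype]], to = id, edge_type = etype,
        weight = w, stringsAsFactors = FALSE)
    }
  }
  target_nodes <- character(0)
  if (!is.null(targets) && nrow(targets)) {
    extra <- setdiff(unique(targets$ncrna_id), ids)
    if (length(extra)) {
      warning("target ncRNA(s) absent from site counts: ",
              paste(extra, collapse = ", "))
      ids <- c(ids, extra)
    }
    target_nodes <- sort(unique(tolower(targets$gene_locus)))
    for (i in seq_len(nrow(targets))) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = targets$ncrna_id[i], to = tolower(targets$gene_locus[i]),
        edge_type = "ncrna_target", weight = 1L, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(from = character(), to = character(),
               edge_type = character(), weight = integer(),
               stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$edge_type, edges$to,
                       method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- rbind(
    data.frame(name = sort(unique(unname(MASTER_REGULATORS))),
               type = "master_protein", stringsAsFactors = FALSE),
    if (length(ids)) {
      data.frame(name = sort(ids), type = "ncrna",
                 stringsAsFactors = FALSE)
    },
    if (length(target_nodes)) {
      data.frame(name = target_nodes, type = "target_transcript",
                 stringsAsFactors = FALSE)
    }
  )
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' ncRNAs regulated by at least k distinct master regulators
#'
#' @param network A `regulatory_network`.
#' @param k Minimum number of distinct incoming master regulators;
#'   default 2.
#' @return data.frame `ncrna`, `n_regulators`, sorted by decreasing
#'   in-degree then name.
#' @export
multiregulated <- function(network, k = 2) {
  reg_edges <- network$edges[network$edges$edge_type != "ncrna_target",
                             , drop = FALSE]
  if (!nrow(reg_edges)) {
    return(data.frame(ncrna = character(), n_regulators = integer(),
                      stringsAsFactors = FALSE))
  }
  deg <- tapply(reg_edges$from, reg_edges$to,
                function(v) length(unique(v)))
  out <- data.frame(ncrna = names(deg), n_regulators = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[out$n_regulators >= k, , drop = FALSE]
  out <- out[order(-out$n_regulators, out$ncrna, method = "radix"),
             , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}

#' Export a regulatory network
#'
#' SIF is one line per edge, `source<TAB>edge_type<TAB>target`, edges in
#' lexicographic order; TSV is the edge table with weights; GraphML
#' (via igraph) carries node `type` and edge `edge_type` / `weight`
#' attributes. Output is byte-identical for identical inputs.
#'
#' @param network A `regulatory_network`.
#' @param path Output file path.
#' @param format `"sif"`, `"tsv"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("sif", "tsv",
                                                     "graphml")) {
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", e$from, e$edge_type, e$to)
    writeLines(sort(lines, method = "radix"), path)
  } else if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML network export back
#' @param path GraphML file written by [export_network()].
#' @return A `regulatory_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(name = igraph::V(g)$name, type = igraph::V(g)$type,
                      stringsAsFactors = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(from = el$from, to = el$to,
                      edge_type = el$edge_type,
                      weight = as.integer(el$weight),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$edge_type, edges$to,
                       method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}
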
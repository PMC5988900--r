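test_that("network build applies the CtrA full/half collapse rule", {
  counts <- caulo_site_counts()
  net <- build_network(counts)
  e <- net$edges
  r94 <- e[e$to == "CCNA_R0094", ]
  # full = 2, half = 4 -> single CtrA edge typed full, weight 2
  expect_equal(r94$edge_type[r94$from == "CtrA"], "ctra_full")
  expect_equal(r94$weight[r94$from == "CtrA"], 2L)
  expect_false(any(e$edge_type == "ctra_half" & e$to == "CCNA_R0094"))

  r116 <- e[e$to == "CCNA_R0116", ]
  expect_setequal(r116$edge_type, c("ctra_half", "ccrm_site", "gcra_peak"))
  expect_setequal(r116$from, c("CtrA", "CcrM", "GcrA"))
  expect_equal(r116$weight[r116$edge_type == "ccrm_site"], 3L)

  # collapse invariant over every pair
  ctra <- e[e$from == "CtrA", ]
  expect_equal(anyDuplicated(ctra$to), 0L)

  # all-zero rows become isolated ncRNA nodes
  zero_ids <- names(which(tapply(
    counts$ctra_full + counts$ctra_half + counts$ccrm + counts$dnaa +
      counts$gcra_peaks, counts$ccna, sum) == 0))
  expect_true(all(zero_ids %in% net$nodes$name[net$nodes$type == "ncrna"]))
  expect_false(any(e$to %in% zero_ids))
})

test_that("edge count equals collapsed class count plus target pairs", {
  counts <- caulo_site_counts()
  targets <- data.frame(ncrna_id = c("CCNA_R0094", "CCNA_R0123"),
                        gene_locus = c("dnaA", "dnaA"))
  net <- build_network(counts, targets)
  agg <- stats::aggregate(
    counts[c("ctra_full", "ctra_half", "ccrm", "dnaa", "gcra_peaks")],
    by = list(ccna = counts$ccna), FUN = sum)
  per_ncrna <- apply(agg[-1], 1, function(v) {
    classes <- sum(v > 0)
    if (v["ctra_full"] > 0 && v["ctra_half"] > 0) classes <- classes - 1
    classes
  })
  expect_equal(nrow(net$edges), sum(per_ncrna) + nrow(targets))
  expect_true(all(net$edges$from[net$edges$edge_type == "ncrna_target"]
                  %in% net$nodes$name[net$nodes$type == "ncrna"]))
  expect_true("dnaa" %in% net$nodes$name[net$nodes$type ==
                                           "target_transcript"])
})

test_that("multiregulated ranks ncRNAs by distinct incoming regulators", {
  net <- build_network(caulo_site_counts())
  multi <- multiregulated(net, k = 2)
  expect_true("CCNA_R0116" %in% multi$ncrna)
  expect_equal(multi$n_regulators[multi$ncrna == "CCNA_R0116"], 3L)
  at3 <- multiregulated(net, k = 3)
  expect_true(all(at3$n_regulators >= 3))
  expect_true(all(diff(at3$n_regulators) <= 0))

  empty <- build_network(caulo_site_counts()[0, ])
  expect_equal(nrow(multiregulated(empty)), 0L)
})

test_that("exports are deterministic and round-trip", {
  counts <- caulo_site_counts()
  targets <- data.frame(ncrna_id = "CCNA_R0094", gene_locus = "dnaA")
  net <- build_network(counts, targets)
  sif1 <- withr::local_tempfile(fileext = ".sif")
  sif2 <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif1, "sif")
  export_network(build_network(counts, targets), sif2, "sif")
  expect_identical(readLines(sif1), readLines(sif2))
  lines <- readLines(sif1)
  expect_true("CtrA\tctra_full\tCCNA_R0094" %in% lines)
  expect_equal(length(lines), nrow(net$edges))

  one <- build_network(
    data.frame(ccna = "CCNA_R0094", ctra_full = 2L, ctra_half = 4L,
               ccrm = 0L, dnaa = 0L, gcra_peaks = 0L))
  sif3 <- withr::local_tempfile(fileext = ".sif")
  export_network(one, sif3, "sif")
  expect_equal(readLines(sif3), "CtrA\tctra_full\tCCNA_R0094")

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- read_network_graphml(gml)
  expect_setequal(back$nodes$name, net$nodes$name)
  expect_equal(back$edges[c("from", "to", "edge_type", "weight")],
               net$edges[c("from", "to", "edge_type", "weight")])

  empty <- build_network(counts[0, ])
  sif4 <- withr::local_tempfile(fileext = ".sif")
  export_network(empty, sif4, "sif")
  expect_identical(readLines(sif4), character(0))

  expect_error(export_network(net, sif4, "dot"), "arg")
})
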
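test_that("generators are pure functions of the seed", {
  set.seed(71)
  a <- sim_genome(500, list(list(pwm = build_pwm(rep("TTGACA", 5)),
                                 n = 3, rel_range = c(0.8, 1))))
  set.seed(71)
  b <- sim_genome(500, list(list(pwm = build_pwm(rep("TTGACA", 5)),
                                 n = 3, rel_range = c(0.8, 1))))
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth, b$truth)

  set.seed(72)
  t1 <- sim_timecourses(c(G1 = 5, S = 5))
  set.seed(72)
  t2 <- sim_timecourses(c(G1 = 5, S = 5))
  expect_identical(t1, t2)
})

test_that("planted sites rescore inside their requested range", {
  set.seed(73)
  pw <- build_pwm(rep("TTGACAGCT", 10), motif_id = "sharp")
  rng <- c(0.7, 0.9)
  sg <- sim_genome(4000, list(list(pwm = pw, n = 8, rel_range = rng)))
  expect_equal(nrow(sg$truth), 8L)
  chars <- strsplit(sg$genome$sequence, "")[[1]]
  smax <- pwm_max_score(pw)
  for (j in seq_len(nrow(sg$truth))) {
    w <- paste(chars[sg$truth$start[j]:sg$truth$end[j]], collapse = "")
    if (sg$truth$strand[j] == "-") w <- reverse_complement(w)
    rel <- oracle_score(pw$f, w) / smax
    expect_gte(rel, rng[1])
    expect_lte(rel, rng[2])
  }
  expect_error(
    sim_genome(200, list(list(pwm = pw, n = 1, rel_range = c(0.99, 0.991))),
               max_tries = 5),
    "could not sample")
})

test_that("background without planted sites matches the oracle", {
  set.seed(74)
  pw <- build_pwm(rep("TTGACAGCT", 10), motif_id = "sharp")
  g <- sim_background(1000)
  hits <- scan_genome(pw, g, 0.95)
  orc <- oracle_scan(pw, g, 0.95)
  expect_equal(hits$start, orc$start)
})

test_that("noiseless templates classify to their phase", {
  for (ph in c("G1", "G1-S", "S", "G2", "G1-G2")) {
    expect_equal(classify_phase(sRNAcycle:::phase_template(ph)), ph)
  }
  expect_true(is.na(classify_phase(sRNAcycle:::phase_template("none"))))
  set.seed(75)
  flat <- sim_timecourses(c(none = 20), noise_sigma = 0)
  expect_true(all(is.na(classify_catalog(flat)$phase_called)))
})

test_that("prediction tables honour the configured overlap", {
  truth <- list(R1 = c("dnaa", "hdaa"), R2 = c("ctra", "mipz", "ftsz"))
  set.seed(76)
  full <- sim_prediction_tables(truth, p_copra = 1, p_targetrna2 = 1)
  got <- confirmed_targets(full$predator, full$copra, full$targetrna2)
  expect_setequal(paste(got$ncrna_id, got$gene_locus),
                  c("R1 dnaa", "R1 hdaa", "R2 ctra", "R2 mipz", "R2 ftsz"))

  set.seed(76)
  none <- sim_prediction_tables(truth, p_copra = 0, p_targetrna2 = 0)
  expect_equal(nrow(confirmed_targets(none$predator, none$copra,
                                      none$targetrna2)), 0L)

  # intermediate overlap equals a set-algebra oracle on the tables
  set.seed(77)
  mid <- sim_prediction_tables(truth, p_copra = 0.5, p_targetrna2 = 0.5)
  got_mid <- confirmed_targets(mid$predator, mid$copra, mid$targetrna2,
                               top_n = 100, p_max = 0.05)
  oracle <- character(0)
  for (id in names(truth)) {
    pred <- mid$predator[mid$predator$ncrna_id == id, ]
    top <- tolower(pred$gene_locus[pred$rank <= 100])
    cop <- tolower(mid$copra$gene_locus[mid$copra$ncrna_id == id])
    t2 <- mid$targetrna2[mid$targetrna2$ncrna_id == id, ]
    sig <- tolower(t2$gene_locus[!is.na(t2$p_value) & t2$p_value < 0.05])
    oracle <- c(oracle, paste(id, intersect(top, union(cop, sig))))
  }
  expect_setequal(paste(got_mid$ncrna_id, got_mid$gene_locus), oracle)
})

test_that("random peaks stay inside the chromosome", {
  set.seed(78)
  pk <- sim_peaks(50, 10000)
  expect_true(all(pk$start >= 1 & pk$end <= 10000 & pk$start <= pk$end))
})
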
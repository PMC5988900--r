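test_that("PWM construction matches pseudocount arithmetic", {
  p <- build_pwm(c("GG", "GA"), pseudocount = 0.5)
  expect_equal(unname(p$f[2, "A"]), 0.375)
  expect_equal(unname(p$f[2, "G"]), 0.375)
  expect_equal(unname(p$f[1, "G"]), 0.625)

  p10 <- build_pwm(rep("AAAA", 10), pseudocount = 0)
  expect_equal(unname(p10$f[, "A"]), rep(1, 4))
  expect_equal(pwm_max_score(p10), 2.0)

  p4 <- build_pwm(c("A", "C", "G", "T"), pseudocount = 0)
  expect_equal(score_window(p4, "G"), 0)

  expect_error(build_pwm(c("AA", "A")), "same length")

  # zero pseudocount: unseen bases are impossible, not just unlikely
  p0 <- build_pwm(c("AA", "AC"), pseudocount = 0)
  expect_equal(score_window(p0, "AA"), 1.5)
  expect_equal(score_window(p0, "AT"), -Inf)
})

test_that("window scores follow the information-score formula", {
  p10 <- build_pwm(rep("ACGT", 10), pseudocount = 0)
  expect_equal(score_window(p10, "ACGT"), 2.0)

  unif <- pwm_from_matrix(matrix(0.25, 3, 4,
                                 dimnames = list(NULL, c("A", "C", "G", "T"))))
  expect_equal(score_window(unif, "CGA"), 0.0)

  f <- matrix(0.05, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  f[, "A"] <- 0.85
  p <- pwm_from_matrix(f)
  expect_equal(score_window(p, "AAA"), 2 + log2(0.85), tolerance = 1e-12)
  # one mismatch at position 2; frozen value computed by the
  # independent oracle: (2*(2+log2 .85) + (2+log2 .05))/3
  expect_equal(score_window(p, "ACA"), 0.4030471, tolerance = 1e-6)
  expect_equal(score_window(p, "ACA"), oracle_score(p$f, "ACA"))

  expect_true(is.na(score_window(p, "ANA")))
  expect_error(score_window(p, "AAAA"), "length")
})

test_that("genome scanning equals the brute-force oracle", {
  set.seed(11)
  for (i in 1:8) {
    L <- sample(3:8, 1)
    pwm <- random_pwm(L, id = "r")
    g <- sim_background(sample(150:400, 1), gc = runif(1, 0.3, 0.7),
                        circular = i %% 2 == 0)
    thr <- sample(c(0.5, 0.6, 0.75), 1)
    hits <- scan_genome(pwm, g, thr)
    orc <- oracle_scan(pwm, g, thr)
    expect_equal(nrow(hits), nrow(orc))
    expect_equal(hits$start, orc$start)
    expect_equal(hits$strand, orc$strand)
    expect_equal(hits$score, orc$score, tolerance = 1e-12)
    expect_true(all(hits$rel_score <= 1 + 1e-12))
    expect_true(all(hits$score <= pwm_max_score(pwm) + 1e-12))
  }
})

test_that("the 60% retention boundary is sharp", {
  # dyadic frequencies make score contributions exact: 1, 0, -1, -1 bits
  f <- matrix(rep(c(0.5, 0.25, 0.125, 0.125), each = 5), 5, 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  p <- pwm_from_matrix(f)
  expect_equal(pwm_max_score(p), 1.0)
  expect_equal(score_window(p, "AAACC"), 0.6)  # exactly 0.6 * S_max
  g <- genome_seq("GGGGGAAACCGGGGG", circular = FALSE)
  hits <- scan_genome(p, g, rel_threshold = 0.6)
  expect_true(any(hits$start == 6 & hits$strand == "+"))

  # second PWM puts a window a hair under 60%: rejected
  f2 <- f
  f2[5, ] <- c(0.4999, 0.2509, 0.2491, 0.0001)
  p2 <- pwm_from_matrix(f2)
  rel <- score_window(p2, "AAACG") / pwm_max_score(p2)
  expect_gt(rel, 0.5985)
  expect_lt(rel, 0.5995)
  g2 <- genome_seq("GGGGGAAACGGGGGG", circular = FALSE)
  hits2 <- scan_genome(p2, g2, rel_threshold = 0.6)
  expect_false(any(hits2$start == 6 & hits2$strand == "+"))

  unif <- pwm_from_matrix(matrix(0.25, 4, 4,
                                 dimnames = list(NULL, c("A", "C", "G", "T"))))
  expect_error(scan_genome(unif, g), "degenerate PWM")
})

test_that("circular scanning reports origin-spanning hits", {
  p <- build_pwm(rep("TTGCA", 8), pseudocount = 0.5, motif_id = "wrap")
  # consensus starts at position 18 of a 20 nt circle and wraps: the
  # sequence ends ...TTG and begins CA...
  g <- genome_seq(paste0("CA", strrep("G", 15), "TTG"))
  hits <- scan_genome(p, g, 0.9)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 18L)
  expect_equal(hits$end, 2L)
  expect_equal(hits$seq, "TTGCA")
  # linear scanning of the same sequence finds nothing
  g$circular <- FALSE
  expect_equal(nrow(scan_genome(p, g, 0.9)), 0L)
})

test_that("strand symmetry: revcomp genome + revcomp PWM mirrors hits", {
  set.seed(23)
  pwm <- random_pwm(6, id = "sym")
  g <- sim_background(300, circular = FALSE)
  h1 <- scan_genome(pwm, g, 0.55)
  g_rc <- genome_seq(reverse_complement(g$sequence), circular = FALSE)
  h2 <- scan_genome(pwm_reverse_complement(pwm), g_rc, 0.55)
  n <- genome_length(g)
  mirrored_start <- sort(n - h2$end + 1)
  expect_equal(sort(h1$start), mirrored_start)
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-12)
})

test_that("duplex palindromy is detected under IUPAC complement", {
  expect_true(is_iupac_palindrome("GANTC"))
  expect_true(is_iupac_palindrome("GAATTC"))
  expect_false(is_iupac_palindrome("GANTT"))
  expect_false(is_iupac_palindrome("GGANTC"))
})

test_that("degenerate matching equals sliding-window enumeration", {
  g1 <- genome_seq("GAATC", circular = FALSE)
  expect_equal(match_degenerate("GANTC", g1)$start, 1L)

  g2 <- genome_seq("GACTCGAGTC", circular = FALSE)
  expect_equal(match_degenerate("GANTC", g2)$start, c(1L, 6L))

  set.seed(31)
  g <- sim_background(10000)
  hits <- match_degenerate("GANTC", g)
  expect_equal(hits$start, oracle_iupac_starts("GANTC", g))
  # duplex palindrome: one report per duplex site, plus-only equals both
  plus_only <- match_degenerate("GANTC", g, both_strands = FALSE)
  expect_equal(nrow(hits), nrow(plus_only))
  expect_true(all(hits$strand == "+"))

  # non-palindromic pattern reports both strands separately
  hits_np <- match_degenerate("GGANTC", g)
  expect_equal(sort(hits_np$start[hits_np$strand == "+"]),
               oracle_iupac_starts("GGANTC", g, "+"))
  expect_equal(sort(hits_np$start[hits_np$strand == "-"]),
               oracle_iupac_starts("GGANTC", g, "-"))

  expect_error(match_degenerate("GAXTC", g), "invalid IUPAC")
})

test_that("promoter windows follow the strand-mirrored 151 nt layout", {
  w <- promoter_window(938932, "+", genome_length = 4e6)
  expect_equal(c(w$start, w$end), c(938832L, 938982L))
  w2 <- promoter_window(757263, "-", genome_length = 4e6)
  expect_equal(c(w2$start, w2$end), c(757213L, 757363L))
  expect_equal(w$width, 151L)
  expect_equal(w2$width, 151L)

  w3 <- promoter_window(50, "+", genome_length = 1000)
  expect_equal(c(w3$start, w3$end), c(950L, 100L))
  expect_equal(length(sRNAcycle:::interval_positions(w3$start, w3$end, 1000)),
               151L)
  expect_error(promoter_window(0, "+"), "nonpositive")
})

test_that("site counting uses full containment, peaks any overlap", {
  win <- promoter_window(200, "+", genome_length = 1000)  # [100, 250]
  hits <- data.frame(
    motif_id = "m", start = c(110L, 150L, 240L, 245L),
    end = c(119L, 159L, 249L, 254L), strand = "+",
    score = 1, rel_score = 1, seq = "NNNNNNNNNN")
  expect_equal(count_sites_in_window(hits, win, 1000), 3L)
  expect_equal(count_sites_in_window(hits[0, ], win, 1000), 0L)

  peaks <- data.frame(chrom = "chr", start = c(100L, 100L, 251L),
                      end = c(200L, 149L, 400L), label = NA)
  w2 <- promoter_window(200, "+", genome_length = 1000)
  expect_equal(count_peak_overlaps(peaks[1, ], w2, 1000), 1L)
  expect_equal(count_peak_overlaps(peaks[3, ], w2, 1000), 0L)

  set.seed(41)
  n <- 5000L
  rnd_peaks <- sim_peaks(100, n, c(20, 200))
  for (i in 1:10) {
    tss <- sample.int(n, 1)
    w <- promoter_window(tss, sample(c("+", "-"), 1), genome_length = n)
    expect_equal(count_peak_overlaps(rnd_peaks, w, n),
                 oracle_overlap_count(rnd_peaks, w$start, w$end, n))
  }
})

test_that("wrap-aware containment counts planted full sites", {
  set.seed(43)
  pw <- build_pwm(rep("TTGACAGCT", 10), motif_id = "m")
  sg <- sim_genome(3000, list(list(pwm = pw, n = 6, rel_range = c(0.9, 1))))
  hits <- scan_genome(pw, sg$genome, 0.9)
  for (i in 1:4) {
    tss <- sample.int(3000, 1)
    w <- promoter_window(tss, "+", genome_length = 3000)
    pos <- sRNAcycle:::interval_positions(w$start, w$end, 3000)
    manual <- sum(vapply(seq_len(nrow(sg$truth)), function(j) {
      all(sg$truth$start[j]:sg$truth$end[j] %in% pos)
    }, TRUE))
    expect_gte(count_sites_in_window(hits, w, 3000), manual)
  }
})

test_that("loop accessibility is the unpaired fraction of the interval", {
  expect_equal(loop_accessibility("((((....))))", c(5, 8)), 1.0)
  expect_equal(loop_accessibility("((((....))))", c(1, 4)), 0.0)
  expect_equal(loop_accessibility("..((..))..", c(1, 10)), 0.6)
  expect_error(loop_accessibility("((..", c(1, 2)), "unbalanced")
  expect_error(loop_accessibility("....", c(2, 9)), "out of range")
  expect_error(loop_accessibility("..x.", c(1, 2)), "only")
})
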
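# Independent brute-force oracles. These deliberately share no code with
# the package internals: scoring walks the frequency matrix character by
# character, scanning enumerates every window, overlap counting is
# quadratic set intersection.

BASES <- c("A", "C", "G", "T")

# score one window directly from the frequency matrix
oracle_score <- function(f, window) {
  idx <- match(strsplit(toupper(window), "")[[1]], BASES)
  if (anyNA(idx)) return(NA_real_)
  tot <- 0
  for (k in seq_along(idx)) tot <- tot + 2 + log2(f[k, idx[k]])
  unname(tot / length(idx))
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

oracle_window_at <- function(chars, start, L, circular) {
  n <- length(chars)
  idx <- start + 0:(L - 1)
  if (circular) idx <- ((idx - 1) %% n) + 1
  if (any(idx > n)) return(NA_character_)
  paste(chars[idx], collapse = "")
}

# enumerate every window on both strands; returns data.frame start,
# strand, score, rel for windows at/above threshold
oracle_scan <- function(pwm, genome, thr) {
  f <- pwm$f
  L <- nrow(f)
  smax <- mean(apply(2 + log2(f), 1, max))
  chars <- strsplit(genome$sequence, "")[[1]]
  n <- length(chars)
  starts <- if (genome$circular) 1:n else seq_len(n - L + 1)
  out <- list()
  for (st in starts) {
    w <- oracle_window_at(chars, st, L, genome$circular)
    if (is.na(w)) next
    for (strand in c("+", "-")) {
      ws <- if (strand == "+") w else oracle_revcomp(w)
      s <- oracle_score(f, ws)
      if (!is.na(s) && s / smax >= thr - 1e-9) {
        out[[length(out) + 1]] <- data.frame(
          start = st, strand = strand, score = s, rel = s / smax)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric(), rel = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = BASES)

# sliding-window degenerate match start positions on the given strand
oracle_iupac_starts <- function(pattern, genome, strand = "+") {
  pat <- if (strand == "+") pattern else oracle_revcomp(pattern)
  sets <- IUPAC_SETS[strsplit(toupper(pat), "")[[1]]]
  chars <- strsplit(genome$sequence, "")[[1]]
  n <- length(chars)
  L <- length(sets)
  starts <- if (genome$circular) 1:n else seq_len(n - L + 1)
  hits <- integer(0)
  for (st in starts) {
    w <- oracle_window_at(chars, st, L, genome$circular)
    wc <- strsplit(w, "")[[1]]
    ok <- TRUE
    for (k in seq_len(L)) {
      if (!(wc[k] %in% sets[[k]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, st)
  }
  hits
}

# quadratic any-overlap counter over explicit position sets
oracle_overlap_count <- function(peaks, win_start, win_end, n) {
  span <- function(a, b) {
    if (a <= b) a:b else c(a:n, 1:b)
  }
  wpos <- span(win_start, win_end)
  cnt <- 0
  for (i in seq_len(nrow(peaks))) {
    if (length(intersect(span(peaks$start[i], peaks$end[i]), wpos))) {
      cnt <- cnt + 1
    }
  }
  cnt
}

# random PWM from a Dirichlet-ish draw, biased toward a consensus
random_pwm <- function(L, sharp = 2, id = "rand") {
  f <- matrix(0, L, 4, dimnames = list(NULL, BASES))
  for (k in seq_len(L)) {
    a <- stats::rgamma(4, shape = c(sharp, rep(0.5, 3)))
    f[k, ] <- sample(a / sum(a))
  }
  pwm_from_matrix(f, motif_id = id)
}

catalog_profile <- function(catalog, id, mt = NA_integer_) {
  sel <- catalog$ccna == id &
    (is.na(mt) | catalog$multiple_tss %in% mt)
  as.numeric(catalog[which(sel)[1], paste0("t", seq(0, 140, 20))])
}
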
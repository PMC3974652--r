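# Independent oracles used by the tests. These deliberately re-derive
# results by brute force (full DP, enumeration, direct recomputation) and
# must stay independent of the package code paths they check.

# exhaustive Smith-Waterman local alignment; returns identities in the best
# local alignment (affine-ish scoring: gap open applies to every gap column
# opening, extension to the rest)
sw_oracle <- function(pattern, subject, match = 1, mismatch = -1,
                      gap_open = 2, gap_ext = 1) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  n <- length(p); m <- length(s)
  H <- matrix(0, n + 1, m + 1)   # best ending in match/mismatch or 0
  E <- matrix(-Inf, n + 1, m + 1)  # gap in pattern (consume subject)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject (consume pattern)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      sc <- if (p[i - 1] == s[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
      if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
    }
  }
  # traceback to count identities
  ident <- 0L
  i <- bi; j <- bj
  while (i > 1 && j > 1 && H[i, j] > 0) {
    sc <- if (p[i - 1] == s[j - 1]) match else mismatch
    if (H[i, j] == H[i - 1, j - 1] + sc) {
      if (p[i - 1] == s[j - 1]) ident <- ident + 1L
      i <- i - 1; j <- j - 1
    } else if (H[i, j] == E[i, j]) {
      while (j > 1 && E[i, j] != H[i, j - 1] - gap_open - gap_ext &&
             is.finite(E[i, j - 1])) j <- j - 1
      j <- j - 1
    } else {
      while (i > 1 && F[i, j] != H[i - 1, j] - gap_open - gap_ext &&
             is.finite(F[i - 1, j])) i <- i - 1
      i <- i - 1
    }
  }
  list(score = best, identities = ident)
}

# naive sliding-window seed-site scan (direct definition of the predictor)
naive_target_scan <- function(mature, utrs, end_exclusion = 15L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(x) paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
  out <- list()
  for (i in seq_len(nrow(mature))) {
    m <- gsub("U", "T", toupper(mature$seq[i]))
    site <- rc(substr(m, 2, 7))
    m8c <- unname(comp[substr(m, 8, 8)])
    for (tx in names(utrs)) {
      u <- toupper(utrs[[tx]])
      for (p in seq_len(nchar(u) - 5)) {
        if (substr(u, p, p + 5) != site) next
        if (p - 1 < end_exclusion) next
        has_m8 <- p > 1 && !is.na(m8c) && substr(u, p - 1, p - 1) == m8c
        has_1a <- p + 6 <= nchar(u) && substr(u, p + 6, p + 6) == "A"
        cls <- if (has_m8 && has_1a) "8mer" else if (has_m8) "7mer-m8" else
          if (has_1a) "7mer-1A" else "6mer"
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = mature$mature_id[i], transcript_id = tx, position = p,
          site_class = cls, distance_to_utr_start = p - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               position = integer(0), site_class = character(0),
               distance_to_utr_start = integer(0), stringsAsFactors = FALSE)
}

# brute-force reachability components (union-find oracle)
components_oracle <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(edges))) {
    a <- find(edges$from[k]); b <- find(edges$to[k])
    if (a != b) parent[[a]] <- b
  }
  vapply(nodes, find, character(1))
}

# reverse complement for test-side constructions
rc_str <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(toupper(x), "")[[1]]])), collapse = "")
}
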
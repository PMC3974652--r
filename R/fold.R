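#' Scan a sequence for locally stable fold-back structures
#'
#' Slides a window along the sequence (both strands unless `strand`
#' restricts it) and reports, per window, disjoint minimum-free-energy
#' fold-back candidates from the folding engine. The built-in engine is a
#' nearest-neighbor stacking model over nested structures (stacks, hairpin,
#' bulge and internal loops; no multibranch loops) compiled in C++; it is a
#' deterministic surrogate for an external local folder and is pluggable via
#' `engine`.
#'
#' Candidates from overlapping windows sharing more than `dedup_overlap` of
#' the shorter interval collapse to the lowest-energy representative.
#'
#' @param sequence nucleotide string (alphabet ACGTUN; N never pairs).
#' @param window,step sliding-window size and step in nt.
#' @param min_span,max_span candidate span bounds in nt passed to the
#'   engine (loose pre-filter; the hairpin filter applies the real bounds).
#' @param e_cutoff report candidates with energy below this (kcal/mol).
#' @param maxloop largest bulge/internal loop handled by the DP (nt).
#' @param trim_delta outer helix segments contributing more than
#'   `-trim_delta` kcal/mol (i.e. weaker) are trimmed off a candidate;
#'   suppresses accidental background pairing around a genuine stem.
#' @param strand `"both"`, `"+"` or `"-"`.
#' @param dedup_overlap overlap fraction above which overlapping candidates
#'   collapse (default 0.8).
#' @param chrom chromosome name recorded in the output.
#' @param engine a function `(window_sequence) -> data.frame(start, end,
#'   energy, structure)` in window-local 1-based coordinates; defaults to
#'   the built-in engine.
#' @return data.frame of class `hairpin_candidates`: chrom, start, end
#'   (1-based inclusive, on the input sequence), strand, sequence
#'   (strand-oriented), structure (dot-bracket), energy, loops (list column
#'   of unpaired-run lengths).
#' @export
scan_local_structures <- function(sequence, window = 300L, step = 50L,
                                  min_span = 40L, max_span = 250L,
                                  e_cutoff = -5, maxloop = 15L,
                                  trim_delta = 3,
                                  strand = c("both", "+", "-"),
                                  dedup_overlap = 0.8, chrom = "seq",
                                  engine = NULL) {
  strand <- match.arg(strand)
  stopifnot(nchar(sequence) > 0)
  if (window < min_span) stop("window shorter than the minimum hairpin span")
  sequence <- toupper(sequence)
  if (is.null(engine)) {
    engine <- function(s) {
      as.data.frame(fold_window_cpp(s, min_span, max_span, maxloop,
                                    e_cutoff, 10L, trim_delta),
                    stringsAsFactors = FALSE)
    }
  }
  L <- nchar(sequence)
  strands <- switch(strand, both = c("+", "-"), "+" = "+", "-" = "-")
  out <- list()
  for (st in strands) {
    seq_st <- if (st == "+") sequence else revcomp_str(sequence)
    starts <- unique(c(seq(1L, max(1L, L - window + 1L), by = step),
                       max(1L, L - window + 1L)))
    for (w0 in starts) {
      w1 <- min(L, w0 + window - 1L)
      cand <- engine(substr(seq_st, w0, w1))
      if (!nrow(cand)) next
      for (i in seq_len(nrow(cand))) {
        s_local <- w0 + cand$start[i] - 1L   # on the scanned strand
        e_local <- w0 + cand$end[i] - 1L
        if (st == "+") {
          gs <- s_local; ge <- e_local
        } else {
          gs <- L - e_local + 1L; ge <- L - s_local + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = gs, end = ge, strand = st,
          sequence = substr(seq_st, s_local, e_local),
          structure = cand$structure[i], energy = cand$energy[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), sequence = character(0),
               structure = character(0), energy = numeric(0),
               stringsAsFactors = FALSE)
  res <- dedupe_candidates(res, dedup_overlap)
  res$loops <- lapply(res$structure, unpaired_runs)
  rownames(res) <- NULL
  class(res) <- c("hairpin_candidates", "data.frame")
  res
}

# collapse candidates overlapping > frac of the shorter interval (same
# strand) onto the lowest-energy one; overlap pairs found via IRanges so
# genome-scale candidate lists stay O(n log n)
dedupe_candidates <- function(df, frac) {
  if (nrow(df) <= 1) return(df)
  df <- df[order(df$energy), , drop = FALSE]
  ir <- IRanges::IRanges(df$start, df$end)
  hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same <- df$strand[qi] == df$strand[si] & df$chrom[qi] == df$chrom[si]
  qi <- qi[same]; si <- si[same]
  ov <- pmin(df$end[qi], df$end[si]) - pmax(df$start[qi], df$start[si]) + 1L
  wmin <- pmin(df$end[qi] - df$start[qi], df$end[si] - df$start[si]) + 1L
  conflict <- ov > frac * wmin
  qi <- qi[conflict]; si <- si[conflict]
  keep <- rep(TRUE, nrow(df))
  if (length(qi)) {
    # rows are in energy order: walk down, dropping anything that conflicts
    # with an already-kept candidate
    adj <- split(c(si, qi), c(qi, si))
    for (i in seq_len(nrow(df))) {
      if (!keep[i]) next
      nb <- adj[[as.character(i)]]
      if (!is.null(nb)) keep[nb[nb > i]] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

# lengths of maximal unpaired runs in a dot-bracket string
unpaired_runs <- function(structure) {
  r <- rle(strsplit(structure, "")[[1]] == ".")
  r$lengths[r$values]
}

#' Fold a single sequence with the built-in engine
#'
#' Returns the best single fold-back structure over the full sequence as a
#' full-length dot-bracket (positions outside the closed stem are dots).
#' Used to attach structures to reference precursors before feature
#' extraction.
#'
#' @param sequence nucleotide string.
#' @param maxloop largest interior loop handled by the DP.
#' @return list with `structure`, `energy` (kcal/mol), `start`, `end` of the
#'   closed stem.
#' @export
fold_sequence <- function(sequence, maxloop = 15L) {
  stopifnot(nchar(sequence) > 0)
  fold_one_cpp(toupper(sequence), maxloop)
}
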
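#' Triplet-element feature vector
#'
#' Encodes a sequence/structure pair as the classic 32-dimensional triplet
#' feature vector used for pre-miRNA classification: brackets are collapsed
#' to a paired/unpaired state, and for every interior position the
#' (left, self, right) pairing pattern (8 possibilities) is combined with
#' the middle nucleotide's identity (A, C, G, U) and tallied. Counts are
#' normalized to frequencies. Windows whose middle base is N, or containing
#' N in the flanks, are skipped.
#'
#' @param sequence nucleotide string.
#' @param structure dot-bracket string of the same length.
#' @return named numeric vector of length 32 summing to 1 for non-degenerate
#'   input (names like `"A(.("`, nucleotide then left/self/right states).
#' @export
triplet_features <- function(sequence, structure) {
  if (nchar(sequence) != nchar(structure)) {
    stop("sequence/structure length mismatch")
  }
  nt <- strsplit(gsub("U", "T", toupper(sequence)), "")[[1]]
  st <- strsplit(structure, "")[[1]]
  if (!all(st %in% c("(", ")", "."))) stop("invalid dot-bracket structure")
  paired <- ifelse(st == ".", ".", "(")  # collapse bracket orientation

  bases <- c("A", "C", "G", "T")
  pats <- apply(expand.grid(c("(", "."), c("(", "."), c("(", "."),
                            stringsAsFactors = FALSE)[, 3:1], 1, paste,
                collapse = "")
  bins <- as.vector(outer(bases, pats, paste0))
  counts <- stats::setNames(numeric(32), bins)

  n <- length(nt)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      window_nt <- nt[(i - 1):(i + 1)]
      if (any(!window_nt %in% bases)) next  # N never pairs, window skipped
      key <- paste0(nt[i], paired[i - 1], paired[i], paired[i + 1])
      counts[key] <- counts[key] + 1
    }
  }
  tot <- sum(counts)
  if (tot > 0) counts <- counts / tot
  # report with U-style names for readability of RNA work
  names(counts) <- sub("^T", "U", names(counts))
  counts
}
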
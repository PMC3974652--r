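#' Filter small-RNA read alignments
#'
#' Applies the read-cleaning rules used before coverage-based confidence
#' classification: any read with an alignment to an annotated non-miRNA
#' feature (mRNA, tRNA, lncRNA, ...) is discarded entirely; surviving
#' alignments must have at most `max_mismatch` mismatches and the read at
#' most `max_alignments` reported alignments. The operation is idempotent.
#'
#' @param alignments data.frame with read_id, rname, pos, seq, n_mismatch
#'   (a `read_set`, [read_sam()] output, or [align_reads()] output).
#' @param non_mirna character vector of reference names annotated as
#'   non-miRNA transcripts.
#' @param max_mismatch maximum mismatches per alignment (default 2).
#' @param max_alignments maximum alignments per read (default 3).
#' @return the retained alignments.
#' @export
filter_reads <- function(alignments, non_mirna = character(0),
                         max_mismatch = 2L, max_alignments = 3L) {
  req <- c("read_id", "rname", "pos", "seq", "n_mismatch")
  if (!all(req %in% names(alignments))) {
    stop("malformed alignment records: need columns ",
         paste(req, collapse = ", "))
  }
  x <- alignments
  bad_reads <- unique(x$read_id[x$rname %in% non_mirna])
  x <- x[!x$read_id %in% bad_reads, , drop = FALSE]
  x <- x[x$n_mismatch <= max_mismatch, , drop = FALSE]
  n_aln <- table(x$read_id)
  multi <- names(n_aln)[n_aln > max_alignments]
  x <- x[!x$read_id %in% multi, , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Align reads to reference sequences (built-in matcher)
#'
#' A substring matcher with up to `max_mismatch` mismatches (no indels),
#' for synthetic reads when no external aligner/SAM file is involved.
#' Reports every matching position on every reference.
#'
#' @param reads data.frame with read_id and seq, or a named character
#'   vector.
#' @param references named character vector of reference sequences.
#' @param max_mismatch maximum mismatches.
#' @return data.frame: read_id, rname, pos, seq, n_mismatch.
#' @export
align_reads <- function(reads, references, max_mismatch = 2L) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = names(reads), seq = unname(reads),
                        stringsAsFactors = FALSE)
  }
  refs <- Biostrings::DNAStringSet(gsub("U", "T", toupper(references)))
  out <- list()
  for (i in seq_len(nrow(reads))) {
    pat <- Biostrings::DNAString(gsub("U", "T", toupper(reads$seq[i])))
    for (rn in names(refs)) {
      m <- Biostrings::matchPattern(pat, refs[[rn]],
                                    max.mismatch = max_mismatch)
      if (!length(m)) next
      starts <- IRanges::start(m)
      nmm <- vapply(seq_along(m), function(k) {
        sum(strsplit(as.character(m[[k]]), "")[[1]] !=
              strsplit(as.character(pat), "")[[1]])
      }, integer(1))
      out[[length(out) + 1L]] <- data.frame(
        read_id = reads$read_id[i], rname = rn, pos = starts,
        seq = reads$seq[i], n_mismatch = nmm, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), rname = character(0), pos = integer(0),
               seq = character(0), n_mismatch = integer(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Per-nucleotide coverage of a hairpin
#'
#' Depth semantics: every retained alignment contributes to every position
#' it covers, and the mature coverage is the arithmetic mean depth over the
#' mature interval (coverage of the mature sequence is a per-base notion).
#'
#' @param alignments retained alignments ([filter_reads()]).
#' @param hairpin_id reference name of the hairpin.
#' @param hairpin_length hairpin length in nt.
#' @param mature_interval length-2 integer vector, 1-based inclusive within
#'   the hairpin.
#' @return object of class `coverage_profile`: list with hairpin_id, depth
#'   (integer vector), mature_interval, mature_mean_coverage.
#' @export
coverage_profile <- function(alignments, hairpin_id, hairpin_length,
                             mature_interval) {
  stopifnot(length(mature_interval) == 2L,
            mature_interval[1] <= mature_interval[2])
  if (mature_interval[1] < 1 || mature_interval[2] > hairpin_length) {
    stop("mature interval outside hairpin")
  }
  depth <- integer(hairpin_length)
  a <- alignments[alignments$rname == hairpin_id, , drop = FALSE]
  for (i in seq_len(nrow(a))) {
    s <- max(1L, a$pos[i])
    e <- min(hairpin_length, a$pos[i] + nchar(a$seq[i]) - 1L)
    if (s <= e) depth[s:e] <- depth[s:e] + 1L
  }
  structure(list(
    hairpin_id = hairpin_id, depth = depth,
    mature_interval = as.integer(mature_interval),
    mature_mean_coverage = mean(depth[mature_interval[1]:mature_interval[2]])
  ), class = "coverage_profile")
}

#' Confidence label from mature coverage
#'
#' `high` iff mean mature coverage >= 10, `medium` iff >= 3 and < 10,
#' `low` otherwise (hairpins supported only by the array assay).
#'
#' @param profile a [coverage_profile()] result, or a bare numeric mean
#'   coverage.
#' @return data.frame: label (factor low < medium < high),
#'   mature_mean_coverage.
#' @export
classify_confidence <- function(profile) {
  cov <- if (inherits(profile, "coverage_profile")) {
    profile$mature_mean_coverage
  } else as.numeric(profile)
  label <- ifelse(cov >= 10, "high", ifelse(cov >= 3, "medium", "low"))
  data.frame(label = factor(label, levels = c("low", "medium", "high"),
                            ordered = TRUE),
             mature_mean_coverage = cov)
}
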
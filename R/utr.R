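#' Drop redundant transcript clusters
#'
#' A cluster (e.g. an EST/UniGene-style feature) is discarded iff its
#' aligned interval overlaps an annotated transcript by strictly more than
#' `overlap_threshold` of the *cluster's* length; an overlap of exactly the
#' threshold is kept.
#'
#' @param clusters data.frame with id, chrom, start, end (1-based
#'   inclusive).
#' @param annotated data.frame with chrom, start, end.
#' @param overlap_threshold fraction of the cluster length (default 0.4).
#' @return the retained clusters.
#' @export
dedupe_transcripts <- function(clusters, annotated, overlap_threshold = 0.4) {
  if (!nrow(clusters)) return(clusters)
  keep <- vapply(seq_len(nrow(clusters)), function(i) {
    len <- clusters$end[i] - clusters$start[i] + 1L
    ann <- annotated[annotated$chrom == clusters$chrom[i], , drop = FALSE]
    if (!nrow(ann)) return(TRUE)
    ov <- pmin(clusters$end[i], ann$end) - pmax(clusters$start[i], ann$start) + 1L
    max(c(ov, 0L)) / len <= overlap_threshold
  }, logical(1))
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive a 3'UTR from an alignment chain
#'
#' Chains co-linear alignment blocks whose inter-block gaps do not exceed
#' `max_gap`, picks the most extended chain (largest aligned length, then
#' largest genomic span), and returns the genomic tail covering the last
#' `tail_len` nucleotides toward the transcript 3' end (strand-aware: the
#' right end on "+", the left end on "-").
#'
#' @param blocks data.frame with chrom, start, end (1-based inclusive) and
#'   optionally strand (single value; default "+"). Blocks are one
#'   transcript's high-scoring alignment segments.
#' @param max_gap largest allowed gap between consecutive blocks (nt;
#'   default 50 kb).
#' @param tail_len UTR tail length (nt; default 894).
#' @param transcript_id id recorded in the output.
#' @return data.frame (one row): transcript_id, source, chrom, start, end,
#'   strand. `source` is "tail-894"-style when the tail was clipped,
#'   "annotated" when the chain is shorter than `tail_len`.
#' @export
derive_utr <- function(blocks, max_gap = 50000L, tail_len = 894L,
                       transcript_id = "tx") {
  if (!nrow(blocks)) stop("no alignment blocks")
  strand <- if (!is.null(blocks$strand)) blocks$strand[1] else "+"
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  # partition into maximal co-linear chains under the gap rule
  gap <- blocks$start[-1] - blocks$end[-nrow(blocks)] - 1L
  chain_id <- cumsum(c(1L, as.integer(gap > max_gap)))
  chains <- split(seq_len(nrow(blocks)), chain_id)
  alen <- vapply(chains, function(ix) {
    sum(as.numeric(blocks$end[ix] - blocks$start[ix] + 1))
  }, numeric(1))
  span <- vapply(chains, function(ix) {
    as.numeric(max(blocks$end[ix]) - min(blocks$start[ix]) + 1)
  }, numeric(1))
  best <- chains[[order(-alen, -span)[1]]]
  cs <- min(blocks$start[best]); ce <- max(blocks$end[best])
  clen <- ce - cs + 1L
  if (clen > tail_len) {
    if (strand == "+") cs <- ce - tail_len + 1L else ce <- cs + tail_len - 1L
    src <- paste0("tail-", tail_len)
  } else {
    src <- "annotated"
  }
  data.frame(transcript_id = transcript_id, source = src,
             chrom = blocks$chrom[1], start = cs, end = ce, strand = strand,
             stringsAsFactors = FALSE)
}
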
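#' File input/output helpers
#'
#' Thin wrappers around the standard formats used by the pipeline: FASTA
#' (via Biostrings), TSV, BED (1-based inclusive intervals are converted to
#' 0-based half-open on write) and a minimal text SAM reader/writer for the
#' small-RNA alignment path.
#'
#' @name io
NULL

#' @rdname io
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(gsub("U", "T", toupper(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname io
#' @param df data.frame to write.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param intervals data.frame with columns chrom, start, end (1-based
#'   inclusive), name, score, strand.
#' @export
write_bed <- function(intervals, path) {
  bed <- data.frame(
    chrom = intervals$chrom,
    start = intervals$start - 1L,  # 0-based half-open
    end = intervals$end,
    name = if (!is.null(intervals$name)) intervals$name else ".",
    score = if (!is.null(intervals$score)) intervals$score else 0,
    strand = if (!is.null(intervals$strand)) intervals$strand else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a read set as text SAM
#'
#' Emits a minimal valid SAM file: `@HD`/`@SQ` header lines and one
#' 11-column record per read (flag 0, MAPQ 255, full-length match CIGAR)
#' plus an `NM` tag carrying the mismatch count.
#'
#' @param reads a `read_set` data.frame ([generate_reads()]).
#' @param ref_lengths named integer vector: length of each reference
#'   sequence named in `reads$rname`.
#' @param path output file.
#' @export
write_sam <- function(reads, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (rn in names(ref_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", rn, ref_lengths[[rn]]), con)
  }
  if (nrow(reads)) {
    rec <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                   reads$read_id, reads$rname, reads$pos,
                   nchar(reads$seq), reads$seq, reads$n_mismatch)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read a text SAM file into an alignment table
#'
#' Minimal parser for the 11 mandatory columns plus the `NM` tag. Unmapped
#' reads (flag bit 0x4) are dropped; secondary alignments (0x100) are kept
#' and flagged, since multi-mapper handling is a filtering decision
#' downstream.
#'
#' @param path SAM file.
#' @return data.frame: read_id, flag, rname, pos, seq, n_mismatch,
#'   secondary.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(read_id = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      seq = character(0), n_mismatch = integer(0),
                      secondary = logical(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 11L
  if (any(bad)) stop("malformed alignment records at lines: ",
                     paste(utils::head(which(bad)), collapse = ", "))
  nm <- vapply(parts, function(p) {
    tag <- grep("^NM:i:", p[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else 0L
  }, integer(1))
  flag <- as.integer(vapply(parts, `[`, character(1), 2L))
  out <- data.frame(
    read_id = vapply(parts, `[`, character(1), 1L),
    flag = flag,
    rname = vapply(parts, `[`, character(1), 3L),
    pos = as.integer(vapply(parts, `[`, character(1), 4L)),
    seq = vapply(parts, `[`, character(1), 10L),
    n_mismatch = nm,
    secondary = bitwAnd(flag, 0x100L) > 0L,
    stringsAsFactors = FALSE)
  out[bitwAnd(out$flag, 0x4L) == 0L, , drop = FALSE]
}
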
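#' Simulate small-RNA reads from planted mature sequences
#'
#' Draws full-length reads from each mature sequence with Poisson counts
#' (mean `coverage_mean`; full-length reads make the read count equal the
#' per-nt coverage), applies uniform per-site mismatches, and adds decoy
#' reads sampled from decoy regions so that the "discard reads mapping to
#' non-miRNA transcripts" rule is exercisable. Truth alignments follow SAM
#' conventions (1-based leftmost position on the named reference).
#'
#' @param mature_set data.frame as from [mature_set_from_genome()].
#' @param coverage_mean expected reads per mature.
#' @param mismatch_rate per-site probability of a read mismatch.
#' @param decoy_fraction expected decoy reads as a fraction of mature reads.
#' @param genome optional [generate_genome()] result supplying decoy regions
#'   (required when `decoy_fraction > 0`).
#' @param rng_seed seed.
#' @return An object of class `read_set`: data.frame with read_id, seq,
#'   rname (source reference: hairpin_id or decoy_id), pos (1-based within
#'   source), n_mismatch, source_class ("mature"/"decoy").
#' @export
generate_reads <- function(mature_set, coverage_mean, mismatch_rate = 0,
                           decoy_fraction = 0, genome = NULL, rng_seed = 1L) {
  stopifnot(is.data.frame(mature_set), coverage_mean >= 0,
            mismatch_rate >= 0, mismatch_rate <= 1, decoy_fraction >= 0)
  set.seed(rng_seed)
  rows <- list()
  n_tot <- 0L
  for (i in seq_len(nrow(mature_set))) {
    n <- stats::rpois(1L, coverage_mean)
    if (n == 0L) next
    for (r in seq_len(n)) {
      chars <- strsplit(mature_set$seq[i], "")[[1]]
      mut <- mutate_chars(chars, mismatch_rate)
      n_tot <- n_tot + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("read%06d", n_tot),
        seq = paste(mut, collapse = ""),
        rname = mature_set$hairpin_id[i],
        pos = mature_set$start_in_hairpin[i],
        n_mismatch = sum(mut != chars),
        source_class = "mature", stringsAsFactors = FALSE)
    }
  }
  if (decoy_fraction > 0) {
    if (is.null(genome) || nrow(genome$decoy_truth) == 0) {
      stop("decoy_fraction > 0 requires a genome with decoy regions")
    }
    n_decoy <- stats::rpois(1L, decoy_fraction * max(n_tot, 1L))
    dt <- genome$decoy_truth
    rl <- if (nrow(mature_set)) nchar(mature_set$seq[1]) else 22L
    for (r in seq_len(n_decoy)) {
      d <- sample.int(nrow(dt), 1L)
      dl <- nchar(dt$sequence[d])
      if (dl < rl) next
      p <- sample.int(dl - rl + 1L, 1L)
      n_tot <- n_tot + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("read%06d", n_tot),
        seq = substr(dt$sequence[d], p, p + rl - 1L),
        rname = dt$decoy_id[d], pos = p, n_mismatch = 0L,
        source_class = "decoy", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), seq = character(0),
               rname = character(0), pos = integer(0),
               n_mismatch = integer(0), source_class = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}
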
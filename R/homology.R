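#' Scan a genome for conserved pre-miRNAs
#'
#' For each reference precursor, finds the best local alignment to either
#' genome strand and calls the locus conserved iff (i) the alignment
#' identity, expressed as identities divided by the full precursor length,
#' is at least `min_similarity` percent, and (ii) the seed (positions 2-7 of
#' an annotated mature) aligns identity-perfect and gap-free. Similarity is
#' deliberately normalized by the whole precursor length, so partial
#' coverage is penalized.
#'
#' Multiple loci per precursor are found by masking each accepted locus with
#' Ns and re-aligning (up to `max_hits` times); loci overlapping a previous,
#' higher-similarity hit by more than half of either interval are dropped.
#'
#' @param reference a [generate_reference_set()] result, or any data.frame
#'   with columns precursor_id, precursor, mature_start, species (optional).
#' @param genome named character vector of chromosome sequences, or a
#'   [generate_genome()] result.
#' @param min_similarity retention threshold in percent (default 50).
#' @param match,mismatch,gap_opening,gap_extension local-alignment scoring
#'   (gap penalties positive, as in Biostrings).
#' @param max_hits maximum loci reported per precursor.
#' @return data.frame of class `conservation_hits`: reference_id, species,
#'   chrom, start, end, strand, similarity_pct, seed_exact.
#' @export
conserved_scan <- function(reference, genome, min_similarity = 50,
                           match = 1, mismatch = -1,
                           gap_opening = 2, gap_extension = 1,
                           max_hits = 3L) {
  seqs <- if (inherits(genome, "planted_genome")) {
    c(genome = genome$sequence)
  } else {
    stopifnot(is.character(genome), !is.null(names(genome)))
    genome
  }
  ref <- as.data.frame(reference)
  if (is.null(ref$species)) ref$species <- "unknown"
  # one row per precursor, with the seed positions of all annotated matures
  prec <- unique(ref[, c("precursor_id", "precursor", "species")])
  mat_len <- if (!is.null(ref$mature)) nchar(ref$mature[1]) else 22L
  short <- nchar(prec$precursor) < mat_len
  if (any(short)) {
    stop("precursor shorter than its annotated mature: ",
         paste(prec$precursor_id[short], collapse = ", "))
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)

  hits <- list()
  for (i in seq_len(nrow(prec))) {
    pid <- prec$precursor_id[i]
    pseq <- gsub("U", "T", toupper(prec$precursor[i]))
    seed_starts <- ref$mature_start[ref$precursor_id == pid] + 1L  # pos 2..7
    found <- list()
    for (chrom in names(seqs)) {
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") seqs[[chrom]] else revcomp_str(seqs[[chrom]])
        L <- nchar(subj)
        for (h in seq_len(max_hits)) {
          hit <- best_local_hit(pseq, subj, submat, gap_opening, gap_extension,
                                seed_starts)
          if (is.null(hit) || hit$similarity < min_similarity) break
          gstart <- hit$sstart; gend <- hit$send
          if (strand == "-") {
            gstart <- L - hit$send + 1L
            gend <- L - hit$sstart + 1L
          }
          found[[length(found) + 1L]] <- data.frame(
            reference_id = pid, species = prec$species[i], chrom = chrom,
            start = gstart, end = gend, strand = strand,
            similarity_pct = hit$similarity, seed_exact = hit$seed_exact,
            stringsAsFactors = FALSE)
          # mask and re-align for further loci
          substr(subj, hit$sstart, hit$send) <-
            paste(rep("N", hit$send - hit$sstart + 1L), collapse = "")
        }
      }
    }
    if (!length(found)) next
    fd <- do.call(rbind, found)
    fd <- fd[fd$similarity_pct >= min_similarity & fd$seed_exact, , drop = FALSE]
    hits[[length(hits) + 1L]] <- dedupe_hits(fd)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(reference_id = character(0), species = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), similarity_pct = numeric(0),
               seed_exact = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("conservation_hits", "data.frame")
  out
}

# best local alignment of pattern against subject; similarity is identities
# over full pattern length; seed_exact checks a gap-free perfect 6-mer at
# any of the given pattern seed start positions
best_local_hit <- function(pseq, subj, submat, gap_opening, gap_extension,
                           seed_starts) {
  aln <- Biostrings::pairwiseAlignment(
    pseq, subj, type = "local", substitutionMatrix = submat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  if (Biostrings::score(aln) <= 0) return(NULL)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  p0 <- IRanges::start(Biostrings::pattern(aln))
  n_ident <- sum(pat == sub & pat != "-")
  similarity <- 100 * n_ident / nchar(pseq)
  # map pattern positions -> alignment column / subject char / gap status
  ppos <- cumsum(pat != "-") + p0 - 1L
  seed_exact <- FALSE
  for (st in seed_starts) {
    cols <- which(ppos %in% st:(st + 5L) & pat != "-")
    if (length(cols) != 6L) next
    if (any(diff(cols) != 1L)) next                     # inserted gap inside seed
    if (all(pat[cols] == sub[cols]) && !any(sub[cols] == "-")) {
      seed_exact <- TRUE
      break
    }
  }
  list(similarity = similarity, seed_exact = seed_exact,
       sstart = IRanges::start(Biostrings::subject(aln)),
       send = IRanges::end(Biostrings::subject(aln)))
}

# overlap > 50% of either interval collapses to the higher-similarity hit
dedupe_hits <- function(fd) {
  if (nrow(fd) <= 1) return(fd)
  fd <- fd[order(-fd$similarity_pct), , drop = FALSE]
  keep <- rep(TRUE, nrow(fd))
  for (i in seq_len(nrow(fd) - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):nrow(fd)) {
      if (!keep[j] || fd$chrom[i] != fd$chrom[j]) next
      ov <- min(fd$end[i], fd$end[j]) - max(fd$start[i], fd$start[j]) + 1L
      if (ov <= 0) next
      wi <- fd$end[i] - fd$start[i] + 1L
      wj <- fd$end[j] - fd$start[j] + 1L
      if (ov > 0.5 * min(wi, wj)) keep[j] <- FALSE
    }
  }
  fd[keep, , drop = FALSE]
}

#' Per-species conservation counts
#'
#' @param hits a [conserved_scan()] result.
#' @param reference the reference collection the scan used (grouped by its
#'   `species` column).
#' @param distances named numeric vector of phylogenetic distances, one per
#'   species.
#' @return data.frame: species, n_reference, n_conserved, fraction_conserved,
#'   phylo_distance. Species with zero references are excluded.
#' @export
conservation_by_species <- function(hits, reference, distances) {
  ref <- as.data.frame(reference)
  species <- unique(ref$species)
  rows <- lapply(species, function(sp) {
    precs <- unique(ref$precursor_id[ref$species == sp])
    if (!length(precs)) return(NULL)
    n_cons <- length(unique(hits$reference_id[hits$reference_id %in% precs]))
    data.frame(species = sp, n_reference = length(precs),
               n_conserved = n_cons,
               fraction_conserved = n_cons / length(precs),
               phylo_distance = unname(distances[sp]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation of conservation with phylogenetic distance
#'
#' Sample Pearson correlation between `phylo_distance` and
#' `fraction_conserved` over species records.
#'
#' @param records a [conservation_by_species()] result.
#' @return Pearson r.
#' @export
conservation_distance_correlation <- function(records) {
  stopifnot(nrow(records) >= 3)
  if (stats::sd(records$phylo_distance) == 0 ||
      stats::sd(records$fraction_conserved) == 0) {
    stop("correlation undefined: constant distances or fractions")
  }
  stats::cor(records$phylo_distance, records$fraction_conserved)
}
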
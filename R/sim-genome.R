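#' Generate a genome with planted hairpins and decoys
#'
#' Builds a random background sequence and plants (i) canonical pre-miRNA
#' stem-loops (a perfect inverted repeat around a terminal loop, then
#' point-mutated at `mutation_rate`) and (ii) decoy elements: tRNA-like
#' cloverleafs (several short stems, many loops) and CDS-like open reading
#' frames (codon-structured, weakly structured sequence). Every planted
#' element is recorded in a truth table; the generators never emit untracked
#' signal.
#'
#' Coordinates are 1-based and inclusive throughout the package. Planted
#' mature sequences are the first `mature_length` nt of the 5' arm (the 5p
#' mature) and the last `mature_length` nt of the 3' arm (the 3p mature),
#' recorded in genome coordinates.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `planted_genome`: a list with elements
#'   `sequence` (character scalar), `hairpin_truth` (data.frame: hairpin_id,
#'   start, end, strand, m5p_start, m5p_end, m3p_start, m3p_end, precursor),
#'   `decoy_truth` (data.frame: decoy_id, start, end, class, sequence) and
#'   `config`.
#' @export
#' @examples
#' g <- generate_genome(sim_config(rng_seed = 1, n_hairpins = 3,
#'                                 genome_length = 20000, n_decoys = 2))
#' g$hairpin_truth
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$rng_seed, "genome"))

  hp <- lapply(seq_len(config$n_hairpins), function(i) build_hairpin(config, i))
  dc <- lapply(seq_len(config$n_decoys), function(i) build_decoy(config, i))
  elements <- c(hp, dc)
  lens <- vapply(elements, function(e) nchar(e$seq), integer(1))
  n_el <- length(elements)
  slack <- config$genome_length - sum(lens)
  if (slack < n_el) {
    stop("planted elements exceed sequence capacity: need ",
         sum(lens) + n_el, " nt, genome is ", config$genome_length, " nt")
  }

  # random placement: shuffle elements, split the slack into n_el + 1 gaps
  ord <- sample.int(n_el)
  cuts <- sort(sample.int(slack, n_el))
  gaps <- diff(c(0L, cuts))  # first n_el gaps; remainder is the tail

  pieces <- character(0)
  hp_rows <- list(); dc_rows <- list()
  pos <- 0L
  for (k in seq_len(n_el)) {
    gap <- gaps[k]
    pieces <- c(pieces, rand_seq(gap))
    pos <- pos + gap
    el <- elements[[ord[k]]]
    start <- pos + 1L
    end <- pos + nchar(el$seq)
    if (el$kind == "hairpin") {
      hp_rows[[length(hp_rows) + 1L]] <- hairpin_truth_row(el, start, end)
    } else {
      dc_rows[[length(dc_rows) + 1L]] <- data.frame(
        decoy_id = el$id, start = start, end = end, class = el$class,
        sequence = el$seq, stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, el$planted)
    pos <- end
  }
  pieces <- c(pieces, rand_seq(config$genome_length - pos))

  hairpin_truth <- if (length(hp_rows)) {
    df <- do.call(rbind, hp_rows)
    df[order(df$start), , drop = FALSE]
  } else empty_hairpin_truth()
  decoy_truth <- if (length(dc_rows)) {
    df <- do.call(rbind, dc_rows)
    df[order(df$start), , drop = FALSE]
  } else {
    data.frame(decoy_id = character(0), start = integer(0), end = integer(0),
               class = character(0), sequence = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(hairpin_truth) <- NULL
  rownames(decoy_truth) <- NULL

  structure(list(
    sequence = paste(pieces, collapse = ""),
    hairpin_truth = hairpin_truth,
    decoy_truth = decoy_truth,
    config = config
  ), class = "planted_genome")
}

empty_hairpin_truth <- function() {
  data.frame(hairpin_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), m5p_start = integer(0), m5p_end = integer(0),
             m3p_start = integer(0), m3p_end = integer(0),
             precursor = character(0), stringsAsFactors = FALSE)
}

rand_seq <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# A canonical hairpin: left arm, terminal loop, revcomp(left arm), then
# point mutations over the whole precursor. `seq` is the precursor 5'->3';
# `planted` is what goes into the + genome strand (revcomp when strand "-").
build_hairpin <- function(config, i) {
  s <- sample(seq(config$stem_length_range[1], config$stem_length_range[2]), 1L)
  l <- sample(seq(config$loop_length_range[1], config$loop_length_range[2]), 1L)
  left <- sample(DNA_BASES, s, replace = TRUE)
  loop <- sample(DNA_BASES, l, replace = TRUE)
  chars <- c(left, loop, revcomp_chars(left))
  chars <- mutate_chars(chars, config$mutation_rate)
  seq <- paste(chars, collapse = "")
  strand <- sample(c("+", "-"), 1L)
  list(kind = "hairpin", id = sprintf("hp%03d", i), seq = seq,
       planted = if (strand == "+") seq else revcomp_str(seq),
       strand = strand, stem = s, loop = l,
       mature_length = config$mature_length)
}

hairpin_truth_row <- function(el, start, end) {
  L <- nchar(el$seq)
  ml <- el$mature_length
  # precursor-relative mature intervals: 5p = 1..ml, 3p = (L-ml+1)..L
  if (el$strand == "+") {
    m5p <- c(start, start + ml - 1L)
    m3p <- c(end - ml + 1L, end)
  } else {
    # precursor position p maps to genome position end - p + 1
    m5p <- c(end - ml + 1L, end)
    m3p <- c(start, start + ml - 1L)
  }
  data.frame(hairpin_id = el$id, start = start, end = end, strand = el$strand,
             m5p_start = m5p[1], m5p_end = m5p[2],
             m3p_start = m3p[1], m3p_end = m3p[2],
             precursor = el$seq, stringsAsFactors = FALSE)
}

build_decoy <- function(config, i) {
  class <- if (i %% 2L == 1L) "tRNA-like" else "CDS-like"
  if (class == "tRNA-like") {
    # cloverleaf: acceptor stem plus three short arm stems with 7-8 nt loops
    acc <- sample(DNA_BASES, 7L, replace = TRUE)
    arms <- lapply(1:3, function(a) {
      st <- sample(DNA_BASES, sample(4:5, 1L), replace = TRUE)
      lp <- sample(DNA_BASES, sample(7:8, 1L), replace = TRUE)
      c(st, lp, revcomp_chars(st))
    })
    spacer <- function() sample(DNA_BASES, sample(1:3, 1L), replace = TRUE)
    chars <- c(acc, spacer(), arms[[1]], spacer(), arms[[2]], spacer(),
               arms[[3]], spacer(), revcomp_chars(acc))
    seq <- paste(chars, collapse = "")
  } else {
    # codon-structured sequence with a biased third position, start/stop
    n_codon <- sample(50:90, 1L)
    first <- sample(DNA_BASES, n_codon, replace = TRUE, prob = c(.3, .2, .3, .2))
    second <- sample(DNA_BASES, n_codon, replace = TRUE)
    third <- sample(DNA_BASES, n_codon, replace = TRUE, prob = c(.15, .35, .35, .15))
    seq <- paste0("ATG", paste(rbind(first, second, third), collapse = ""), "TAA")
  }
  list(kind = "decoy", id = sprintf("decoy%03d", i), class = class,
       seq = seq, planted = seq)
}

#' @export
print.planted_genome <- function(x, ...) {
  cat("Planted genome: ", nchar(x$sequence), " nt, ",
      nrow(x$hairpin_truth), " hairpins, ", nrow(x$decoy_truth),
      " decoys\n", sep = "")
  invisible(x)
}

#' Extract the planted mature set of a genome
#'
#' Returns one row per planted mature sequence (both arms of every planted
#' hairpin), with the mature sequence in transcript orientation and its
#' 1-based start within the precursor.
#'
#' @param genome a [generate_genome()] result.
#' @return data.frame: mature_id, hairpin_id, arm, seq, start_in_hairpin,
#'   seed (mature positions 2-7).
#' @export
mature_set_from_genome <- function(genome) {
  stopifnot(inherits(genome, "planted_genome"))
  tr <- genome$hairpin_truth
  ml <- genome$config$mature_length
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    L <- nchar(tr$precursor[i])
    m5 <- substr(tr$precursor[i], 1L, ml)
    m3 <- substr(tr$precursor[i], L - ml + 1L, L)
    data.frame(
      mature_id = paste0(tr$hairpin_id[i], "-", c("5p", "3p")),
      hairpin_id = tr$hairpin_id[i], arm = c("5p", "3p"),
      seq = c(m5, m3), start_in_hairpin = c(1L, L - ml + 1L),
      seed = c(substr(m5, 2L, 7L), substr(m3, 2L, 7L)),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mature_id = character(0), hairpin_id = character(0),
               arm = character(0), seq = character(0),
               start_in_hairpin = integer(0), seed = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a "foreign species" reference pre-miRNA collection
#'
#' For each planted hairpin, emits one homolog per divergence level: the
#' precursor mutated at the given per-site rate, with the seed (positions
#' 2-7 of both planted matures) left intact iff `preserve_seed`. This
#' emulates a cross-species miRNA reference collection with known
#' evolutionary distances.
#'
#' @param genome a [generate_genome()] result.
#' @param divergence_levels numeric vector of per-site mutation
#'   probabilities in `[0, 1]`; one pseudo-species per level.
#' @param preserve_seed logical; keep seed positions untouched.
#' @param species_names optional character names for the pseudo-species.
#' @param rng_seed seed (defaults to a sub-seed of the genome's config).
#' @return An object of class `mir_reference`: a data.frame with columns
#'   species, divergence, precursor_id, source_hairpin, precursor, arm,
#'   mature, mature_start (1-based within precursor), seed.
#' @export
generate_reference_set <- function(genome, divergence_levels,
                                   preserve_seed = TRUE,
                                   species_names = NULL,
                                   rng_seed = NULL) {
  stopifnot(inherits(genome, "planted_genome"),
            all(divergence_levels >= 0), all(divergence_levels <= 1))
  if (is.null(rng_seed)) rng_seed <- sub_seed(genome$config$rng_seed, "reference")
  set.seed(rng_seed)
  if (is.null(species_names)) {
    species_names <- sprintf("species_%02d", seq_along(divergence_levels))
  }
  stopifnot(length(species_names) == length(divergence_levels))
  tr <- genome$hairpin_truth
  ml <- genome$config$mature_length
  rows <- list()
  for (d in seq_along(divergence_levels)) {
    for (i in seq_len(nrow(tr))) {
      chars <- strsplit(tr$precursor[i], "")[[1]]
      L <- length(chars)
      keep <- if (preserve_seed) c(2:7, (L - ml + 2L):(L - ml + 7L)) else integer(0)
      hom <- mutate_chars(chars, divergence_levels[d], keep = keep)
      hom_seq <- paste(hom, collapse = "")
      for (arm in c("5p", "3p")) {
        mstart <- if (arm == "5p") 1L else L - ml + 1L
        mature <- substr(hom_seq, mstart, mstart + ml - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          species = species_names[d], divergence = divergence_levels[d],
          precursor_id = paste0(species_names[d], "-", tr$hairpin_id[i]),
          source_hairpin = tr$hairpin_id[i], precursor = hom_seq, arm = arm,
          mature = mature, mature_start = mstart,
          seed = substr(mature, 2L, 7L), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mir_reference", "data.frame")
  out
}
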
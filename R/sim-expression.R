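#' Simulate matched miRNA / mRNA / lincRNA tissue expression
#'
#' Builds three expression matrices sharing the same tissue columns, with
#' planted structure achieved by construction (shared latent profile + sign
#' flip + noise, not rejection sampling):
#'
#' * planted (miRNA, target mRNA) pairs have expected Pearson correlation
#'   `planted_target_correlation` (negative);
#' * planted (lincRNA sponge, miRNA) pairs have the mirrored positive
#'   expected correlation;
#' * all non-planted profiles are independent.
#'
#' With latent `z ~ N(0,1)` and independent noise of variance `s^2` on both
#' members, `cor(z + e1, -z + e2) = -1/(1 + s^2)`, so `s^2 = -1/r - 1`
#' yields the requested expected correlation exactly; `r = -1` gives `s = 0`
#' and a sample correlation of exactly -1.
#'
#' The generator also emits a random mRNA-mRNA interaction edge list, a
#' random mature sequence per miRNA, and one 3'UTR per mRNA containing an
#' exact seed-complement site for each planted regulator (placed at least
#' `site_min_pos` nt from the UTR 5' boundary), so that target prediction,
#' anti-correlation filtering and network construction can all be evaluated
#' against planted truth.
#'
#' @param config a [sim_config()]; supplies `n_tissues`, `noise_sd` is not
#'   used here (expression noise is set by the correlation construction),
#'   and `planted_target_correlation`.
#' @param n_mirna,n_mrna,n_linc entity counts.
#' @param n_planted_pairs planted miRNA-target pairs (each mRNA targeted by
#'   at most one planted miRNA).
#' @param n_sponges planted lincRNA-miRNA sponge pairs.
#' @param n_edges random mRNA-mRNA interaction edges.
#' @param utr_length 3'UTR length in nt.
#' @param site_min_pos minimum 1-based UTR position of a planted seed site.
#' @param rng_seed optional seed override.
#' @return An object of class `tissue_sim`: list with matrices `mirna`,
#'   `mrna`, `lincrna` (rows entities, columns tissues), `mature`
#'   (data.frame: mature_id, seq, seed), `utrs` (named character vector),
#'   `pairs`, `sponges`, `edges` (data.frames), `config`.
#' @export
generate_tissue_expression <- function(config,
                                       n_mirna = 20L, n_mrna = 100L,
                                       n_linc = 10L, n_planted_pairs = 30L,
                                       n_sponges = 5L, n_edges = 150L,
                                       utr_length = 500L, site_min_pos = 50L,
                                       rng_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  nt <- config$n_tissues
  if (nt < 3) stop("fewer than 3 tissues: correlation is degenerate")
  r <- config$planted_target_correlation
  stopifnot(n_planted_pairs <= n_mrna, n_sponges <= min(n_linc, n_mirna))
  if (is.null(rng_seed)) rng_seed <- sub_seed(config$rng_seed, "expression")
  set.seed(rng_seed)

  tissues <- sprintf("tissue_%02d", seq_len(nt))
  mir_ids <- sprintf("miR-%03d", seq_len(n_mirna))
  mrna_ids <- sprintf("gene%04d", seq_len(n_mrna))
  linc_ids <- sprintf("linc%03d", seq_len(n_linc))

  s2 <- if (r == 0) Inf else -1 / r - 1  # noise variance for E[cor] = r
  noise <- function() if (is.finite(s2)) stats::rnorm(nt, 0, sqrt(s2)) else
    stats::rnorm(nt, 0, 1)

  mirna <- matrix(stats::rnorm(n_mirna * nt), n_mirna, nt,
                  dimnames = list(mir_ids, tissues))
  mrna <- matrix(stats::rnorm(n_mrna * nt), n_mrna, nt,
                 dimnames = list(mrna_ids, tissues))
  lincrna <- matrix(stats::rnorm(n_linc * nt), n_linc, nt,
                    dimnames = list(linc_ids, tissues))

  # planted targeting pairs: targets drawn without replacement
  pair_mirna <- sample(mir_ids, n_planted_pairs, replace = TRUE)
  pair_target <- sample(mrna_ids, n_planted_pairs, replace = FALSE)
  latent <- matrix(stats::rnorm(n_mirna * nt), n_mirna, nt,
                   dimnames = list(mir_ids, tissues))
  planted_mirs <- unique(pair_mirna)
  if (r < 0) {
    for (m in planted_mirs) mirna[m, ] <- latent[m, ] + noise()
    for (p in seq_len(n_planted_pairs)) {
      mrna[pair_target[p], ] <- -latent[pair_mirna[p], ] + noise()
    }
  }

  sponge_linc <- sample(linc_ids, n_sponges)
  sponge_mir <- sample(planted_mirs, n_sponges,
                       replace = n_sponges > length(planted_mirs))
  if (r < 0) {
    for (p in seq_len(n_sponges)) {
      lincrna[sponge_linc[p], ] <- latent[sponge_mir[p], ] + noise()
    }
  }

  # shift to a microarray-like log2 scale (does not change correlations)
  mirna <- mirna + 8; mrna <- mrna + 8; lincrna <- lincrna + 8

  edges <- unique(data.frame(
    a = sample(mrna_ids, n_edges, replace = TRUE),
    b = sample(mrna_ids, n_edges, replace = TRUE),
    stringsAsFactors = FALSE))
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  rownames(edges) <- NULL

  mature <- data.frame(
    mature_id = mir_ids,
    seq = vapply(seq_len(n_mirna), function(i) rand_seq(22L), character(1)),
    stringsAsFactors = FALSE)
  mature$seed <- substr(mature$seq, 2L, 7L)

  utrs <- vapply(seq_len(n_mrna), function(i) rand_seq(utr_length), character(1))
  names(utrs) <- mrna_ids
  for (p in seq_len(n_planted_pairs)) {
    site <- revcomp_str(mature$seed[match(pair_mirna[p], mature$mature_id)])
    pos <- sample(seq(site_min_pos, utr_length - nchar(site) - 10L), 1L)
    u <- utrs[[pair_target[p]]]
    substr(u, pos, pos + nchar(site) - 1L) <- site
    utrs[[pair_target[p]]] <- u
  }

  structure(list(
    mirna = mirna, mrna = mrna, lincrna = lincrna,
    mature = mature, utrs = utrs,
    pairs = data.frame(mirna = pair_mirna, target = pair_target,
                       stringsAsFactors = FALSE),
    sponges = data.frame(lincrna = sponge_linc, mirna = sponge_mir,
                         stringsAsFactors = FALSE),
    edges = edges, config = config
  ), class = "tissue_sim")
}

#' @export
print.tissue_sim <- function(x, ...) {
  cat("Tissue simulation: ", nrow(x$mirna), " miRNAs, ", nrow(x$mrna),
      " mRNAs, ", nrow(x$lincrna), " lincRNAs x ", ncol(x$mirna),
      " tissues; ", nrow(x$pairs), " planted pairs, ", nrow(x$sponges),
      " sponges\n", sep = "")
  invisible(x)
}
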
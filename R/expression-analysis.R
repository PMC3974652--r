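#' Hierarchical tissue clustering with resampling support
#'
#' Clusters the sample (tissue) columns with average linkage on the
#' 1 - Pearson correlation distance, then estimates node support by
#' resampling the features (rows) with replacement `n_resamples` times and
#' counting how often each leaf bipartition of the original tree recurs
#' (via [ape::prop.clades()]).
#'
#' @param matrix entities x samples expression matrix (>= 2 samples).
#' @param n_resamples number of feature resamplings (default 200).
#' @param rng_seed seed.
#' @return list of class `tissue_clustering`: `hclust` (the tree),
#'   `support` (per-internal-node fraction in `[0, 1]`, in
#'   [ape::prop.clades()] node order), `n_resamples`.
#' @export
cluster_tissues <- function(matrix, n_resamples = 200L, rng_seed = 1L) {
  if (ncol(matrix) < 2) stop("need >= 2 samples to cluster")
  set.seed(rng_seed)
  cluster_once <- function(m) {
    cc <- stats::cor(m)
    cc[is.na(cc)] <- 0  # zero-variance resampled column: treat as unrelated
    stats::hclust(stats::as.dist(1 - cc), method = "average")
  }
  hc <- cluster_once(matrix)
  phy <- ape::as.phylo(hc)
  reps <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    rows <- sample.int(nrow(matrix), replace = TRUE)
    reps[[b]] <- ape::as.phylo(cluster_once(matrix[rows, , drop = FALSE]))
  }
  counts <- ape::prop.clades(phy, reps, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  structure(list(hclust = hc, phylo = phy,
                 support = counts / n_resamples,
                 n_resamples = as.integer(n_resamples)),
            class = "tissue_clustering")
}

#' Arm-dominance profiles for hairpins with both arms quantified
#'
#' For each hairpin with quantified 5p and 3p matures, computes the
#' per-tissue log2 ratio 5p/3p and the Pearson correlation of the two arm
#' profiles. Below-detection (`NA`) entries propagate as missing; hairpins
#' lacking either arm are skipped.
#'
#' @param mature_matrix matures x tissues matrix; row names must follow the
#'   underscore ID convention ending in `_5p`/`_3p` (or be given as
#'   `<hairpin>-5p`).
#' @return list: `ratios` (hairpins x tissues log2(5p/3p) matrix),
#'   `correlations` (named numeric, cross-arm Pearson r).
#' @export
arm_ratio_profiles <- function(mature_matrix) {
  ids <- rownames(mature_matrix)
  arm <- ifelse(grepl("[_-]5p$", ids), "5p",
                ifelse(grepl("[_-]3p$", ids), "3p", NA))
  hp <- sub("[_-][53]p$", "", ids)
  ok_hp <- intersect(hp[arm == "5p" & !is.na(arm)],
                     hp[arm == "3p" & !is.na(arm)])
  if (!length(ok_hp)) {
    return(list(ratios = matrix(numeric(0), 0, ncol(mature_matrix)),
                correlations = stats::setNames(numeric(0), character(0))))
  }
  ratios <- t(vapply(ok_hp, function(h) {
    x5 <- mature_matrix[which(hp == h & arm == "5p")[1], ]
    x3 <- mature_matrix[which(hp == h & arm == "3p")[1], ]
    log2(x5 / x3)
  }, numeric(ncol(mature_matrix))))
  colnames(ratios) <- colnames(mature_matrix)
  correlations <- vapply(ok_hp, function(h) {
    x5 <- mature_matrix[which(hp == h & arm == "5p")[1], ]
    x3 <- mature_matrix[which(hp == h & arm == "3p")[1], ]
    ok <- is.finite(x5) & is.finite(x3)
    if (sum(ok) < 3 || stats::sd(x5[ok]) == 0 || stats::sd(x3[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(x5[ok], x3[ok])
  }, numeric(1))
  list(ratios = ratios, correlations = correlations)
}

#' Hypergeometric miRNA-family enrichment
#'
#' One-sided hypergeometric tail probability of observing at least the
#' realized number of family members in the subset, per family. Families
#' with no members in the universe are skipped.
#'
#' @param subset character vector of miRNA ids (must be contained in the
#'   universe).
#' @param families named list: family -> character vector of member ids.
#' @param universe character vector of all miRNA ids considered.
#' @return data.frame: family, n_universe, n_subset, p_value.
#' @export
family_enrichment <- function(subset, families, universe) {
  if (!all(subset %in% universe)) stop("subset not contained in universe")
  N <- length(unique(universe))
  n <- length(unique(subset))
  rows <- lapply(names(families), function(fam) {
    members <- intersect(families[[fam]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, subset))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(family = fam, n_universe = K, n_subset = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect lincRNA sponge candidates
#'
#' Reports (lincRNA, miRNA) pairs whose expression profiles correlate at
#' least `threshold` (Pearson) across the shared tissues — the signature
#' expected of a transcript sequestering a miRNA.
#'
#' @param lincrna_matrix,mirna_matrix matrices with shared tissue columns.
#' @param threshold positive correlation cut (default 0.9).
#' @return data.frame: lincrna, mirna, pearson_r.
#' @export
sponge_candidates <- function(lincrna_matrix, mirna_matrix, threshold = 0.9) {
  if (!identical(colnames(lincrna_matrix), colnames(mirna_matrix))) {
    stop("tissue mismatch between lincRNA and miRNA matrices")
  }
  r <- stats::cor(t(lincrna_matrix), t(mirna_matrix))
  idx <- which(r >= threshold - 1e-12, arr.ind = TRUE)  # fp-safe at r = 1
  out <- data.frame(lincrna = rownames(lincrna_matrix)[idx[, 1]],
                    mirna = rownames(mirna_matrix)[idx[, 2]],
                    pearson_r = r[idx], stringsAsFactors = FALSE)
  out <- out[order(-out$pearson_r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantile-normalize an expression matrix
#'
#' After normalization every column shares the identical sorted value
#' distribution (each column's sorted values equal the row-wise means of
#' the sorted input columns). Backed by [limma::normalizeQuantiles()].
#'
#' @param matrix entities x samples matrix.
#' @return normalized matrix, same shape and dimnames.
#' @export
quantile_normalize <- function(matrix) {
  out <- limma::normalizeQuantiles(matrix)
  dimnames(out) <- dimnames(matrix)
  out
}
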
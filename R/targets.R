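#' Predict seed-match target sites in 3'UTRs
#'
#' Scans each UTR (5'->3') for exact reverse complements of each miRNA
#' seed (mature positions 2-7). A site at UTR positions `p..p+5` pairs the
#' seed antiparallel; it is classified by its flanks:
#'
#' * `8mer`: the base 5' of the site (position p-1) pairs mature position 8
#'   *and* the base 3' of the site (position p+6) is an A;
#' * `7mer-m8`: only the position-8 match;
#' * `7mer-1A`: only the 3' A;
#' * `6mer`: neither.
#'
#' Sites whose distance from the UTR 5' boundary (`p - 1`) is below
#' `end_exclusion` are removed — sites too close to the stop codon are not
#' considered functional.
#'
#' @param mature data.frame with mature_id (or id_string) and seq columns,
#'   or a named character vector of mature sequences.
#' @param utrs named character vector of UTR sequences.
#' @param end_exclusion minimum distance (nt) from the UTR start (default
#'   15).
#' @param site_classes classes to report.
#' @return data.frame of class `target_sites`: mirna_id, transcript_id,
#'   position (1-based in UTR), site_class, distance_to_utr_start.
#' @export
predict_targets <- function(mature, utrs, end_exclusion = 15L,
                            site_classes = c("6mer", "7mer-1A", "7mer-m8",
                                             "8mer")) {
  if (is.character(mature)) {
    mature <- data.frame(mature_id = names(mature), seq = unname(mature),
                         stringsAsFactors = FALSE)
  }
  if (is.null(mature$mature_id)) mature$mature_id <- mature$id_string
  stopifnot(!is.null(names(utrs)))
  out <- list()
  for (i in seq_len(nrow(mature))) {
    mseq <- gsub("U", "T", toupper(mature$seq[i]))
    seed <- substr(mseq, 2L, 7L)
    if (grepl("[^ACGT]", seed)) stop("degenerate (non-ACGT) seed for ",
                                     mature$mature_id[i])
    site <- revcomp_str(seed)
    m8 <- substr(mseq, 8L, 8L)
    m8c <- if (m8 %in% DNA_BASES) revcomp_str(m8) else ""
    for (tx in names(utrs)) {
      u <- gsub("U", "T", toupper(utrs[[tx]]))
      hits <- find_all_fixed(u, site)
      for (p in hits) {
        left <- if (p > 1) substr(u, p - 1L, p - 1L) else ""
        right <- if (p + 6L <= nchar(u)) substr(u, p + 6L, p + 6L) else ""
        has_m8 <- nzchar(m8c) && left == m8c
        has_1a <- right == "A"
        cls <- if (has_m8 && has_1a) "8mer" else if (has_m8) "7mer-m8" else
          if (has_1a) "7mer-1A" else "6mer"
        if (!cls %in% site_classes) next
        dist <- p - 1L
        if (dist < end_exclusion) next
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = mature$mature_id[i], transcript_id = tx, position = p,
          site_class = cls, distance_to_utr_start = dist,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               position = integer(0), site_class = character(0),
               distance_to_utr_start = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("target_sites", "data.frame")
  res
}

# all (possibly overlapping) start positions of fixed pattern in text
find_all_fixed <- function(text, pattern) {
  res <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(pattern, substr(text, from, nchar(text)), fixed = TRUE)
    if (p < 0) break
    res <- c(res, from + as.integer(p) - 1L)
    from <- from + as.integer(p)
  }
  res
}

#' Filter predicted targets by expression anti-correlation
#'
#' For each predicted (miRNA, transcript) pair, computes the sample Pearson
#' correlation of their expression profiles across the shared tissue
#' columns; the pair passes iff `r <= threshold`. Pairs with a
#' zero-variance profile (correlation undefined) are excluded.
#'
#' @param sites a [predict_targets()] result (or any data.frame with
#'   mirna_id and transcript_id).
#' @param mirna_matrix,mrna_matrix matrices, rows entities x columns
#'   tissues; columns must agree.
#' @param threshold anti-correlation cut (default -0.7).
#' @return data.frame of class `filtered_targets`: the site columns plus
#'   pearson_r and passes.
#' @export
anticorrelation_filter <- function(sites, mirna_matrix, mrna_matrix,
                                   threshold = -0.7) {
  if (!identical(colnames(mirna_matrix), colnames(mrna_matrix))) {
    stop("tissue mismatch between miRNA and mRNA matrices")
  }
  if (ncol(mirna_matrix) < 3) stop("need >= 3 tissues")
  pairs <- unique(sites[, c("mirna_id", "transcript_id")])
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- mirna_matrix[pairs$mirna_id[i], ]
    y <- mrna_matrix[pairs$transcript_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  pairs$pearson_r <- r
  pairs <- pairs[!is.na(r), , drop = FALSE]
  pairs$passes <- pairs$pearson_r <= threshold
  out <- merge(sites, pairs, by = c("mirna_id", "transcript_id"))
  out <- out[order(out$mirna_id, out$transcript_id, out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("filtered_targets", "data.frame")
  out
}
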
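#' Leave-one-out bootstrap endpoint probability
#'
#' For a probe group of k fluorescence values, holds out the value at
#' `index` and draws `n_boot` simulated groups of size k-1 by sampling the
#' k-1 remaining values with replacement. The returned probability is the
#' fraction of simulated groups whose mean fluorescence is strictly lower
#' than the held-out value: a probe well above its group background gets a
#' probability near 1.
#'
#' @param group_values numeric vector of one replicate's probe group
#'   (length >= 3).
#' @param index held-out probe position.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @return probability in `[0, 1]`.
#' @export
endpoint_bootstrap <- function(group_values, index, n_boot = 10000L) {
  k <- length(group_values)
  if (k < 3) stop("group size must be >= 3")
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (index < 1 || index > k) stop("index out of range")
  boot_prob_cpp(group_values[-index], group_values[index], as.integer(n_boot))
}

#' Call mature endpoints from a tiling experiment
#'
#' Runs the leave-one-out bootstrap on every probe of every group and
#' replicate, then calls a position iff its probability exceeds the
#' end-type threshold (0.75 for 3' ends, 0.65 for 5' ends by default) in
#' all replicates (`consensus = "all"`, the default; `"majority"` is
#' available behind the flag). For 5' groups, positions passing the relaxed
#' 0.58 threshold in all replicates without reaching the strict one are
#' emitted flagged `low_stringency`. Multiple calls per group are allowed
#' (alternative ends).
#'
#' The bootstrap RNG is seeded per (hairpin, arm, replicate) from
#' `master_seed`, so calls are reproducible regardless of group order.
#'
#' @param experiment a [generate_tiling()] result, or its `tiling`
#'   data.frame.
#' @param thresholds named list: `"3prime"`, `"5prime"`, `relaxed_5prime`.
#' @param required_replicates named list: minimum replicate count per end
#'   type (defaults 4 for 3', 3 for 5').
#' @param n_boot bootstrap resamples per probe.
#' @param master_seed master RNG seed.
#' @param consensus `"all"` or `"majority"`.
#' @return data.frame of class `endpoint_calls`: hairpin_id, arm, end_type,
#'   probe_offset, position, probability (minimum across replicates),
#'   mean_fluor, n_replicates_passing, low_stringency.
#' @export
call_endpoints <- function(experiment,
                           thresholds = list("3prime" = 0.75,
                                             "5prime" = 0.65,
                                             relaxed_5prime = 0.58),
                           required_replicates = list("3prime" = 4L,
                                                      "5prime" = 3L),
                           n_boot = 10000L, master_seed = 1L,
                           consensus = c("all", "majority")) {
  consensus <- match.arg(consensus)
  tiling <- if (inherits(experiment, "tiling_experiment")) experiment$tiling
            else experiment
  stopifnot(all(c("hairpin_id", "arm", "end_type", "probe_offset",
                  "replicate", "fluorescence") %in% names(tiling)))
  if (is.null(tiling$pos)) tiling$pos <- tiling$probe_offset

  groups <- unique(tiling[, c("hairpin_id", "arm", "end_type")])
  out <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- tiling$hairpin_id == groups$hairpin_id[g] &
      tiling$arm == groups$arm[g] & tiling$end_type == groups$end_type[g]
    gt <- tiling[sel, , drop = FALSE]
    end_type <- groups$end_type[g]
    thr <- thresholds[[end_type]]
    if (is.null(thr)) stop("no threshold for end type ", end_type)
    req <- required_replicates[[end_type]]
    reps <- sort(unique(gt$replicate))
    if (length(reps) < req) {
      stop("replicate count ", length(reps), " below required ", req,
           " for ", end_type, " calls")
    }
    offs <- sort(unique(gt$probe_offset))
    k <- length(offs)
    pmat <- matrix(NA_real_, k, length(reps))
    fmat <- matrix(NA_real_, k, length(reps))
    for (ri in seq_along(reps)) {
      vals <- gt$fluorescence[gt$replicate == reps[ri]][order(
        gt$probe_offset[gt$replicate == reps[ri]])]
      set.seed(group_seed(master_seed, groups$hairpin_id[g],
                          groups$arm[g], reps[ri]))
      pmat[, ri] <- boot_group_cpp(vals, as.integer(n_boot))
      fmat[, ri] <- vals
    }
    need <- if (consensus == "all") length(reps) else ceiling(length(reps) / 2)
    n_pass <- rowSums(pmat > thr)
    called <- n_pass >= need
    low <- rep(FALSE, k)
    if (end_type == "5prime" && !is.null(thresholds$relaxed_5prime)) {
      n_relax <- rowSums(pmat > thresholds$relaxed_5prime)
      low <- !called & (n_relax >= need)
      called <- called | low
    }
    if (!any(called)) next
    idx <- which(called)
    pos_map <- gt$pos[match(offs, gt$probe_offset)]
    out[[length(out) + 1L]] <- data.frame(
      hairpin_id = groups$hairpin_id[g], arm = groups$arm[g],
      end_type = end_type, probe_offset = offs[idx],
      position = pos_map[idx],
      probability = apply(pmat[idx, , drop = FALSE], 1, min),
      mean_fluor = rowMeans(fmat[idx, , drop = FALSE]),
      n_replicates_passing = n_pass[idx],
      low_stringency = low[idx], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(hairpin_id = character(0), arm = character(0),
               end_type = character(0), probe_offset = integer(0),
               position = integer(0), probability = numeric(0),
               mean_fluor = numeric(0), n_replicates_passing = integer(0),
               low_stringency = logical(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("endpoint_calls", "data.frame")
  res
}

# deterministic per-(hairpin, arm, replicate) bootstrap seed
group_seed <- function(master_seed, hairpin_id, arm, replicate) {
  h <- sum(utf8ToInt(paste(hairpin_id, arm, sep = "/")) *
             seq_along(utf8ToInt(paste(hairpin_id, arm, sep = "/"))))
  (as.integer(master_seed) * 48271L + h * 131L + as.integer(replicate)) %%
    2147483399L
}

#' Reconstruct mature miRNAs from endpoint calls
#'
#' Pairs every 5' call with every 3' call on the same hairpin arm; pairs
#' whose implied mature length falls inside `length_window` become mature
#' calls. Per arm, the pair with the highest joint probability (product of
#' the two call probabilities) is the canonical mature; remaining pairs are
#' isomiRs pointing at it. Ties are broken by higher combined mean
#' fluorescence, then by the 5'-most position. When both arms of a hairpin
#' yield a canonical call, each is annotated with its miRNA* partner.
#'
#' Mature IDs follow the underscore convention
#' `prefix_chrom_start_stop_strand_arm` built from the *hairpin* interval,
#' e.g. `P_16_68474541_68474601_+_5p`.
#'
#' @param calls an `endpoint_calls` data.frame (rbind the 3' and 5' assay
#'   calls).
#' @param hairpins data.frame with hairpin_id, start, end, strand and
#'   optionally precursor (sequence) and chrom.
#' @param length_window allowed mature length range in nt.
#' @param prefix ID prefix (default "P", de-novo prediction).
#' @return data.frame of class `mature_calls`: hairpin_id, arm, five_prime,
#'   three_prime, length, sequence, seed, id_string, probability, canonical,
#'   isomiR_of, star_partner.
#' @export
reconstruct_mature <- function(calls, hairpins, length_window = c(18L, 26L),
                               prefix = "P") {
  stopifnot(all(c("hairpin_id", "arm", "end_type", "position",
                  "probability") %in% names(calls)))
  if (is.null(hairpins$chrom)) hairpins$chrom <- "1"
  unknown <- setdiff(unique(calls$hairpin_id), hairpins$hairpin_id)
  if (length(unknown)) stop("calls reference unknown hairpins: ",
                            paste(unknown, collapse = ", "))
  out <- list()
  arms <- unique(calls[, c("hairpin_id", "arm")])
  for (a in seq_len(nrow(arms))) {
    hp <- hairpins[hairpins$hairpin_id == arms$hairpin_id[a], , drop = FALSE]
    c5 <- calls[calls$hairpin_id == arms$hairpin_id[a] &
                  calls$arm == arms$arm[a] & calls$end_type == "5prime", ]
    c3 <- calls[calls$hairpin_id == arms$hairpin_id[a] &
                  calls$arm == arms$arm[a] & calls$end_type == "3prime", ]
    if (!nrow(c5) || !nrow(c3)) next
    pairs <- expand.grid(i5 = seq_len(nrow(c5)), i3 = seq_len(nrow(c3)))
    for (p in seq_len(nrow(pairs))) {
      p5 <- c5$position[pairs$i5[p]]; p3 <- c3$position[pairs$i3[p]]
      if (hp$strand == "+" && p5 > p3) next
      if (hp$strand == "-" && p5 < p3) next
      len <- abs(p3 - p5) + 1L
      if (len < length_window[1] || len > length_window[2]) next
      lo <- min(p5, p3); hi <- max(p5, p3)
      if (lo < hp$start || hi > hp$end) next  # call exits its hairpin
      seq <- mature_sequence(hp, p5, p3)
      out[[length(out) + 1L]] <- data.frame(
        hairpin_id = hp$hairpin_id, arm = arms$arm[a],
        five_prime = p5, three_prime = p3, length = len, sequence = seq,
        seed = if (is.na(seq)) NA_character_ else substr(seq, 2L, 7L),
        id_string = paste(prefix, hp$chrom, hp$start, hp$end, hp$strand,
                          arms$arm[a], sep = "_"),
        probability = c5$probability[pairs$i5[p]] * c3$probability[pairs$i3[p]],
        mean_fluor = (c5$mean_fluor[pairs$i5[p]] %||% 0) +
          (c3$mean_fluor[pairs$i3[p]] %||% 0),
        strand = hp$strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    res <- data.frame(hairpin_id = character(0), arm = character(0),
                      five_prime = integer(0), three_prime = integer(0),
                      length = integer(0), sequence = character(0),
                      seed = character(0), id_string = character(0),
                      probability = numeric(0), mean_fluor = numeric(0),
                      strand = character(0), canonical = logical(0),
                      isomiR_of = character(0), star_partner = character(0),
                      stringsAsFactors = FALSE)
    class(res) <- c("mature_calls", "data.frame")
    return(res)
  }
  res <- do.call(rbind, out)
  # canonical selection per (hairpin, arm), deterministic ordering
  key <- paste(res$hairpin_id, res$arm)
  res$canonical <- FALSE
  for (k in unique(key)) {
    idx <- which(key == k)
    ord <- idx[order(-res$probability[idx], -res$mean_fluor[idx],
                     res$five_prime[idx])]
    res$canonical[ord[1]] <- TRUE
  }
  canon_key <- paste(res$hairpin_id[res$canonical], res$arm[res$canonical])
  canon_id <- stats::setNames(res$id_string[res$canonical], canon_key)
  res$isomiR_of <- ifelse(res$canonical, NA_character_,
                          unname(canon_id[key]))
  other_arm <- ifelse(res$arm == "5p", "3p", "5p")
  res$star_partner <- unname(canon_id[paste(res$hairpin_id, other_arm)])
  rownames(res) <- NULL
  class(res) <- c("mature_calls", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

# extract the mature sequence (transcript orientation) from the precursor
mature_sequence <- function(hp, p5, p3) {
  if (is.null(hp$precursor) || is.na(hp$precursor)) return(NA_character_)
  if (hp$strand == "+") {
    substr(hp$precursor, p5 - hp$start + 1L, p3 - hp$start + 1L)
  } else {
    substr(hp$precursor, hp$end - p5 + 1L, hp$end - p3 + 1L)
  }
}
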
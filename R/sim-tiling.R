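#' Simulate a tiling-array endpoint-mapping experiment
#'
#' Emulates the array design used to map mature miRNA ends: for each hairpin
#' arm, a tiling of single-nucleotide-shifted probes interrogates candidate
#' end positions (22 probes for the 3'-end assay, 16 for the 5'-end assay).
#' The probe matching the planted mature end fluoresces at
#' `background_fluor * signal_fold`; all values carry multiplicative
#' log-normal noise of standard deviation `noise_sd` (log scale). A spike-in
#' titration series spanning 1e-18 to 1e-14 mol is appended, with
#' log-log-linear fluorescence response.
#'
#' @param genome a [generate_genome()] result.
#' @param end `"3p-assay"` (22 probes per arm, maps 3' ends) or `"5p-assay"`
#'   (16 probes per arm, maps 5' ends).
#' @param replicates number of independent replicate arrays (>= 1).
#' @param config a [sim_config()]; defaults to the genome's own.
#' @param rng_seed optional seed override.
#' @return An object of class `tiling_experiment`: list with `tiling`
#'   (data.frame: hairpin_id, arm, end_type, probe_offset, pos, replicate,
#'   fluorescence), `spikes` (amount_mol, replicate, fluorescence), `truth`
#'   (hairpin_id, arm, end_type, true_offset, true_pos), `end`, `replicates`,
#'   `config`.
#' @export
generate_tiling <- function(genome, end = c("3p-assay", "5p-assay"),
                            replicates = 4L, config = genome$config,
                            rng_seed = NULL) {
  stopifnot(inherits(genome, "planted_genome"))
  end <- match.arg(end)
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.null(rng_seed)) {
    rng_seed <- sub_seed(config$rng_seed,
                         if (end == "3p-assay") "tiling3" else "tiling5")
  }
  set.seed(rng_seed)

  k <- if (end == "3p-assay") 22L else 16L
  end_type <- if (end == "3p-assay") "3prime" else "5prime"
  tr <- genome$hairpin_truth
  B <- log(config$background_fluor)
  lf <- log(config$signal_fold)

  tl <- list(); truth <- list()
  for (i in seq_len(nrow(tr))) {
    for (arm in c("5p", "3p")) {
      # genomic coordinate of the interrogated end of this arm's mature
      ends <- mature_end_coords(tr[i, ], arm)
      true_pos <- if (end_type == "3prime") ends["e3"] else ends["e5"]
      dir <- if (tr$strand[i] == "+") 1L else -1L
      true_offset <- sample.int(k, 1L)
      pos <- true_pos + (seq_len(k) - true_offset) * dir
      mu <- rep(B, k)
      mu[true_offset] <- mu[true_offset] + lf
      for (r in seq_len(replicates)) {
        fl <- exp(mu + stats::rnorm(k, 0, config$noise_sd))
        tl[[length(tl) + 1L]] <- data.frame(
          hairpin_id = tr$hairpin_id[i], arm = arm, end_type = end_type,
          probe_offset = seq_len(k), pos = as.integer(pos), replicate = r,
          fluorescence = fl, stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        hairpin_id = tr$hairpin_id[i], arm = arm, end_type = end_type,
        true_offset = true_offset, true_pos = as.integer(true_pos),
        stringsAsFactors = FALSE)
    }
  }

  # spike-in series: log-log linear response, eight points per decade range
  amounts <- 10^seq(-18, -14, length.out = 8)
  sp <- list()
  for (r in seq_len(replicates)) {
    lfl <- 22 + log10(amounts)  # 1e-18 mol -> 1e4 fluorescence units
    fl <- 10^(lfl + stats::rnorm(length(amounts), 0, config$noise_sd / log(10)))
    sp[[r]] <- data.frame(amount_mol = amounts, replicate = r,
                          fluorescence = fl)
  }

  structure(list(
    tiling = if (length(tl)) do.call(rbind, tl) else NULL,
    spikes = do.call(rbind, sp),
    truth = if (length(truth)) do.call(rbind, truth) else NULL,
    end = end, replicates = as.integer(replicates), config = config
  ), class = "tiling_experiment")
}

# genomic coordinates of the 5' and 3' transcript ends of one arm's mature
mature_end_coords <- function(row, arm) {
  a <- if (arm == "5p") c(row$m5p_start, row$m5p_end) else
    c(row$m3p_start, row$m3p_end)
  if (row$strand == "+") c(e5 = a[1], e3 = a[2]) else c(e5 = a[2], e3 = a[1])
}

#' @export
print.tiling_experiment <- function(x, ...) {
  cat("Tiling experiment (", x$end, "): ",
      if (is.null(x$tiling)) 0L else length(unique(paste(x$tiling$hairpin_id, x$tiling$arm))),
      " probe groups x ", x$replicates, " replicates\n", sep = "")
  invisible(x)
}
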
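#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Identical
#' configurations (including `rng_seed`) produce bit-identical outputs from
#' every generator in the package.
#'
#' @param rng_seed integer master seed; all generator randomness derives
#'   from it.
#' @param n_hairpins number of canonical pre-miRNA stem-loops planted in the
#'   genome.
#' @param genome_length total genome length in nt.
#' @param n_decoys number of decoy elements (split between tRNA-like
#'   cloverleafs and CDS-like open reading frames).
#' @param stem_length_range integer range (nt) for planted stem arms.
#' @param loop_length_range integer range (nt) for planted terminal loops.
#' @param mature_length length of planted mature miRNAs (nt).
#' @param mutation_rate per-site probability of a point mutation applied to a
#'   planted hairpin after its perfect stem is built.
#' @param noise_sd standard deviation of log-fluorescence noise
#'   (multiplicative log-normal noise, the microarray convention).
#' @param signal_fold fold-change of the probe matching a planted mature end
#'   over background fluorescence.
#' @param background_fluor background fluorescence level of the simulated
#'   arrays.
#' @param coverage_mean mean sequencing depth (reads per mature nt; reads are
#'   full-length so this is also the expected read count per mature).
#' @param n_tissues number of tissue columns in simulated expression
#'   matrices.
#' @param planted_target_correlation expected Pearson correlation of planted
#'   miRNA-target expression pairs, in `[-1, 0)`.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(rng_seed = 7, n_hairpins = 5, genome_length = 20000)
sim_config <- function(rng_seed = 1L,
                       n_hairpins = 20L,
                       genome_length = 100000L,
                       n_decoys = 20L,
                       stem_length_range = c(30L, 45L),
                       loop_length_range = c(4L, 15L),
                       mature_length = 22L,
                       mutation_rate = 0.05,
                       noise_sd = 0.3,
                       signal_fold = 10,
                       background_fluor = 5e4,
                       coverage_mean = 20,
                       n_tissues = 14L,
                       planted_target_correlation = -0.9) {
  stopifnot(
    length(rng_seed) == 1L, is.finite(rng_seed),
    n_hairpins >= 0, genome_length > 0, n_decoys >= 0,
    length(stem_length_range) == 2L, stem_length_range[1] <= stem_length_range[2],
    stem_length_range[1] >= 10,
    length(loop_length_range) == 2L, loop_length_range[1] <= loop_length_range[2],
    loop_length_range[1] >= 3,
    mature_length >= 16, mature_length <= 2 * stem_length_range[1],
    mutation_rate >= 0, mutation_rate <= 1,
    noise_sd >= 0, signal_fold > 0, background_fluor > 0,
    coverage_mean >= 0, n_tissues >= 1,
    planted_target_correlation >= -1, planted_target_correlation <= 0
  )
  structure(list(
    rng_seed = as.integer(rng_seed),
    n_hairpins = as.integer(n_hairpins),
    genome_length = as.integer(genome_length),
    n_decoys = as.integer(n_decoys),
    stem_length_range = as.integer(stem_length_range),
    loop_length_range = as.integer(loop_length_range),
    mature_length = as.integer(mature_length),
    mutation_rate = mutation_rate,
    noise_sd = noise_sd,
    signal_fold = signal_fold,
    background_fluor = background_fluor,
    coverage_mean = coverage_mean,
    n_tissues = as.integer(n_tissues),
    planted_target_correlation = planted_target_correlation
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config (seed ", x$rng_seed, "): ",
      x$n_hairpins, " hairpins + ", x$n_decoys, " decoys in ",
      x$genome_length, " nt; ", x$n_tissues, " tissues\n", sep = "")
  invisible(x)
}

# internal: derive a sub-seed for a generator stage from the master seed.
# Offsets keep stages independent while staying below .Machine$integer.max.
sub_seed <- function(seed, stage) {
  offsets <- c(genome = 11L, reference = 23L, tiling3 = 37L, tiling5 = 41L,
               reads = 53L, expression = 67L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483587L
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[x]))
}

revcomp_str <- function(s) {
  paste(revcomp_chars(strsplit(s, "")[[1]]), collapse = "")
}

# mutate character vector at per-site rate, never to the same base;
# positions in `keep` are left untouched
mutate_chars <- function(x, rate, keep = integer(0)) {
  if (rate <= 0) return(x)
  hit <- which(stats::runif(length(x)) < rate)
  hit <- setdiff(hit, keep)
  for (i in hit) {
    x[i] <- sample(setdiff(DNA_BASES, x[i]), 1L)
  }
  x
}
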
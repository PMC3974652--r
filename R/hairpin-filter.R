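#' Hairpin filter configuration
#'
#' The canonical pre-miRNA filter: candidates are retained when strictly
#' longer than `min_len_exclusive`, strictly shorter than
#' `max_len_exclusive`, with free energy strictly below
#' `max_energy_exclusive` and at most `max_loops` loops. A loop is an
#' unpaired run of `loop_len_range[1]` to `loop_len_range[2]` nt (terminal
#' loop, internal-loop side or bulge alike); runs longer than the upper
#' bound disqualify the candidate outright, runs shorter than the lower
#' bound are ignored.
#'
#' @param min_len_exclusive,max_len_exclusive length bounds in nt (both
#'   strict).
#' @param max_energy_exclusive free-energy bound in kcal/mol (strict).
#' @param max_loops maximum number of counted loops.
#' @param loop_len_range unpaired-run length range counted as a loop.
#' @return list of class `hairpin_filter_config`.
#' @export
hairpin_filter_config <- function(min_len_exclusive = 54L,
                                  max_len_exclusive = 217L,
                                  max_energy_exclusive = -27,
                                  max_loops = 2L,
                                  loop_len_range = c(3L, 30L)) {
  stopifnot(min_len_exclusive < max_len_exclusive,
            length(loop_len_range) == 2L,
            loop_len_range[1] <= loop_len_range[2], max_loops >= 0)
  structure(list(min_len_exclusive = as.integer(min_len_exclusive),
                 max_len_exclusive = as.integer(max_len_exclusive),
                 max_energy_exclusive = max_energy_exclusive,
                 max_loops = as.integer(max_loops),
                 loop_len_range = as.integer(loop_len_range)),
            class = "hairpin_filter_config")
}

#' Apply the canonical pre-miRNA filters
#'
#' @param candidates a `hairpin_candidates` data.frame
#'   ([scan_local_structures()]), or any data.frame with `sequence`,
#'   `structure` and `energy` columns.
#' @param config a [hairpin_filter_config()].
#' @return the retained subset, same class as the input.
#' @export
filter_hairpins <- function(candidates, config = hairpin_filter_config()) {
  stopifnot(inherits(config, "hairpin_filter_config"))
  if (!nrow(candidates)) return(candidates)
  len <- nchar(candidates$sequence)
  runs <- lapply(candidates$structure, unpaired_runs)
  n_loops <- vapply(runs, function(r) {
    if (any(r > config$loop_len_range[2])) return(NA_integer_)  # giant loop
    sum(r >= config$loop_len_range[1])
  }, integer(1))
  ok <- len > config$min_len_exclusive &
    len < config$max_len_exclusive &
    candidates$energy < config$max_energy_exclusive &
    !is.na(n_loops) & n_loops <= config$max_loops
  candidates[ok, , drop = FALSE]
}
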
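test_that("config validation rejects bad parameters", {
  expect_error(sim_config(mutation_rate = 1.5))
  expect_error(sim_config(stem_length_range = c(40, 30)))
  expect_error(sim_config(planted_target_correlation = 0.5))
  expect_s3_class(sim_config(), "sim_config")
})

test_that("genome generation: empty case, determinism, sizing error", {
  g0 <- generate_genome(sim_config(rng_seed = 1, n_hairpins = 0,
                                   genome_length = 5000, n_decoys = 0))
  expect_equal(nrow(g0$hairpin_truth), 0)
  expect_equal(nchar(g0$sequence), 5000)

  cfg <- sim_config(rng_seed = 7, n_hairpins = 3, genome_length = 10000,
                    n_decoys = 2)
  expect_identical(generate_genome(cfg)$sequence,
                   generate_genome(cfg)$sequence)
  g1 <- generate_genome(sim_config(rng_seed = 8, n_hairpins = 3,
                                   genome_length = 10000, n_decoys = 2))
  expect_false(identical(generate_genome(cfg)$sequence, g1$sequence))

  expect_error(generate_genome(sim_config(n_hairpins = 50,
                                          genome_length = 2000)),
               "capacity")
})

test_that("mutation_rate = 0 gives perfectly self-complementary stems", {
  g <- generate_genome(sim_config(rng_seed = 3, n_hairpins = 5,
                                  genome_length = 15000, n_decoys = 0,
                                  mutation_rate = 0))
  for (i in seq_len(nrow(g$hairpin_truth))) {
    prec <- g$hairpin_truth$precursor[i]
    L <- nchar(prec)
    # oracle: direct reverse-complement comparison of the two stem arms.
    # stem length is unknown per hairpin, but at least the minimum config
    # stem; check the largest s with arm1 == revcomp(arm2).
    smax <- 0
    for (s in seq_len(L %/% 2)) {
      if (substr(prec, 1, s) == rc_str(substr(prec, L - s + 1, L))) smax <- s
    }
    expect_gte(smax, 30)
  }
  # planted elements appear verbatim in the genome
  tr <- g$hairpin_truth[1, ]
  planted <- substr(g$sequence, tr$start, tr$end)
  expect_true(planted == tr$precursor || planted == rc_str(tr$precursor))
})

test_that("truth records are complete and within bounds", {
  g <- small_genome()
  tr <- g$hairpin_truth
  expect_true(all(tr$start >= 1 & tr$end <= nchar(g$sequence)))
  expect_true(all(tr$m5p_start >= tr$start & tr$m5p_end <= tr$end))
  expect_true(all(tr$m3p_start >= tr$start & tr$m3p_end <= tr$end))
  expect_true(all(g$decoy_truth$class %in% c("tRNA-like", "CDS-like")))
  expect_equal(anyDuplicated(tr$hairpin_id), 0)
})

test_that("reference set divergence behaves as configured", {
  g <- small_genome()
  r0 <- generate_reference_set(g, divergence_levels = 0)
  expect_true(all(r0$precursor ==
                    g$hairpin_truth$precursor[match(r0$source_hairpin,
                                                    g$hairpin_truth$hairpin_id)]))

  # realized identity at divergence 0.3 within binomial bounds, by direct
  # position-wise comparison (the oracle)
  r3 <- generate_reference_set(g, divergence_levels = 0.3,
                               preserve_seed = FALSE, rng_seed = 5)
  prec <- unique(r3[, c("source_hairpin", "precursor")])
  idents <- lens <- numeric(0)
  for (i in seq_len(nrow(prec))) {
    orig <- g$hairpin_truth$precursor[match(prec$source_hairpin[i],
                                            g$hairpin_truth$hairpin_id)]
    a <- strsplit(orig, "")[[1]]; b <- strsplit(prec$precursor[i], "")[[1]]
    idents <- c(idents, sum(a == b)); lens <- c(lens, length(a))
  }
  p_keep <- 1 - 0.3
  n <- sum(lens)
  expect_lt(abs(sum(idents) / n - p_keep), 3 * sqrt(p_keep * (1 - p_keep) / n))

  # preserve_seed keeps mature positions 2-7 intact even at divergence 1
  r1 <- generate_reference_set(g, divergence_levels = 1, preserve_seed = TRUE,
                               rng_seed = 6)
  ms <- mature_set_from_genome(g)
  m <- merge(r1, ms, by.x = c("source_hairpin", "arm"),
             by.y = c("hairpin_id", "arm"))
  expect_true(all(m$seed.x == m$seed.y))
  # ...and without preserve_seed a fully diverged homolog changes the seed
  r1n <- generate_reference_set(g, divergence_levels = 1,
                                preserve_seed = FALSE, rng_seed = 6)
  mn <- merge(r1n, ms, by.x = c("source_hairpin", "arm"),
              by.y = c("hairpin_id", "arm"))
  expect_true(all(mn$seed.x != mn$seed.y))
})

test_that("tiling experiment has planted peaks and the stated geometry", {
  g <- small_genome()
  tl <- generate_tiling(g, end = "3p-assay", replicates = 4)
  grp <- split(tl$tiling, paste(tl$tiling$hairpin_id, tl$tiling$arm,
                                tl$tiling$replicate))
  expect_true(all(vapply(grp, nrow, integer(1)) == 22))
  tl5 <- generate_tiling(g, end = "5p-assay", replicates = 3)
  expect_true(all(table(paste(tl5$tiling$hairpin_id, tl5$tiling$arm,
                              tl5$tiling$replicate)) == 16))
  expect_error(generate_tiling(g, replicates = 0), "replicates")

  # noise_sd = 0, signal_fold = 10: planted position is the unique maximum
  # in every replicate
  g2 <- generate_genome(sim_config(rng_seed = 55, n_hairpins = 4,
                                   genome_length = 12000, n_decoys = 0,
                                   noise_sd = 0, signal_fold = 10))
  tl0 <- generate_tiling(g2, end = "3p-assay", replicates = 4)
  for (key in unique(paste(tl0$tiling$hairpin_id, tl0$tiling$arm))) {
    gt <- tl0$tiling[paste(tl0$tiling$hairpin_id, tl0$tiling$arm) == key, ]
    tt <- tl0$truth[paste(tl0$truth$hairpin_id, tl0$truth$arm) == key, ]
    for (r in unique(gt$replicate)) {
      v <- gt[gt$replicate == r, ]
      expect_equal(v$probe_offset[which.max(v$fluorescence)], tt$true_offset)
    }
  }

  # every probe group has exactly one truth record
  expect_equal(nrow(tl$truth), nrow(g$hairpin_truth) * 2)
})

test_that("read generation respects coverage, mismatches and decoys", {
  g <- small_genome()
  ms <- mature_set_from_genome(g)
  expect_equal(nrow(generate_reads(ms, coverage_mean = 0)), 0)

  r0 <- generate_reads(ms, coverage_mean = 10, mismatch_rate = 0,
                       rng_seed = 2)
  src <- ms$seq[match(paste(r0$rname, r0$pos),
                      paste(ms$hairpin_id, ms$start_in_hairpin))]
  expect_true(all(r0$seq == src))  # exact substrings of the source mature

  # mean per-nt coverage ~ Poisson(20), recounted from truth alignments
  r20 <- generate_reads(ms, coverage_mean = 20, rng_seed = 3)
  cov <- table(factor(r20$rname, levels = unique(ms$hairpin_id)))  # full-length reads
  lambda <- 20; n <- nrow(ms)
  expect_lt(abs(mean(cov) / 2 - lambda), 3 * sqrt(lambda / (n / 2)))

  rd <- generate_reads(ms, coverage_mean = 10, decoy_fraction = 0.2,
                       genome = g, rng_seed = 4)
  expect_gt(sum(rd$source_class == "decoy"), 0)
  expect_error(generate_reads(ms, 10, decoy_fraction = 0.2, rng_seed = 1),
               "decoy")
})

test_that("tissue expression plants the advertised correlation structure", {
  expect_error(generate_tissue_expression(sim_config(n_tissues = 2)),
               "tissues")

  # exact r = -1 when the planted correlation is -1 (zero noise)
  ts1 <- generate_tissue_expression(
    sim_config(rng_seed = 31, n_tissues = 10,
               planted_target_correlation = -1))
  r <- vapply(seq_len(nrow(ts1$pairs)), function(i) {
    stats::cor(ts1$mirna[ts1$pairs$mirna[i], ],
               ts1$mrna[ts1$pairs$target[i], ])
  }, numeric(1))
  expect_equal(r, rep(-1, length(r)), tolerance = 1e-12)

  ts <- small_tissue_sim()
  cfg <- ts$config
  expect_identical(generate_tissue_expression(cfg)$mirna, ts$mirna)

  # non-planted pairs are independent: |r| > 0.9 no more often than under
  # a tissue-label permutation null (the oracle)
  planted <- paste(ts$pairs$mirna, ts$pairs$target)
  set.seed(9)
  obs <- perm <- 0L; n_checked <- 0L
  for (m in rownames(ts$mirna)) {
    for (tx in sample(rownames(ts$mrna), 25)) {
      if (paste(m, tx) %in% planted) next
      n_checked <- n_checked + 1L
      x <- ts$mirna[m, ]; y <- ts$mrna[tx, ]
      if (abs(stats::cor(x, y)) > 0.9) obs <- obs + 1L
      if (abs(stats::cor(x, sample(y))) > 0.9) perm <- perm + 1L
    }
  }
  expect_lte(obs, perm + 3 * sqrt(max(perm, 1)))

  # sponges correlate positively at the mirrored strength
  sp <- vapply(seq_len(nrow(ts$sponges)), function(i) {
    stats::cor(ts$lincrna[ts$sponges$lincrna[i], ],
               ts$mirna[ts$sponges$mirna[i], ])
  }, numeric(1))
  expect_true(all(sp > 0.5))

  # planted seed sites exist in the target UTRs
  for (i in seq_len(nrow(ts$pairs))) {
    seed <- ts$mature$seed[match(ts$pairs$mirna[i], ts$mature$mature_id)]
    expect_true(grepl(rc_str(seed), ts$utrs[[ts$pairs$target[i]]],
                      fixed = TRUE))
  }
})
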
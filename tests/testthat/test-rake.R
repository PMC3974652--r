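test_that("bootstrap probability is forced at the extremes", {
  set.seed(1)
  expect_equal(endpoint_bootstrap(c(1, 2, 3, 100), 4), 1.0)
  expect_equal(endpoint_bootstrap(c(50, 60, 70, 1), 4), 0.0)
  expect_error(endpoint_bootstrap(c(1, 2), 1), "group size")
  expect_error(endpoint_bootstrap(c(1, 2, 3, 4), 9), "index")
})

test_that("bootstrap is monotone non-decreasing in the held-out value", {
  rest <- c(3, 7, 5, 9, 2, 8, 4, 6, 1, 10)
  probs <- vapply(c(0, 2.5, 5.5, 8.5, 12), function(v) {
    set.seed(99)
    endpoint_bootstrap(c(v, rest), 1, n_boot = 4000)
  }, numeric(1))
  expect_true(all(diff(probs) >= 0))
})

test_that("bootstrap matches the exhaustive enumeration oracle (k = 4)", {
  set.seed(123)
  for (rep in 1:25) {
    vals <- round(stats::runif(4, 0, 10), 2)
    idx <- sample.int(4, 1)
    rest <- vals[-idx]
    grid <- expand.grid(rest, rest, rest)  # all 27 equally likely resamples
    exact <- mean(rowMeans(grid) < vals[idx])
    set.seed(1000 + rep)
    est <- endpoint_bootstrap(vals, idx, n_boot = 10000)
    tol <- 3 * sqrt(exact * (1 - exact) / 10000)
    expect_lte(abs(est - exact), max(tol, 1e-12))
  }
})

test_that("noise-free planted peaks are called with probability 1 in all replicates", {
  g <- generate_genome(sim_config(rng_seed = 42, n_hairpins = 3,
                                  genome_length = 10000, n_decoys = 0,
                                  noise_sd = 0, signal_fold = 10))
  tl <- generate_tiling(g, end = "3p-assay", replicates = 4)
  calls <- call_endpoints(tl, master_seed = 2, n_boot = 2000)
  expect_equal(nrow(calls), nrow(tl$truth))
  m <- merge(calls, tl$truth, by = c("hairpin_id", "arm", "end_type"))
  expect_true(all(m$probe_offset == m$true_offset))
  expect_true(all(m$position == m$true_pos))
  expect_true(all(m$probability == 1.0))
  expect_true(all(m$n_replicates_passing == 4))
})

test_that("stricter thresholds call a subset; replicate floor is enforced", {
  g <- generate_genome(sim_config(rng_seed = 43, n_hairpins = 5,
                                  genome_length = 15000, n_decoys = 0,
                                  noise_sd = 0.6, signal_fold = 4))
  tl <- generate_tiling(g, end = "5p-assay", replicates = 3)
  loose <- call_endpoints(tl, thresholds = list("5prime" = 0.55),
                          master_seed = 3, n_boot = 2000)
  strict <- call_endpoints(tl, thresholds = list("5prime" = 0.80),
                           master_seed = 3, n_boot = 2000)
  expect_true(all(paste(strict$hairpin_id, strict$arm, strict$probe_offset)
                  %in% paste(loose$hairpin_id, loose$arm, loose$probe_offset)))

  expect_error(call_endpoints(generate_tiling(g, end = "3p-assay",
                                              replicates = 2),
                              master_seed = 1, n_boot = 100),
               "below required")
})

test_that("relaxed 5' calls are flagged low-stringency", {
  g <- generate_genome(sim_config(rng_seed = 44, n_hairpins = 8,
                                  genome_length = 20000, n_decoys = 0,
                                  noise_sd = 0.5, signal_fold = 3))
  tl <- generate_tiling(g, end = "5p-assay", replicates = 3)
  calls <- call_endpoints(tl, master_seed = 4, n_boot = 2000)
  if (any(calls$low_stringency)) {
    expect_true(all(calls$probability[calls$low_stringency] <= 0.65))
    expect_true(all(calls$probability[calls$low_stringency] > 0.58))
  }
  expect_true(all(calls$probability[!calls$low_stringency] > 0.65))
})

test_that("mature reconstruction applies the length window and ID convention", {
  hairpins <- data.frame(hairpin_id = "hpX", chrom = "16",
                         start = 68474541, end = 68474601, strand = "+",
                         precursor = NA, stringsAsFactors = FALSE)
  mkcall <- function(end_type, pos, p = 0.9) {
    data.frame(hairpin_id = "hpX", arm = "5p", end_type = end_type,
               probe_offset = 1L, position = pos, probability = p,
               mean_fluor = 100, n_replicates_passing = 4L,
               low_stringency = FALSE, stringsAsFactors = FALSE)
  }
  # 5' at (start+0), 3' 22 nt downstream -> accepted, canonical ID string
  calls <- rbind(mkcall("5prime", 68474541), mkcall("3prime", 68474562))
  mat <- reconstruct_mature(calls, hairpins)
  expect_equal(nrow(mat), 1)
  expect_equal(mat$length, 22)
  expect_equal(mat$id_string, "P_16_68474541_68474601_+_5p")
  expect_true(mat$canonical)

  # length 41 is outside the 18-26 window
  calls2 <- rbind(mkcall("5prime", 68474541), mkcall("3prime", 68474581))
  expect_equal(nrow(reconstruct_mature(calls2, hairpins)), 0)

  # a pair exiting the hairpin is dropped
  calls3 <- rbind(mkcall("5prime", 68474590), mkcall("3prime", 68474611))
  expect_equal(nrow(reconstruct_mature(calls3, hairpins)), 0)

  expect_error(reconstruct_mature(mkcall("5prime", 5), hairpins[0, ]),
               "unknown hairpins")
})

test_that("canonical selection, isomiRs and star partners are annotated", {
  g <- generate_genome(sim_config(rng_seed = 45, n_hairpins = 4,
                                  genome_length = 12000, n_decoys = 0,
                                  noise_sd = 0, signal_fold = 10))
  c3 <- call_endpoints(generate_tiling(g, end = "3p-assay", replicates = 4),
                       master_seed = 5, n_boot = 1000)
  c5 <- call_endpoints(generate_tiling(g, end = "5p-assay", replicates = 3),
                       master_seed = 5, n_boot = 1000)
  hairpins <- g$hairpin_truth
  mat <- reconstruct_mature(rbind(c3, c5), hairpins)
  expect_true(all(table(paste(mat$hairpin_id, mat$arm),
                        mat$canonical)[, "TRUE"] == 1))
  # both arms called for every hairpin -> star partner annotated
  expect_true(all(!is.na(mat$star_partner)))
  # reconstructed sequences equal the planted matures
  ms <- mature_set_from_genome(g)
  mm <- merge(mat[mat$canonical, ], ms, by = c("hairpin_id", "arm"))
  expect_true(all(mm$sequence == mm$seq))
  expect_true(all(mm$seed.x == mm$seed.y))
  # intervals never exit the hairpin
  hp <- hairpins[match(mat$hairpin_id, hairpins$hairpin_id), ]
  expect_true(all(pmin(mat$five_prime, mat$three_prime) >= hp$start &
                    pmax(mat$five_prime, mat$three_prime) <= hp$end))
})

test_that("spike calibration round-trips and flags the detection floor", {
  pts <- data.frame(amount_mol = 10^c(-18, -16, -14),
                    fluorescence = 10^c(4, 6, 8))
  cal <- spikein_calibrate(pts)
  q <- quantify(cal, pts$fluorescence)
  expect_equal(q$amount_mol, pts$amount_mol, tolerance = 1e-9)

  # two-point fit: quantify o calibrate is the identity
  cal2 <- spikein_calibrate(pts[c(1, 3), ])
  q2 <- quantify(cal2, pts$fluorescence[c(1, 3)])
  expect_equal(q2$amount_mol, pts$amount_mol[c(1, 3)], tolerance = 1e-12)

  # geometric-mean interpolation (closed-form line inversion)
  fmid <- sqrt(pts$fluorescence[1] * pts$fluorescence[2])
  qmid <- quantify(cal2, fmid)
  expect_equal(qmid$amount_mol, sqrt(pts$amount_mol[1] * pts$amount_mol[2]),
               tolerance = 1e-9)

  expect_true(quantify(cal, 10)$below_detection)
  expect_true(is.na(quantify(cal, 10)$amount_mol))

  bad <- data.frame(amount_mol = 10^c(-18, -16, -14),
                    fluorescence = c(1e6, 1e4, 1e8))
  expect_error(spikein_calibrate(bad), "monotone")
  expect_error(spikein_calibrate(pts[1, ]), "distinct")
})

test_that("spike-anchored normalization corrects global scale and keeps NAs", {
  set.seed(8)
  base <- matrix(2^stats::rnorm(200, 10, 1), 50, 4)
  rownames(base) <- c(sprintf("probe%02d", 1:44), sprintf("spike%d", 1:6))
  spikes <- sprintf("spike%d", 1:6)
  base[spikes, ] <- matrix(rep(2^seq(6, 16, by = 2), 4), 6, 4)

  # identical arrays: normalization is a no-op up to tolerance
  out <- normalize_mirna_matrix(base, spikes)
  expect_equal(out, base, tolerance = 1e-8)

  # one array scaled x2 globally: after anchoring, all arrays agree at the
  # spikes (closed form: each lands on the across-array geometric mean) and
  # the spikes' inter-array CV shrinks
  scaled <- base
  scaled[, 2] <- scaled[, 2] * 2
  out2 <- normalize_mirna_matrix(scaled, spikes)
  for (j in 2:4) {
    expect_equal(out2[spikes, 1], out2[spikes, j], tolerance = 1e-6)
  }
  cv <- function(m) mean(apply(m[spikes, ], 1, stats::sd) /
                           rowMeans(m[spikes, ]))
  expect_lt(cv(out2), cv(scaled))

  # shape and below-detection NAs preserved
  nay <- scaled
  nay["probe01", 3] <- NA
  out3 <- normalize_mirna_matrix(nay, spikes)
  expect_equal(dim(out3), dim(nay))
  expect_true(is.na(out3["probe01", 3]))

  expect_error(normalize_mirna_matrix(base, "nonexistent"), "missing spikes")
})
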
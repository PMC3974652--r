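two_state_matrices <- function() {
  # 4 tissues; miR-up targets gene-down in tissue_1, miR-dn releases gene-up
  tissues <- paste0("tissue_", 1:4)
  mir <- rbind("miR-up" = c(8, 2, 2, 2), "miR-dn" = c(1, 6, 6, 6))
  mrna <- rbind(geneA = c(1, 6, 6, 6),   # down in tissue_1
                geneB = c(9, 3, 3, 3),   # up in tissue_1
                geneC = c(1, 7, 7, 7))  # down in tissue_1
  colnames(mir) <- colnames(mrna) <- tissues
  list(mir = mir, mrna = mrna)
}

mk_ft <- function(mirna, target, r = -0.95) {
  data.frame(mirna_id = mirna, transcript_id = target, position = 50L,
             site_class = "7mer-m8", distance_to_utr_start = 49L,
             pearson_r = r, passes = TRUE, stringsAsFactors = FALSE)
}

test_that("bipartition sends edges to the correct side and drops the rest", {
  m <- two_state_matrices()
  no_edges <- data.frame(a = character(0), b = character(0))

  net <- build_tissue_network(mk_ft("miR-up", "geneA"), no_edges,
                              m$mir, m$mrna, "tissue_1")
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$partition, "repressive")

  net2 <- build_tissue_network(mk_ft("miR-dn", "geneB"), no_edges,
                               m$mir, m$mrna, "tissue_1")
  expect_equal(net2$edges$partition, "permissive")

  # up-miRNA / up-mRNA: no targeting edge on either side
  net3 <- build_tissue_network(mk_ft("miR-up", "geneB"), no_edges,
                               m$mir, m$mrna, "tissue_1")
  expect_equal(nrow(net3$edges), 0)

  # interaction edges join same-state mRNAs only
  net4 <- build_tissue_network(mk_ft("miR-up", "geneA"),
                               data.frame(a = c("geneA", "geneA"),
                                          b = c("geneC", "geneB")),
                               m$mir, m$mrna, "tissue_1")
  e <- net4$edges[net4$edges$type == "interaction", ]
  expect_equal(nrow(e), 1)  # geneA-geneC (both down); geneA-geneB mixed
  expect_equal(e$partition, "repressive")

  expect_error(build_tissue_network(mk_ft("miR-up", "geneA"), no_edges,
                                    m$mir, m$mrna, "nope"), "tissue")
})

test_that("below-detection nodes are excluded (grey semantics)", {
  m <- two_state_matrices()
  m$mrna["geneA", 1] <- NA
  net <- build_tissue_network(mk_ft("miR-up", "geneA"),
                              data.frame(a = character(0), b = character(0)),
                              m$mir, m$mrna, "tissue_1")
  expect_equal(nrow(net$edges), 0)
})

test_that("network invariants hold on simulated tissue networks", {
  ts <- small_tissue_sim()
  sites <- predict_targets(ts$mature, ts$utrs)
  ft <- anticorrelation_filter(sites, ts$mirna, ts$mrna)
  for (tissue in colnames(ts$mirna)[c(1, 7, 14)]) {
    net <- build_tissue_network(ft, ts$edges, ts$mirna, ts$mrna, tissue)
    e <- net$edges; n <- net$nodes
    tgt <- e[e$type == "targeting", ]
    # targeting edges only miRNA -> mRNA
    expect_true(all(n$type[match(tgt$from, n$id)] == "miRNA"))
    expect_true(all(n$type[match(tgt$to, n$id)] == "mRNA"))
    # permissive side: no up-regulated miRNA; repressive: no down-regulated
    perm_mir <- tgt$from[tgt$partition == "permissive"]
    rep_mir <- tgt$from[tgt$partition == "repressive"]
    expect_true(all(n$state[match(perm_mir, n$id)] == "down"))
    expect_true(all(n$state[match(rep_mir, n$id)] == "up"))
    expect_true(all(n$state[match(tgt$to[tgt$partition == "permissive"],
                                  n$id)] == "up"))
    expect_true(all(n$state[match(tgt$to[tgt$partition == "repressive"],
                                  n$id)] == "down"))
  }
})

test_that("module decomposition equals the union-find oracle", {
  m <- two_state_matrices()
  ft <- rbind(mk_ft("miR-up", "geneA"), mk_ft("miR-dn", "geneB"))
  net <- build_tissue_network(ft, data.frame(a = character(0),
                                             b = character(0)),
                              m$mir, m$mrna, "tissue_1")
  mod <- decompose_modules(net)
  # two disjoint planted components, one per side
  expect_equal(nrow(mod), 4)
  expect_equal(length(unique(paste(mod$partition, mod$module))), 2)

  # random planted graph: components match brute-force reachability
  set.seed(23)
  nodes <- sprintf("g%02d", 1:30)
  edges <- data.frame(from = sample(nodes, 40, TRUE),
                      to = sample(nodes, 40, TRUE),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, ]
  edges$type <- "interaction"; edges$partition <- "permissive"
  edges$n_sites <- NA
  fake <- structure(list(edges = edges,
                         nodes = data.frame(id = nodes),
                         tissue = "t"), class = "regulatory_network")
  mod2 <- decompose_modules(fake)
  oracle <- components_oracle(edges)
  # same partition of nodes into components
  sig <- function(sp) sort(unname(vapply(sp, function(m)
    paste(sort(m), collapse = ","), character(1))))
  expect_setequal(sig(split(mod2$node, mod2$module)),
                  sig(split(names(oracle), oracle)))
})

test_that("fully connected side yields a single module", {
  edges <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                      type = "interaction", partition = "repressive",
                      n_sites = NA)
  fake <- structure(list(edges = edges, nodes = data.frame(id = c("a", "b", "c")),
                         tissue = "t"), class = "regulatory_network")
  expect_equal(unique(decompose_modules(fake)$module), 1L)
})

test_that("tissue clustering reports sane resampling support", {
  set.seed(4)
  # two well-separated planted groups of tissues
  sig <- stats::rnorm(60)
  m <- cbind(sapply(1:4, function(i) sig + stats::rnorm(60, 0, 0.2)),
             sapply(1:4, function(i) -sig + stats::rnorm(60, 0, 0.2)))
  colnames(m) <- paste0("t", 1:8)
  cl <- cluster_tissues(m, n_resamples = 100, rng_seed = 5)
  expect_true(all(cl$support >= 0 & cl$support <= 1))
  # the split between the groups is (nearly) always recovered
  expect_gte(max(cl$support), 0.95)

  # duplicated sample columns join first with full support
  m2 <- m; m2[, 2] <- m2[, 1]
  cl2 <- cluster_tissues(m2, n_resamples = 50, rng_seed = 6)
  expect_equal(cl2$hclust$height[1], 0, tolerance = 1e-12)
  expect_error(cluster_tissues(m[, 1, drop = FALSE]), "2 samples")
})

test_that("arm ratios recompute element-wise and catch anti-correlation", {
  tissues <- paste0("t", 1:6)
  m5 <- c(4, 8, 2, 6, 10, 3)
  mat <- rbind("hp1_5p" = m5, "hp1_3p" = m5,            # identical arms
               "hp2_5p" = m5, "hp2_3p" = 12 - m5,            # exact anti-corr
               "solo_5p" = m5)                          # partner missing
  colnames(mat) <- tissues
  ar <- arm_ratio_profiles(mat)
  expect_setequal(rownames(ar$ratios), c("hp1", "hp2"))
  expect_equal(unname(ar$ratios["hp1", ]), rep(0, 6))
  expect_equal(unname(ar$correlations["hp1"]), 1)
  expect_equal(unname(ar$correlations["hp2"]), -1, tolerance = 1e-9)
  # element-wise brute force
  expect_equal(unname(ar$ratios["hp2", ]),
               unname(log2(mat["hp2_5p", ] / mat["hp2_3p", ])))
  # below-detection entries propagate
  mat[1, 2] <- NA
  ar2 <- arm_ratio_profiles(mat)
  expect_true(is.na(ar2$ratios["hp1", 2]))
})

test_that("family enrichment is the exact hypergeometric tail", {
  universe <- sprintf("mir%02d", 1:20)
  fams <- list(famA = universe[1:5], famB = universe[6:8],
               famEmpty = c("zz1", "zz2"))
  # subset = the whole of famA: p = 1 / C(20,5)
  res <- family_enrichment(universe[1:5], fams, universe)
  expect_equal(res$p_value[res$family == "famA"], 1 / choose(20, 5))
  expect_false("famEmpty" %in% res$family)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))

  # subset = family = universe -> p = 1
  res2 <- family_enrichment(universe, list(all = universe), universe)
  expect_equal(res2$p_value, 1)

  expect_error(family_enrichment(c("nope"), fams, universe), "universe")
})

test_that("sponge detection reports planted positives and respects thresholds", {
  ts <- small_tissue_sim()
  sg <- sponge_candidates(ts$lincrna, ts$mirna, threshold = 0.7)
  planted <- paste(ts$sponges$lincrna, ts$sponges$mirna)
  expect_true(all(planted %in% paste(sg$lincrna, sg$mirna)))

  # threshold 1.0 keeps only exactly collinear pairs
  lm <- ts$lincrna
  lm["linc010", ] <- ts$mirna["miR-010", ]
  sg1 <- sponge_candidates(lm, ts$mirna, threshold = 1.0)
  expect_equal(paste(sg1$lincrna, sg1$mirna), "linc010 miR-010")

  # independent profiles exceed the cut no more than a permutation null
  set.seed(12)
  perm_mir <- ts$mirna[, sample(ncol(ts$mirna))]
  colnames(perm_mir) <- colnames(ts$mirna)
  null_hits <- nrow(sponge_candidates(ts$lincrna, perm_mir, threshold = 0.9))
  obs_nonplanted <- sum(!paste(sg$lincrna, sg$mirna) %in% planted &
                          sg$pearson_r >= 0.9)
  expect_lte(obs_nonplanted, null_hits + 3 * sqrt(max(null_hits, 1)))

  bad <- ts$mirna; colnames(bad) <- rev(colnames(bad))
  expect_error(sponge_candidates(ts$lincrna, bad), "mismatch")
})

test_that("quantile normalization matches its definition and a naive oracle", {
  set.seed(31)
  m <- matrix(stats::rnorm(60, 8, 2), 15, 4,
              dimnames = list(paste0("g", 1:15), paste0("t", 1:4)))
  qn <- quantile_normalize(m)
  expect_equal(dim(qn), dim(m))
  # identical columns unchanged
  same <- matrix(rep(sort(stats::rnorm(10)), 3), 10, 3)
  expect_equal(quantile_normalize(same), same, ignore_attr = TRUE)
  # every column's sorted values equal the row means of the sorted input
  target <- rowMeans(apply(m, 2, sort))
  for (j in 1:4) expect_equal(sort(qn[, j]), target, ignore_attr = TRUE)
  # naive two-pass reference implementation
  naive <- m
  rk <- apply(m, 2, rank, ties.method = "first")
  for (j in 1:4) naive[, j] <- target[rk[, j]]
  expect_equal(qn, naive, tolerance = 1e-12)
})
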
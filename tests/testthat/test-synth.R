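# Synthetic cohort generator: truth-ledger invariants, planted effect
# sizes, interaction tables, PPI structure and survival generation.

test_that("null gradient gives a zero truth ledger and valid invariants", {
  cfg <- test_config(effect_gradient = rep(0, 5), seed = 11)
  cohort <- generate_cohort(cfg)
  expect_true(all(cohort$truth$true_lfc == 0))
  pa <- cohort$truth$planted_axes
  # planted axes are pairwise feature-disjoint within each modality
  expect_false(anyDuplicated(pa$circRNA) > 0)
  expect_false(anyDuplicated(pa$miRNA) > 0)
  expect_false(anyDuplicated(pa$gene) > 0)
})

test_that("interaction tables contain planted pairs plus the requested decoys", {
  cfg <- test_config(n_planted_axes = 3, decoy_interactions_per_true = 0,
                     seed = 2)
  cohort <- generate_cohort(cfg)
  tabs <- generate_interaction_tables(cohort$truth, cfg)
  expect_equal(nrow(tabs$circ_mir), 3L)
  expect_equal(nrow(tabs$mir_gene), 3L)

  cfg2 <- test_config(n_planted_axes = 1, decoy_interactions_per_true = 2,
                      seed = 3)
  cohort2 <- generate_cohort(cfg2)
  tabs2 <- generate_interaction_tables(cohort2$truth, cfg2)
  expect_equal(nrow(tabs2$circ_mir), 3L)
  expect_equal(nrow(tabs2$mir_gene), 3L)
  # planted pairs always present regardless of decoy draw
  pa <- cohort2$truth$planted_axes
  expect_true(paste(pa$circRNA, pa$miRNA) %in%
                paste(tabs2$circ_mir$source, tabs2$circ_mir$target))
  expect_true(paste(pa$miRNA, pa$gene) %in%
                paste(tabs2$mir_gene$source, tabs2$mir_gene$target))
  # decoys never connect two planted features
  planted_feats <- unlist(pa[, c("circRNA", "miRNA", "gene")])
  dec <- tabs2$decoy_pairs
  expect_false(any(dec$source %in% planted_feats &
                     dec$target %in% planted_feats))
})

test_that("identical seeds give identical cohorts and tables", {
  cfg <- test_config(seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  t1 <- generate_interaction_tables(c1$truth, cfg)
  t2 <- generate_interaction_tables(c2$truth, cfg)
  expect_identical(t1, t2)
})

test_that("planted Basal shift matches the generating gradient within MC error", {
  cfg <- synth_config(n_control = 20L, n_per_subtype = 20L,
                      n_features = c(circRNA = 30L, miRNA = 30L, mRNA = 60L),
                      effect_gradient = c(0.5, 1, 1.5, 2, 3),
                      noise_sd = 0.5, seed = 7)
  cohort <- generate_cohort(cfg)
  pa <- cohort$truth$planted_axes
  up_gene <- pa$gene[pa$direction_pattern == "up-down-up"][1]
  ds <- cohort$datasets[[1]]
  basal <- ds$meta$sample_id[!is.na(ds$meta$subtype) &
                               ds$meta$subtype == "Basal"]
  ctrl <- ds$meta$sample_id[ds$meta$group == "control"]
  diff <- mean(ds$expr$mRNA[up_gene, basal]) -
    mean(ds$expr$mRNA[up_gene, ctrl])
  # feature sd inflated by coupling: sqrt(noise^2 + c^2 noise^2)
  sd_feat <- sqrt(0.5^2 + cfg$coupling_strength^2 * 0.5^2)
  se <- sd_feat * sqrt(1 / 20 + 1 / 20)
  expect_lt(abs(diff - 3.0), 3 * se)
})

test_that("effect gradients must be non-decreasing and groups populated", {
  expect_error(test_config(effect_gradient = c(1, 0.5, 1.5, 2, 3)),
               "non-decreasing")
  expect_error(synth_config(n_per_subtype = c(NormalLike = 0, LumA = 10,
                                              LumB = 10, HER2 = 10,
                                              Basal = 10)),
               "at least 2")
})

test_that("PPI generator emits the planted clique and thresholdable background", {
  cfg <- test_config(n_planted_axes = 4, seed = 5,
                     ppi_background_prob = 0)
  cohort <- generate_cohort(cfg)
  genes <- rownames(cohort$datasets[[1]]$expr$mRNA)
  ppi <- generate_ppi(genes, cohort$truth, cfg)
  k <- 4
  expect_equal(nrow(ppi), k * (k - 1) / 2)    # clique on planted genes only
  expect_true(all(ppi$score > 0.4))

  cfg2 <- test_config(n_planted_axes = 4, seed = 5,
                      ppi_background_prob = 0.2)
  cohort2 <- generate_cohort(cfg2)
  ppi2 <- generate_ppi(genes, cohort2$truth, cfg2)
  expect_gt(nrow(ppi2), k * (k - 1) / 2)
  # default background scores sit at or below the 0.4 loading threshold,
  # so strict thresholding recovers exactly the community
  g <- load_ppi(ppi2, score_threshold = 0.4)
  expect_setequal(igraph::V(g)$name, sort(cohort2$truth$planted_axes$gene))
})

test_that("survival generator honours censoring, null effects and risk genes", {
  cfg <- test_config(censor_rate = 0, seed = 9)
  cohort <- generate_cohort(cfg)
  expr <- cohort$datasets[[1]]$expr$mRNA
  sv <- generate_survival(expr, cohort$truth, cfg)
  expect_true(all(sv$event == 1L))

  cfg2 <- test_config(censor_rate = 0.4, seed = 9)
  sv2 <- generate_survival(expr, cohort$truth, cfg2)
  expect_lt(abs(mean(sv2$event == 0) - 0.4), 0.1)

  # unknown risk gene rejected
  bad_truth <- cohort$truth
  bad_truth$risk_genes <- data.frame(gene = "no_such_gene", sign = 1)
  expect_error(generate_survival(expr, bad_truth, cfg), "unknown risk gene")

  # null effect: median-split log-rank rarely significant
  cfg3 <- test_config(survival_beta = 0, seed = 10)
  pvals <- vapply(1:20, function(s) {
    cfg_s <- test_config(survival_beta = 0, seed = 100 + s)
    co <- generate_cohort(cfg_s)
    e <- co$datasets[[1]]$expr$mRNA
    sv <- generate_survival(e, co$truth, cfg_s)
    g <- co$truth$risk_genes$gene[1]
    grp <- dichotomize_by_median(e[g, sv$sample_id])
    logrank_test(sv$time, sv$event, grp)$p
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.25)
})

test_that("true planted profiles satisfy the sponge predicates by construction", {
  cfg <- test_config(seed = 21)
  cohort <- generate_cohort(cfg)
  pa <- cohort$truth$planted_axes
  lfc <- cohort$truth$true_lfc
  # direction alternation: circ and gene share sign, miRNA is opposite
  for (i in seq_len(nrow(pa))) {
    expect_equal(sign(lfc[pa$circRNA[i], "Basal"]),
                 sign(lfc[pa$gene[i], "Basal"]))
    expect_equal(sign(lfc[pa$miRNA[i], "Basal"]),
                 -sign(lfc[pa$circRNA[i], "Basal"]))
  }
  # pan-flute holds on the true profiles with zero tolerance
  prof <- lfc[pa$gene, , drop = FALSE]
  expect_setequal(pan_flute_filter(prof, tau = 0), pa$gene)
})
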
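# Axis assembly and filtering: intersections, sponge matching, top-k,
# pan-flute trend filter and Spearman correlation.

de_set <- function(features, directions, lfc = NULL) {
  if (is.null(lfc)) lfc <- ifelse(directions == "up", 2, -2)
  data.frame(feature = features, log2FC = lfc, direction = directions,
             stringsAsFactors = FALSE)
}

test_that("DE intersection respects identity, disjointness and direction", {
  a <- de_set(c("A", "B"), c("up", "up"))
  b <- de_set(c("A", "B"), c("down", "up"))
  expect_equal(intersect_de(a, b)$feature, "B")
  expect_equal(nrow(intersect_de(a, de_set("C", "up"))), 0)
  expect_equal(intersect_de(a, a)$feature, c("A", "B"))
  # without direction requirement the conflicting feature survives
  expect_setequal(intersect_de(a, b, require_same_direction = FALSE)$feature,
                  c("A", "B"))
})

test_that("cross-subtype sharing requires presence and direction consistency", {
  subs <- pam50_subtypes()
  per <- setNames(lapply(subs, function(s) de_set(c("X", "Y"), c("up", "up"))),
                  subs)
  expect_setequal(shared_across_subtypes(per)$feature, c("X", "Y"))

  per$NormalLike <- de_set("Y", "up")              # X absent in one subtype
  expect_equal(shared_across_subtypes(per)$feature, "Y")

  per$NormalLike <- de_set(c("X", "Y"), c("up", "down"))  # Y flips
  expect_equal(shared_across_subtypes(per)$feature, "X")

  expect_error(shared_across_subtypes(per[-1]), "missing subtype")
})

test_that("sponge matching keeps only direction-opposite knowledge-base pairs", {
  kb <- data.frame(source = c("c1", "c1", "c2"),
                   target = c("m1", "m2", "m1"))
  circ <- de_set(c("c1", "c2"), c("up", "up"))
  mir <- de_set(c("m1", "m2"), c("down", "up"))
  pairs <- match_sponge_pairs(circ, mir, kb)
  # c1-m1 and c2-m1 opposite; c1-m2 same direction; c2-m2 not in table
  expect_setequal(paste(pairs$source, pairs$target), c("c1 m1", "c2 m1"))
})

test_that("axis assembly equals the join product with alternating directions", {
  cm <- data.frame(source = c("c1", "c2"), target = "m1",
                   source_direction = "up", target_direction = "down")
  mg <- data.frame(source = "m1", target = c("g1", "g2", "g3"),
                   source_direction = "down", target_direction = "up")
  ax <- assemble_axes(cm, mg)
  expect_equal(nrow(ax), 6)
  expect_true(all(ax$direction_pattern == "up-down-up"))

  # nested-loop oracle on a random pair configuration
  set.seed(8)
  cm2 <- unique(data.frame(
    source = sample(sprintf("c%d", 1:4), 10, TRUE),
    target = sample(sprintf("m%d", 1:3), 10, TRUE),
    source_direction = "down", target_direction = "up"))
  mg2 <- unique(data.frame(
    source = sample(sprintf("m%d", 1:3), 10, TRUE),
    target = sample(sprintf("g%d", 1:5), 10, TRUE),
    source_direction = "up", target_direction = "down"))
  oracle_n <- 0
  for (i in seq_len(nrow(cm2))) {
    for (j in seq_len(nrow(mg2))) {
      if (cm2$target[i] == mg2$source[j]) oracle_n <- oracle_n + 1
    }
  }
  expect_equal(nrow(assemble_axes(cm2, mg2)), oracle_n)

  # no shared miRNA
  mg3 <- transform(mg2, source = "m99")
  expect_equal(nrow(assemble_axes(cm2, mg3)), 0)
})

test_that("the published hub network assembles into exactly 13 axes", {
  cm <- read.delim(blbc_example_path("circ_mir.tsv"))
  mg <- read.delim(blbc_example_path("mir_gene.tsv"))
  ax <- assemble_axes(cm, mg)
  expect_equal(nrow(ax), 13)
  expect_true("hsa_circRNA_100435" %in% ax$circRNA[ax$gene == "AHNAK"])
})

test_that("top-k target selection ranks by |log2FC| with lexicographic ties", {
  ax <- data.frame(circRNA = "c1", miRNA = "m1",
                   gene = c("g1", "g2", "g3"),
                   direction_pattern = "up-down-up", provenance = "matched")
  lfc <- c(g1 = 3, g2 = -2, g3 = 1)
  expect_setequal(top_k_targets(ax, lfc, 2)$gene, c("g1", "g2"))
  expect_equal(nrow(top_k_targets(ax, lfc, 10)), 3)

  # tie at the boundary: smaller gene id among the tied pair is kept
  lfc_tie <- c(g1 = 2, g2 = 1, g3 = 1)
  expect_setequal(top_k_targets(ax, lfc_tie, 2)$gene, c("g1", "g2"))
  expect_error(top_k_targets(ax, lfc[1:2], 2), "log2FC")
})

test_that("pan-flute filter reproduces the worked profiles and mode identity", {
  prof <- rbind(
    strict = c(0.5, 1.0, 1.5, 2.0, 3.0),
    dip    = c(1.0, 2.0, 1.5, 2.5, 3.0),
    flat   = c(1, 1, 1, 1, 1)
  )
  colnames(prof) <- pam50_subtypes()
  expect_equal(pan_flute_filter(prof, tau = 0), "strict")
  expect_setequal(pan_flute_filter(prof, tau = 0.6), c("strict", "dip"))
  expect_false("flat" %in% pan_flute_filter(prof, tau = 0))

  # down-regulated profiles are judged on magnitude
  neg <- matrix(-c(0.5, 1, 1.5, 2, 3), nrow = 1,
                dimnames = list("down", pam50_subtypes()))
  expect_equal(pan_flute_filter(neg, tau = 0), "down")

  # monotone mode with infinite tolerance reduces to peak-at-basal
  set.seed(13)
  rnd <- matrix(runif(200, 0, 3), ncol = 5,
                dimnames = list(sprintf("f%02d", 1:40), pam50_subtypes()))
  expect_equal(pan_flute_filter(rnd, tau = Inf, mode = "monotone"),
               pan_flute_filter(rnd, mode = "peak-at-basal"))

  expect_error(pan_flute_filter(rnd[, 1:4]), "5 subtype")
})

test_that("Spearman correlation matches rank-formula values and subsetting", {
  mir <- matrix(c(1, 2, 3), nrow = 1,
                dimnames = list("m1", c("s1", "s2", "s3")))
  gene_id <- matrix(c(10, 20, 30), nrow = 1,
                    dimnames = list("g1", c("s1", "s2", "s3")))
  expect_equal(spearman_matrix(mir, gene_id)$rho[1, 1], 1)

  gene_rev <- matrix(c(30, 20, 10), nrow = 1,
                     dimnames = list("g1", c("s1", "s2", "s3")))
  expect_equal(spearman_matrix(mir, gene_rev)$rho[1, 1], -1)

  gene_perm <- matrix(c(3, 1, 2), nrow = 1,
                      dimnames = list("g1", c("s1", "s2", "s3")))
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d = (0, 1, 1) ... sum d^2 = 6
  expect_equal(spearman_matrix(mir, gene_perm)$rho[1, 1], -0.5)

  # subtype restriction: only the named samples enter
  mir4 <- cbind(mir, s4 = 4)
  gene4 <- cbind(gene_perm, s4 = 4)
  full <- spearman_matrix(mir4, gene4)
  sub <- spearman_matrix(mir4, gene4, sample_subset = c("s1", "s2", "s3"))
  expect_equal(sub$n, 3)
  expect_equal(sub$rho[1, 1], -0.5)
  expect_false(isTRUE(all.equal(full$rho[1, 1], sub$rho[1, 1])))

  expect_error(spearman_matrix(mir[, 1:2, drop = FALSE],
                               gene_perm[, 1:2, drop = FALSE]),
               "3 shared samples")
})
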
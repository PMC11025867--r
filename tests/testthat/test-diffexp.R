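# Differential-expression engines: normalization, moderated t, rank sum,
# Welch t, BH adjustment and threshold filtering.

test_that("log2-CPM normalization follows the pseudo-count formula", {
  counts <- matrix(c(0, rep(1, 9)), ncol = 1,
                   dimnames = list(sprintf("g%d", 1:10), "s1"))
  counts[2, 1] <- 1e6 - 8          # libsize exactly 1e6 with the zero row
  cpm <- normalize_counts(counts)
  expect_equal(cpm["g1", 1], log2(0.5 / (1e6 + 1) * 1e6),
               tolerance = 1e-12)

  # all-equal column gives all-equal entries
  eq <- matrix(5, nrow = 4, ncol = 2)
  expect_true(all(abs(diff(normalize_counts(eq)[, 1])) < 1e-12))

  # CPM is scale-invariant within a column: doubling every count also
  # doubles the library size, so entries change only by the vanishing
  # pseudo-count perturbation
  set.seed(11)
  big <- matrix(rpois(40, 5000) + 1, nrow = 8)
  d <- normalize_counts(2 * big) - normalize_counts(big)
  expect_true(all(abs(d) < 1e-3))

  expect_error(normalize_counts(matrix(-1)), "non-negative")
})

test_that("moderated t handles degenerate features and matches pooled t when unshrunk", {
  tg <- two_group_matrix(50, 6, 6, seed = 3)
  m <- tg$m
  m[1, ] <- c(rep(1, 6), rep(1, 6))          # identical groups, constant
  m[2, 7:12] <- m[2, 1:6]                    # identical group values
  tab <- moderated_t(m, tg$groups)
  expect_equal(tab$log2FC[1], 0)
  expect_equal(tab$stat[1], 0)
  expect_equal(tab$p[1], 1)
  expect_equal(tab$stat[2], 0)

  # shrink = FALSE reduces to the textbook pooled two-sample t
  tab0 <- moderated_t(tg$m, tg$groups, shrink = FALSE)
  hand <- apply(tg$m, 1L, function(x) {
    x1 <- x[1:6]; x2 <- x[7:12]
    sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / 10
    (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / 6 + 1 / 6))
  })
  expect_equal(tab0$stat, unname(hand), tolerance = 1e-10)
  expect_equal(tab0$p, unname(2 * pt(-abs(hand), df = 10)),
               tolerance = 1e-12)
})

test_that("moderated t agrees with the independent limma implementation", {
  library(limma)
  tg <- two_group_matrix(300, 8, 10, seed = 17)
  design <- cbind(1, as.integer(tg$groups == "b"))
  fit <- limma::eBayes(limma::lmFit(tg$m, design))
  tab <- moderated_t(tg$m, tg$groups)
  expect_equal(tab$log2FC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(tab$stat, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(tab$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("moderated t p-values are uniform under the null", {
  tg <- two_group_matrix(1000, 10, 10, seed = 23)
  tab <- moderated_t(tg$m, tg$groups)
  ks <- suppressWarnings(ks.test(tab$p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("DE engines are invariant to sample permutation within groups", {
  tg <- two_group_matrix(40, 6, 6, seed = 5)
  perm <- c(sample(1:6), sample(7:12))
  for (fun in list(moderated_t, rank_sum_test, welch_t_test)) {
    a <- fun(tg$m, tg$groups)
    b <- fun(tg$m[, perm], tg$groups[perm])
    expect_equal(a$stat, b$stat, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
})

test_that("rank-sum test is exact for small untied samples and symmetric", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("f1", NULL))
  g <- factor(rep(c("a", "b"), each = 3), levels = c("a", "b"))
  tab <- rank_sum_test(m, g)
  expect_equal(tab$p, 0.1)
  expect_equal(tab$p, oracle_ranksum_exact(c(1, 2, 3), c(4, 5, 6)))

  # identical samples in both groups
  m2 <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1)
  expect_equal(rank_sum_test(m2, g)$p, 1)

  # swapping labels leaves p unchanged and negates log2FC
  g_swapped <- factor(rep(c("b", "a"), each = 3), levels = c("a", "b"))
  tab_sw <- rank_sum_test(m, g_swapped)
  expect_equal(tab_sw$p, tab$p)
  expect_equal(tab_sw$log2FC, -tab$log2FC)

  # exactness against the enumeration oracle on random untied data
  set.seed(31)
  for (i in 1:5) {
    x <- sample(100, 9) / 10
    mm <- matrix(x, nrow = 1)
    gg <- factor(rep(c("a", "b"), c(4, 5)), levels = c("a", "b"))
    expect_equal(rank_sum_test(mm, gg)$p,
                 oracle_ranksum_exact(x[1:4], x[5:9]),
                 tolerance = 1e-12)
  }
})

test_that("Welch t matches hand evaluation and reduces to pooled t", {
  m <- matrix(c(1, 2, 3, 4, 2, 3, 4, 5), nrow = 1)
  g <- factor(rep(c("a", "b"), each = 4), levels = c("a", "b"))
  tab <- welch_t_test(m, g)
  v1 <- var(c(1, 2, 3, 4)); v2 <- var(c(2, 3, 4, 5))
  t_hand <- (mean(c(2, 3, 4, 5)) - mean(c(1, 2, 3, 4))) /
    sqrt(v1 / 4 + v2 / 4)
  df_hand <- (v1 / 4 + v2 / 4)^2 /
    ((v1 / 4)^2 / 3 + (v2 / 4)^2 / 3)
  expect_equal(tab$stat, t_hand, tolerance = 1e-10)
  expect_equal(tab$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)

  # equal group means -> t = 0, p = 1
  m0 <- matrix(c(1, 3, 2, 2), nrow = 1)
  g0 <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  tab0 <- welch_t_test(m0, g0)
  expect_equal(tab0$stat, 0)
  expect_equal(tab0$p, 1)
})

test_that("BH adjustment matches the worked examples and the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("DE filtering applies strict alpha and non-strict fold-change bounds", {
  tab <- data.frame(
    feature = c("a", "b", "c", "d"),
    log2FC = c(1.0, 0.99, -2, 1.5),
    stat = 0, p = c(0.049, 0.001, 0.2, 0.01),
    fdr = c(0.3, 0.01, 0.01, 0.002),
    direction = c("up", "up", "down", "up"),
    contrast = NA_character_)
  pm <- filter_de(tab, de_thresholds(1, 0.05, use_fdr = FALSE))
  expect_true("a" %in% pm$kept$feature)      # p 0.049 < 0.05, lfc 1.0 >= 1
  expect_false("b" %in% pm$kept$feature)     # below lfc_min

  fm <- filter_de(tab, de_thresholds(1, 0.01, use_fdr = TRUE))
  expect_false("c" %in% fm$kept$feature)     # fdr == alpha: strict <
  expect_true("d" %in% fm$kept$feature)
  # up/down partition the kept set
  expect_setequal(c(fm$up$feature, fm$down$feature), fm$kept$feature)
  expect_length(intersect(fm$up$feature, fm$down$feature), 0)
})
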
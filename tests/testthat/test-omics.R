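# Differential-abundance filter, EASE enrichment, pathway z-scores,
# mtDNA copy-number ratio.

# exact hypergeometric tail from first principles (the oracle)
hyper_tail <- function(k_min, K, N, n) {
  ks <- max(0, n + K - N):min(n, K)
  ks <- ks[ks >= k_min]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

test_that("EASE p matches the combinatorial oracle", {
  expect_equal(ease_fisher(0, 5, 5, 20), 1)
  # N=20, K=5, n=5, k=3: P(X >= 2) = 1 - P(0) - P(1) = 0.36608
  p <- ease_fisher(3, 5, 5, 20)
  expect_equal(p, hyper_tail(2, 5, 20, 5), tolerance = 1e-12)
  expect_equal(p, 0.366099, tolerance = 1e-6)
  expect_error(ease_fisher(6, 5, 5, 20), "margins")
})

test_that("unmodified variant equals classical one-sided Fisher", {
  for (N in 4:9) for (n in 0:N) for (K in 0:N)
    for (k in max(0, n + K - N):min(n, K)) {
      tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
      expect_equal(ease_fisher(k, n, K, N, method = "fisher"),
                   fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-9)
    }
})

test_that("the EASE penalty never makes enrichment look stronger", {
  for (N in c(6, 10, 12)) for (n in 1:N) for (K in 1:N)
    for (k in max(1, n + K - N):min(n, K))
      expect_gte(ease_fisher(k, n, K, N),
                 ease_fisher(k, n, K, N, method = "fisher") - 1e-12)
})

test_that("de_filter applies the joint fold and p gate", {
  # 2 groups x 4 samples; one protein shifted 1.6-fold, one 1.4-fold
  set.seed(2)
  mat <- matrix(2^rnorm(4 * 8, 10, 0.05), nrow = 4,
                dimnames = list(paste0("P", 1:4), paste0("s", 1:8)))
  groups <- rep(c("Ctrl", "Cvs"), each = 4)
  mat[1, 5:8] <- mat[1, 5:8] * 1.6
  mat[2, 5:8] <- mat[2, 5:8] * 1.4
  de <- de_filter(mat, groups)
  tab <- de$table
  expect_equal(tab$direction[1], "up")
  expect_true(tab$p[2] < 0.05 && !tab$significant[2])  # fold gate blocks
  expect_equal(unname(de$summary["up"]), 1L)
})

test_that("empty and degenerate tables are handled", {
  m0 <- matrix(numeric(0), nrow = 0, ncol = 6,
               dimnames = list(NULL, paste0("s", 1:6)))
  de0 <- de_filter(m0, rep(c("a", "b"), each = 3))
  expect_equal(unname(de0$summary), c(0L, 0L, 0L))
  # identical samples: fold 1 everywhere, nothing passes, excluded rows
  m1 <- matrix(rep(c(4, 8, 16), 6), nrow = 3,
               dimnames = list(paste0("P", 1:3), paste0("s", 1:6)))
  de1 <- de_filter(m1, rep(c("a", "b"), each = 3))
  expect_equal(de1$table$fold_change, rep(1, 3))
  expect_false(any(de1$table$significant))
  expect_match(de1$table$excluded[1], "zero variance")
  expect_error(de_filter(m1, rep(c("a", "b"), each = 3),
                         fold_threshold = -1), "positive")
})

test_that("de_filter agrees with a naive double-loop oracle", {
  cfg <- generator_config(seed = 21,
                          omics = list(n_proteins = 200L,
                                       n_samples_per_group = 6L,
                                       n_up = 15L, n_down = 5L))
  mat <- gen_abundance_table(cfg)
  groups <- attr(mat, "groups")
  de <- de_filter(mat, groups)
  x <- log2(mat)
  ref <- groups == "Ctrl"
  for (i in seq_len(nrow(mat))) {
    p <- t.test(x[i, !ref], x[i, ref], var.equal = TRUE)$p.value
    fc <- 2^(mean(x[i, !ref]) - mean(x[i, ref]))
    sig <- p < 0.05 && (fc >= 1.5 || fc <= 1 / 1.5)
    expect_equal(de$table$p[i], p, tolerance = 1e-12)
    expect_equal(de$table$fold_change[i], fc, tolerance = 1e-12)
    expect_equal(de$table$significant[i], sig)
  }
})

test_that("enrichment finds the planted pathway with BH control", {
  cfg <- generator_config(seed = 22,
                          omics = list(n_proteins = 300L, n_up = 20L,
                                       n_down = 0L, fold_up = 3))
  mat <- gen_abundance_table(cfg)
  truth <- attr(mat, "truth")
  de <- de_filter(mat, attr(mat, "groups"))
  paths <- list(planted = truth$up,
                random = rownames(mat)[250:280])
  enr <- enrich_pathways(de$table$protein_id[de$table$significant],
                         paths, rownames(mat))
  expect_lt(enr$q[enr$pathway == "planted"], 0.01)
  expect_gt(enr$p[enr$pathway == "random"], 0.05)
})

test_that("z-scores standardize to mean 0, variance 1 per protein", {
  cfg <- generator_config(seed = 23,
                          omics = list(n_proteins = 40L, n_up = 0L,
                                       n_down = 0L))
  mat <- gen_abundance_table(cfg)
  pz <- pathway_zscores(mat, rownames(mat)[1:10], attr(mat, "groups"))
  expect_equal(unname(rowMeans(pz$z)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(pz$z, 1, sd)), rep(1, 10), tolerance = 1e-12)
  # normalization conservation over all members and samples
  expect_equal(mean(pz$z), 0, tolerance = 1e-12)
})

test_that("pathway contrast responds to a planted shift", {
  # identical groups: zero difference, CI containing 0
  m <- matrix(2^matrix(rnorm(6 * 8, 10, 0.3), nrow = 6), nrow = 6,
              dimnames = list(paste0("P", 1:6), paste0("s", 1:8)))
  m[, 5:8] <- m[, 1:4]
  pz0 <- pathway_zscores(m, rownames(m)[1:4],
                         rep(c("a", "b"), each = 4))
  expect_equal(pz0$mean_difference, 0, tolerance = 1e-12)
  expect_true(pz0$conf_int[1] <= 0 && pz0$conf_int[2] >= 0)
  # 4 proteins shifted +1 SD in one group: positive, CI excludes 0
  set.seed(7)
  base <- matrix(rnorm(4 * 10, 10, 0.2), nrow = 4)
  base[, 6:10] <- base[, 6:10] + 0.2   # +1 within-group SD
  m2 <- 2^base
  dimnames(m2) <- list(paste0("Q", 1:4), paste0("s", 1:10))
  pz <- pathway_zscores(m2, rownames(m2), rep(c("a", "b"), each = 5))
  expect_gt(pz$mean_difference, 0)
  expect_gt(pz$conf_int[1], 0)
  # singleton pathway: CI undefined but flagged
  pz1 <- pathway_zscores(m2, "Q1", rep(c("a", "b"), each = 5))
  expect_true(pz1$singleton && all(is.na(pz1$conf_int)))
})

test_that("mtDNA ratio doubles per Ct cycle and averages replicates first", {
  rec <- data.frame(animal_id = "A1", group = "Ctrl",
                    gene = rep(c("Nd1", "Lpl"), each = 3),
                    replicate = rep(1:3, 2),
                    ct = c(20, 20, 20, 20, 20, 20))
  expect_equal(mtdna_ratio(rec)$ratio, 1)
  rec$ct <- c(20, 20, 20, 21, 21, 21)
  expect_equal(mtdna_ratio(rec)$ratio, 2)
  # mean-first: scattered replicates with the same means give the same ratio
  rec$ct <- c(19.5, 20, 20.5, 20.8, 21, 21.2)
  expect_equal(mtdna_ratio(rec)$ratio, 2)
  # invariant to a constant shift of all Cts of an animal
  rec2 <- rec; rec2$ct <- rec$ct + 3
  expect_equal(mtdna_ratio(rec2)$ratio, mtdna_ratio(rec)$ratio)
  # missing gene names the animal
  expect_error(mtdna_ratio(rec[rec$gene == "Nd1", ]), "A1")
})
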
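test_that("relative gene coverage masks strictly above the discard bound", {
  r <- relative_gene_coverage(c(30, 31, 0, 1), genome_depth = 10)
  expect_equal(r[1], 3.0)                       # boundary retained
  expect_true(is.na(r[2]))                      # 3.1 masked
  expect_equal(r[3], 0)                         # absent gene is a real zero
  expect_equal(r[4], 0.1)                       # detection boundary value
  expect_identical(attr(r, "masked"), c(FALSE, TRUE, FALSE, FALSE))
  expect_error(relative_gene_coverage(c(1, 2), 0), "genome_depth")
})

test_that("differential presence finds a planted signal and respects BH", {
  set.seed(12)
  n_genes <- 60
  labels <- rep(c("HOT", "BATS"), each = 10)
  mat <- matrix(pmax(rnorm(n_genes * 20, 1, 0.05), 0), n_genes, 20)
  rownames(mat) <- sprintf("gene_%03d", 1:n_genes)
  # gene 1: present at HOT, absent at BATS
  mat[1, ] <- c(pmax(rnorm(10, 1, 0.05), 0), abs(rnorm(10, 0, 0.01)))
  res <- differential_gene_presence(mat, labels)
  expect_true(res$differential[1])
  expect_lt(mean(res$differential[-1]), 0.05)
  # single tested gene: adjusted p equals raw p
  single <- differential_gene_presence(mat[1, , drop = FALSE], labels)
  expect_equal(single$p_adj, single$p)
})

test_that("genes with too few unmasked values are reported untested", {
  mat <- matrix(1, 2, 8)
  rownames(mat) <- c("g1", "g2")
  mat[2, 1:3] <- NA          # one group left with a single value
  labels <- rep(c("a", "b"), each = 4)
  res <- differential_gene_presence(mat, labels)
  expect_true(res$tested[1])
  expect_false(res$tested[2])
  expect_true(is.na(res$p[2]))
})

test_that("null differential-presence calls are rare and p is uniform-ish", {
  set.seed(13)
  n_genes <- 800
  labels <- rep(c("HOT", "BATS"), each = 8)
  mat <- matrix(pmax(rnorm(n_genes * 16, 1, 0.2), 0), n_genes, 16)
  rownames(mat) <- sprintf("g%04d", 1:n_genes)
  res <- differential_gene_presence(mat, labels)
  expect_lt(mean(res$differential), 0.005)
  expect_gt(mean(res$p, na.rm = TRUE), 0.45)
  expect_lt(mean(res$p, na.rm = TRUE), 0.55)
})

test_that("basin-specific classification applies the detection rules", {
  labels <- rep(c("HOT", "BATS"), each = 3)
  mat <- rbind(
    hot_specific = c(0.8, 0.9, 0.7, 0.05, 0.02, 0.0),
    shared       = c(0.8, 0.9, 0.7, 0.5, 0.6, 0.7),
    boundary     = c(0.8, 0.9, 0.7, 0.10, 0.10, 0.10),
    bats_specific = c(0.0, 0.05, 0.09, 0.9, 0.8, 0.95))
  diff_tab <- data.frame(gene_id = rownames(mat),
                         f_stat = 100, p = 1e-8, p_adj = 1e-7,
                         tested = TRUE, differential = TRUE)
  res <- basin_specific_genes(mat, labels, diff_tab)
  expect_equal(res$classification[1], "HOT_specific")
  expect_equal(res$classification[2], "shared")
  # r = 0.10 exactly: not detected and not absent-qualified -> shared
  expect_equal(res$classification[3], "shared")
  expect_equal(res$classification[4], "BATS_specific")
  # symmetric under swapping the site labels
  swapped <- basin_specific_genes(mat, rev(labels), diff_tab)
  expect_equal(swapped$classification[1], "BATS_specific")
  expect_equal(swapped$classification[4], "HOT_specific")
  # outside the gate: unclassified
  diff_tab$p_adj <- 0.5
  res2 <- basin_specific_genes(mat, labels, diff_tab)
  expect_true(all(is.na(res2$classification)))
})

test_that("spiked site-exclusive genes are recovered from read coverage", {
  ann <- small_annotation()
  dp <- simulate_deme_pair(ann, n_strains = 20, target_fst = 0.1,
                           pi_within = 0.01, n_exclusive_a = 3,
                           n_exclusive_b = 3, seed = 91)
  pl <- list()
  for (t in 1:3) {
    pl[[paste0("HOT_", t)]] <- build_pileup(
      simulate_sample_reads(dp$pool_a, 40, seed = 910 + t,
                            absent_ranges = dp$absent_ranges_a), ann)
    pl[[paste0("BATS_", t)]] <- build_pileup(
      simulate_sample_reads(dp$pool_b, 40, seed = 920 + t,
                            absent_ranges = dp$absent_ranges_b), ann)
  }
  labels <- rep(c("HOT", "BATS"), 3)[order(rep(1:3, 2))]
  labels <- ifelse(grepl("HOT", names(pl)), "HOT", "BATS")
  mat <- gene_coverage_matrix(pl, ann)
  diff_tab <- differential_gene_presence(mat, labels)
  res <- basin_specific_genes(mat, labels, diff_tab)
  called_hot <- res$gene_id[!is.na(res$classification) &
                              res$classification == "HOT_specific"]
  called_bats <- res$gene_id[!is.na(res$classification) &
                               res$classification == "BATS_specific"]
  expect_setequal(called_hot, dp$truth$exclusive_a)
  expect_setequal(called_bats, dp$truth$exclusive_b)
})

test_that("openness fit: accumulation is monotone, gamma spans the extremes", {
  pa <- simulate_presence_absence(12, gamma = 0.4, seed = 5)
  fit <- pangenome_openness(pa, n_permutations = 30, seed = 6)
  expect_true(all(diff(fit$curve$median) >= 0))
  expect_true(is.finite(fit$gamma))
  # identical genomes: flat curve, gamma ~ 0
  ident <- matrix(1L, 6, 40,
                  dimnames = list(NULL, sprintf("c%02d", 1:40)))
  expect_lt(abs(pangenome_openness(ident, 20, seed = 1)$gamma), 1e-8)
  # fully disjoint gene blocks: P(N) = kN, gamma -> 1
  disjoint <- matrix(0L, 20, 400)
  for (i in 1:20) disjoint[i, ((i - 1) * 20 + 1):(i * 20)] <- 1L
  colnames(disjoint) <- sprintf("c%03d", 1:400)
  expect_gte(pangenome_openness(disjoint, 20, seed = 1)$gamma, 0.9)
  expect_error(pangenome_openness(matrix(1L, 3, 5), seed = 1), "4 genomes")
  expect_error(pangenome_openness(cbind(ident, 0L), seed = 1), "empty")
})

test_that("openness recovers the generator's target exponent over seeds", {
  fits <- vapply(1:5, function(s) {
    pa <- simulate_presence_absence(20, gamma = 0.4, seed = s)
    pangenome_openness(pa, n_permutations = 50, seed = s + 100)$gamma
  }, numeric(1))
  expect_true(all(fits >= 0.35 & fits <= 0.45))
})
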
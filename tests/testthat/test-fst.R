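make_locus_pileups <- function(p1, p2, n1, n2, L = 2000L, spacing = 50L) {
  # two pileups with biallelic A/G loci at given frequencies and depths
  k <- length(p1)
  pos <- seq(100L, by = spacing, length.out = k)
  ca <- matrix(0L, L, 4)
  cb <- matrix(0L, L, 4)
  ca[pos, 1] <- round(p1 * n1)
  ca[pos, 3] <- n1 - round(p1 * n1)
  cb[pos, 1] <- round(p2 * n2)
  cb[pos, 3] <- n2 - round(p2 * n2)
  list(a = make_pileup(ca), b = make_pileup(cb), pos = pos)
}

test_that("locus-level Hudson FST matches hand arithmetic", {
  # fixed difference -> 1
  lp <- make_locus_pileups(1.0, 0.0, 20, 20)
  loci <- strainpop:::fst_loci(lp$a, lp$b, min_depth = 20)
  expect_equal(nrow(loci), 1L)
  expect_equal(strainpop:::hudson_fst_from_loci(loci), 1)
  # identical frequencies at depth 21: num = -0.025, den = 0.5 -> -0.05
  lp2 <- make_locus_pileups(10.5 / 21, 10.5 / 21, 21, 21)
  # 0.5 not exactly representable in counts of 21; construct manually
  loci2 <- data.frame(pos = 1L, a1 = 1L, a2 = 3L, p1 = 0.5, p2 = 0.5,
                      n1 = 21, n2 = 21)
  expect_equal(strainpop:::hudson_fst_from_loci(loci2), -0.05)
})

test_that("identical high-depth samples give near-zero gene FST", {
  ann <- small_annotation()
  pool <- small_pool()
  reads <- simulate_sample_reads(pool, coverage = 200, seed = 41)
  p <- build_pileup(reads, ann)
  tab <- fst_by_gene(p, p, ann)
  defined <- !is.na(tab$fst)
  expect_gt(sum(defined), 5)
  expect_true(all(abs(tab$fst[defined]) < 0.02))
})

test_that("pooled-count FST matches the infinite-depth haplotype oracle", {
  # explicit two subpopulations of haplotypes at <= 10 SNV loci
  set.seed(77)
  for (rep in 1:5) {
    k <- sample(3:10, 1)
    f1 <- runif(k, 0.1, 0.9)
    f2 <- pmin(pmax(f1 + runif(k, -0.4, 0.4), 0.05), 0.95)
    # oracle: Hudson ratio-of-sums from the population frequencies
    num <- sum((f1 - f2)^2)
    den <- sum(f1 * (1 - f2) + f2 * (1 - f1))
    oracle <- num / den
    # implementation at very high depth (finite-depth correction -> 0)
    n <- 200000L
    lp <- make_locus_pileups(f1, f2, n, n)
    loci <- strainpop:::fst_loci(lp$a, lp$b, min_depth = 20)
    est <- strainpop:::hudson_fst_from_loci(loci)
    expect_equal(est, oracle, tolerance = 0.01)
  }
})

test_that("two-deme simulation recovers the truth FST within 15%", {
  ann <- small_annotation()
  for (tf in c(0.05, 0.2, 0.45)) {
    dp <- simulate_deme_pair(ann, n_strains = 30, target_fst = tf,
                             pi_within = 0.01, seed = 50 + round(100 * tf))
    ra <- simulate_sample_reads(dp$pool_a, coverage = 50, seed = 51)
    rb <- simulate_sample_reads(dp$pool_b, coverage = 50, seed = 52)
    pa <- build_pileup(ra, ann)
    pb <- build_pileup(rb, ann)
    est <- strainpop:::hudson_fst_from_loci(
      strainpop:::fst_loci(pa, pb, min_depth = 20))
    truth <- dp$truth$fst_genome
    expect_lt(abs(truth - tf) / tf, 0.05)    # calibration held
    expect_lt(abs(est - truth) / truth, 0.15)
  }
})

test_that("samples from one pool show negligible mean FST", {
  ann <- small_annotation()
  pool <- small_pool()
  r1 <- simulate_sample_reads(pool, coverage = 50, seed = 61)
  r2 <- simulate_sample_reads(pool, coverage = 50, seed = 62)
  pl <- list(s1 = build_pileup(r1, ann), s2 = build_pileup(r2, ann))
  pw <- pairwise_mean_fst(pl, ann)
  expect_true(isSymmetric(pw$fst))
  expect_equal(unname(diag(pw$fst)), c(0, 0))
  expect_lt(abs(pw$fst[1, 2]), 0.01)
  expect_error(pairwise_mean_fst(pl[1], ann), "2 samples")
})

test_that("FST outlier Z test flags the documented extreme gene", {
  # background distribution matching the genome-wide mean 0.038, sd 0.032;
  # one gene at 0.442 gives z ~ 12.6 and an adjusted p far below 0.05
  set.seed(8)
  fst <- c(rnorm(200, 0.038, 0.032), 0.442)
  names(fst) <- sprintf("g%03d", seq_along(fst))
  res <- fst_outlier_test(fst)
  expect_true(res$outlier[201])
  expect_gt(res$z[201], 8)
  # all-identical FSTs: warning and nothing flagged
  expect_warning(res0 <- fst_outlier_test(rep(0.1, 20)), "zero variance")
  expect_false(any(res0$outlier))
  expect_error(fst_outlier_test(c(0.1, 0.2)), "at least 10")
})

test_that("FST outlier test controls type I error on null simulations", {
  ann <- small_annotation()
  pool <- small_pool()
  frac <- vapply(1:3, function(s) {
    r1 <- simulate_sample_reads(pool, coverage = 50, seed = 70 + s)
    r2 <- simulate_sample_reads(pool, coverage = 50, seed = 80 + s)
    tab <- fst_by_gene(build_pileup(r1, ann), build_pileup(r2, ann), ann)
    res <- fst_outlier_test(setNames(tab$fst, tab$gene_id))
    mean(res$outlier[!is.na(res$fst)])
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("PCoA with Cailliez correction embeds non-Euclidean matrices", {
  # collinear points: already Euclidean, no correction, axis 1 explains all
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  fit <- pcoa_cailliez(d3)
  expect_equal(fit$correction, 0)
  expect_equal(fit$explained[1], 1)
  # zero matrix: all coordinates zero
  z <- pcoa_cailliez(matrix(0, 4, 4))
  expect_true(all(z$coordinates == 0))
  # non-Euclidean 4x4: corrected Gram matrix has no negative eigenvalues and
  # embedded distances reproduce the corrected dissimilarities
  d <- matrix(0, 4, 4)
  d[upper.tri(d)] <- c(1, 1, 1, 1, 1, 1.95)
  d <- d + t(d)
  fit2 <- pcoa_cailliez(d)
  expect_gt(fit2$correction, 0)
  dc <- d + fit2$correction
  diag(dc) <- 0
  emb <- as.matrix(dist(fit2$coordinates))
  expect_lt(max(abs(emb - dc)), 1e-6)
  gram_min <- min(eigen(strainpop:::gower_center(dc^2),
                        symmetric = TRUE, only.values = TRUE)$values)
  expect_gt(gram_min, -1e-8)
  expect_error(pcoa_cailliez(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("our PCoA agrees with the reference implementation", {
  skip_if_not_installed("ape")
  set.seed(3)
  x <- matrix(rnorm(20), 5, 4)
  d <- as.matrix(dist(x))^1.7
  rownames(d) <- colnames(d) <- paste0("s", 1:5)
  ours <- pcoa_cailliez(d)
  ref <- ape::pcoa(stats::as.dist(d), correction = "cailliez")
  k <- min(ncol(ours$coordinates), sum(ref$values$Corr_eig > 1e-8))
  expect_equal(ours$eigenvalues[1:k], ref$values$Corr_eig[1:k],
               tolerance = 1e-6)
  for (ax in 1:2) {
    expect_equal(abs(ours$coordinates[, ax]),
                 abs(ref$vectors.cor[, ax]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("consensus divergence dating is zero on identity", {
  ann <- small_annotation()
  p <- small_pileup()
  self <- consensus_divergence_time(p, p, ann)
  expect_equal(self$generations, 0)
  expect_equal(self$n_diff, 0L)
  expect_equal(self$years, 0)
})

test_that("divergence dating recovers simulated third-position divergence", {
  # two populations whose consensus differs at a known fraction of
  # third positions
  ann <- small_annotation()
  map <- strainpop:::site_codon_map(ann)
  third <- map$pos[map$codon_pos == 3L]
  set.seed(9)
  flip <- sample(third, round(0.002 * length(third) / 1))
  ref_chars <- strsplit(ann$contig_seq, "")[[1]]
  counts_a <- matrix(0L, ann$length, 4)
  idx <- match(ref_chars, c("A", "C", "G", "T"))
  for (i in seq_len(ann$length)) counts_a[i, idx[i]] <- 30L
  counts_b <- counts_a
  for (ps in flip) {
    counts_b[ps, ] <- 0L
    counts_b[ps, (idx[ps] %% 4) + 1L] <- 30L
  }
  est <- consensus_divergence_time(make_pileup(counts_a),
                                   make_pileup(counts_b), ann)
  d3_true <- length(flip) / length(third)
  expect_equal(est$d3, d3_true, tolerance = 1e-9)
  expect_equal(est$generations, d3_true / (2 * 1e-10))
  expect_equal(est$years, est$generations * 7 / 365.25)
})
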
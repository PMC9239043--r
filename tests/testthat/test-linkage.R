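test_that("r-squared matches hand arithmetic and its invariants", {
  expect_equal(r_squared(c(10, 0, 0, 10)), 1)
  expect_equal(r_squared(c(5, 5, 5, 5)), 0)
  # counts (12,2,2,4): f_A = f_B = 0.7, f_AB = 0.6, D = 0.11
  expect_equal(r_squared(c(12, 2, 2, 4)), 0.11^2 / (0.21 * 0.21),
               tolerance = 1e-12)
  # label swap at either site leaves r^2 unchanged
  set.seed(1)
  for (k in 1:20) {
    n <- as.numeric(rmultinom(1, 40, c(0.4, 0.2, 0.2, 0.2)))
    r0 <- r_squared(n)
    expect_equal(r_squared(n[c(3, 4, 1, 2)]), r0)   # swap site 1 alleles
    expect_equal(r_squared(n[c(2, 1, 4, 3)]), r0)   # swap site 2 alleles
  }
  # monomorphic margin undefined
  expect_true(is.na(r_squared(c(20, 0, 0, 0))))
})

test_that("rarefied r2 equals raw when counts equal the subsample size", {
  counts <- c(12, 2, 2, 4)
  expect_equal(r_squared_rarefied(counts, subsample_size = 20, seed = 1),
               r_squared(counts))
  expect_error(r_squared_rarefied(c(5, 5, 5, 4), subsample_size = 20,
                                  seed = 1), "fewer")
})

test_that("rarefied r2 is an unbiased-looking subsample mean, seeded", {
  counts <- c(60, 15, 15, 30)
  v1 <- r_squared_rarefied(counts, seed = 5)
  v2 <- r_squared_rarefied(counts, seed = 5)
  expect_identical(v1, v2)
  expect_gte(v1, 0)
  expect_lte(v1, 1)
  # perfectly linked counts stay 1 under any subsample
  expect_equal(r_squared_rarefied(c(50, 0, 0, 30), seed = 2), 1)
})

test_that("pair enumeration enforces distance and connecting-pair gates", {
  snvs <- small_snvs()
  reads <- small_reads()
  pairs <- enumerate_linked_pairs(snvs, reads, max_dist = 420,
                                  min_connecting_pairs = 20)
  expect_gt(nrow(pairs), 10)
  expect_true(all(pairs$distance <= 420))
  expect_true(all(pairs$n_total >= 20))
  expect_true(all(pairs$class_pair %in% c("N-N", "N-S", "S-S")))
  # intergenic SNVs excluded by default
  ig <- snvs$pos[snvs$class == "intergenic"]
  expect_false(any(pairs$pos1 %in% ig | pairs$pos2 %in% ig))
  # stricter gates retain a subset
  strict <- enumerate_linked_pairs(snvs, reads, max_dist = 200,
                                   min_connecting_pairs = 30)
  expect_true(all(strict$distance <= 200))
  expect_true(all(strict$n_total >= 30))
  expect_lte(nrow(strict), nrow(pairs))
})

test_that("joint counts agree with brute-force iteration over read pairs", {
  snvs <- small_snvs()
  reads <- small_reads()[1:800, ]
  pairs <- enumerate_linked_pairs(snvs, reads, max_dist = 420,
                                  min_connecting_pairs = 5)
  expect_gt(nrow(pairs), 5)
  # independent oracle: direct per-read-pair base lookup
  base_at <- function(row, pos) {
    b <- character(0)
    if (pos >= row$start1 && pos <= row$end1) {
      b <- c(b, substr(row$seq1, pos - row$start1 + 1,
                       pos - row$start1 + 1))
    }
    if (pos >= row$start2 && pos <= row$end2) {
      b <- c(b, substr(row$seq2, pos - row$start2 + 1,
                       pos - row$start2 + 1))
    }
    u <- unique(b)
    if (length(u) == 1L) u else NA_character_
  }
  idx <- sample.int(nrow(pairs), min(8, nrow(pairs)))
  for (k in idx) {
    pr <- pairs[k, ]
    s1 <- snvs[snvs$pos == pr$pos1, ]
    s2 <- snvs[snvs$pos == pr$pos2, ]
    cnt <- c(0L, 0L, 0L, 0L)
    for (i in seq_len(nrow(reads))) {
      row <- reads[i, ]
      b1 <- base_at(row, pr$pos1)
      b2 <- base_at(row, pr$pos2)
      if (is.na(b1) || is.na(b2)) next
      a1 <- if (b1 == s1$consensus) 0L else if (b1 == s1$minor) 1L else NA
      a2 <- if (b2 == s2$consensus) 0L else if (b2 == s2$minor) 1L else NA
      if (is.na(a1) || is.na(a2)) next
      cell <- 2L * a1 + a2 + 1L
      cnt[cell] <- cnt[cell] + 1L
    }
    expect_identical(unname(unlist(pr[c("n_AB", "n_Ab", "n_aB", "n_ab")])),
                     cnt)
  }
})

test_that("decay curve bins average pair values and report empty bins", {
  pairs <- data.frame(pos1 = c(10, 10, 10), pos2 = c(20, 40, 400),
                      distance = c(10, 30, 390),
                      class_pair = c("S-S", "S-S", "S-S"),
                      n_AB = 10, n_Ab = 5, n_aB = 3, n_ab = 2, n_total = 20,
                      r2_raw = c(0.2, 0.4, 0.5),
                      r2_rarefied = c(0.2, 0.4, 0.5))
  curve <- linkage_decay_curve(pairs, bin_width = 30)
  all_rows <- curve[curve$stratum == "all", ]
  expect_equal(all_rows$mean_r2[1], 0.3)          # (0.2 + 0.4) / 2 in (0,30]
  expect_equal(all_rows$n_pairs[1], 2L)
  expect_true(is.na(all_rows$mean_r2[5]))         # empty bin reported NA
  expect_equal(all_rows$n_pairs[5], 0L)
  expect_equal(sum(all_rows$n_pairs), 3L)
  # flat input -> flat curve
  pairs$r2_rarefied <- 0.5
  flat <- linkage_decay_curve(pairs, bin_width = 30)
  vals <- flat$mean_r2[flat$stratum == "all"]
  expect_true(all(vals[!is.na(vals)] == 0.5))
})

test_that("mean genome r2 is the unweighted mean over retained pairs", {
  pairs <- data.frame(r2_rarefied = c(0.2, 0.4))
  expect_equal(mean_genome_r2(pairs), 0.3)
  expect_equal(mean_genome_r2(data.frame(r2_rarefied = 1)), 1)
  expect_true(is.na(mean_genome_r2(data.frame(r2_rarefied = numeric()))))
})

test_that("free recombination gives near-null linkage, clonal gives r2 = 1", {
  ann <- small_annotation()
  free <- simulate_strain_pool(ann, n_strains = 40, target_pi = 0.01,
                               recomb_block_len = 1, seed = 31)
  reads <- simulate_sample_reads(free, coverage = 60, seed = 32)
  p <- build_pileup(reads, ann)
  snvs <- call_snvs(p, ann)
  pairs <- add_rarefied_r2(enumerate_linked_pairs(snvs, reads), seed = 33)
  # finite-sample null for r2 at 20 draws is ~1/20
  expect_lt(mean_genome_r2(pairs), 0.15)

  two <- simulate_strain_pool(ann, n_strains = 2, target_pi = 0.01,
                              recomb_block_len = Inf, seed = 34,
                              strain_freqs = c(0.5, 0.5))
  reads2 <- simulate_sample_reads(two, coverage = 60, seed = 35)
  p2 <- build_pileup(reads2, ann)
  snvs2 <- call_snvs(p2, ann)
  pairs2 <- add_rarefied_r2(enumerate_linked_pairs(snvs2, reads2),
                            seed = 36)
  expect_gt(nrow(pairs2), 10)
  expect_gt(mean(pairs2$r2_rarefied), 0.95)
})
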
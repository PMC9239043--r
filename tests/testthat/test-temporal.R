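make_traj <- function(freqs, classes) {
  snvs <- data.frame(contig = "contig_1", pos = seq_len(nrow(freqs)),
                     class = classes, stringsAsFactors = FALSE)
  rownames(freqs) <- paste0("contig_1:", snvs$pos)
  structure(list(freqs = freqs, snvs = snvs, min_coverage = 20),
            class = "trajectory_matrix")
}

test_that("frequency matrix records focal-allele frequencies with missing", {
  ann <- small_annotation()
  counts1 <- matrix(0L, ann$length, 4)
  counts2 <- matrix(0L, ann$length, 4)
  ref_idx <- match(strsplit(ann$contig_seq, "")[[1]],
                   c("A", "C", "G", "T"))
  for (i in seq_len(ann$length)) {
    counts1[i, ref_idx[i]] <- 60L
    counts2[i, ref_idx[i]] <- 10L     # below the 20x trajectory gate
  }
  # a site with A/G split 60/40 in sample 1; reference there must be A
  pos <- which(strsplit(ann$contig_seq, "")[[1]] == "A")[5]
  counts1[pos, ] <- c(60L, 0L, 40L, 0L)
  counts2[pos, ] <- c(6L, 0L, 4L, 0L)
  pl <- list(s1 = make_pileup(counts1), s2 = make_pileup(counts2))
  traj <- snv_frequency_matrix(pl, ann, min_coverage = 20)
  row <- which(traj$snvs$pos == pos)
  expect_equal(unname(traj$freqs[row, "s1"]), 0.40)
  expect_true(is.na(traj$freqs[row, "s2"]))
  f <- traj$freqs[!is.na(traj$freqs)]
  expect_true(all(f >= 0 & f <= 1))
})

test_that("monotone frequency-temperature coupling gives rho 1 and a flag", {
  temp <- c(10, 11, 12, 13, 14, 15, 16, 17, 18, 19)
  freqs <- rbind(seq(0.1, 0.55, length.out = 10),
                 rep(0.4, 10))
  traj <- make_traj(freqs, c("nonsynonymous", "nonsynonymous"))
  res <- covariate_correlated_snvs(traj, temp)
  expect_equal(res$rho[1], 1)
  expect_true(res$significant[1])
  expect_false(isTRUE(res$significant[2]))
  # synonymous SNVs are not tested by default but can be opted in
  traj2 <- make_traj(freqs, c("synonymous", "synonymous"))
  res2 <- covariate_correlated_snvs(traj2, temp)
  expect_false(any(res2$tested))
  res3 <- covariate_correlated_snvs(traj2, temp,
                                    classes = c("synonymous",
                                                "nonsynonymous"))
  expect_true(res3$tested[1])
})

test_that("too few observations leave an SNV untested", {
  temp <- 1:10
  f <- rep(NA_real_, 10)
  f[1:3] <- c(0.1, 0.2, 0.3)
  traj <- make_traj(rbind(f), "nonsynonymous")
  res <- covariate_correlated_snvs(traj, temp, min_points = 8)
  expect_false(res$tested[1])
  expect_equal(res$n_obs[1], 3L)
})

test_that("rho is invariant under monotone transforms of the covariate", {
  set.seed(5)
  temp <- sort(runif(12, 5, 20))
  freqs <- rbind(runif(12), runif(12))
  traj <- make_traj(freqs, rep("nonsynonymous", 2))
  r1 <- covariate_correlated_snvs(traj, temp)
  r2 <- covariate_correlated_snvs(traj, exp(temp / 3))
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p, r2$p)
})

test_that("permuted-covariate null yields uniform p and near-zero flags", {
  set.seed(6)
  n <- 1000
  freqs <- matrix(pmin(pmax(rnorm(n * 12, 0.4, 0.05), 0), 1), n, 12)
  traj <- make_traj(freqs, rep("nonsynonymous", n))
  temp <- sample(seq(8, 19, length.out = 12))
  res <- covariate_correlated_snvs(traj, temp)
  expect_lt(mean(res$significant), 0.005)
  expect_gt(mean(res$p), 0.45)
  expect_lt(mean(res$p), 0.55)
})

test_that("simulated responsive SNVs are recovered with high sensitivity", {
  ann <- small_annotation()
  pool <- small_pool()
  env <- simulate_env_series(12, site = "HOT", seed = 7)
  stats <- vapply(c(71, 72, 73), function(s) {
    ts <- simulate_time_series(pool, env, n_responsive = 20, coupling = 3,
                               coverage = 50, seed = s)
    pl <- lapply(ts$reads, build_pileup, annotation = ann)
    traj <- snv_frequency_matrix(pl, ann, min_coverage = 20)
    res <- covariate_correlated_snvs(traj, env$temperature_c)
    hit <- res$pos[res$significant]
    c(sens = mean(ts$truth$responsive_pos %in% hit),
      fdp = if (length(hit)) mean(!(hit %in% ts$truth$responsive_pos))
            else 0)
  }, numeric(2))
  expect_gte(mean(stats["sens", ]), 0.8)
  expect_lte(mean(stats["fdp", ]), 0.1)
})

test_that("time-series simulation validates inputs and is deterministic", {
  pool <- small_pool()
  env <- simulate_env_series(6, seed = 1)
  expect_error(simulate_time_series(pool, env[1:3, ], 5, 2, seed = 1),
               "4 samples")
  ts1 <- simulate_time_series(pool, env, n_responsive = 5, coupling = 2,
                              coverage = 10, seed = 3)
  ts2 <- simulate_time_series(pool, env, n_responsive = 5, coupling = 2,
                              coverage = 10, seed = 3)
  expect_identical(ts1$reads, ts2$reads)
  expect_identical(ts1$truth$responsive_pos, ts2$truth$responsive_pos)
  # coupling 0 disables responsiveness
  ts0 <- simulate_time_series(pool, env, n_responsive = 5, coupling = 0,
                              coverage = 10, seed = 3)
  expect_length(ts0$truth$responsive_pos, 0)
})
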
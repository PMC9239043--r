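test_that("per-site diversity follows 1 - sum(f^2)", {
  counts <- matrix(0L, 6, 4)
  counts[1, ] <- c(100L, 0L, 0L, 0L)       # monomorphic: 0
  counts[2, ] <- c(50L, 50L, 0L, 0L)       # balanced biallelic: 0.5
  counts[3, ] <- c(25L, 25L, 25L, 25L)     # maximal: 0.75
  counts[4, ] <- c(90L, 10L, 0L, 0L)       # 1 - 0.81 - 0.01 = 0.18
  counts[5, ] <- c(3L, 1L, 0L, 0L)         # below min coverage: excluded
  p <- make_pileup(counts)
  d <- nucleotide_diversity(p, min_coverage = 5)
  expect_equal(d$pi_site[1], 0)
  expect_equal(d$pi_site[2], 0.5)
  expect_equal(d$pi_site[3], 0.75)
  expect_equal(d$pi_site[4], 0.18)
  expect_true(is.na(d$pi_site[5]))
  expect_true(is.na(d$pi_site[6]))
  expect_equal(d$n_sites, 4L)
  expect_equal(d$genome_pi, mean(c(0, 0.5, 0.75, 0.18)))
})

test_that("diversity is undefined, not zero, with no eligible sites", {
  p <- make_pileup(matrix(0L, 10, 4))
  d <- nucleotide_diversity(p, min_coverage = 5)
  expect_true(is.na(d$genome_pi))
  expect_equal(d$n_sites, 0L)
})

test_that("pN/pS single-codon worked example: GGG gives sites (1, 2)", {
  # all 9 single-base changes of GGG: third position GGA/GGC/GGT all Gly
  # (3 synonymous), positions 1-2 all nonsynonymous -> S = 1, N = 2
  cds <- paste0("ATG", "GGG", "TAA")
  ann <- make_gene_annotation(cds)
  counts <- matrix(0L, ann$length, 4)
  ref_idx <- match(strsplit(ann$contig_seq, "")[[1]], c("A", "C", "G", "T"))
  for (i in seq_len(ann$length)) counts[i, ref_idx[i]] <- 50L
  gstart <- ann$genes$start
  # one synonymous SNV at GGG third position, one nonsynonymous at first
  counts[gstart + 5L, ] <- c(10L, 0L, 40L, 0L)  # GGG -> GGA syn
  counts[gstart + 3L, ] <- c(10L, 0L, 40L, 0L)  # GGG -> AGG nonsyn
  p <- make_pileup(counts)
  snvs <- call_snvs(p, ann)
  res <- pnps(snvs, ann, p)
  g <- res$by_gene
  # whole gene: ATG (0 syn sites) + GGG (1 syn) + stop codon
  codon_syn <- strainpop:::codon_syn_counts()
  expected_s <- sum(rowSums(codon_syn[c("ATG", "GGG", "TAA"), ])) / 3
  expect_equal(g$s_sites, expected_s)
  expect_equal(g$n_sites, 9 - expected_s)
  expect_equal(g$s_snv, 1)
  expect_equal(g$n_snv, 1)
  expect_equal(g$pnps, (1 / g$n_sites) / (1 / g$s_sites))
})

test_that("pN/pS is zero with only synonymous SNVs and averages unweighted", {
  by_gene <- data.frame(pnps = c(0.2, 0.4, NA))
  expect_equal(mean(by_gene$pnps, na.rm = TRUE), 0.3)
  # genome value from the implementation on a two-gene synthetic case
  snvs <- small_snvs()
  ann <- small_annotation()
  p <- small_pileup()
  res <- pnps(snvs, ann, p)
  defined <- !is.na(res$by_gene$pnps)
  expect_equal(res$genome_pnps, mean(res$by_gene$pnps[defined]))
  only_syn <- res$by_gene$s_snv > 0 & res$by_gene$n_snv == 0
  if (any(only_syn)) {
    expect_true(all(res$by_gene$pnps[only_syn] == 0))
  }
})

test_that("site counting matches exhaustive codon-substitution enumeration", {
  # independent oracle: translate every possible single-base change of every
  # codon of a gene and count synonymous fractions directly
  set.seed(42)
  ann <- simulate_reference(4000, 5, gc = 0.45, seed = 42,
                            min_gene_len = 60, max_gene_len = 90)
  counts <- matrix(0L, ann$length, 4)
  ref_idx <- match(strsplit(ann$contig_seq, "")[[1]], c("A", "C", "G", "T"))
  for (i in seq_len(ann$length)) counts[i, ref_idx[i]] <- 30L
  p <- make_pileup(counts)
  res <- pnps(call_snvs(p, ann), ann, p)
  gc_map <- Biostrings::GENETIC_CODE
  for (gi in seq_len(nrow(ann$genes))) {
    g <- ann$genes[gi, ]
    cds <- substr(ann$contig_seq, g$start, g$end)
    if (g$strand == "-") {
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    }
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                        seq(3, nchar(cds), 3))
    s_sites <- 0
    for (cd in codons) {
      for (pp in 1:3) {
        for (b in setdiff(c("A", "C", "G", "T"),
                          substr(cd, pp, pp))) {
          cd2 <- cd
          substr(cd2, pp, pp) <- b
          if (gc_map[[cd2]] == gc_map[[cd]]) s_sites <- s_sites + 1 / 3
        }
      }
    }
    row <- res$by_gene[res$by_gene$gene_id == g$gene_id, ]
    expect_equal(row$s_sites, s_sites, tolerance = 1e-9)
    expect_equal(row$n_sites, 3 * length(codons) - s_sites,
                 tolerance = 1e-9)
  }
})

test_that("neutral third-position diversity averages only eligible sites", {
  # gene of 4-fold codons (GGx): every third position is eligible
  cds <- paste0("ATG", strrep("GGA", 10), "TAA")
  ann <- make_gene_annotation(cds)
  counts <- matrix(0L, ann$length, 4)
  ref_idx <- match(strsplit(ann$contig_seq, "")[[1]], c("A", "C", "G", "T"))
  for (i in seq_len(ann$length)) counts[i, ref_idx[i]] <- 50L
  gstart <- ann$genes$start
  # exactly one polymorphic eligible site with pi = 0.5
  counts[gstart + 5L, ] <- c(25L, 0L, 25L, 0L)
  p <- make_pileup(counts)
  res <- neutral_third_position_pi(p, ann)
  # eligible: 10 GGA third positions (GGx is 4-fold); ATG and TAA are not
  expect_equal(res$n, 10L)
  expect_equal(res$pi_neutral, 0.5 / 10)
})

test_that("neutral diversity is undefined without 4-fold codons", {
  # AAA/TTT codons are not 4-fold degenerate at position 3
  cds <- paste0("ATG", strrep("AAA", 5), "TAA")
  ann <- make_gene_annotation(cds)
  counts <- matrix(0L, ann$length, 4)
  ref_idx <- match(strsplit(ann$contig_seq, "")[[1]], c("A", "C", "G", "T"))
  for (i in seq_len(ann$length)) counts[i, ref_idx[i]] <- 50L
  res <- neutral_third_position_pi(make_pileup(counts), ann)
  expect_true(is.na(res$pi_neutral))
  expect_equal(res$n, 0L)
})

test_that("effective population size formula and domain behave", {
  # headline evaluation: pi_neutral = 0.284, mu = 1e-10 -> ~2.3e9
  ne <- effective_population_size(0.284, 1e-10)
  expect_equal(signif(ne, 2), 2.3e9)
  expect_equal(effective_population_size(0, 1e-10), 0)
  expect_equal(effective_population_size(0.1, 1e-9),
               0.15 / (1e-9 * 2.6))
  # strictly increasing in pi
  pis <- seq(0.01, 0.7, by = 0.01)
  nes <- vapply(pis, effective_population_size, numeric(1), mu = 1e-10)
  expect_true(all(diff(nes) > 0))
  expect_error(effective_population_size(0.75, 1e-10), "0.75")
  expect_error(effective_population_size(0.2, 0), "mu")
})

test_that("diversity estimate recovers the simulated target at 50x", {
  ann <- small_annotation()
  pool <- small_pool()            # target pi 0.02
  p <- small_pileup()
  d <- nucleotide_diversity(p, min_coverage = 5)
  truth <- pool_pi_from_haplotypes(pool)
  expect_lt(abs(d$genome_pi - truth) / truth, 0.10)
  expect_lt(abs(d$genome_pi - 0.02) / 0.02, 0.10)
})
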
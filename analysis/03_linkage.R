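#!/usr/bin/env Rscript
# Read-pair linkage disequilibrium: r2 for SNV pairs co-observed on read
# pairs (<= 420 bp apart, >= 20 connecting pairs, rarefied to 20), the
# distance-decay curve stratified by mutation class, and the relationship
# between genome-wide mean r2 and nucleotide diversity across pools that
# differ in recombination block length.

suppressPackageStartupMessages(library(strainpop))

cm <- readRDS("scratch/community.rds")
ann <- cm$annotation
out <- "results/linkage"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- cm$seed
ds <- function(k) strainpop:::derive_seed(seed, 300 + k)

# decay showcase: a recombining pool (300 bp ancestral blocks) at the
# community's diversity level -- the time-series samples themselves are
# re-realized per time point and carry no block structure
pool <- simulate_strain_pool(ann, n_strains = 20, target_pi = 0.02,
                             recomb_block_len = 300, seed = ds(99))
reads <- simulate_sample_reads(pool, coverage = 60, seed = ds(98))
p <- build_pileup(reads, ann)
snvs <- call_snvs(p, ann)
pairs <- add_rarefied_r2(enumerate_linked_pairs(snvs, reads), seed = ds(1))
strainpop:::write_tsv(pairs, file.path(out, "linkage_pairs.tsv"))
curve <- linkage_decay_curve(pairs)
strainpop:::write_tsv(curve, file.path(out, "decay_curve.tsv"))
near <- mean(pairs$r2_rarefied[pairs$distance <= 100], na.rm = TRUE)
far <- mean(pairs$r2_rarefied[pairs$distance >= 300], na.rm = TRUE)
message(sprintf("%d SNV pairs; mean r2 %.3f; r2 decays %.3f (<=100 bp) -> %.3f (>=300 bp)",
                nrow(pairs), mean_genome_r2(pairs), near, far))
strata <- tapply(pairs$r2_rarefied, pairs$class_pair, mean, na.rm = TRUE)
message("mean r2 by mutation-class stratum: ",
        paste(names(strata), round(strata, 3), collapse = ", "))

# mean r2 vs diversity across pools whose diversity is recombination-driven
pis <- c(0.005, 0.01, 0.02, 0.04)
blocks <- c(2000, 800, 300, 120)
mean_r2 <- numeric(length(pis))
for (i in seq_along(pis)) {
  pool <- simulate_strain_pool(ann, 20, pis[i], blocks[i], seed = ds(10 + i))
  rd <- simulate_sample_reads(pool, coverage = 60, seed = ds(20 + i))
  pp <- build_pileup(rd, ann)
  pr <- add_rarefied_r2(enumerate_linked_pairs(call_snvs(pp, ann), rd),
                        seed = ds(30 + i))
  mean_r2[i] <- mean_genome_r2(pr)
}
ens <- data.frame(target_pi = pis, recomb_block_len = blocks,
                  mean_r2 = mean_r2)
strainpop:::write_tsv(ens, file.path(out, "mean_r2_vs_pi.tsv"))
rho <- suppressWarnings(cor(mean_r2, pis, method = "spearman"))
message(sprintf("mean r2 vs pi across pools: Spearman rho = %.2f", rho))
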
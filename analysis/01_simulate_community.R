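#!/usr/bin/env Rscript
# Simulate the study system: a streamlined ~20 kb marine archaeal-like
# reference, a two-deme (HOT vs BATS) strain community with site-exclusive
# accessory genes, and a 12-month sampled time series per site with
# temperature-responsive nonsynonymous SNVs. Everything downstream
# (02..06) re-derives population-genetic quantities from the reads alone;
# this script also writes the ground truth so the recovery can be judged.

suppressPackageStartupMessages(library(strainpop))

seed <- 20260921L
out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
ds <- function(k) strainpop:::derive_seed(seed, k)

ann <- simulate_reference(20000, 20, gc = 0.40, seed = ds(1))
write_reference_fasta(ann, file.path(out, "reference.fasta"))
write_genes_gff3(ann, file.path(out, "genes.gff3"))
message(sprintf("reference: %d bp, %d genes", ann$length, nrow(ann$genes)))

demes <- simulate_deme_pair(ann, n_strains = 30, target_fst = 0.05,
                            pi_within = 0.02, n_exclusive_a = 3,
                            n_exclusive_b = 6,
                            outlier_genes = "gene_010", outlier_fst = 0.6,
                            seed = ds(2))
message(sprintf(paste0("two demes: background truth FST %.3f; planted ",
                       "high-FST gene_010; %d HOT-only / %d BATS-only genes"),
                demes$truth$fst_genome, length(demes$truth$exclusive_a),
                length(demes$truth$exclusive_b)))

env_hot <- simulate_env_series(12, site = "HOT", seed = ds(3))
env_bats <- simulate_env_series(12, site = "BATS", seed = ds(4),
                                temp_amplitude = 1.5)
write_env_tsv(rbind(env_hot, env_bats), file.path(out, "env_series.tsv"))

# per-site time series: HOT carries 20 temperature-responsive
# nonsynonymous SNVs, BATS none
ts_hot <- simulate_time_series(demes$pool_a, env_hot, n_responsive = 20,
                               coupling = 3, coverage = 50,
                               error_rate = 0.002, seed = ds(5),
                               absent_ranges = demes$absent_ranges_a)
ts_bats <- simulate_time_series(demes$pool_b, env_bats, n_responsive = 0,
                                coupling = 0, coverage = 50,
                                error_rate = 0.002, seed = ds(6),
                                absent_ranges = demes$absent_ranges_b)

saveRDS(list(annotation = ann, demes = demes, ts_hot = ts_hot,
             ts_bats = ts_bats, env_hot = env_hot, env_bats = env_bats,
             seed = seed),
        "scratch/community.rds")   # large binary intermediate: scratch only

write_tsv <- strainpop:::write_tsv
write_tsv(data.frame(pos = demes$truth$pos,
                     freq_hot = demes$truth$freq_a,
                     freq_bats = demes$truth$freq_b),
          file.path(out, "truth_site_frequencies.tsv"))
write_tsv(demes$truth$fst_by_gene, file.path(out, "truth_gene_fst.tsv"))
write_tsv(data.frame(gene_id = c(demes$truth$exclusive_a,
                                 demes$truth$exclusive_b),
                     site = rep(c("HOT", "BATS"),
                                c(length(demes$truth$exclusive_a),
                                  length(demes$truth$exclusive_b)))),
          file.path(out, "truth_exclusive_genes.tsv"))
write_tsv(data.frame(pos = ts_hot$truth$responsive_pos,
                     sign = ts_hot$truth$responsive_sign),
          file.path(out, "truth_responsive_snvs.tsv"))
# one example SAM so the mapped-read format path is exercised end to end
# (bulky: kept under scratch/)
write_sam(ts_hot$reads[[1]], "scratch/HOT_t01.sam")
message("wrote reference and truth tables under ", out,
        "; example SAM under scratch/")
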
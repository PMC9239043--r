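#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate control: p-values are sorted ascending,
#' adj_i = min over j >= i of p_(j) * m / j capped at 1, and the original
#' order is restored. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in [0, 1] (NAs not allowed).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] with no missing values", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Default pipeline configuration
#'
#' All analysis thresholds at their standard values (the profiling defaults
#' this package documents throughout), plus the synthetic-community settings
#' used when no input files are given. Each threshold carries a provenance
#' tag ("default" / "user") in the run manifest.
#'
#' @param seed Master seed.
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    thresholds = list(
      min_read_identity = 0.94,
      min_coverage = 5, min_allele_freq = 0.05, min_allele_count = 2,
      detection_coverage = 5, detection_breadth = 0.5,
      linkage_max_dist = 420, linkage_min_pairs = 20,
      rarefaction_size = 20, rarefaction_reps = 100,
      fst_min_depth = 20, fst_sd_filter = 2,
      differential_p = 0.001, basin_gate_p = 0.01, detect_rel_cov = 0.10,
      discard_rel_cov = 3, trajectory_min_coverage = 20,
      temporal_min_points = 8, temporal_p = 0.05,
      mu = 1e-10, generation_days = 7),
    simulate = list(
      genome_length = 30000L, n_genes = 30L, gc = 0.40,
      n_strains = 20L, target_pi = 0.02, recomb_block_len = 300,
      coverage = 50, error_rate = 0.002,
      fst_between_sites = 0.2, n_exclusive_a = 3L, n_exclusive_b = 6L,
      n_timepoints = 8L, n_responsive = 10L, coupling = 3),
    inputs = NULL), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the structure of [default_config()]; missing
#'   entries fall back to defaults.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = user$seed %||% 1L)
  for (k in names(user$thresholds)) {
    cfg$thresholds[[k]] <- user$thresholds[[k]]
    attr(cfg$thresholds[[k]], "provenance") <- "user"
  }
  for (k in names(user$simulate)) cfg$simulate[[k]] <- user$simulate[[k]]
  cfg$inputs <- user$inputs
  cfg
}

#' Run the full analysis end-to-end on a synthetic two-site time series
#'
#' Simulates a reference, a two-deme community with site-exclusive genes, and
#' per-site time series reads; then profiles every sample (pileup, SNVs,
#' diversity, pN/pS), computes linkage decay, between-site FST with outliers
#' and PCoA, divergence dating, pangenome differential presence and
#' basin-specific genes, and temperature-correlated SNVs. All primary tables
#' are written as TSV plus a JSON run manifest (seeds, thresholds with
#' provenance), so identical configs reproduce byte-identical outputs.
#'
#' @param config A `pipeline_config` (see [default_config()]); alternatively
#'   a path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_full_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  th <- config$thresholds
  sm <- config$simulate
  seed <- config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ann <- simulate_reference(sm$genome_length, sm$n_genes, gc = sm$gc,
                            seed = derive_seed(seed, 1))
  write_reference_fasta(ann, file.path(out_dir, "reference.fasta"))
  write_genes_gff3(ann, file.path(out_dir, "genes.gff3"))

  demes <- simulate_deme_pair(ann, n_strains = sm$n_strains,
                              target_fst = sm$fst_between_sites,
                              pi_within = sm$target_pi,
                              n_exclusive_a = sm$n_exclusive_a,
                              n_exclusive_b = sm$n_exclusive_b,
                              seed = derive_seed(seed, 2))
  env_a <- simulate_env_series(sm$n_timepoints, site = "HOT",
                               seed = derive_seed(seed, 3))
  env_b <- simulate_env_series(sm$n_timepoints, site = "BATS",
                               seed = derive_seed(seed, 4))
  write_env_tsv(rbind(env_a, env_b), file.path(out_dir, "env_series.tsv"))

  sample_reads <- list()
  for (t in seq_len(sm$n_timepoints)) {
    sample_reads[[env_a$sample_id[t]]] <-
      simulate_sample_reads(demes$pool_a, coverage = sm$coverage,
                            error_rate = sm$error_rate,
                            seed = derive_seed(seed, 10 + t),
                            absent_ranges = demes$absent_ranges_a)
    sample_reads[[env_b$sample_id[t]]] <-
      simulate_sample_reads(demes$pool_b, coverage = sm$coverage,
                            error_rate = sm$error_rate,
                            seed = derive_seed(seed, 40 + t),
                            absent_ranges = demes$absent_ranges_b)
  }

  pileups <- lapply(sample_reads, build_pileup, annotation = ann,
                    min_read_identity = th$min_read_identity)

  # per-sample profiles
  profile_rows <- list()
  snv_tables <- list()
  for (nm in names(pileups)) {
    p <- pileups[[nm]]
    snvs <- call_snvs(p, ann, min_coverage = th$min_coverage,
                      min_allele_freq = th$min_allele_freq,
                      min_allele_count = th$min_allele_count)
    snv_tables[[nm]] <- snvs
    div <- nucleotide_diversity(p, min_coverage = th$min_coverage)
    pn <- pnps(snvs, ann, p)
    neut <- neutral_third_position_pi(p, ann,
                                      min_coverage = th$min_coverage)
    profile_rows[[nm]] <- data.frame(
      sample_id = nm, mean_coverage = p$mean_coverage, breadth = p$breadth,
      detected = population_detection(p, th$detection_coverage,
                                      th$detection_breadth),
      n_snvs = nrow(snvs), pi = div$genome_pi, pnps = pn$genome_pnps,
      pi_neutral = neut$pi_neutral, n_neutral_sites = neut$n,
      stringsAsFactors = FALSE)
  }
  profile_tab <- do.call(rbind, profile_rows)
  write_tsv(profile_tab, file.path(out_dir, "sample_profiles.tsv"))
  for (nm in names(snv_tables)) {
    write_tsv(snv_tables[[nm]],
              file.path(out_dir, sprintf("snvs_%s.tsv", nm)))
  }

  # linkage on the first sample of site A
  s1 <- env_a$sample_id[1]
  lp <- enumerate_linked_pairs(snv_tables[[s1]], sample_reads[[s1]],
                               max_dist = th$linkage_max_dist,
                               min_connecting_pairs = th$linkage_min_pairs)
  lp <- add_rarefied_r2(lp, subsample_size = th$rarefaction_size,
                        n_reps = th$rarefaction_reps,
                        seed = derive_seed(seed, 70))
  write_tsv(lp, file.path(out_dir, "linkage_pairs.tsv"))
  write_tsv(linkage_decay_curve(lp), file.path(out_dir, "linkage_decay.tsv"))

  # between-site differentiation (pooled pileup per site)
  pool_a <- pool_pileups(pileups[env_a$sample_id])
  pool_b <- pool_pileups(pileups[env_b$sample_id])
  gene_fst <- fst_by_gene(pool_a, pool_b, ann, min_depth = th$fst_min_depth,
                          sd_filter = th$fst_sd_filter)
  write_tsv(gene_fst, file.path(out_dir, "gene_fst.tsv"))
  outliers <- tryCatch(
    fst_outlier_test(setNames(gene_fst$fst, gene_fst$gene_id)),
    error = function(e) NULL)
  if (!is.null(outliers)) {
    write_tsv(outliers, file.path(out_dir, "fst_outliers.tsv"))
  }
  pw <- pairwise_mean_fst(pileups, ann, min_genome_cov = th$fst_min_depth,
                          min_depth = th$fst_min_depth,
                          sd_filter = th$fst_sd_filter)
  write_tsv(cbind(sample_id = rownames(pw$fst), as.data.frame(pw$fst)),
            file.path(out_dir, "pairwise_fst.tsv"))
  # negative mean FSTs (finite-depth estimator noise) are zero distance
  ord <- pcoa_cailliez(pmax(pw$fst, 0))
  write_tsv(cbind(sample_id = rownames(ord$coordinates),
                  as.data.frame(ord$coordinates)),
            file.path(out_dir, "pcoa_coordinates.tsv"))
  divergence <- consensus_divergence_time(pool_a, pool_b, ann, mu = th$mu,
                                          generation_days = th$generation_days)

  # pangenome flexibility from relative gene coverage
  site_labels <- ifelse(names(pileups) %in% env_a$sample_id, "HOT", "BATS")
  gcm <- gene_coverage_matrix(pileups, ann,
                              discard_threshold = th$discard_rel_cov)
  diff_tab <- differential_gene_presence(gcm, site_labels,
                                         p_threshold = th$differential_p)
  basin <- basin_specific_genes(gcm, site_labels, diff_tab,
                                basin_gate_p = th$basin_gate_p,
                                detect_threshold = th$detect_rel_cov)
  write_tsv(merge(diff_tab, basin, by = "gene_id", sort = TRUE),
            file.path(out_dir, "differential_genes.tsv"))

  # temperature-correlated SNVs at site A
  traj <- snv_frequency_matrix(pileups[env_a$sample_id], ann,
                               min_coverage = th$trajectory_min_coverage)
  corr <- covariate_correlated_snvs(traj, env_a$temperature_c,
                                    min_points = min(th$temporal_min_points,
                                                     sm$n_timepoints),
                                    p_threshold = th$temporal_p)
  write_tsv(corr, file.path(out_dir, "temperature_correlated_snvs.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("strainpop")),
    seed = seed,
    thresholds = lapply(names(th), function(k) list(
      name = k, value = th[[k]],
      provenance = attr(th[[k]], "provenance") %||% "default")),
    simulate = sm,
    samples = names(pileups),
    truth = list(fst_genome = demes$truth$fst_genome,
                 exclusive_a = demes$truth$exclusive_a,
                 exclusive_b = demes$truth$exclusive_b),
    divergence = unclass(divergence))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(annotation = ann, demes = demes, pileups = pileups,
                 profiles = profile_tab, snvs = snv_tables, linkage = lp,
                 gene_fst = gene_fst, outliers = outliers,
                 pairwise_fst = pw, pcoa = ord, divergence = divergence,
                 gene_coverage = gcm, differential = diff_tab,
                 basin_specific = basin, trajectories = traj,
                 temperature_correlated = corr))
}
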
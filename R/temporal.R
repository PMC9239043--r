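#' Allele-frequency trajectory matrix across a sample series
#'
#' SNVs are called on the pooled pileup across all samples (so the SNV set
#' and the focal allele are fixed study-wide); the focal allele is the most
#' frequent non-consensus allele in the pooled data. Per sample the focal
#' allele frequency is recorded; entries where the site's coverage is below
#' `min_coverage` are missing (NA), which is distinct from frequency 0.
#'
#' @param pileups Named list of per-sample `pileup_table`s over one reference.
#' @param annotation A `genome_annotation`.
#' @param min_coverage Per-sample coverage gate (default 20, matching the
#'   differentiation analyses' locus gate).
#' @param ... Passed to [call_snvs()] for the pooled calling thresholds.
#' @return List of class `trajectory_matrix`: `freqs` (SNVs x samples),
#'   `snvs` (pooled `snv_table`).
#' @export
snv_frequency_matrix <- function(pileups, annotation, min_coverage = 20,
                                 ...) {
  pooled <- pool_pileups(pileups)
  snvs <- call_snvs(pooled, annotation, ...)
  n_snv <- nrow(snvs)
  freqs <- matrix(NA_real_, nrow = n_snv, ncol = length(pileups),
                  dimnames = list(
                    if (n_snv) paste0(snvs$contig, ":", snvs$pos) else NULL,
                    names(pileups)))
  focal_col <- match(snvs$minor, DNA_BASES)
  for (j in seq_along(pileups)) {
    p <- pileups[[j]]
    cov <- p$coverage[snvs$pos]
    cnt <- p$counts[cbind(snvs$pos, focal_col)]
    f <- ifelse(cov >= min_coverage, cnt / cov, NA_real_)
    freqs[, j] <- f
  }
  structure(list(freqs = freqs, snvs = snvs, min_coverage = min_coverage),
            class = "trajectory_matrix")
}

#' SNVs whose frequency trajectories correlate with a covariate
#'
#' Spearman rank correlation (average ranks, t-approximation p-values) of
#' each SNV's frequency trajectory against the covariate over pairwise-
#' complete observations, Benjamini-Hochberg adjusted over tested SNVs and
#' flagged at `p_threshold`. By default only nonsynonymous SNVs are tested,
#' the class where environment-tracking frequency shifts indicate selection;
#' SNVs with fewer than `min_points` non-missing observations are untested.
#'
#' @param traj A `trajectory_matrix`.
#' @param covariate Numeric vector aligned to the samples (e.g. temperature).
#' @param min_points Minimum non-missing observations (default 8).
#' @param p_threshold Adjusted-p flag threshold (default 0.05).
#' @param classes SNV classes to test (default "nonsynonymous").
#' @return data.frame: snv_id, pos, class, n_obs, rho, p, p_adj, tested,
#'   significant.
#' @export
covariate_correlated_snvs <- function(traj, covariate, min_points = 8,
                                      p_threshold = 0.05,
                                      classes = "nonsynonymous") {
  stopifnot(length(covariate) == ncol(traj$freqs))
  snvs <- traj$snvs
  n <- nrow(snvs)
  out <- data.frame(snv_id = rownames(traj$freqs) %||% character(n),
                    pos = snvs$pos, class = snvs$class,
                    n_obs = 0L, rho = NA_real_, p = NA_real_,
                    p_adj = NA_real_, tested = FALSE, significant = FALSE,
                    stringsAsFactors = FALSE)
  candidates <- which(snvs$class %in% classes)
  for (i in candidates) {
    f <- traj$freqs[i, ]
    ok <- !is.na(f)
    out$n_obs[i] <- sum(ok)
    if (sum(ok) < min_points) next
    if (stats::var(f[ok]) == 0 || stats::var(covariate[ok]) == 0) next
    ct <- suppressWarnings(cor.test(f[ok], covariate[ok],
                                    method = "spearman", exact = FALSE))
    out$tested[i] <- TRUE
    out$rho[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out$p_adj[out$tested] <- bh_adjust(out$p[out$tested])
  out$significant <- out$tested & !is.na(out$p_adj) &
    out$p_adj < p_threshold
  out
}
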
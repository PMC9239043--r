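# Between-sample differentiation: Hudson-style FST from pooled allele
# frequencies with a finite-depth correction, aggregated per gene as a ratio
# of sums; outlier detection; PCoA embedding; consensus-SNP divergence dating.

# Candidate FST loci between two pileups: sites where the pooled (A + B)
# counts show >= 2 alleles passing the calling thresholds. Applies the depth
# gate (both samples >= min_depth) and the per-sample two-sided 2-SD depth
# filter around the mean depth over candidate loci.
fst_loci <- function(pileup_a, pileup_b, min_depth = 20, sd_filter = 2,
                     min_allele_freq = 0.05, min_allele_count = 2) {
  counts <- pileup_a$counts + pileup_b$counts
  cov <- rowSums(counts)
  freqs <- counts / pmax(cov, 1L)
  pass <- counts >= min_allele_count & freqs >= min_allele_freq
  poly <- which(rowSums(pass) >= 2L)
  if (length(poly) == 0L) {
    return(data.frame(pos = integer(), a1 = integer(), a2 = integer(),
                      p1 = numeric(), p2 = numeric(),
                      n1 = numeric(), n2 = numeric()))
  }
  # biallelic projection on pooled counts: top two alleles
  sub <- counts[poly, , drop = FALSE]
  a1 <- max.col(sub, ties.method = "first")
  sub2 <- sub
  sub2[cbind(seq_along(poly), a1)] <- -1L
  a2 <- max.col(sub2, ties.method = "first")

  ca <- pileup_a$counts[poly, , drop = FALSE]
  cb <- pileup_b$counts[poly, , drop = FALSE]
  i1 <- cbind(seq_along(poly), a1)
  i2 <- cbind(seq_along(poly), a2)
  n1 <- ca[i1] + ca[i2]
  n2 <- cb[i1] + cb[i2]
  p1 <- ifelse(n1 > 0, ca[i1] / n1, NA_real_)
  p2 <- ifelse(n2 > 0, cb[i1] / n2, NA_real_)

  keep <- n1 >= min_depth & n2 >= min_depth
  # two-sided depth filter per sample over the candidate loci
  for (n in list(n1, n2)) {
    mu <- mean(n[keep])
    s <- sd(n[keep])
    if (!is.na(s) && s > 0) {
      keep <- keep & n >= mu - sd_filter * s & n <= mu + sd_filter * s
    }
  }
  data.frame(pos = poly[keep], a1 = a1[keep], a2 = a2[keep],
             p1 = p1[keep], p2 = p2[keep], n1 = n1[keep], n2 = n2[keep])
}

# Hudson FST with finite-depth correction, ratio of sums over loci:
# num_l = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)
# den_l = p1(1-p2) + p2(1-p1)
hudson_fst_from_loci <- function(loci) {
  l <- loci[loci$n1 >= 2 & loci$n2 >= 2, , drop = FALSE]
  if (nrow(l) == 0L) return(NA_real_)
  num <- (l$p1 - l$p2)^2 -
    l$p1 * (1 - l$p1) / (l$n1 - 1) -
    l$p2 * (1 - l$p2) / (l$n2 - 1)
  den <- l$p1 * (1 - l$p2) + l$p2 * (1 - l$p1)
  if (sum(den) <= 0) return(NA_real_)
  sum(num) / sum(den)
}

#' Hudson-style FST for one gene between two pooled samples
#'
#' Loci are SNV sites (pooled across the two samples) inside the gene with
#' depth at least `min_depth` in both samples and within `sd_filter` standard
#' deviations of each sample's mean locus depth. Per locus the Hudson
#' estimator with finite-depth correction is used and the gene value is the
#' ratio of summed numerators to summed denominators, which may be slightly
#' negative at low differentiation.
#'
#' @param pileup_a,pileup_b `pileup_table`s of the two samples.
#' @param gene A single row of `annotation$genes` (or a list with start/end).
#' @param min_depth Minimum locus depth in both samples (default 20).
#' @param sd_filter Depth filter width in standard deviations (default 2).
#' @return Gene FST (NA when undefined).
#' @export
hudson_fst_gene <- function(pileup_a, pileup_b, gene, min_depth = 20,
                            sd_filter = 2) {
  loci <- fst_loci(pileup_a, pileup_b, min_depth = min_depth,
                   sd_filter = sd_filter)
  loci <- loci[loci$pos >= gene$start & loci$pos <= gene$end, , drop = FALSE]
  hudson_fst_from_loci(loci)
}

#' Per-gene FST table between two samples
#'
#' @inheritParams hudson_fst_gene
#' @param annotation A `genome_annotation`.
#' @return data.frame: gene_id, fst, n_loci, mean_depth_a, mean_depth_b.
#' @export
fst_by_gene <- function(pileup_a, pileup_b, annotation, min_depth = 20,
                        sd_filter = 2) {
  loci <- fst_loci(pileup_a, pileup_b, min_depth = min_depth,
                   sd_filter = sd_filter)
  g <- annotation$genes
  gene_map <- gene_index_map(annotation)
  loci$gene <- gene_map[loci$pos]
  res <- data.frame(gene_id = g$gene_id, fst = NA_real_, n_loci = 0L,
                    mean_depth_a = NA_real_, mean_depth_b = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    sub <- loci[!is.na(loci$gene) & loci$gene == i, , drop = FALSE]
    if (nrow(sub) == 0L) next
    res$fst[i] <- hudson_fst_from_loci(sub)
    res$n_loci[i] <- nrow(sub)
    res$mean_depth_a[i] <- mean(sub$n1)
    res$mean_depth_b[i] <- mean(sub$n2)
  }
  res
}

#' Pairwise mean-FST matrix across samples
#'
#' Only samples where the genome is covered above `min_genome_cov` enter; for
#' each retained pair the entry is the unweighted mean of defined gene FSTs
#' over genes covered above `min_genome_cov` in both samples of the pair.
#' The diagonal is 0 by construction so the matrix is a proper dissimilarity.
#'
#' @param pileups Named list of `pileup_table`s.
#' @param annotation A `genome_annotation`.
#' @param min_genome_cov Genome mean-coverage gate for samples and gene
#'   mean-depth gate for genes (default 20, strict >).
#' @param min_depth,sd_filter Locus filters (see [hudson_fst_gene()]).
#' @return List: `fst` (symmetric matrix), `samples` (retained names).
#' @export
pairwise_mean_fst <- function(pileups, annotation, min_genome_cov = 20,
                              min_depth = 20, sd_filter = 2) {
  covs <- vapply(pileups, `[[`, numeric(1), "mean_coverage")
  keep <- names(pileups)[covs > min_genome_cov]
  if (length(keep) < 2L) {
    stop("fewer than 2 samples pass the coverage gate", call. = FALSE)
  }
  pileups <- pileups[keep]
  g <- annotation$genes
  gene_cov <- vapply(pileups, function(p) {
    vapply(seq_len(nrow(g)), function(i)
      mean(p$coverage[g$start[i]:g$end[i]]), numeric(1))
  }, numeric(nrow(g)))

  n <- length(pileups)
  m <- matrix(0, n, n, dimnames = list(keep, keep))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok_genes <- gene_cov[, i] > min_genome_cov &
        gene_cov[, j] > min_genome_cov
      tab <- fst_by_gene(pileups[[i]], pileups[[j]], annotation,
                         min_depth = min_depth, sd_filter = sd_filter)
      v <- tab$fst[ok_genes]
      m[i, j] <- m[j, i] <- mean(v, na.rm = TRUE)
    }
  }
  list(fst = m, samples = keep)
}

#' Right-tailed Z test for FST outlier genes
#'
#' Standardizes gene FSTs against the genome-wide mean and SD, takes the
#' upper-tail normal p-value and adjusts with Benjamini-Hochberg; genes with
#' adjusted p below `p_threshold` are flagged as candidate targets of
#' gene-specific selection.
#'
#' @param gene_fsts Named (or plain) numeric vector of gene FST values; NAs
#'   are reported untested.
#' @param p_threshold Flagging threshold on adjusted p (default 0.05).
#' @return data.frame: gene_id, fst, z, p, p_adj, outlier.
#' @export
fst_outlier_test <- function(gene_fsts, p_threshold = 0.05) {
  ids <- names(gene_fsts) %||% as.character(seq_along(gene_fsts))
  defined <- !is.na(gene_fsts)
  if (sum(defined) < 10L) {
    stop("need at least 10 genes with defined FST", call. = FALSE)
  }
  mu <- mean(gene_fsts[defined])
  s <- sd(gene_fsts[defined])
  out <- data.frame(gene_id = ids, fst = as.numeric(gene_fsts),
                    z = NA_real_, p = NA_real_, p_adj = NA_real_,
                    outlier = FALSE, stringsAsFactors = FALSE)
  if (is.na(s) || s == 0) {
    warning("zero variance among gene FSTs; no outliers flagged")
    return(out)
  }
  out$z[defined] <- (gene_fsts[defined] - mu) / s
  out$p[defined] <- pnorm(out$z[defined], lower.tail = FALSE)
  out$p_adj[defined] <- bh_adjust(out$p[defined])
  out$outlier <- !is.na(out$p_adj) & out$p_adj < p_threshold
  out
}

# Gower double-centering of -m/2 (the Gram matrix of squared distances)
gower_center <- function(m) {
  n <- nrow(m)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% m %*% J
}

#' Principal-coordinate analysis with Cailliez correction
#'
#' Classical metric MDS of a dissimilarity matrix after adding the smallest
#' constant to all off-diagonal entries that makes the configuration
#' Euclidean (Cailliez's c1), so that all represented eigenvalues are
#' non-negative and pairwise distances between the returned coordinates
#' reproduce the corrected dissimilarities.
#'
#' @param d Symmetric, zero-diagonal, non-negative dissimilarity matrix
#'   (e.g. pairwise mean FST).
#' @return List: `coordinates` (samples x axes), `eigenvalues`,
#'   `explained` (fraction of total positive inertia), `correction` (the
#'   constant added).
#' @export
pcoa_cailliez <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("`d` must be a symmetric matrix", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("`d` must have a zero diagonal", call. = FALSE)
  if (any(d < -1e-12)) stop("`d` must be non-negative", call. = FALSE)
  if (all(d == 0)) {
    return(list(coordinates = matrix(0, n, 1,
                                     dimnames = list(rownames(d), "Axis1")),
                eigenvalues = 0, explained = 1, correction = 0))
  }

  min_eig <- function(dd) min(eigen(gower_center(dd^2), symmetric = TRUE,
                                    only.values = TRUE)$values)
  cc <- 0
  if (min_eig(d) < -1e-8 * max(d)) {
    # Cailliez constant: largest real eigenvalue of the 2n x 2n block matrix
    d1 <- gower_center(d^2)
    d2 <- gower_center(2 * d)
    big <- rbind(cbind(matrix(0, n, n), 2 * d1),
                 cbind(-diag(n), -2 * d2))
    ev <- eigen(big, only.values = TRUE)$values
    cc <- max(Re(ev[abs(Im(ev)) < 1e-8]))
    cc <- max(cc, 0)
    d <- d + cc
    diag(d) <- 0
  }
  fit <- cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE)
  eig <- fit$eig
  pos <- eig > 1e-8 * max(abs(eig))
  coords <- fit$points[, seq_len(max(1L, sum(pos))), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = eig[seq_len(ncol(coords))],
       explained = eig[seq_len(ncol(coords))] / sum(eig[eig > 0]),
       correction = cc)
}

#' Divergence time from consensus differences at third codon positions
#'
#' Counts sites among annotated third codon positions, covered at
#' `min_coverage` in both samples, where the two majority-rule consensus
#' alleles differ (consensus SNPs); the per-site divergence d3 is converted
#' to generations as T = d3 / (2 mu) (both lineages accumulate mutations)
#' and to years with a fixed generation time. A lower bound: shared
#' polymorphism and saturation both deflate d3.
#'
#' @param pileup_a,pileup_b `pileup_table`s of the two populations.
#' @param annotation A `genome_annotation`.
#' @param mu Mutation rate per bp per generation (default 1e-10).
#' @param generation_days Generation time in days (default 7).
#' @param min_coverage Minimum per-sample coverage at a site (default 5).
#' @return List of class `divergence_estimate`: n_diff, n_sites, d3,
#'   generations, years.
#' @export
consensus_divergence_time <- function(pileup_a, pileup_b, annotation,
                                      mu = 1e-10, generation_days = 7,
                                      min_coverage = 5) {
  map <- site_codon_map(annotation)
  third_pos <- map$pos[map$codon_pos == 3L]
  if (length(third_pos) == 0L) {
    stop("annotation has no coding third positions", call. = FALSE)
  }
  joint <- third_pos[pileup_a$coverage[third_pos] >= min_coverage &
                     pileup_b$coverage[third_pos] >= min_coverage]
  if (length(joint) == 0L) {
    stop("no third-codon positions jointly covered", call. = FALSE)
  }
  if (length(joint) / length(third_pos) < 0.5) {
    warning("fewer than 50% of third positions jointly covered; ",
            "divergence estimate may be unstable")
  }
  cons_a <- consensus_sequence(pileup_a, annotation)[joint]
  cons_b <- consensus_sequence(pileup_b, annotation)[joint]
  n_diff <- sum(cons_a != cons_b)
  d3 <- n_diff / length(joint)
  gens <- d3 / (2 * mu)
  structure(list(n_diff = n_diff, n_sites = length(joint), d3 = d3,
                 generations = gens,
                 years = gens * generation_days / 365.25),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf(paste0("<divergence_estimate> %d/%d third-position consensus ",
                     "differences (d3 = %.3g): %.3g generations, %.3g yr\n"),
              x$n_diff, x$n_sites, x$d3, x$generations, x$years))
  invisible(x)
}
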
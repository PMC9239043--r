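# Gene-content variation from coverage: relative gene coverage, differential
# presence between sites, basin-specific classification, and Heaps-law
# pangenome openness from presence/absence matrices.

#' Relative gene coverage for one sample
#'
#' r = (gene mean depth) / (genome mean depth), the coverage-based proxy for
#' the fraction of the population carrying the gene. Entries with r above
#' `discard_threshold` (strictly) are masked -- such genes are likely shared
#' with other populations or mis-binned -- and a masked entry is
#' distinguishable from a genuine 0 (absent gene).
#'
#' @param gene_depths Numeric vector of per-gene mean depths.
#' @param genome_depth Genome-wide mean depth (> 0).
#' @param discard_threshold Masking threshold (default 3; r = 3 is retained).
#' @return Numeric vector of r with masked entries NA and a logical
#'   `masked` attribute.
#' @export
relative_gene_coverage <- function(gene_depths, genome_depth,
                                   discard_threshold = 3) {
  if (!is.numeric(genome_depth) || genome_depth <= 0) {
    stop("`genome_depth` must be > 0 (sample excluded otherwise)",
         call. = FALSE)
  }
  r <- gene_depths / genome_depth
  masked <- r > discard_threshold
  r[masked] <- NA_real_
  attr(r, "masked") <- masked
  r
}

#' Genes x samples relative-coverage matrix from pileups
#'
#' @param pileups Named list of `pileup_table`s.
#' @param annotation A `genome_annotation`.
#' @param discard_threshold See [relative_gene_coverage()].
#' @return Matrix genes x samples (NA = masked) with attribute `masked`.
#' @export
gene_coverage_matrix <- function(pileups, annotation,
                                 discard_threshold = 3) {
  g <- annotation$genes
  cols <- lapply(pileups, function(p) {
    depths <- vapply(seq_len(nrow(g)), function(i)
      mean(p$coverage[g$start[i]:g$end[i]]), numeric(1))
    relative_gene_coverage(depths, p$mean_coverage,
                           discard_threshold = discard_threshold)
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(g$gene_id, names(pileups))
  attr(m, "masked") <- do.call(cbind, lapply(cols, attr, "masked"))
  m
}

#' Differential gene presence between two sites (one-way ANOVA + BH)
#'
#' Per gene, a one-way ANOVA of relative coverage across the two site groups
#' (masked entries excluded); p-values are Benjamini-Hochberg adjusted over
#' all tested genes and flagged at `p_threshold`. Genes with fewer than two
#' unmasked values in either group are reported untested.
#'
#' @param mat Genes x samples relative-coverage matrix (NA = masked).
#' @param site_labels Factor/character of length ncol(mat) with two levels.
#' @param p_threshold Adjusted-p flag threshold (default 0.001).
#' @return data.frame: gene_id, f_stat, p, p_adj, tested, differential.
#' @export
differential_gene_presence <- function(mat, site_labels,
                                       p_threshold = 0.001) {
  site_labels <- as.factor(site_labels)
  if (nlevels(site_labels) != 2L) {
    stop("`site_labels` must have exactly two levels", call. = FALSE)
  }
  if (length(site_labels) != ncol(mat)) {
    stop("`site_labels` length must match ncol(mat)", call. = FALSE)
  }
  n_genes <- nrow(mat)
  f_stat <- p <- rep(NA_real_, n_genes)
  tested <- rep(FALSE, n_genes)
  ga <- site_labels == levels(site_labels)[1]
  for (i in seq_len(n_genes)) {
    x <- mat[i, ga]
    y <- mat[i, !ga]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) next
    tested[i] <- TRUE
    if (stats::var(c(x, y)) == 0) {
      f_stat[i] <- 0
      p[i] <- 1
    } else if (stats::var(x) == 0 && stats::var(y) == 0) {
      # group means differ with zero residual variance
      f_stat[i] <- Inf
      p[i] <- 0
    } else {
      ft <- oneway.test(v ~ grp,
                        data = data.frame(v = c(x, y),
                                          grp = rep(c("a", "b"),
                                                    c(length(x), length(y)))),
                        var.equal = TRUE)
      f_stat[i] <- unname(ft$statistic)
      p[i] <- ft$p.value
    }
  }
  p_adj <- rep(NA_real_, n_genes)
  p_adj[tested] <- bh_adjust(p[tested])
  data.frame(gene_id = rownames(mat) %||% as.character(seq_len(n_genes)),
             f_stat = f_stat, p = p, p_adj = p_adj, tested = tested,
             differential = tested & !is.na(p_adj) & p_adj < p_threshold,
             stringsAsFactors = FALSE)
}

#' Classify differential genes as basin-specific or shared
#'
#' Within the gate set (genes with adjusted p below `basin_gate_p`), a gene is
#' specific to site A when it is detected (r strictly > `detect_threshold`)
#' in at least one A sample and below `detect_threshold` (strictly) in every
#' unmasked B sample; symmetrically for B; otherwise shared. A boundary value
#' r = `detect_threshold` counts as neither detected nor absent-qualified.
#' Masked entries never contribute.
#'
#' @param mat Genes x samples relative-coverage matrix (NA = masked).
#' @param site_labels Two-level factor/character over samples.
#' @param diff_table Output of [differential_gene_presence()].
#' @param basin_gate_p Gate on adjusted p (default 0.01).
#' @param detect_threshold Detection threshold on r (default 0.10).
#' @return data.frame: gene_id, classification (one of
#'   "<siteA>_specific", "<siteB>_specific", "shared", NA outside the gate).
#' @export
basin_specific_genes <- function(mat, site_labels, diff_table,
                                 basin_gate_p = 0.01,
                                 detect_threshold = 0.10) {
  site_labels <- as.factor(site_labels)
  lv <- levels(site_labels)
  stopifnot(length(lv) == 2L)
  gate <- diff_table$tested & !is.na(diff_table$p_adj) &
    diff_table$p_adj < basin_gate_p
  cls <- rep(NA_character_, nrow(mat))
  ga <- site_labels == lv[1]
  for (i in which(gate)) {
    a <- mat[i, ga]
    b <- mat[i, !ga]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    det_a <- any(a > detect_threshold)
    det_b <- any(b > detect_threshold)
    abs_a <- length(a) > 0L && all(a < detect_threshold)
    abs_b <- length(b) > 0L && all(b < detect_threshold)
    cls[i] <- if (det_a && abs_b) {
      paste0(lv[1], "_specific")
    } else if (det_b && abs_a) {
      paste0(lv[2], "_specific")
    } else {
      "shared"
    }
  }
  data.frame(gene_id = diff_table$gene_id, classification = cls,
             stringsAsFactors = FALSE)
}

#' Heaps-law pangenome openness from a presence/absence matrix
#'
#' For each of `n_permutations` random genome orders the gene accumulation
#' curve P(N) (cumulative distinct gene clusters) is computed; the power law
#' P(N) = kappa * N^gamma is fitted by least squares on the log-log median
#' curve. Larger gamma means a more open pangenome.
#'
#' @param pa Binary matrix, genomes x gene clusters (no empty columns).
#' @param n_permutations Number of genome-order permutations (default 100).
#' @param seed Integer seed.
#' @return List of class `openness_fit`: `gamma`, `kappa`,
#'   `n_permutations`, `curve` (data.frame N, median, q25, q75).
#' @export
pangenome_openness <- function(pa, n_permutations = 100, seed) {
  pa <- as.matrix(pa)
  if (nrow(pa) < 4L) stop("need at least 4 genomes", call. = FALSE)
  if (any(colSums(pa) == 0L)) {
    stop("presence/absence matrix has empty gene-cluster columns",
         call. = FALSE)
  }
  n <- nrow(pa)
  with_seed(seed, {
    curves <- matrix(0L, nrow = n, ncol = n_permutations)
    for (k in seq_len(n_permutations)) {
      perm <- sample.int(n)
      seen <- apply(pa[perm, , drop = FALSE] > 0L, 2L, cummax)
      curves[, k] <- as.integer(rowSums(seen))
    }
    med <- apply(curves, 1L, median)
    q25 <- apply(curves, 1L, stats::quantile, probs = 0.25)
    q75 <- apply(curves, 1L, stats::quantile, probs = 0.75)
    fit <- lm(log(med) ~ log(seq_len(n)))
    structure(list(gamma = unname(coef(fit)[2]),
                   kappa = unname(exp(coef(fit)[1])),
                   n_permutations = n_permutations,
                   curve = data.frame(N = seq_len(n), median = med,
                                      q25 = q25, q75 = q75)),
              class = "openness_fit")
  })
}

#' @export
print.openness_fit <- function(x, ...) {
  cat(sprintf(paste0("<openness_fit> gamma = %.3f, kappa = %.1f ",
                     "(%d permutations, %d genomes)\n"),
              x$gamma, x$kappa, x$n_permutations, nrow(x$curve)))
  invisible(x)
}
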
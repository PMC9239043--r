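#' Call and classify single nucleotide variants from a pileup
#'
#' A site is an SNV when its coverage reaches `min_coverage` and at least two
#' alleles each pass both the frequency and the absolute-count threshold.
#' Coding SNVs are classified by substituting each called non-consensus allele
#' into the sample's consensus codon: if any such substitution changes the
#' amino acid the SNV is nonsynonymous (the conservative tie-break for
#' multi-allelic sites), otherwise synonymous. Sites outside genes are
#' intergenic.
#'
#' @param pileup A `pileup_table`.
#' @param annotation A `genome_annotation`.
#' @param min_coverage Minimum site coverage (default 5).
#' @param min_allele_freq Minimum allele frequency (default 0.05; must be
#'   < 0.5 so two alleles can pass).
#' @param min_allele_count Minimum allele read count (default 2).
#' @return Object of class `snv_table` (a data.frame): contig, pos, ref,
#'   consensus, coverage, count_A..count_T, freq_A..freq_T, minor (most
#'   frequent called non-consensus allele), minor_freq, class, gene_id.
#' @export
call_snvs <- function(pileup, annotation, min_coverage = 5,
                      min_allele_freq = 0.05, min_allele_count = 2) {
  if (min_allele_freq >= 0.5) {
    stop("`min_allele_freq` must be < 0.5", call. = FALSE)
  }
  counts <- pileup$counts
  cov <- pileup$coverage
  L <- pileup$length
  freqs <- counts / pmax(cov, 1L)
  pass <- counts >= min_allele_count & freqs >= min_allele_freq &
    cov >= min_coverage
  n_pass <- rowSums(pass)
  snv_pos <- which(n_pass >= 2L)

  ref_chars <- str_to_chars(annotation$contig_seq)
  cons_chars <- consensus_sequence(pileup, annotation)

  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), consensus = character(),
                      coverage = integer(),
                      count_A = integer(), count_C = integer(),
                      count_G = integer(), count_T = integer(),
                      freq_A = numeric(), freq_C = numeric(),
                      freq_G = numeric(), freq_T = numeric(),
                      minor = character(), minor_freq = numeric(),
                      class = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (length(snv_pos) == 0L) {
    class(empty) <- c("snv_table", "data.frame")
    return(empty)
  }

  sc <- counts[snv_pos, , drop = FALSE]
  scov <- cov[snv_pos]
  sfreq <- sc / scov
  consensus <- cons_chars[snv_pos]

  # most frequent called non-consensus allele per site
  spass <- pass[snv_pos, , drop = FALSE]
  minor <- character(length(snv_pos))
  minor_freq <- numeric(length(snv_pos))
  cons_idx <- match(consensus, DNA_BASES)
  for (i in seq_along(snv_pos)) {
    cand <- which(spass[i, ])
    cand <- setdiff(cand, cons_idx[i])
    j <- cand[which.max(sc[i, cand])]
    minor[i] <- DNA_BASES[j]
    minor_freq[i] <- sfreq[i, j]
  }

  # coding-effect classification against the consensus codon context
  map <- site_codon_map(annotation)
  map_idx <- match(snv_pos, map$pos)
  cls <- rep("intergenic", length(snv_pos))
  gene_id <- rep(NA_character_, length(snv_pos))
  coding <- which(!is.na(map_idx))
  if (length(coding) > 0L) {
    rows <- map[map_idx[coding], ]
    gene_id[coding] <- rows$gene_id
    cons_codon <- codons_from_consensus(rows, cons_chars)
    cls[coding] <- "synonymous"
    for (k in seq_along(coding)) {
      i <- coding[k]
      called <- DNA_BASES[spass[i, ]]
      alts <- setdiff(called, consensus[i])
      alt_chars <- if (rows$strand[k] == "-") {
        complement_chars(alts)
      } else {
        alts
      }
      codon_alts <- vapply(alt_chars, function(b) {
        cd <- cons_codon[k]
        substr(cd, rows$codon_pos[k], rows$codon_pos[k]) <- b
        cd
      }, character(1))
      if (any(!is_synonymous_change(rep(cons_codon[k], length(codon_alts)),
                                    codon_alts))) {
        cls[i] <- "nonsynonymous"
      }
    }
  }

  out <- data.frame(contig = pileup$contig, pos = snv_pos,
                    ref = ref_chars[snv_pos], consensus = consensus,
                    coverage = scov,
                    count_A = sc[, "A"], count_C = sc[, "C"],
                    count_G = sc[, "G"], count_T = sc[, "T"],
                    freq_A = sfreq[, "A"], freq_C = sfreq[, "C"],
                    freq_G = sfreq[, "G"], freq_T = sfreq[, "T"],
                    minor = minor, minor_freq = minor_freq,
                    class = cls, gene_id = gene_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("snv_table", "data.frame")
  out
}

#' Nucleotide diversity from a pileup
#'
#' Per-site diversity is \eqn{\pi_s = 1 - \sum_b f_b^2} over the four bases,
#' the expected pairwise difference among pooled reads. The genome value is
#' the unweighted mean over sites with coverage at or above `min_coverage`;
#' sites below the threshold are excluded from numerator and denominator.
#' No small-sample (n/(n-1)) correction is applied, matching the pooled-read
#' definition of the statistic.
#'
#' @param pileup A `pileup_table`.
#' @param min_coverage Minimum site coverage (default 5).
#' @param annotation Optional `genome_annotation` for per-gene diversity.
#' @return List of class `diversity_profile`: `pi_site` (length-L vector, NA
#'   where ineligible), `genome_pi` (NA when no site is eligible),
#'   `n_sites`, and, with an annotation, `gene_pi` (data.frame).
#' @export
nucleotide_diversity <- function(pileup, min_coverage = 5,
                                 annotation = NULL) {
  cov <- pileup$coverage
  eligible <- cov >= min_coverage
  pi_site <- rep(NA_real_, pileup$length)
  if (any(eligible)) {
    f <- pileup$counts[eligible, , drop = FALSE] / cov[eligible]
    pi_site[eligible] <- 1 - rowSums(f^2)
  }
  genome_pi <- if (any(eligible)) mean(pi_site[eligible]) else NA_real_
  out <- list(pi_site = pi_site, genome_pi = genome_pi,
              n_sites = sum(eligible), min_coverage = min_coverage)
  if (!is.null(annotation)) {
    g <- annotation$genes
    gene_pi <- vapply(seq_len(nrow(g)), function(i) {
      idx <- g$start[i]:g$end[i]
      v <- pi_site[idx]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    out$gene_pi <- data.frame(gene_id = g$gene_id, pi = gene_pi,
                              stringsAsFactors = FALSE)
  }
  class(out) <- "diversity_profile"
  out
}

#' Per-gene and genome-wide pN/pS from called SNVs
#'
#' Synonymous and nonsynonymous mutational opportunities are counted
#' Nei-Gojobori style from the sample's consensus codons: each codon position
#' contributes a fractional synonymous weight equal to the fraction of its
#' three possible substitutions that are synonymous. Per gene,
#' pN/pS = (N_snv / N_sites) / (S_snv / S_sites); genes with no synonymous
#' SNVs have an undefined ratio and the genome-wide value is the unweighted
#' mean over genes where it is defined.
#'
#' @param snvs An `snv_table`.
#' @param annotation A `genome_annotation`.
#' @param pileup The `pileup_table` the SNVs came from (for the consensus).
#' @return List of class `pnps_profile`: `by_gene` (data.frame with gene_id,
#'   s_sites, n_sites, s_snv, n_snv, pnps) and `genome_pnps`.
#' @export
pnps <- function(snvs, annotation, pileup) {
  g <- annotation$genes
  if (any((g$end - g$start + 1L) %% 3L != 0L)) {
    stop("gene length not divisible by 3 in annotation", call. = FALSE)
  }
  cons_chars <- consensus_sequence(pileup, annotation)
  map <- site_codon_map(annotation)
  syn <- codon_syn_counts()

  # third/first/second position synonymous weights from consensus codons,
  # summed per gene over codon positions
  third <- map[map$codon_pos == 1L, , drop = FALSE]  # one row per codon
  codons <- codons_from_consensus(third, cons_chars)
  known <- codons %in% rownames(syn)
  s_by_codon <- rowSums(syn[codons[known], , drop = FALSE]) / 3
  s_sites <- tapply(s_by_codon, third$gene_id[known], sum)
  codon_count <- tapply(rep(1, sum(known)), third$gene_id[known], sum)

  by_gene <- data.frame(gene_id = g$gene_id, stringsAsFactors = FALSE)
  by_gene$s_sites <- as.numeric(s_sites[by_gene$gene_id])
  by_gene$n_sites <- 3 * as.numeric(codon_count[by_gene$gene_id]) -
    by_gene$s_sites

  coding_snvs <- snvs[!is.na(snvs$gene_id), , drop = FALSE]
  cnt <- function(cl) {
    t <- table(coding_snvs$gene_id[coding_snvs$class == cl])
    v <- as.numeric(t[by_gene$gene_id])
    ifelse(is.na(v), 0, v)
  }
  by_gene$s_snv <- cnt("synonymous")
  by_gene$n_snv <- cnt("nonsynonymous")
  by_gene$pnps <- ifelse(
    by_gene$s_snv == 0, NA_real_,
    (by_gene$n_snv / by_gene$n_sites) / (by_gene$s_snv / by_gene$s_sites))

  genome <- if (all(is.na(by_gene$pnps))) NA_real_ else
    mean(by_gene$pnps, na.rm = TRUE)
  structure(list(by_gene = by_gene, genome_pnps = genome),
            class = "pnps_profile")
}

#' Neutral diversity at third positions of 4-fold degenerate codons
#'
#' Eligible sites are third codon positions of consensus codons whose third
#' position is 4-fold degenerate (any base keeps the amino acid), the standard
#' neutrality proxy. Returns the mean per-site diversity over eligible sites
#' with coverage at or above `min_coverage` and the eligible-site count.
#'
#' @param pileup A `pileup_table`.
#' @param annotation A `genome_annotation`.
#' @param min_coverage Minimum site coverage (default 5).
#' @return List: `pi_neutral` (NA when no site qualifies), `n`.
#' @export
neutral_third_position_pi <- function(pileup, annotation, min_coverage = 5) {
  cons_chars <- consensus_sequence(pileup, annotation)
  map <- site_codon_map(annotation)
  third <- map[map$codon_pos == 3L, , drop = FALSE]
  if (nrow(third) == 0L) return(list(pi_neutral = NA_real_, n = 0L))
  codons <- codons_from_consensus(third, cons_chars)
  ff <- codons %in% fourfold_codons()
  pos <- third$pos[ff]
  pos <- pos[pileup$coverage[pos] >= min_coverage]
  if (length(pos) == 0L) return(list(pi_neutral = NA_real_, n = 0L))
  f <- pileup$counts[pos, , drop = FALSE] / pileup$coverage[pos]
  pi_site <- 1 - rowSums(f^2)
  list(pi_neutral = mean(pi_site), n = length(pos))
}

#' Lower-bound effective population size from neutral diversity
#'
#' Evaluates \eqn{N_e = 1.5 \pi_{neutral} / (\mu (3 - 4 \pi_{neutral}))},
#' the finite-sites estimator relating neutral nucleotide diversity to
#' effective population size under mutation rate \eqn{\mu} per bp per
#' generation. Because not all third positions are neutral and near-saturated
#' sites under-report diversity, the result is a lower bound.
#'
#' @param pi_neutral Neutral nucleotide diversity in [0, 0.75).
#' @param mu Mutation rate per bp per generation (default 1e-10).
#' @return Effective population size (generations^-1 scale free).
#' @export
effective_population_size <- function(pi_neutral, mu = 1e-10) {
  if (is.na(pi_neutral) || pi_neutral < 0 || pi_neutral >= 0.75) {
    stop("`pi_neutral` must be in [0, 0.75): the denominator 3 - 4*pi ",
         "vanishes at 0.75", call. = FALSE)
  }
  if (mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  1.5 * pi_neutral / (mu * (3 - 4 * pi_neutral))
}
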
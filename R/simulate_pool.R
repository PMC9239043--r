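#' Simulate a pool of strain haplotypes with controlled diversity and linkage
#'
#' Strains are mosaics of ancestral allele blocks: the genome is partitioned
#' into blocks of `recomb_block_len` bp, each strain draws an ancestor
#' independently per block, and segregating sites inherit the allele of the
#' strain's ancestor for that block. Sites are therefore linked within a block
#' and unlinked across blocks, so smaller blocks give faster linkage decay --
#' the controlled analogue of homologous recombination. The set of segregating
#' sites is calibrated so the expected nucleotide diversity
#' \eqn{\pi = \sum_s (1 - \sum_a f_a^2)/L} (allele frequencies weighted by
#' strain frequencies) matches `target_pi`.
#'
#' @param annotation A `genome_annotation` (see [simulate_reference()]).
#' @param n_strains Number of haplotypes.
#' @param target_pi Target genome-wide nucleotide diversity in [0, 0.75].
#' @param recomb_block_len Ancestral block length in bp; `Inf` for a clonal
#'   (non-recombining) pool where all sites are fully linked.
#' @param seed Integer seed.
#' @param n_ancestors Number of ancestral haplotypes per block.
#' @param freq_shape Two Beta parameters for the allele-frequency spectrum at
#'   segregating sites (default Beta(0.5, 0.5): both common and rare variants).
#' @param strain_freqs Optional simplex weights (length `n_strains`); default
#'   symmetric Dirichlet(3) draw.
#'
#' @return Object of class `strain_pool`: haplotypes (character vector),
#'   `strain_freqs`, `sites` (data.frame: pos, ref, site π), `allele_matrix`
#'   (strains x sites base characters), `expected_pi`, `recomb_block_len`.
#' @export
simulate_strain_pool <- function(annotation, n_strains, target_pi,
                                 recomb_block_len = 1000, seed,
                                 n_ancestors = 4L,
                                 freq_shape = c(0.5, 0.5),
                                 strain_freqs = NULL) {
  stopifnot(n_strains >= 1)
  if (target_pi < 0 || target_pi > 0.75) {
    stop("`target_pi` must be in [0, 0.75]: biallelic sites cap pi at 0.5 ",
         "and four balanced alleles at 0.75", call. = FALSE)
  }
  L <- annotation$length
  ref_chars <- str_to_chars(annotation$contig_seq)

  with_seed(seed, {
    if (is.null(strain_freqs)) {
      w <- stats::rgamma(n_strains, shape = 3)
      strain_freqs <- w / sum(w)
    } else {
      stopifnot(length(strain_freqs) == n_strains,
                abs(sum(strain_freqs) - 1) < 1e-9)
    }

    empty_pool <- function() {
      structure(list(annotation = annotation,
                     haplotypes = rep(annotation$contig_seq, n_strains),
                     strain_freqs = strain_freqs,
                     sites = data.frame(pos = integer(), ref = character(),
                                        pi = numeric(),
                                        stringsAsFactors = FALSE),
                     allele_matrix = matrix(character(), nrow = n_strains,
                                            ncol = 0L),
                     expected_pi = 0,
                     recomb_block_len = recomb_block_len,
                     seed = seed),
                class = "strain_pool")
    }
    if (n_strains == 1L || target_pi == 0) {
      return(empty_pool())
    }

    # block partition and per-block ancestry
    if (is.infinite(recomb_block_len)) {
      block_of <- rep(1L, L)
      n_blocks <- 1L
    } else {
      block_of <- as.integer((seq_len(L) - 1L) %/% recomb_block_len + 1L)
      n_blocks <- max(block_of)
    }
    # balanced ancestor assignment per block: every ancestor group is
    # represented (up to rounding), so any block can realize polymorphism
    ancestry <- vapply(seq_len(n_blocks), function(b)
      sample(rep_len(seq_len(n_ancestors), n_strains)),
      integer(n_strains))
    ancestry <- matrix(ancestry, nrow = n_strains, ncol = n_blocks)

    # candidate segregating sites at a density generous enough to reach the
    # target after thinning
    d0 <- min(1, max(0.02, 5 * target_pi))
    n_cand <- max(10L, round(d0 * L))
    cand_pos <- sort(sample.int(L, n_cand))

    # per candidate site: ancestor alleles Bernoulli(f), f ~ Beta(shape)
    f <- stats::rbeta(n_cand, freq_shape[1], freq_shape[2])
    anc_alt <- matrix(runif(n_ancestors * n_cand) <
                        rep(f, each = n_ancestors),
                      nrow = n_ancestors, ncol = n_cand)
    alt_base <- vapply(cand_pos, function(p)
      sample(setdiff(DNA_BASES, ref_chars[p]), 1L), character(1))

    # strain x site alt indicator via block ancestry
    site_block <- block_of[cand_pos]
    strain_alt <- matrix(FALSE, nrow = n_strains, ncol = n_cand)
    for (s in seq_len(n_strains)) {
      strain_alt[s, ] <- anc_alt[cbind(ancestry[s, site_block],
                                       seq_len(n_cand))]
    }

    site_pi <- function(alt_ind) {
      p_alt <- as.vector(strain_freqs %*% alt_ind)
      2 * p_alt * (1 - p_alt)
    }
    pi_i <- site_pi(strain_alt)
    target_total <- target_pi * L

    # boost stage: if total realizable diversity is short, rebalance random
    # sites toward 50/50 ancestor splits, then (for very high targets) convert
    # sites to four balanced alleles (per-site pi up to 0.75)
    four_allele <- rep(FALSE, n_cand)
    total <- sum(pi_i)
    if (total < target_total && n_cand > 0L) {
      ord <- sample.int(n_cand)
      half <- sample.int(n_ancestors, ceiling(n_ancestors / 2))
      for (j in ord) {
        if (total >= target_total) break
        strain_alt[, j] <- ancestry[, site_block[j]] %in% half
        pi_j <- site_pi(strain_alt[, j, drop = FALSE])
        total <- total + pi_j - pi_i[j]
        pi_i[j] <- pi_j
      }
    }
    if (total < target_total && n_cand > 0L) {
      ord <- sample.int(n_cand)
      for (j in ord) {
        if (total >= target_total) break
        four_allele[j] <- TRUE
        grp <- (ancestry[, site_block[j]] - 1L) %% 4L + 1L
        p_g <- vapply(1:4, function(g) sum(strain_freqs[grp == g]), numeric(1))
        total <- total + (1 - sum(p_g^2)) - pi_i[j]
        pi_i[j] <- 1 - sum(p_g^2)
      }
    }

    keep <- which(pi_i > 0)
    if (length(keep) == 0L) {
      stop("no realizable polymorphism: increase n_strains or n_ancestors",
           call. = FALSE)
    }

    # thinning: random order over realizable sites, keep the prefix whose
    # cumulative pi best approaches the target
    ord <- sample(keep)
    cum <- cumsum(pi_i[ord])
    k <- which.min(abs(cum - target_total))
    sel <- sort(ord[seq_len(k)])

    pos <- cand_pos[sel]
    alt_base <- alt_base[sel]
    strain_alt <- strain_alt[, sel, drop = FALSE]
    four_allele <- four_allele[sel]
    pi_i <- pi_i[sel]
    site_block_sel <- site_block[sel]

    # realize the allele matrix (base characters per strain x site)
    n_sites <- length(pos)
    allele_mat <- matrix(rep(ref_chars[pos], each = n_strains),
                         nrow = n_strains, ncol = n_sites)
    for (j in seq_len(n_sites)) {
      if (four_allele[j]) {
        grp <- (ancestry[, site_block_sel[j]] - 1L) %% 4L + 1L
        allele_mat[, j] <- DNA_BASES[grp]
      } else {
        allele_mat[strain_alt[, j], j] <- alt_base[j]
      }
    }

    # recompute per-site pi from the final allele matrix (exact truth)
    pi_final <- vapply(seq_len(n_sites), function(j) {
      fr <- vapply(DNA_BASES, function(b)
        sum(strain_freqs[allele_mat[, j] == b]), numeric(1))
      1 - sum(fr^2)
    }, numeric(1))

    expected_pi <- sum(pi_final) / L
    if (target_pi >= 0.005 &&
        abs(expected_pi - target_pi) / target_pi > 0.10) {
      stop(sprintf(paste0("could not calibrate pool diversity: realized ",
                          "expected pi %.4f vs target %.4f"),
                   expected_pi, target_pi), call. = FALSE)
    }

    haplotypes <- vapply(seq_len(n_strains), function(s) {
      h <- ref_chars
      h[pos] <- allele_mat[s, ]
      chars_to_str(h)
    }, character(1))

    structure(list(annotation = annotation,
                   haplotypes = haplotypes,
                   strain_freqs = strain_freqs,
                   sites = data.frame(pos = pos, ref = ref_chars[pos],
                                      pi = pi_final,
                                      stringsAsFactors = FALSE),
                   allele_matrix = allele_mat,
                   expected_pi = expected_pi,
                   recomb_block_len = recomb_block_len,
                   seed = seed),
              class = "strain_pool")
  })
}

#' @export
print.strain_pool <- function(x, ...) {
  cat(sprintf(paste0("<strain_pool> %d strains, %d segregating sites, ",
                     "expected pi = %.4f, block length = %s bp\n"),
              length(x$haplotypes), nrow(x$sites), x$expected_pi,
              format(x$recomb_block_len)))
  invisible(x)
}

#' Nucleotide diversity of a strain pool computed directly from haplotypes
#'
#' Independent of the site bookkeeping in the pool object: splits every
#' haplotype into characters and evaluates
#' \eqn{\sum_s (1 - \sum_a f_a^2) / L} with strain-frequency weights. Used as
#' the truth oracle in recovery tests.
#'
#' @param pool A `strain_pool`.
#' @return Genome-wide expected nucleotide diversity.
#' @export
pool_pi_from_haplotypes <- function(pool) {
  L <- pool$annotation$length
  hap_mat <- do.call(rbind, strsplit(pool$haplotypes, "", fixed = TRUE))
  w <- pool$strain_freqs
  total <- 0
  for (b in DNA_BASES) {
    fb <- as.vector(w %*% (hap_mat == b))
    total <- total + sum(fb^2)
  }
  (L - total) / L
}
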
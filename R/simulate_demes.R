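#' Simulate a two-deme community with controlled differentiation
#'
#' Builds two strain pools over a shared reference whose pooled allele
#' frequencies differ according to a Balding-Nichols model: per segregating
#' site an ancestral frequency p ~ Beta(0.5, 0.5) is drawn, and each deme's
#' frequency is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F) so that the expected
#' Hudson FST across sites equals F. The differentiation parameter is
#' calibrated iteratively so the truth FST computed from the realized strain
#' haplotype frequencies (ratio of sums over sites) matches `target_fst`
#' within 2%. Optionally, accessory genes exclusive to one deme are spiked in:
#' reads from the other deme are never drawn from those gene intervals.
#'
#' @param annotation A `genome_annotation`.
#' @param n_strains Strains per deme.
#' @param target_fst Target genome-wide Hudson FST in (0, 0.95).
#' @param pi_within Approximate within-deme diversity (controls the number of
#'   segregating sites).
#' @param n_exclusive_a,n_exclusive_b Number of genes exclusive to deme A / B.
#' @param outlier_genes Optional character vector of gene ids whose sites get
#'   `outlier_fst` instead of the genome-wide target -- planted targets of
#'   gene-specific differentiation for the FST outlier test.
#' @param outlier_fst Differentiation of the outlier genes (default 0.6).
#' @param seed Integer seed.
#'
#' @return Object of class `deme_pair`: `pool_a`, `pool_b` (strain pools),
#'   `truth` (site positions, per-deme allele frequencies, truth FST by gene
#'   and genome-wide, exclusive gene ids), `absent_ranges_a/b` (intervals the
#'   deme lacks), `target_fst`.
#' @export
simulate_deme_pair <- function(annotation, n_strains = 30L, target_fst,
                               pi_within = 0.01, n_exclusive_a = 0L,
                               n_exclusive_b = 0L, outlier_genes = NULL,
                               outlier_fst = 0.6, seed) {
  stopifnot(target_fst > 0, target_fst < 0.95, n_strains >= 2)
  L <- annotation$length
  ref_chars <- str_to_chars(annotation$contig_seq)
  gene_map <- gene_index_map(annotation)

  with_seed(seed, {
    n_sites <- max(20L, round(pi_within * L / 0.25))
    pos <- sort(sample.int(L, n_sites))
    alt_base <- vapply(pos, function(p)
      sample(setdiff(DNA_BASES, ref_chars[p]), 1L), character(1))
    p_anc <- stats::rbeta(n_sites, 0.5, 0.5)
    p_anc <- pmin(pmax(p_anc, 0.05), 0.95)

    is_outlier_site <- rep(FALSE, n_sites)
    if (!is.null(outlier_genes) && length(outlier_genes) > 0L) {
      gi <- match(outlier_genes, annotation$genes$gene_id)
      if (anyNA(gi)) stop("unknown outlier gene id", call. = FALSE)
      site_gene0 <- gene_map[pos]
      is_outlier_site <- !is.na(site_gene0) & site_gene0 %in% gi
    }

    realize <- function(F_param) {
      Fv <- ifelse(is_outlier_site, outlier_fst, F_param)
      a <- p_anc * (1 - Fv) / Fv
      b <- (1 - p_anc) * (1 - Fv) / Fv
      p_a <- stats::rbeta(n_sites, a, b)
      p_b <- stats::rbeta(n_sites, a, b)
      alt_a <- matrix(runif(n_strains * n_sites) <
                        rep(p_a, each = n_strains), n_strains, n_sites)
      alt_b <- matrix(runif(n_strains * n_sites) <
                        rep(p_b, each = n_strains), n_strains, n_sites)
      f_a <- colMeans(alt_a)
      f_b <- colMeans(alt_b)
      num <- (f_a - f_b)^2
      den <- f_a * (1 - f_b) + f_b * (1 - f_a)
      bg <- !is_outlier_site
      fst <- sum(num[bg]) / sum(den[bg])   # calibrate on the background
      list(alt_a = alt_a, alt_b = alt_b, f_a = f_a, f_b = f_b, fst = fst)
    }

    # calibrate F so realized truth FST hits the target
    F_param <- target_fst
    best <- NULL
    for (iter in 1:30) {
      r <- realize(F_param)
      if (is.null(best) || abs(r$fst - target_fst) < abs(best$fst - target_fst)) {
        best <- r
      }
      if (abs(r$fst - target_fst) / target_fst < 0.02) {
        best <- r
        break
      }
      F_param <- max(1e-4, min(0.95, F_param * target_fst / r$fst))
    }
    r <- best

    make_pool <- function(alt_mat) {
      w <- rep(1 / n_strains, n_strains)
      allele_mat <- matrix(rep(ref_chars[pos], each = n_strains),
                           n_strains, n_sites)
      for (j in seq_len(n_sites)) {
        allele_mat[alt_mat[, j], j] <- alt_base[j]
      }
      pi_site <- vapply(seq_len(n_sites), function(j) {
        fr <- vapply(DNA_BASES, function(b)
          sum(w[allele_mat[, j] == b]), numeric(1))
        1 - sum(fr^2)
      }, numeric(1))
      haplotypes <- vapply(seq_len(n_strains), function(s) {
        h <- ref_chars
        h[pos] <- allele_mat[s, ]
        chars_to_str(h)
      }, character(1))
      structure(list(annotation = annotation, haplotypes = haplotypes,
                     strain_freqs = w,
                     sites = data.frame(pos = pos, ref = ref_chars[pos],
                                        pi = pi_site,
                                        stringsAsFactors = FALSE),
                     allele_matrix = allele_mat,
                     expected_pi = sum(pi_site) / L,
                     recomb_block_len = 1,
                     seed = seed),
                class = "strain_pool")
    }
    pool_a <- make_pool(r$alt_a)
    pool_b <- make_pool(r$alt_b)

    # per-gene truth FST (ratio of sums over the gene's sites)
    site_gene <- gene_map[pos]
    gene_fst <- tapply(seq_len(n_sites), site_gene, function(idx) {
      num <- sum((r$f_a[idx] - r$f_b[idx])^2)
      den <- sum(r$f_a[idx] * (1 - r$f_b[idx]) +
                 r$f_b[idx] * (1 - r$f_a[idx]))
      if (den > 0) num / den else NA_real_
    })
    gene_fst_df <- data.frame(
      gene_id = annotation$genes$gene_id[as.integer(names(gene_fst))],
      fst_truth = as.numeric(gene_fst), stringsAsFactors = FALSE)

    # spiked site-exclusive accessory genes
    n_excl <- n_exclusive_a + n_exclusive_b
    exclusive_a <- character()
    exclusive_b <- character()
    absent_a <- data.frame(start = integer(), end = integer())
    absent_b <- data.frame(start = integer(), end = integer())
    if (n_excl > 0L) {
      eligible <- setdiff(seq_len(nrow(annotation$genes)),
                          match(outlier_genes %||% character(),
                                annotation$genes$gene_id))
      if (n_excl > length(eligible)) {
        stop("more exclusive genes requested than genes in the annotation",
             call. = FALSE)
      }
      pick <- sample(eligible, n_excl)
      a_idx <- pick[seq_len(n_exclusive_a)]
      b_idx <- setdiff(pick, a_idx)
      exclusive_a <- annotation$genes$gene_id[a_idx]
      exclusive_b <- annotation$genes$gene_id[b_idx]
      # deme B lacks A-exclusive genes and vice versa
      absent_b <- data.frame(start = annotation$genes$start[a_idx],
                             end = annotation$genes$end[a_idx])
      absent_a <- data.frame(start = annotation$genes$start[b_idx],
                             end = annotation$genes$end[b_idx])
    }

    structure(list(pool_a = pool_a, pool_b = pool_b,
                   absent_ranges_a = absent_a, absent_ranges_b = absent_b,
                   target_fst = target_fst,
                   truth = list(pos = pos, alt_base = alt_base,
                                freq_a = r$f_a, freq_b = r$f_b,
                                fst_genome = r$fst,
                                fst_by_gene = gene_fst_df,
                                exclusive_a = exclusive_a,
                                exclusive_b = exclusive_b,
                                outlier_genes = outlier_genes %||%
                                  character(),
                                seed = seed)),
              class = "deme_pair")
  })
}

#' @export
print.deme_pair <- function(x, ...) {
  cat(sprintf(paste0("<deme_pair> %d strains/deme, %d shared sites, truth ",
                     "FST = %.3f (target %.3f), %d + %d exclusive genes\n"),
              length(x$pool_a$haplotypes), length(x$truth$pos),
              x$truth$fst_genome, x$target_fst,
              length(x$truth$exclusive_a), length(x$truth$exclusive_b)))
  invisible(x)
}

#' Simulate an environmental time series (dates, temperature) for one site
#'
#' Monthly samples with a seasonal temperature cycle plus noise; the covariate
#' downstream allele-frequency trajectories can be coupled to.
#'
#' @param n_samples Number of time points (>= 4).
#' @param site Site label.
#' @param seed Integer seed.
#' @param start_date First sampling date.
#' @param temp_mean,temp_amplitude,temp_noise_sd Temperature model (deg C).
#' @return data.frame: sample_id, date, site, temperature_c (class
#'   `env_series`).
#' @export
simulate_env_series <- function(n_samples, site = "HOT", seed,
                                start_date = as.Date("2003-01-15"),
                                temp_mean = 12, temp_amplitude = 3,
                                temp_noise_sd = 0.8) {
  if (n_samples < 4) {
    stop("need at least 4 samples for downstream correlation", call. = FALSE)
  }
  with_seed(seed, {
    t <- seq_len(n_samples)
    dates <- seq(start_date, by = "month", length.out = n_samples)
    temp <- temp_mean + temp_amplitude * sin(2 * pi * t / 12) +
      rnorm(n_samples, 0, temp_noise_sd)
    out <- data.frame(sample_id = sprintf("%s_t%02d", site, t),
                      date = dates, site = site,
                      temperature_c = round(temp, 2),
                      stringsAsFactors = FALSE)
    class(out) <- c("env_series", "data.frame")
    out
  })
}

#' Simulate a sampled time series with temperature-responsive SNVs
#'
#' A subset of the pool's nonsynonymous segregating sites is made responsive:
#' their population allele frequency at time t follows
#' logistic(a + b * T(t)) plus Gaussian jitter (sd 0.02), giving a monotone
#' association with temperature that a rank correlation can detect. Neutral
#' sites receive exchangeable jitter around their base frequency. Haplotypes
#' are re-realized per time point from the per-site frequencies (equal strain
#' weights) and reads are drawn from them.
#'
#' @param pool A `strain_pool` whose sites supply the SNVs.
#' @param env An `env_series` (>= 4 samples).
#' @param n_responsive Number of responsive nonsynonymous sites.
#' @param coupling Logistic slope per standardized degree; 0 disables
#'   responsiveness entirely. Sign per site is randomized.
#' @param coverage,error_rate,seed Read-simulation settings.
#' @param absent_ranges Intervals absent from this community (accessory
#'   genes of the other deme); passed to [simulate_sample_reads()].
#' @return List with `reads` (list of `read_pair_set`, one per time point),
#'   `truth` (responsive site positions and coupling signs, the full
#'   frequency matrix, seed), and `env`.
#' @export
simulate_time_series <- function(pool, env, n_responsive, coupling,
                                 coverage = 50, error_rate = 0, seed,
                                 absent_ranges = NULL) {
  if (nrow(env) < 4) {
    stop("`env` must have at least 4 samples", call. = FALSE)
  }
  annotation <- pool$annotation
  L <- annotation$length
  ref_chars <- str_to_chars(annotation$contig_seq)
  n_strains <- length(pool$haplotypes)

  with_seed(seed, {
    sites <- pool$sites
    n_sites <- nrow(sites)
    if (n_sites == 0L) stop("pool has no segregating sites", call. = FALSE)

    # nonsynonymous candidates: site in a gene and its major alternative
    # allele changes the amino acid relative to the reference codon
    cls <- classify_pool_sites(pool)
    ns_idx <- which(cls == "nonsynonymous")
    if (!is.null(absent_ranges) && nrow(absent_ranges) > 0L) {
      # sites this community never emits reads from cannot be responsive
      observable <- !vapply(sites$pos, function(p)
        any(p >= absent_ranges$start & p <= absent_ranges$end), logical(1))
      ns_idx <- ns_idx[observable[ns_idx]]
    }
    if (coupling == 0) n_responsive <- 0L
    if (n_responsive > length(ns_idx)) {
      stop(sprintf("requested %d responsive SNVs but only %d nonsynonymous %s",
                   n_responsive, length(ns_idx), "sites are available"),
           call. = FALSE)
    }
    resp_idx <- if (n_responsive > 0L) {
      sort(sample(ns_idx, n_responsive))
    } else {
      integer()
    }
    sign_b <- sample(c(-1, 1), n_responsive, replace = TRUE)

    # base alt frequency per site from the pool's allele matrix
    alt_allele <- vapply(seq_len(n_sites), function(j) {
      ab <- pool$allele_matrix[, j]
      tab <- table(ab[ab != sites$ref[j]])
      if (length(tab) == 0L) sites$ref[j] else names(which.max(tab))
    }, character(1))
    base_freq <- vapply(seq_len(n_sites), function(j)
      sum(pool$strain_freqs[pool$allele_matrix[, j] == alt_allele[j]]),
      numeric(1))
    base_freq <- pmin(pmax(base_freq, 0.05), 0.95)

    temp_z <- as.numeric(scale(env$temperature_c))
    n_t <- nrow(env)
    freq_mat <- matrix(NA_real_, n_sites, n_t)
    logit <- function(p) log(p / (1 - p))
    inv_logit <- function(x) 1 / (1 + exp(-x))
    for (j in seq_len(n_sites)) {
      k <- match(j, resp_idx)
      if (!is.na(k)) {
        f <- inv_logit(logit(base_freq[j]) + coupling * sign_b[k] * temp_z)
      } else {
        f <- rep(base_freq[j], n_t)
      }
      f <- f + rnorm(n_t, 0, 0.02)
      freq_mat[j, ] <- pmin(pmax(f, 0.02), 0.98)
    }

    reads <- vector("list", n_t)
    for (t in seq_len(n_t)) {
      # realize exactly round(f * n) alt-carrying strains per site so the
      # realized frequency tracks the model trajectory (no binomial noise on
      # top of the modelled jitter)
      alt_ind <- matrix(FALSE, n_strains, n_sites)
      k_alt <- pmin(pmax(as.integer(round(freq_mat[, t] * n_strains)), 0L),
                    n_strains)
      for (j in seq_len(n_sites)) {
        if (k_alt[j] > 0L) {
          alt_ind[sample.int(n_strains, k_alt[j]), j] <- TRUE
        }
      }
      haps <- vapply(seq_len(n_strains), function(s) {
        h <- ref_chars
        h[sites$pos] <- ifelse(alt_ind[s, ], alt_allele, sites$ref)
        chars_to_str(h)
      }, character(1))
      pool_t <- structure(list(annotation = annotation, haplotypes = haps,
                               strain_freqs = rep(1 / n_strains, n_strains),
                               sites = sites,
                               recomb_block_len = pool$recomb_block_len),
                          class = "strain_pool")
      reads[[t]] <- simulate_sample_reads(pool_t, coverage = coverage,
                                          error_rate = error_rate,
                                          seed = derive_seed(seed, t),
                                          absent_ranges = absent_ranges)
    }
    names(reads) <- env$sample_id

    list(reads = reads,
         truth = list(responsive_pos = sites$pos[resp_idx],
                      responsive_sign = sign_b,
                      alt_allele = alt_allele,
                      pos = sites$pos,
                      freq_matrix = freq_mat,
                      seed = seed),
         env = env)
  })
}

# Classify each pool segregating site by the coding effect of its major
# alternative allele against the reference codon (truth-side classification,
# used to pick responsive nonsynonymous sites).
classify_pool_sites <- function(pool) {
  annotation <- pool$annotation
  sites <- pool$sites
  if (nrow(sites) == 0L) return(character())
  ref_chars <- str_to_chars(annotation$contig_seq)
  map <- site_codon_map(annotation)
  map_idx <- match(sites$pos, map$pos)
  cls <- rep("intergenic", nrow(sites))
  coding <- !is.na(map_idx)
  if (!any(coding)) return(cls)
  rows <- map[map_idx[coding], ]
  ref_codon <- codons_from_consensus(rows, ref_chars)
  alt_allele <- vapply(which(coding), function(j) {
    ab <- pool$allele_matrix[, j]
    tab <- table(ab[ab != sites$ref[j]])
    if (length(tab) == 0L) NA_character_ else names(which.max(tab))
  }, character(1))
  alt_chars <- alt_allele
  neg <- rows$strand == "-"
  alt_chars[neg] <- complement_chars(alt_chars[neg])
  alt_codon <- ref_codon
  substr(alt_codon, rows$codon_pos, rows$codon_pos) <- alt_chars
  syn <- is_synonymous_change(ref_codon, alt_codon)
  cls[coding] <- ifelse(is.na(alt_allele), "intergenic",
                        ifelse(syn, "synonymous", "nonsynonymous"))
  cls
}

#' Simulate a genome presence/absence matrix with power-law gene pool
#'
#' Generates a binary genomes x gene-clusters matrix whose gene accumulation
#' curve follows Heaps' law with exponent `gamma`: cluster occurrence
#' probabilities are drawn from a density proportional to theta^(-1-alpha) on
#' [theta_min, 1] and presence is Bernoulli per genome. Because truncation
#' and finite genome counts curve the expected accumulation away from a pure
#' power law, the latent exponent alpha is calibrated (numerically, from the
#' closed-form expected curve) so that the log-log least-squares slope of the
#' expected accumulation over N = 1..n_genomes equals the requested `gamma`
#' -- i.e. the generator targets the same Heaps fit the analysis performs.
#' Used for recovery tests of the pangenome openness fit.
#'
#' @param n_genomes Number of genomes (rows).
#' @param gamma Target Heaps exponent in (0, 1).
#' @param n_clusters Size of the latent gene-cluster pool.
#' @param theta_min Lower truncation of occurrence probabilities.
#' @param seed Integer seed.
#' @return Binary matrix (genomes x clusters, empty clusters dropped).
#' @export
simulate_presence_absence <- function(n_genomes, gamma, n_clusters = 3000L,
                                      theta_min = 0.01, seed) {
  stopifnot(gamma > 0, gamma < 1, n_genomes >= 2)

  # expected log-log Heaps slope of the accumulation curve for latent
  # exponent `alpha` (expectation over the theta distribution, M -> infinity)
  expected_slope <- function(alpha, tmin) {
    th <- seq(tmin, 1, length.out = 4000L)
    w <- th^(-1 - alpha)
    w <- w / sum(w)
    N <- seq_len(n_genomes)
    ep <- vapply(N, function(n) sum(w * (1 - (1 - th)^n)), numeric(1))
    unname(coef(lm(log(ep) ~ log(N)))[2])
  }
  # openness is controlled mainly by how rare the rarest clusters are:
  # calibrate the truncation (fixed latent exponent 0.5) so the expected
  # accumulation slope equals gamma; slope is monotone decreasing in the
  # truncation
  alpha <- 0.5
  t_lo <- 1e-4
  t_hi <- 0.9
  if (expected_slope(alpha, t_lo) < gamma) {
    # very open pangenome: additionally steepen the latent exponent
    theta_min <- t_lo
    if (expected_slope(0.98, t_lo) < gamma) {
      stop("`gamma` outside the calibratable range", call. = FALSE)
    }
    alpha <- stats::uniroot(function(a) expected_slope(a, t_lo) - gamma,
                            c(alpha, 0.98), tol = 1e-4)$root
  } else if (expected_slope(alpha, t_hi) > gamma) {
    stop("`gamma` outside the calibratable range", call. = FALSE)
  } else {
    theta_min <- stats::uniroot(
      function(t) expected_slope(alpha, t) - gamma,
      c(t_lo, t_hi), tol = 1e-5)$root
  }

  with_seed(seed, {
    u <- runif(n_clusters)
    # inverse CDF of density ~ theta^(-1-alpha) on [theta_min, 1]
    theta <- (theta_min^(-alpha) - u * (theta_min^(-alpha) - 1))^(-1 / alpha)
    m <- matrix(runif(n_genomes * n_clusters) <
                  rep(theta, each = n_genomes),
                nrow = n_genomes, ncol = n_clusters) + 0L
    keep <- colSums(m) > 0L
    m <- m[, keep, drop = FALSE]
    rownames(m) <- sprintf("genome_%02d", seq_len(n_genomes))
    colnames(m) <- sprintf("cluster_%05d", seq_len(ncol(m)))
    m
  })
}
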
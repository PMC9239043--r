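#' Enumerate SNV pairs co-observed on read pairs
#'
#' Links SNVs through the read pairs that physically connect them: an allele
#' observed on either mate counts, a pair whose two mates disagree at a site
#' is discarded for that site, and each SNV is projected to its two top
#' alleles (consensus vs most frequent called non-consensus). SNV pairs
#' farther apart than `max_dist` or connected by fewer than
#' `min_connecting_pairs` read pairs are dropped. By default only coding SNVs
#' enter, stratified as N-N, N-S or S-S by their coding effects.
#'
#' @param snvs An `snv_table`.
#' @param reads A `read_pair_set`.
#' @param max_dist Maximum pair distance in bp (default 420, about the span a
#'   2 x 150 bp pair with a ~250 bp insert can bridge).
#' @param min_connecting_pairs Minimum connecting read pairs (default 20).
#' @param include_intergenic Include intergenic SNVs (default FALSE).
#' @return data.frame of class `linkage_pairs`: pos1, pos2, distance,
#'   class_pair, n_AB, n_Ab, n_aB, n_ab, n_total, r2_raw. Allele "A"/"B" is
#'   the consensus allele at each site.
#' @export
enumerate_linked_pairs <- function(snvs, reads, max_dist = 420,
                                   min_connecting_pairs = 20,
                                   include_intergenic = FALSE) {
  empty <- data.frame(pos1 = integer(), pos2 = integer(),
                      distance = integer(), class_pair = character(),
                      n_AB = integer(), n_Ab = integer(), n_aB = integer(),
                      n_ab = integer(), n_total = integer(),
                      r2_raw = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("linkage_pairs", "data.frame")
  if (!include_intergenic) {
    snvs <- snvs[snvs$class != "intergenic", , drop = FALSE]
  }
  if (nrow(snvs) < 2L || nrow(reads) == 0L) return(empty)

  obs <- observe_alleles(snvs, reads)
  if (nrow(obs) == 0L) return(empty)

  dt <- data.table::as.data.table(obs)
  pairs <- dt[dt, on = "pair_id", allow.cartesian = TRUE]
  pairs <- pairs[pairs$snv < pairs$i.snv]
  if (nrow(pairs) == 0L) return(empty)
  pos <- snvs$pos
  pairs[, `:=`(pos1 = pos[pairs$snv], pos2 = pos[pairs$i.snv])]
  pairs <- pairs[(pairs$pos2 - pairs$pos1) <= max_dist]
  if (nrow(pairs) == 0L) return(empty)

  # joint haplotype counts: allele 0 = consensus ("A"/"B"), 1 = minor
  pairs[, cell := 2L * allele + i.allele]
  tab <- pairs[, .(n_AB = sum(cell == 0L), n_Ab = sum(cell == 1L),
                   n_aB = sum(cell == 2L), n_ab = sum(cell == 3L)),
               by = .(snv, i.snv, pos1, pos2)]
  tab[, n_total := n_AB + n_Ab + n_aB + n_ab]
  tab <- tab[n_total >= min_connecting_pairs]
  if (nrow(tab) == 0L) return(empty)

  out <- as.data.frame(tab)
  cls <- snvs$class
  c1 <- substr(cls[out$snv], 1, 1)
  c2 <- substr(cls[out$i.snv], 1, 1)
  # order letters so strata are N-N, N-S, S-S
  class_pair <- ifelse(c1 == "i" | c2 == "i", "other",
                       paste(pmin(toupper(c1), toupper(c2)),
                             pmax(toupper(c1), toupper(c2)), sep = "-"))
  res <- data.frame(pos1 = out$pos1, pos2 = out$pos2,
                    distance = out$pos2 - out$pos1,
                    class_pair = class_pair,
                    n_AB = out$n_AB, n_Ab = out$n_Ab,
                    n_aB = out$n_aB, n_ab = out$n_ab,
                    n_total = out$n_total, stringsAsFactors = FALSE)
  res$r2_raw <- apply(res[, c("n_AB", "n_Ab", "n_aB", "n_ab")], 1L,
                      r_squared)
  class(res) <- c("linkage_pairs", "data.frame")
  res
}

# Per (read pair, SNV) allele observations after biallelic projection.
# Returns data.frame(pair_id, snv [row index into snvs], allele [0/1]).
observe_alleles <- function(snvs, reads) {
  read_len <- attr(reads, "read_len")
  snv_ir <- IRanges::IRanges(start = snvs$pos, width = 1L)
  res <- list()
  for (m in 1:2) {
    starts <- reads[[paste0("start", m)]]
    seqs <- reads[[paste0("seq", m)]]
    mate_ir <- IRanges::IRanges(start = starts, width = read_len)
    hits <- IRanges::findOverlaps(mate_ir, snv_ir)
    ri <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(ri) == 0L) next
    off <- snvs$pos[si] - starts[ri] + 1L
    base <- substring(seqs[ri], off, off)
    res[[m]] <- data.frame(pair_id = reads$pair_id[ri], snv = si,
                           base = base, stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, res)
  if (is.null(obs) || nrow(obs) == 0L) {
    return(data.frame(pair_id = integer(), snv = integer(),
                      allele = integer()))
  }
  dt <- data.table::as.data.table(obs)
  # union of mates; a within-pair discordance discards the pair at that site
  dt <- dt[, .(base = if (data.table::uniqueN(base) == 1L) base[1L]
               else NA_character_),
           by = .(pair_id, snv)]
  dt <- dt[!is.na(base)]
  allele <- ifelse(dt$base == snvs$consensus[dt$snv], 0L,
                   ifelse(dt$base == snvs$minor[dt$snv], 1L, NA_integer_))
  keep <- !is.na(allele)
  data.frame(pair_id = dt$pair_id[keep], snv = dt$snv[keep],
             allele = allele[keep])
}

#' Squared allele-correlation (r^2) from joint haplotype counts
#'
#' \eqn{r^2 = (f_{AB} - f_A f_B)^2 / (f_A(1-f_A) f_B(1-f_B))}; undefined (NA)
#' when either site is monomorphic in the counts.
#'
#' @param counts Numeric vector (n_AB, n_Ab, n_aB, n_ab).
#' @return r^2 in [0, 1], or NA.
#' @export
r_squared <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  f_ab <- counts[1] / n
  f_a <- (counts[1] + counts[2]) / n
  f_b <- (counts[1] + counts[3]) / n
  den <- f_a * (1 - f_a) * f_b * (1 - f_b)
  if (den <= 0) return(NA_real_)
  unname((f_ab - f_a * f_b)^2 / den)
}

#' Rarefied (coverage-normalized) r^2 for one SNV pair
#'
#' Subsamples exactly `subsample_size` connecting read pairs without
#' replacement, computes raw r^2 on the subsample, and averages over
#' `n_reps` replicates so linkage is comparable across coverage levels.
#' Replicates where a margin comes out monomorphic are skipped and redrawn,
#' up to `10 * n_reps` attempts; with no usable replicate the value is
#' undefined (NA). When the pair has exactly `subsample_size` connecting
#' pairs the rarefied value equals the raw value.
#'
#' @param counts Numeric vector (n_AB, n_Ab, n_aB, n_ab), sum >= subsample
#'   size.
#' @param subsample_size Connecting pairs per replicate (default 20).
#' @param n_reps Replicates (default 100).
#' @param seed Integer seed.
#' @return Mean r^2 over successful replicates, or NA.
#' @export
r_squared_rarefied <- function(counts, subsample_size = 20, n_reps = 100,
                               seed) {
  n <- sum(counts)
  if (n < subsample_size) {
    stop("fewer connecting pairs than `subsample_size`", call. = FALSE)
  }
  if (n == subsample_size) {
    # every subsample is the full set
    return(r_squared(counts))
  }
  with_seed(seed, {
    pool <- rep.int(1:4, counts)
    vals <- numeric(0)
    attempts <- 0L
    while (length(vals) < n_reps && attempts < 10L * n_reps) {
      attempts <- attempts + 1L
      s <- sample(pool, subsample_size)
      r2 <- r_squared(tabulate(s, nbins = 4L))
      if (!is.na(r2)) vals <- c(vals, r2)
    }
    if (length(vals) == 0L) NA_real_ else mean(vals)
  })
}

#' Attach rarefied r^2 values to a linkage-pair table
#'
#' @param pairs A `linkage_pairs` data.frame.
#' @param subsample_size,n_reps See [r_squared_rarefied()].
#' @param seed Integer seed; per-pair seeds are derived deterministically.
#' @return `pairs` with an `r2_rarefied` column.
#' @export
add_rarefied_r2 <- function(pairs, subsample_size = 20, n_reps = 100, seed) {
  if (nrow(pairs) == 0L) {
    pairs$r2_rarefied <- numeric(0)
    return(pairs)
  }
  pairs$r2_rarefied <- vapply(seq_len(nrow(pairs)), function(i) {
    r_squared_rarefied(as.numeric(pairs[i, c("n_AB", "n_Ab", "n_aB",
                                             "n_ab")]),
                       subsample_size = subsample_size, n_reps = n_reps,
                       seed = derive_seed(seed, i))
  }, numeric(1))
  pairs
}

#' Linkage decay curve over distance bins, per mutation-class stratum
#'
#' @param pairs A `linkage_pairs` table with `r2_rarefied`.
#' @param bin_width Bin width in bp (default 30).
#' @param max_dist Upper distance bound (default 420).
#' @return data.frame: stratum, bin_start, bin_end, mean_r2 (NA for empty
#'   bins), n_pairs.
#' @export
linkage_decay_curve <- function(pairs, bin_width = 30, max_dist = 420) {
  strata <- sort(unique(pairs$class_pair))
  if (length(strata) == 0L) strata <- character()
  breaks <- seq(0, max_dist, by = bin_width)
  if (max(breaks) < max_dist) breaks <- c(breaks, max_dist)
  out <- list()
  for (st in c(strata, "all")) {
    sub <- if (st == "all") pairs else pairs[pairs$class_pair == st, ,
                                             drop = FALSE]
    bin <- cut(sub$distance, breaks = breaks, include.lowest = TRUE,
               right = TRUE)
    mean_r2 <- tapply(sub$r2_rarefied, bin, mean, na.rm = TRUE)
    n <- tapply(rep(1L, nrow(sub)), bin, sum)
    out[[st]] <- data.frame(
      stratum = st,
      bin_start = breaks[-length(breaks)],
      bin_end = breaks[-1],
      mean_r2 = as.numeric(mean_r2),
      n_pairs = ifelse(is.na(as.integer(n)), 0L, as.integer(n)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-wide mean rarefied r^2
#'
#' Unweighted mean over all retained SNV pairs (all strata); the per-sample
#' summary whose variation across populations tracks nucleotide diversity
#' negatively.
#'
#' @param pairs A `linkage_pairs` table with `r2_rarefied`.
#' @return Mean rarefied r^2, or NA when no pair is retained.
#' @export
mean_genome_r2 <- function(pairs) {
  if (nrow(pairs) == 0L) return(NA_real_)
  mean(pairs$r2_rarefied, na.rm = TRUE)
}
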
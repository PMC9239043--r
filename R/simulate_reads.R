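#' Simulate paired-end reads from a strain pool
#'
#' Emits 2 x 150 bp read pairs with a ~250 bp median insert (inner mate
#' distance, so the fragment spans about 550 bp and a pair can physically
#' connect variant sites up to the linkage analysis' 420 bp horizon).
#' Fragment starts are sampled uniformly (Poisson-like per-site depth), the
#' source haplotype of each fragment is drawn from the pool's strain
#' frequencies, and sequencing errors are i.i.d. substitutions uniform over
#' the three alternative bases. No indels are simulated.
#'
#' @param pool A `strain_pool`.
#' @param coverage Target mean coverage (total emitted bases / genome length).
#' @param error_rate Per-base substitution error rate in [0, 0.1).
#' @param seed Integer seed.
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd Inner mate-distance distribution (bp);
#'   negative gaps (overlapping mates) are allowed down to 10 bp short of a
#'   full overlap.
#' @param absent_ranges Optional data.frame (start, end) of intervals absent
#'   from the sampled community (e.g. accessory genes the other deme carries);
#'   fragments overlapping them are rejected and redrawn.
#'
#' @return Object of class `read_pair_set`: data.frame with pair_id, strain,
#'   contig, start1/end1/seq1, start2/end2/seq2 plus attributes `read_len`,
#'   `contig_id`, `contig_length`.
#' @export
simulate_sample_reads <- function(pool, coverage, error_rate = 0, seed,
                                  read_len = 150L, insert_mean = 250,
                                  insert_sd = 60, absent_ranges = NULL) {
  if (coverage <= 0) stop("`coverage` must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.1) {
    stop("`error_rate` must be in [0, 0.1)", call. = FALSE)
  }
  if (length(pool$haplotypes) == 0L) {
    stop("empty strain pool: no haplotypes to sequence", call. = FALSE)
  }
  L <- pool$annotation$length
  read_len <- as.integer(read_len)
  span_max <- 2L * read_len + round(insert_mean + 6 * insert_sd)
  if (L < span_max) {
    stop("contig shorter than the fragment-length distribution", call. = FALSE)
  }

  with_seed(seed, {
    n_pairs <- max(1L, round(coverage * L / (2 * read_len)))
    strain <- sample.int(length(pool$haplotypes), n_pairs, replace = TRUE,
                         prob = pool$strain_freqs)
    draw_frag <- function(n) {
      gap <- round(rnorm(n, insert_mean, insert_sd))
      gap <- pmin(pmax(gap, -(read_len - 10L)),
                  round(insert_mean + 6 * insert_sd))
      span <- 2L * read_len + gap            # outer fragment length
      start <- floor(runif(n, min = 1, max = L - span + 1 + 1))
      list(start = as.integer(start), insert = as.integer(span))
    }
    fr <- draw_frag(n_pairs)

    if (!is.null(absent_ranges) && nrow(absent_ranges) > 0L) {
      overlaps_absent <- function(start, insert) {
        end <- start + insert - 1L
        hit <- rep(FALSE, length(start))
        for (k in seq_len(nrow(absent_ranges))) {
          hit <- hit | (start <= absent_ranges$end[k] &
                        end >= absent_ranges$start[k])
        }
        hit
      }
      for (attempt in 1:50) {
        bad <- overlaps_absent(fr$start, fr$insert)
        if (!any(bad)) break
        redraw <- draw_frag(sum(bad))
        fr$start[bad] <- redraw$start
        fr$insert[bad] <- redraw$insert
      }
      bad <- overlaps_absent(fr$start, fr$insert)
      if (any(bad)) {
        keep <- !bad
        fr$start <- fr$start[keep]
        fr$insert <- fr$insert[keep]
        strain <- strain[keep]
        n_pairs <- sum(keep)
      }
    }

    start1 <- fr$start
    end1 <- start1 + read_len - 1L
    start2 <- fr$start + fr$insert - read_len
    end2 <- start2 + read_len - 1L

    seq1 <- substring(pool$haplotypes[strain], start1, end1)
    seq2 <- substring(pool$haplotypes[strain], start2, end2)

    if (error_rate > 0) {
      inject <- function(seqs) {
        total <- length(seqs) * read_len
        n_err <- rbinom(1L, total, error_rate)
        if (n_err == 0L) return(seqs)
        at <- sample.int(total, n_err)
        read_i <- (at - 1L) %/% read_len + 1L
        pos_i <- (at - 1L) %% read_len + 1L
        for (k in seq_len(n_err)) {
          old <- substr(seqs[read_i[k]], pos_i[k], pos_i[k])
          new <- sample(setdiff(DNA_BASES, old), 1L)
          substr(seqs[read_i[k]], pos_i[k], pos_i[k]) <- new
        }
        seqs
      }
      seq1 <- inject(seq1)
      seq2 <- inject(seq2)
    }

    out <- data.frame(pair_id = seq_len(n_pairs),
                      strain = strain,
                      contig = pool$annotation$contig_id,
                      start1 = start1, end1 = end1, seq1 = seq1,
                      start2 = start2, end2 = end2, seq2 = seq2,
                      stringsAsFactors = FALSE)
    attr(out, "read_len") <- read_len
    attr(out, "contig_id") <- pool$annotation$contig_id
    attr(out, "contig_length") <- L
    class(out) <- c("read_pair_set", "data.frame")
    out
  })
}

#' Insert sizes (inner mate distances) of a read-pair set
#'
#' The distance between the inner ends of the two mates; negative when mates
#' overlap. The fragment's outer span is the insert plus twice the read
#' length.
#'
#' @param reads A `read_pair_set`.
#' @return Integer vector of inner mate distances.
#' @export
insert_sizes <- function(reads) {
  reads$start2 - reads$end1 - 1L
}
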
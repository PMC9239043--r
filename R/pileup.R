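#' Build a per-site pileup from mapped read pairs
#'
#' Tabulates A/C/G/T counts at every reference position from ungapped read
#' pairs. Mates are filtered individually at a minimum percent identity to the
#' reference (default 94%, the mapping-identity gate used for profiling
#' metagenome populations); at positions covered by both mates of a pair the
#' template molecule is counted once, with the first (leftmost) mate winning.
#'
#' @param reads A `read_pair_set` (or a SAM path, imported via [read_sam()]).
#' @param annotation A `genome_annotation` naming the reference contig.
#' @param min_read_identity Minimum fraction of bases matching the reference
#'   for a mate to contribute (default 0.94).
#' @return Object of class `pileup_table`: `counts` (L x 4 matrix, columns
#'   A,C,G,T), `coverage`, `mean_coverage`, `breadth`, `contig`, `length`.
#' @export
build_pileup <- function(reads, annotation, min_read_identity = 0.94) {
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_sam(reads)
  }
  stopifnot(inherits(reads, "read_pair_set"))
  stopifnot_scalar_fraction(min_read_identity, "min_read_identity")
  L <- annotation$length
  contigs <- unique(reads$contig)
  unknown <- setdiff(contigs, annotation$contig_id)
  if (length(unknown) > 0L) {
    stop(sprintf("alignments reference unknown contigs: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  empty <- function() {
    counts <- matrix(0L, nrow = L, ncol = 4L,
                     dimnames = list(NULL, DNA_BASES))
    structure(list(counts = counts, coverage = integer(L),
                   mean_coverage = 0, breadth = 0,
                   contig = annotation$contig_id, length = L,
                   n_mates_used = 0L),
              class = "pileup_table")
  }
  if (nrow(reads) == 0L) return(empty())

  read_len <- attr(reads, "read_len")
  ref_chars <- str_to_chars(annotation$contig_seq)

  # long-format explosion: one row per mate base
  n <- nrow(reads)
  starts <- c(reads$start1, reads$start2)
  seqs <- c(reads$seq1, reads$seq2)
  pair_id <- rep(c(reads$pair_id, reads$pair_id), each = read_len)
  mate <- rep(rep(1:2, each = n), each = read_len)
  pos <- rep(starts, each = read_len) +
    rep.int(seq_len(read_len) - 1L, 2L * n)
  base <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  base_idx <- match(base, DNA_BASES)

  # per-mate identity filter
  is_match <- base == ref_chars[pos]
  mate_id <- rep(seq_len(2L * n), each = read_len)
  matches <- tabulate(mate_id[is_match], nbins = 2L * n)
  pass <- (matches / read_len) >= min_read_identity
  keep <- pass[mate_id] & !is.na(base_idx)
  if (!any(keep)) return(empty())
  pos <- pos[keep]
  base_idx <- base_idx[keep]
  pair_id <- pair_id[keep]
  mate <- mate[keep]

  # overlapping mates of the same pair: count once, first mate wins
  ord <- order(pair_id, mate)
  key <- as.numeric(pair_id[ord]) * (L + 1) + pos[ord]
  dup <- duplicated(key)
  pos <- pos[ord][!dup]
  base_idx <- base_idx[ord][!dup]

  counts_vec <- tabulate(pos + (base_idx - 1L) * L, nbins = 4L * L)
  counts <- matrix(counts_vec, nrow = L, ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  coverage <- as.integer(rowSums(counts))
  structure(list(counts = counts, coverage = coverage,
                 mean_coverage = mean(coverage),
                 breadth = mean(coverage >= 1L),
                 contig = annotation$contig_id, length = L,
                 n_mates_used = sum(pass)),
            class = "pileup_table")
}

#' @export
print.pileup_table <- function(x, ...) {
  cat(sprintf(paste0("<pileup_table> %s: %d bp, mean coverage %.1fx, ",
                     "breadth %.3f\n"),
              x$contig, x$length, x$mean_coverage, x$breadth))
  invisible(x)
}

#' Sum the counts of several pileups (pooled profile across samples)
#' @param pileups List of `pileup_table`s over the same reference.
#' @return A pooled `pileup_table`.
#' @export
pool_pileups <- function(pileups) {
  stopifnot(length(pileups) >= 1L)
  counts <- Reduce(`+`, lapply(pileups, `[[`, "counts"))
  coverage <- as.integer(rowSums(counts))
  structure(list(counts = counts, coverage = coverage,
                 mean_coverage = mean(coverage),
                 breadth = mean(coverage >= 1L),
                 contig = pileups[[1]]$contig, length = pileups[[1]]$length,
                 n_mates_used = NA_integer_),
            class = "pileup_table")
}

#' Majority-rule consensus sequence of a pileup
#'
#' Per site the most frequent base (ties broken A<C<G<T); sites with zero
#' coverage fall back to the reference.
#'
#' @param pileup A `pileup_table`.
#' @param annotation A `genome_annotation` (reference fallback).
#' @return Character vector of single bases, length L.
#' @export
consensus_sequence <- function(pileup, annotation) {
  cons <- DNA_BASES[max.col(pileup$counts, ties.method = "first")]
  zero <- pileup$coverage == 0L
  if (any(zero)) {
    cons[zero] <- str_to_chars(annotation$contig_seq)[zero]
  }
  cons
}

#' Population detection gate from coverage and breadth
#'
#' A population counts as detected in a sample when its mean mapping coverage
#' and breadth both exceed the thresholds (strict inequalities). The default
#' 5x / 0.5 gate is the detection threshold for reliable minor-allele calling;
#' the stricter 10x / 0.8 preset is used when comparing diversity estimates.
#'
#' @param pileup A `pileup_table`.
#' @param min_coverage,min_breadth Gate thresholds (defaults 5, 0.5).
#' @return Logical flag.
#' @export
population_detection <- function(pileup, min_coverage = 5,
                                 min_breadth = 0.5) {
  pileup$mean_coverage > min_coverage && pileup$breadth > min_breadth
}
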
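#' Simulate a reference genome with annotated protein-coding genes
#'
#' Generates a single linear contig carrying non-overlapping protein-coding
#' genes (each a proper ORF: ATG start, no internal stop codons on the
#' annotated strand, terminal stop codon, length divisible by 3) separated by
#' intergenic sequence, at a controllable GC content. The result is the
#' coordinate frame for all site-level statistics downstream.
#'
#' @param length Contig length in bp.
#' @param n_genes Number of genes to place.
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param min_gene_len,max_gene_len Gene length bounds in bp (rounded to
#'   multiples of 3, including the stop codon).
#' @param contig_id Name of the contig.
#'
#' @return An object of class `genome_annotation`: a list with `contig_id`,
#'   `contig_seq` (character), `length`, and `genes` (data.frame with
#'   `gene_id`, `contig_id`, `start`, `end`, `strand`, `frame`; 1-based
#'   inclusive coordinates).
#' @export
simulate_reference <- function(length, n_genes, gc = 0.35, seed,
                               min_gene_len = 300L, max_gene_len = 900L,
                               contig_id = "contig_1") {
  stopifnot(length >= 1, n_genes >= 0)
  stopifnot_scalar_fraction(gc, "gc")
  if (gc <= 0 || gc >= 1) stop("`gc` must be strictly inside (0, 1)", call. = FALSE)
  min_gene_len <- as.integer(3L * ceiling(min_gene_len / 3))
  max_gene_len <- as.integer(3L * floor(max_gene_len / 3))
  min_gap <- 20L

  with_seed(seed, {
    # gene lengths (multiples of 3)
    if (n_genes > 0L) {
      n_codons <- sample(seq(min_gene_len %/% 3L, max_gene_len %/% 3L),
                         n_genes, replace = TRUE)
      gene_lens <- 3L * n_codons
    } else {
      gene_lens <- integer()
    }
    needed <- sum(gene_lens) + (n_genes + 1L) * min_gap
    if (needed > length) {
      stop(sprintf(paste0("cannot fit %d genes (need >= %d bp incl. ",
                          "intergenic gaps) in a %d bp contig"),
                   n_genes, needed, length), call. = FALSE)
    }

    # distribute the spare space randomly over the n_genes + 1 gaps
    spare <- length - sum(gene_lens) - (n_genes + 1L) * min_gap
    if (n_genes > 0L) {
      w <- as.vector(stats::rmultinom(1L, spare, rep(1, n_genes + 1L)))
    } else {
      w <- spare
    }
    gaps <- min_gap + w

    base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    rand_bases <- function(n) {
      if (n == 0L) character() else
        sample(DNA_BASES, n, replace = TRUE, prob = base_probs)
    }

    # codon sampling weights: per-base GC probabilities, stops excluded for
    # internal codons
    codons <- all_codons()
    cw <- vapply(strsplit(codons, ""), function(ch)
      prod(base_probs[ch]), numeric(1))
    aa <- translate_codons(codons)
    internal_codons <- codons[aa != "*"]
    internal_w <- cw[aa != "*"]
    stop_codons <- codons[aa == "*"]
    stop_w <- cw[aa == "*"]

    seq_chars <- character(length)
    genes <- data.frame(gene_id = character(n_genes),
                        contig_id = rep(contig_id, n_genes),
                        start = integer(n_genes), end = integer(n_genes),
                        strand = character(n_genes),
                        frame = integer(n_genes),
                        stringsAsFactors = FALSE)
    cursor <- 1L
    for (i in seq_len(n_genes)) {
      gap_chars <- rand_bases(gaps[i])
      if (gaps[i] > 0L) seq_chars[cursor:(cursor + gaps[i] - 1L)] <- gap_chars
      cursor <- cursor + gaps[i]
      glen <- gene_lens[i]
      ncod <- glen %/% 3L
      body <- sample(internal_codons, ncod - 2L, replace = TRUE,
                     prob = internal_w)
      orf <- c("ATG", body, sample(stop_codons, 1L, prob = stop_w))
      orf_chars <- str_to_chars(paste(orf, collapse = ""))
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        orf_chars <- rev(complement_chars(orf_chars))
      }
      seq_chars[cursor:(cursor + glen - 1L)] <- orf_chars
      genes$gene_id[i] <- sprintf("gene_%03d", i)
      genes$start[i] <- cursor
      genes$end[i] <- cursor + glen - 1L
      genes$strand[i] <- strand
      genes$frame[i] <- 0L
      cursor <- cursor + glen
    }
    tail_n <- length - cursor + 1L
    if (tail_n > 0L) seq_chars[cursor:length] <- rand_bases(tail_n)

    structure(list(contig_id = contig_id,
                   contig_seq = chars_to_str(seq_chars),
                   length = as.integer(length),
                   genes = genes),
              class = "genome_annotation")
  })
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d bp, %d genes (%.1f%% coding)\n",
              x$contig_id, x$length, nrow(x$genes),
              100 * sum(x$genes$end - x$genes$start + 1) / x$length))
  invisible(x)
}

# logical mask of coding positions
coding_mask <- function(annotation) {
  m <- logical(annotation$length)
  g <- annotation$genes
  for (i in seq_len(nrow(g))) m[g$start[i]:g$end[i]] <- TRUE
  m
}

# gene index (row in annotation$genes) per position, NA for intergenic;
# valid because the simulator guarantees non-overlapping genes
gene_index_map <- function(annotation) {
  idx <- rep(NA_integer_, annotation$length)
  g <- annotation$genes
  for (i in seq_len(nrow(g))) idx[g$start[i]:g$end[i]] <- i
  idx
}
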
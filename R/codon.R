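# Codon-level machinery shared by SNV classification, pN/pS site counting and
# neutral third-position diversity. Built once from the standard genetic code
# (Biostrings::GENETIC_CODE) and cached in the package namespace.

.codon_cache <- new.env(parent = emptyenv())

all_codons <- function() {
  if (is.null(.codon_cache$codons)) {
    g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                     stringsAsFactors = FALSE)
    .codon_cache$codons <- paste0(g$b1, g$b2, g$b3)
  }
  .codon_cache$codons
}

# Translate codon strings to single-letter amino acids; stop codons become "*"
# and are treated as a 21st residue (a substitution into or out of a stop is
# nonsynonymous unless both codons are stops).
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# For every codon and codon position, the number of the 3 possible single-base
# substitutions that are synonymous. Rows are codons (names), columns are
# codon positions 1..3. This is the Nei-Gojobori fractional-site machinery:
# a position contributes syn_count/3 synonymous sites and 1 - syn_count/3
# nonsynonymous sites.
codon_syn_counts <- function() {
  if (!is.null(.codon_cache$syn_counts)) {
    return(.codon_cache$syn_counts)
  }
  codons <- all_codons()
  aa <- translate_codons(codons)
  names(aa) <- codons
  m <- matrix(0L, nrow = length(codons), ncol = 3L,
              dimnames = list(codons, NULL))
  for (cd in codons) {
    ch <- str_to_chars(cd)
    for (p in 1:3) {
      alt_bases <- setdiff(DNA_BASES, ch[p])
      n_syn <- 0L
      for (b in alt_bases) {
        ch2 <- ch
        ch2[p] <- b
        if (aa[[chars_to_str(ch2)]] == aa[[cd]]) n_syn <- n_syn + 1L
      }
      m[cd, p] <- n_syn
    }
  }
  .codon_cache$syn_counts <- m
  m
}

# TRUE for codons whose third position is 4-fold degenerate (all four bases
# encode the same amino acid). Used as the neutrality proxy.
fourfold_codons <- function() {
  if (is.null(.codon_cache$fourfold)) {
    m <- codon_syn_counts()
    .codon_cache$fourfold <- rownames(m)[m[, 3] == 3L]
  }
  .codon_cache$fourfold
}

# Is the single-base change codon_from -> codon_to synonymous?
is_synonymous_change <- function(codon_from, codon_to) {
  translate_codons(codon_from) == translate_codons(codon_to)
}

# Map every genomic position of an annotation to its coding context.
# Returns a data.frame with one row per coding position:
#   pos            genomic position (1-based)
#   gene_id, strand
#   codon_pos      1..3 on the coding strand
#   cp1, cp2, cp3  genomic positions of the codon's three bases, in coding
#                  order (for '-' genes these decrease)
site_codon_map <- function(annotation) {
  genes <- annotation$genes
  if (nrow(genes) == 0L) {
    return(data.frame(pos = integer(), gene_id = character(),
                      strand = character(), codon_pos = integer(),
                      cp1 = integer(), cp2 = integer(), cp3 = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- genes$start[i]
    e <- genes$end[i]
    len <- e - s + 1L
    if (len %% 3L != 0L) {
      stop(sprintf("gene %s has length %d not divisible by 3",
                   genes$gene_id[i], len), call. = FALSE)
    }
    if (genes$strand[i] == "+") {
      pos <- s:e
      off <- pos - s                      # 0-based offset in coding order
    } else {
      pos <- s:e
      off <- e - pos                      # coding order runs e -> s
    }
    idx <- off %/% 3L                     # codon index, 0-based
    cpos <- off %% 3L + 1L
    if (genes$strand[i] == "+") {
      c1 <- s + 3L * idx
      c2 <- c1 + 1L
      c3 <- c1 + 2L
    } else {
      c1 <- e - 3L * idx
      c2 <- c1 - 1L
      c3 <- c1 - 2L
    }
    out[[i]] <- data.frame(pos = pos, gene_id = genes$gene_id[i],
                           strand = genes$strand[i], codon_pos = cpos,
                           cp1 = c1, cp2 = c2, cp3 = c3,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Extract consensus codons for a set of map rows given a consensus sequence
# (character vector of single bases, genome-forward). Bases are complemented
# for '-' strand genes so the returned codon reads in coding orientation.
codons_from_consensus <- function(map_rows, consensus_chars) {
  b1 <- consensus_chars[map_rows$cp1]
  b2 <- consensus_chars[map_rows$cp2]
  b3 <- consensus_chars[map_rows$cp3]
  neg <- map_rows$strand == "-"
  if (any(neg)) {
    b1[neg] <- complement_chars(b1[neg])
    b2[neg] <- complement_chars(b2[neg])
    b3[neg] <- complement_chars(b3[neg])
  }
  paste0(b1, b2, b3)
}
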
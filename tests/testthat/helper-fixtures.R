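# Shared fixtures, built in code and cached for the duration of the run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

small_annotation <- function() {
  fixture("ann20k", function()
    simulate_reference(20000, 20, gc = 0.40, seed = 101))
}

small_pool <- function() {
  fixture("pool20k", function()
    simulate_strain_pool(small_annotation(), n_strains = 20,
                         target_pi = 0.02, recomb_block_len = 300,
                         seed = 102))
}

small_reads <- function() {
  fixture("reads20k", function()
    simulate_sample_reads(small_pool(), coverage = 50, error_rate = 0,
                          seed = 103))
}

small_pileup <- function() {
  fixture("pileup20k", function()
    build_pileup(small_reads(), small_annotation()))
}

small_snvs <- function() {
  fixture("snvs20k", function()
    call_snvs(small_pileup(), small_annotation()))
}

# Construct a pileup_table directly from a counts matrix (unit-test scaffold
# for operations that consume pileups).
make_pileup <- function(counts, contig = "contig_1") {
  counts <- as.matrix(counts)
  colnames(counts) <- c("A", "C", "G", "T")
  coverage <- as.integer(rowSums(counts))
  structure(list(counts = counts, coverage = coverage,
                 mean_coverage = mean(coverage),
                 breadth = mean(coverage >= 1L),
                 contig = contig, length = nrow(counts),
                 n_mates_used = NA_integer_),
            class = "pileup_table")
}

# Minimal single-gene annotation with an explicitly chosen coding sequence
# (must start ATG, end with a stop, no internal stops), on the + strand,
# flanked by intergenic sequence.
make_gene_annotation <- function(cds, flank = "ACGTACGTAC") {
  seq <- paste0(flank, cds, flank)
  genes <- data.frame(gene_id = "gene_001", contig_id = "contig_1",
                      start = nchar(flank) + 1L,
                      end = nchar(flank) + nchar(cds),
                      strand = "+", frame = 0L, stringsAsFactors = FALSE)
  structure(list(contig_id = "contig_1", contig_seq = seq,
                 length = nchar(seq), genes = genes),
            class = "genome_annotation")
}

# Hand-built read_pair_set from explicit mate coordinates and sequences.
make_reads <- function(start1, seq1, start2, seq2, contig = "contig_1",
                       contig_length = 100L) {
  read_len <- if (length(seq1)) nchar(seq1[1]) else 150L
  out <- data.frame(pair_id = seq_along(start1),
                    strain = rep(NA_integer_, length(start1)),
                    contig = rep(contig, length(start1)),
                    start1 = as.integer(start1),
                    end1 = as.integer(start1) + read_len - 1L, seq1 = seq1,
                    start2 = as.integer(start2),
                    end2 = as.integer(start2) + read_len - 1L, seq2 = seq2,
                    stringsAsFactors = FALSE)
  attr(out, "read_len") <- as.integer(read_len)
  attr(out, "contig_id") <- contig
  attr(out, "contig_length") <- as.integer(contig_length)
  class(out) <- c("read_pair_set", "data.frame")
  out
}
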
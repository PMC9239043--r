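# Standard-format I/O. FASTA via Biostrings, GFF3 via rtracklayer, SAM export
# written directly (no R package writes SAM from in-memory alignments), SAM
# import via Rsamtools (SAM -> BAM -> records).

#' Write the reference genome to FASTA
#' @param annotation A `genome_annotation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(annotation, path) {
  dna <- Biostrings::DNAStringSet(setNames(annotation$contig_seq,
                                           annotation$contig_id))
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Write gene models to GFF3 (1-based inclusive, CDS features)
#' @param annotation A `genome_annotation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(annotation, path) {
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- g$frame
  S4Vectors::mcols(gr)$ID <- g$gene_id
  GenomeInfoDb::seqlengths(gr) <- setNames(annotation$length,
                                           annotation$contig_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a reference genome and GFF3 gene models into a `genome_annotation`
#' @param fasta_path Reference FASTA (single contig).
#' @param gff3_path GFF3 with CDS features.
#' @return A `genome_annotation`.
#' @export
read_annotation <- function(fasta_path, gff3_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L) {
    stop("expected a single-contig reference FASTA", call. = FALSE)
  }
  contig_id <- sub("\\s.*$", "", names(dna)[1])
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids) || anyNA(ids)) {
    ids <- sprintf("gene_%03d", seq_along(gr))
  }
  genes <- data.frame(gene_id = as.character(ids),
                      contig_id = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      frame = 0L,
                      stringsAsFactors = FALSE)
  bad <- genes$contig_id != contig_id
  if (any(bad)) {
    stop(sprintf("GFF3 references unknown contigs: %s",
                 paste(unique(genes$contig_id[bad]), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(contig_id = contig_id,
                 contig_seq = as.character(dna[[1]]),
                 length = Biostrings::width(dna)[1],
                 genes = genes[order(genes$start), , drop = FALSE]),
            class = "genome_annotation")
}

#' Export simulated read pairs as SAM
#'
#' Both mates are written as mapped, properly paired, ungapped (150M)
#' alignments on the forward strand in genome-forward orientation.
#'
#' @param reads A `read_pair_set`.
#' @param path Output SAM file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path) {
  read_len <- attr(reads, "read_len")
  contig <- attr(reads, "contig_id")
  clen <- attr(reads, "contig_length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, clen)), con)
  cigar <- sprintf("%dM", read_len)
  qual <- strrep("I", read_len)
  qname <- sprintf("pair_%07d", reads$pair_id)
  tlen <- reads$end2 - reads$start1 + 1L
  l1 <- paste(qname, 67L, contig, reads$start1, 60L, cigar, "=",
              reads$start2, tlen, reads$seq1, qual, sep = "\t")
  l2 <- paste(qname, 131L, contig, reads$start2, 60L, cigar, "=",
              reads$start1, -tlen, reads$seq2, qual, sep = "\t")
  writeLines(c(rbind(l1, l2)), con)
  invisible(path)
}

#' Import a SAM file as a `read_pair_set`
#'
#' Converts through BAM with Rsamtools and reassembles mate pairs by query
#' name. Only primary, mapped, ungapped pairs are kept.
#'
#' @param path SAM file.
#' @param read_len Expected read length.
#' @return A `read_pair_set`.
#' @export
read_sam <- function(path, read_len = 150L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM files", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "seq"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  df <- data.frame(qname = res$qname, flag = res$flag,
                   contig = as.character(res$rname), pos = res$pos,
                   seq = as.character(res$seq), stringsAsFactors = FALSE)
  first <- bitwAnd(df$flag, 64L) > 0L
  m1 <- df[first, ]
  m2 <- df[!first, ]
  idx <- match(m1$qname, m2$qname)
  keep <- !is.na(idx)
  m1 <- m1[keep, ]
  m2 <- m2[idx[keep], ]
  out <- data.frame(pair_id = seq_len(nrow(m1)),
                    strain = NA_integer_,
                    contig = m1$contig,
                    start1 = m1$pos, end1 = m1$pos + read_len - 1L,
                    seq1 = m1$seq,
                    start2 = m2$pos, end2 = m2$pos + read_len - 1L,
                    seq2 = m2$seq,
                    stringsAsFactors = FALSE)
  # normalize so mate1 is leftmost (pileup overlap rule is first-mate-wins)
  swap <- out$start2 < out$start1
  if (any(swap)) {
    tmp <- out[swap, c("start1", "end1", "seq1")]
    out[swap, c("start1", "end1", "seq1")] <-
      out[swap, c("start2", "end2", "seq2")]
    out[swap, c("start2", "end2", "seq2")] <- tmp
  }
  attr(out, "read_len") <- as.integer(read_len)
  attr(out, "contig_id") <- names(hdr)[1]
  attr(out, "contig_length") <- unname(hdr[1])
  class(out) <- c("read_pair_set", "data.frame")
  out
}

#' Write an environmental series as TSV
#' @param env An `env_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_env_tsv <- function(env, path) {
  out <- data.frame(sample_id = env$sample_id,
                    iso_date = format(env$date, "%Y-%m-%d"),
                    site = env$site,
                    temperature_c = env$temperature_c)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an environmental series TSV
#' @param path TSV with columns sample_id, iso_date, site, temperature_c.
#' @return An `env_series`.
#' @export
read_env_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(sample_id = df$sample_id,
                    date = as.Date(df$iso_date),
                    site = df$site,
                    temperature_c = df$temperature_c,
                    stringsAsFactors = FALSE)
  class(out) <- c("env_series", "data.frame")
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
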
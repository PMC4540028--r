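## File interchange: FASTA via Biostrings, GFF3 via rtracklayer, plus a
## minimal tag-free SAM text reader/writer (the simulator emits truth
## alignments directly as SAM text; no compressed/binary input is supported).

#' Write gene models as GFF3
#'
#' @param models gene-model tibble with columns `gene_id`, `contig`,
#'   `strand`, `type` (`"exon"`/`"CDS"`), `start`, `end` (1-based inclusive)
#'   and `phase` (CDS rows).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  genes <- models |>
    dplyr::group_by(.data$gene_id, .data$contig, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  gene_gr <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id,
    phase = NA_integer_)
  feat <- models
  feat_gr <- GenomicRanges::GRanges(
    feat$contig, IRanges::IRanges(feat$start, feat$end),
    strand = feat$strand, type = feat$type,
    ID = paste0(feat$gene_id, ".", tolower(feat$type), seq_len(nrow(feat))),
    phase = ifelse(feat$type == "CDS", feat$phase, NA_integer_))
  S4Vectors::mcols(gene_gr)$Parent <- NA_character_
  S4Vectors::mcols(feat_gr)$Parent <- feat$gene_id
  gr <- c(gene_gr, feat_gr)
  gr <- gr[order(S4Vectors::mcols(gr)$Parent, na.last = FALSE)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports exon and CDS features and returns them in the package's
#' gene-model tibble layout (`gene_id`, `contig`, `strand`, `type`,
#' `start`, `end`, `phase`).
#'
#' @param path GFF3 file.
#' @return tibble of gene models.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% c("exon", "CDS")]
  parent <- as.character(S4Vectors::mcols(gr)$Parent)
  tibble(
    gene_id = parent,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    phase = as.integer(S4Vectors::mcols(gr)$phase)
  )
}

#' Write alignments as SAM text
#'
#' @param aln alignment tibble with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`.
#' @param ref_lengths named integer vector of reference contig lengths (for
#'   the `@SQ` header lines).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                      as.integer(ref_lengths)))
  aln <- dplyr::arrange(aln, .data$rname, .data$pos)
  records <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                   aln$cigar, "*", 0L, 0L, aln$seq, aln$qual, sep = "\t")
  readr::write_lines(c(header, records), path)
  invisible(path)
}

#' Read SAM text alignments
#'
#' Parses the eleven mandatory columns of uncompressed SAM; optional tags are
#' ignored and unmapped records (`rname == "*"`) are dropped.
#'
#' @param path SAM text file.
#' @return alignment tibble (`qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`) with the `@SQ` contig lengths in the
#'   `ref_lengths` attribute.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  is_hdr <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  ref_lengths <- stats::setNames(
    as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)),
    sub(".*\tSN:([^\t]+).*", "\\1", sq))
  body <- lines[!is_hdr]
  if (!length(body)) {
    out <- tibble(qname = character(), flag = integer(), rname = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  seq = character(), qual = character())
    attr(out, "ref_lengths") <- ref_lengths
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(f) < 11L
  if (any(bad)) {
    warn(sprintf("skipping %d malformed SAM record(s)", sum(bad)))
    f <- f[!bad]
  }
  get <- function(i) vapply(f, `[[`, character(1), i)
  out <- tibble(qname = get(1), flag = as.integer(get(2)), rname = get(3),
                pos = as.integer(get(4)), mapq = as.integer(get(5)),
                cigar = get(6), seq = get(10), qual = get(11))
  out <- out[out$rname != "*", ]
  attr(out, "ref_lengths") <- ref_lengths
  out
}

#' Write simulated reads as FASTQ
#'
#' Reads flagged as reverse-strand (SAM flag 16) are reverse-complemented so
#' the FASTQ holds the read as sequenced.
#'
#' @param aln alignment tibble from [simulate_reads()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(aln, path) {
  seqs <- aln$seq
  rev <- bitwAnd(aln$flag, 16L) > 0L
  if (any(rev)) {
    seqs[rev] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rev])))
  }
  readr::write_lines(
    as.vector(rbind(paste0("@", aln$qname), seqs, "+", aln$qual)), path)
  invisible(path)
}
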
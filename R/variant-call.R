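#' Pileup-based SNP and InDel calling
#'
#' Builds per-site base and gap columns from gapped alignments against the
#' reference and emits haploid-style consensus calls. A substitution is
#' called where an alternative base reaches `min_alt_fraction` of the site
#' depth; insertions and deletions are taken from the alignments' gap
#' operations, with the supporting fraction computed over reads that span the
#' event junction (reads overlapping both flanking reference bases -- reads
#' that merely touch one side cannot witness the event and are not counted
#' against it). InDels are left-aligned against the reference before
#' reporting.
#'
#' Variant confidence is a Phred-scaled binomial score of the alternative
#' count against a fixed per-base error rate: `-10 log10 P(X >= alt | depth,
#' error_rate)`. Calls are filtered to `pass` when depth >= `min_depth` and
#' quality > `min_qual` (the conventional "quality > 30, depth >= 10"
#' marker-grade filter); input records below `min_mapq` are ignored.
#'
#' @param alignments alignment tibble (e.g. from [simulate_reads()] or
#'   [read_sam()]) or the path to a SAM text file.
#' @param reference [Biostrings::DNAStringSet] or named character vector of
#'   reference contigs.
#' @param min_depth minimum site depth for a `pass` call.
#' @param min_qual Phred threshold; `pass` requires quality strictly above it.
#' @param min_alt_fraction consensus fraction for emitting a call.
#' @param min_mapq mapping-quality floor on input records.
#' @param error_rate fixed per-base error rate of the quality model.
#' @return tibble of calls: `contig`, `position` (1-based; anchor base for
#'   InDels), `ref_allele`, `alt_allele`, `type` (`SNP`/`insertion`/
#'   `deletion`), `depth`, `alt_count`, `alt_fraction`, `qual`, `filter`
#'   (`pass`/`low_depth`/`low_qual`).
#' @export
pileup_call <- function(alignments, reference, min_depth = 10L,
                        min_qual = 30, min_alt_fraction = 0.8,
                        min_mapq = 20L, error_rate = 0.01) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_sam(alignments)
  }
  if (inherits(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  unknown <- setdiff(unique(alignments$rname), names(reference))
  if (length(unknown)) {
    abort(sprintf("alignments reference unknown contig(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  aln <- alignments[alignments$mapq >= min_mapq, ]
  ok_cigar <- grepl("^([0-9]+[MIDNSHP=X])+$", aln$cigar)
  if (any(!ok_cigar)) {
    warn(sprintf("skipping %d record(s) with malformed CIGAR", sum(!ok_cigar)))
    aln <- aln[ok_cigar, ]
  }
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(aln$cigar)
  ok_len <- qw == nchar(aln$seq)
  if (any(!ok_len)) {
    warn(sprintf("skipping %d record(s) whose CIGAR does not match the sequence length",
                 sum(!ok_len)))
    aln <- aln[ok_len, ]
  }
  calls <- map(split(aln, aln$rname), function(a) {
    pileup_one_contig(a, reference[[a$rname[1]]],
                      min_alt_fraction, error_rate)
  })
  calls <- list_rbind(calls[vapply(calls, function(x) !is.null(x) && nrow(x) > 0,
                                   logical(1))])
  if (is.null(calls) || nrow(calls) == 0) {
    return(tibble(contig = character(), position = integer(),
                  ref_allele = character(), alt_allele = character(),
                  type = character(), depth = integer(), alt_count = integer(),
                  alt_fraction = double(), qual = double(), filter = character()))
  }
  calls$filter <- dplyr::case_when(
    calls$depth < min_depth ~ "low_depth",
    calls$qual <= min_qual ~ "low_qual",
    TRUE ~ "pass")
  dplyr::arrange(calls, .data$contig, .data$position)
}

phred_binom <- function(alt, depth, error_rate) {
  -10 * stats::pbinom(alt - 1L, depth, error_rate,
                      lower.tail = FALSE, log.p = TRUE) / log(10)
}

pileup_one_contig <- function(a, refseq, min_alt_fraction, error_rate) {
  contig <- a$rname[1]
  reflen <- nchar(refseq)
  cig <- a$cigar
  pos <- a$pos
  ## site depth from M chunks; junction depth from contiguous read spans
  m_ref <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, pos = pos,
                                                             ops = "M")
  m_qry <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = "M")
  ir <- unlist(m_ref)
  iq <- unlist(m_qry)
  ridx <- rep(seq_along(cig), S4Vectors::elementNROWS(m_ref))
  depth <- as.integer(IRanges::coverage(ir, width = reflen))
  w_ref <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  span <- IRanges::IRanges(pos, pos + w_ref - 1L)
  span <- span[IRanges::width(span) >= 2L]
  jcov <- as.integer(IRanges::coverage(
    IRanges::IRanges(IRanges::start(span), IRanges::end(span) - 1L),
    width = reflen))

  ## substitution columns: compare M chunks, expand only mismatching ones
  read_chunks <- substr(a$seq[ridx], IRanges::start(iq), IRanges::end(iq))
  ref_chunks <- substring(refseq, IRanges::start(ir), IRanges::end(ir))
  neq <- which(read_chunks != ref_chunks)
  snp <- NULL
  if (length(neq)) {
    ev <- map(neq, function(i) {
      rb <- charToRaw(read_chunks[i])
      fb <- charToRaw(ref_chunks[i])
      d <- which(rb != fb)
      list(pos = IRanges::start(ir)[i] + d - 1L, base = rawToChar(rb[d]))
    })
    ev_pos <- unlist(map(ev, "pos"))
    ev_base <- unlist(strsplit(map_chr(ev, "base"), "", fixed = TRUE))
    tab <- tibble(position = ev_pos, base = ev_base) |>
      dplyr::count(.data$position, .data$base, name = "alt_count") |>
      dplyr::group_by(.data$position) |>
      dplyr::slice_max(.data$alt_count, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    tab$depth <- depth[tab$position]
    tab$alt_fraction <- tab$alt_count / tab$depth
    tab <- tab[tab$alt_fraction >= min_alt_fraction, ]
    if (nrow(tab)) {
      snp <- tibble(contig = contig, position = tab$position,
                    ref_allele = substring(refseq, tab$position, tab$position),
                    alt_allele = tab$base, type = "SNP", depth = tab$depth,
                    alt_count = tab$alt_count,
                    alt_fraction = tab$alt_fraction,
                    qual = phred_binom(tab$alt_count, tab$depth, error_rate))
    }
  }

  ## insertions: zero-width ranges on the reference, sequence from the query
  i_ref <- unlist(GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = "I"))
  i_qry_l <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = "I")
  i_qry <- unlist(i_qry_l)
  i_idx <- rep(seq_along(cig), S4Vectors::elementNROWS(i_qry_l))
  ins <- NULL
  if (length(i_ref)) {
    anchors <- IRanges::start(i_ref) - 1L
    seqs <- substr(a$seq[i_idx], IRanges::start(i_qry), IRanges::end(i_qry))
    nrm <- map(seq_along(anchors), function(i) {
      left_align_event(refseq, "ins", anchors[i], seqs[i])
    })
    tab <- tibble(anchor = map_int(nrm, ~ as.integer(.x$pos)),
                  seq = map_chr(nrm, "seq")) |>
      dplyr::count(.data$anchor, .data$seq, name = "alt_count")
    tab <- tab[tab$anchor >= 1L, ]
    if (nrow(tab)) {
      tab$depth <- jcov[tab$anchor]
      tab$alt_fraction <- tab$alt_count / pmax(tab$depth, tab$alt_count)
      tab <- tab[tab$alt_fraction >= min_alt_fraction, ]
    }
    if (nrow(tab)) {
      ab <- substring(refseq, tab$anchor, tab$anchor)
      ins <- tibble(contig = contig, position = tab$anchor, ref_allele = ab,
                    alt_allele = paste0(ab, tab$seq), type = "insertion",
                    depth = tab$depth, alt_count = tab$alt_count,
                    alt_fraction = tab$alt_fraction,
                    qual = phred_binom(tab$alt_count, tab$depth, error_rate))
    }
  }

  ## deletions: D ranges on the reference
  d_ref_l <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, pos = pos,
                                                               ops = "D")
  d_ref <- unlist(d_ref_l)
  del <- NULL
  if (length(d_ref)) {
    nrm <- map(seq_along(d_ref), function(i) {
      p <- IRanges::start(d_ref)[i]
      left_align_event(refseq, "del", p,
                       substring(refseq, p, IRanges::end(d_ref)[i]))
    })
    tab <- tibble(first = map_int(nrm, ~ as.integer(.x$pos)),
                  seq = map_chr(nrm, "seq")) |>
      dplyr::count(.data$first, .data$seq, name = "alt_count")
    tab <- tab[tab$first >= 2L, ]
    if (nrow(tab)) {
      tab$depth <- jcov[tab$first - 1L]
      tab$alt_fraction <- tab$alt_count / pmax(tab$depth, tab$alt_count)
      tab <- tab[tab$alt_fraction >= min_alt_fraction, ]
    }
    if (nrow(tab)) {
      ab <- substring(refseq, tab$first - 1L, tab$first - 1L)
      del <- tibble(contig = contig, position = tab$first - 1L,
                    ref_allele = paste0(ab, tab$seq), alt_allele = ab,
                    type = "deletion", depth = tab$depth,
                    alt_count = tab$alt_count,
                    alt_fraction = tab$alt_fraction,
                    qual = phred_binom(tab$alt_count, tab$depth, error_rate))
    }
  }
  dplyr::bind_rows(snp, ins, del)
}
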
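## Read simulation: the simulator knows each read's true origin in the query
## genotype and the genotype's edit script against the reference, so it emits
## the truth alignment (reference position + gapped CIGAR) directly; no
## external aligner is involved.

## CIGAR of a read from its query->reference coordinate map slice.
## NA entries are inserted bases: internal NAs become I, leading/trailing
## NAs become soft clips; jumps in the reference coordinate become D.
cigar_from_map <- function(slice) {
  L <- length(slice)
  idx <- which(!is.na(slice))
  if (!length(idx)) return(NULL)
  lead <- idx[1] - 1L
  trail <- L - idx[length(idx)]
  core <- slice[idx[1]:idx[length(idx)]]
  ops <- character(0)
  lens <- integer(0)
  r <- rle(is.na(core))
  at <- 1L
  for (j in seq_along(r$lengths)) {
    n <- r$lengths[j]
    if (r$values[j]) {
      ops <- c(ops, "I"); lens <- c(lens, n)
    } else {
      seg <- core[at:(at + n - 1L)]
      jumps <- which(diff(seg) != 1L)
      starts <- c(1L, jumps + 1L)
      ends <- c(jumps, n)
      for (s in seq_along(starts)) {
        ops <- c(ops, "M"); lens <- c(lens, ends[s] - starts[s] + 1L)
        if (s < length(starts)) {
          ops <- c(ops, "D")
          lens <- c(lens, seg[starts[s + 1L]] - seg[ends[s]] - 1L)
        }
      }
    }
    at <- at + n
  }
  if (lead > 0L) { ops <- c("S", ops); lens <- c(lead, lens) }
  if (trail > 0L) { ops <- c(ops, "S"); lens <- c(lens, trail) }
  list(pos = core[1], cigar = paste0(lens, ops, collapse = ""))
}

#' Simulate error-free reads with truth alignments
#'
#' Draws uniformly placed, error-free reads from one genotype's assembly and
#' reports each read's true alignment against the *reference* genotype:
#' position and gapped CIGAR derived from the panel's edit script (reads from
#' the reference itself align as all-match). Half the reads are flagged
#' reverse-strand; their SAM `seq` stays on the forward reference strand, as
#' the format requires.
#'
#' @param panel a `neem_panel`.
#' @param genotype `"G1"`, `"G2"` or `"G3"`.
#' @param coverage mean fold coverage (> 0); defaults to the panel
#'   configuration.
#' @param read_length read length in bases; defaults to the configuration.
#' @param seed integer seed; defaults to a fixed derivation from the panel
#'   seed and genotype, so each genotype's reads are reproducible.
#' @return alignment tibble (`qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`) ready for [write_sam()] / [write_fastq()] /
#'   [pileup_call()].
#' @export
simulate_reads <- function(panel, genotype,
                           coverage = panel$config$coverage,
                           read_length = panel$config$read_length,
                           seed = NULL) {
  stopifnot(inherits(panel, "neem_panel"))
  assert_that_(genotype %in% names(panel$assemblies),
               sprintf("unknown genotype '%s'", genotype))
  assert_that_(coverage > 0, "`coverage` must be > 0")
  if (is.null(seed)) {
    seed <- derive_seed(panel$config$seed,
                        200 + match(genotype, names(panel$assemblies)))
  }
  contigs <- names(panel$reference)
  with_seed_(seed, {
    out <- map(seq_along(contigs), function(ci) {
      qseq <- as.character(panel$assemblies[[genotype]][[ci]])
      qlen <- nchar(qseq)
      if (qlen < read_length) return(NULL)
      qmap <- if (genotype == "G1") NULL else panel$edits[[genotype]][[ci]]$qmap
      n <- max(1L, as.integer(round(coverage * qlen / read_length)))
      starts <- sample.int(qlen - read_length + 1L, n, replace = TRUE)
      seqs <- substring(qseq, starts, starts + read_length - 1L)
      pos <- integer(n)
      cig <- character(n)
      keep <- rep(TRUE, n)
      if (is.null(qmap)) {
        pos <- starts
        cig[] <- paste0(read_length, "M")
      } else {
        simple <- paste0(read_length, "M")
        for (i in seq_len(n)) {
          slice <- qmap[starts[i]:(starts[i] + read_length - 1L)]
          if (!anyNA(slice) &&
              slice[read_length] - slice[1] == read_length - 1L) {
            pos[i] <- slice[1]
            cig[i] <- simple
          } else {
            cm <- cigar_from_map(slice)
            if (is.null(cm)) { keep[i] <- FALSE; next }
            pos[i] <- cm$pos
            cig[i] <- cm$cigar
          }
        }
      }
      tibble(
        qname = sprintf("%s_%s_%06d", tolower(genotype), contigs[ci],
                        seq_len(n)),
        flag = sample(c(0L, 16L), n, replace = TRUE),
        rname = contigs[ci], pos = pos, mapq = 60L, cigar = cig,
        seq = seqs, qual = strrep("I", read_length))[keep, ]
    })
    list_rbind(out[!vapply(out, is.null, logical(1))])
  })
}
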
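# Independent oracles used across the suite.

# Brute-force SSR enumeration: one greedy leftmost backreference regex per
# unit length, then primitivity filtering -- no code shared with scan_ssrs.
brute_force_ssrs <- function(seq, min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  out <- list()
  segs <- gregexpr("[ACGT]+", seq)[[1]]
  if (segs[1] == -1) {
    return(tibble::tibble(start = integer(), end = integer(),
                          motif = character(), unit_length = integer(),
                          repeat_count = integer()))
  }
  primitive <- function(m) {
    k <- nchar(m)
    for (d in seq_len(max(k - 1, 0))) {
      if (k %% d == 0 && strrep(substr(m, 1, d), k / d) == m) return(FALSE)
    }
    TRUE
  }
  for (si in seq_along(segs)) {
    s0 <- segs[si]
    seg <- substr(seq, s0, s0 + attr(segs, "match.length")[si] - 1L)
    for (k in 1:6) {
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, min_repeats[k] - 1L)
      m <- gregexpr(pat, seg, perl = TRUE)[[1]]
      if (m[1] == -1) next
      for (j in seq_along(m)) {
        st <- m[j]
        len <- attr(m, "match.length")[j]
        motif <- substr(seg, st, st + k - 1L)
        if (!primitive(motif)) next
        out[[length(out) + 1L]] <- tibble::tibble(
          start = s0 + st - 1L, end = s0 + st + len - 2L,
          motif = motif, unit_length = k,
          repeat_count = as.integer(len %/% k))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          motif = character(), unit_length = integer(),
                          repeat_count = integer()))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, unit_length, start)
}

# Whole-protein translation oracle for SNP coding effects: mutate the
# reference, rebuild and translate the entire CDS, and diff the proteins.
protein_oracle_effect <- function(reference, models, contig, pos, alt) {
  cds <- models[models$type == "CDS", ]
  g <- cds[cds$contig == contig & cds$start <= pos & cds$end >= pos, ]
  if (!nrow(g)) return("none")
  gg <- cds[cds$gene_id == g$gene_id[1], ]
  gg <- gg[order(gg$start), ]
  refseq <- as.character(reference[[contig]])
  mut <- refseq
  substr(mut, pos, pos) <- alt
  build <- function(s) {
    x <- paste(substring(s, gg$start, gg$end), collapse = "")
    if (gg$strand[1] == "-") {
      x <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    }
    x
  }
  s1 <- build(refseq)
  s2 <- build(mut)
  tr <- function(x) as.character(Biostrings::translate(Biostrings::DNAString(x),
                                                       no.init.codon = TRUE))
  p1 <- tr(s1)
  p2 <- tr(s2)
  d <- which(strsplit(p1, "")[[1]] != strsplit(p2, "")[[1]])
  if (!length(d)) return("synonymous")
  i <- d[1]
  a <- substr(p1, i, i)
  b <- substr(p2, i, i)
  if (i == 1 && substr(s1, 1, 3) == "ATG" && substr(s2, 1, 3) != "ATG") {
    return("start_lost")
  }
  if (i == nchar(p1) && a == "*" && b != "*") return("stop_lost")
  if (b == "*" && a != "*") return("stop_gained")
  "nonsynonymous"
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Reconstruct a query contig from the reference plus VCF-style truth records
# (applied right to left), independently of the generator's edit machinery.
reconstruct_from_truth <- function(refseq, truth) {
  truth <- truth[order(truth$pos, decreasing = TRUE), ]
  s <- refseq
  for (i in seq_len(nrow(truth))) {
    p <- truth$pos[i]
    ref <- truth$ref[i]
    alt <- truth$alt[i]
    stopifnot(substr(s, p, p + nchar(ref) - 1L) == ref)
    s <- paste0(substr(s, 1, p - 1L), alt,
                substr(s, p + nchar(ref), nchar(s)))
  }
  s
}

# One default panel shared across test files (generation is the expensive
# step; everything downstream is deterministic given the panel).
.panel_cache <- new.env(parent = emptyenv())
default_panel <- function(seed = 1L) {
  key <- paste0("panel_", seed)
  if (is.null(.panel_cache[[key]])) {
    .panel_cache[[key]] <- generate_panel(panel_config(seed = seed))
  }
  .panel_cache[[key]]
}

small_panel <- function(seed = 42L) {
  key <- paste0("small_", seed)
  if (is.null(.panel_cache[[key]])) {
    .panel_cache[[key]] <- generate_panel(panel_config(
      seed = seed, n_contigs = 2, contig_length = 30000, n_genes = 20,
      n_ssr_planted = 40, n_ssr_polymorphic = 10, n_corr_genes = 10))
  }
  .panel_cache[[key]]
}

locus_key <- function(d) paste(d$contig, d$start, d$end)
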
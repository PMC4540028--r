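#' Annotate variant calls against gene models
#'
#' Assigns each call a region class by positional overlap with the gene
#' models -- `exonic` > `intronic` > `upstream`/`downstream` (within
#' `flank_window` bases of the gene, strand-aware) > `intergenic` -- and, for
#' exonic SNPs inside a CDS, rebuilds the affected codon on the coding strand
#' and classifies the amino-acid change with the standard genetic code:
#' `synonymous`, `nonsynonymous`, `start_lost` (first codon),
#' `stop_gained`, or `stop_lost` (terminal codon). InDels and non-coding
#' variants get `coding_effect = "none"`.
#'
#' @param calls tibble from [pileup_call()].
#' @param models gene-model tibble (`gene_id`, `contig`, `strand`, `type`,
#'   `start`, `end`, `phase`), e.g. a panel's `$genes` or [read_gff3()].
#' @param reference reference sequences ([Biostrings::DNAStringSet] or named
#'   character) -- needed to rebuild codons.
#' @param flank_window size (bases) of the upstream/downstream windows.
#' @return `calls` with `region_class`, `coding_effect` and `gene_id` columns
#'   appended.
#' @export
annotate_variants <- function(calls, models, reference, flank_window = 5000L) {
  if (inherits(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  if (nrow(calls) == 0) {
    return(dplyr::mutate(calls, region_class = character(0),
                         coding_effect = character(0), gene_id = character(0)))
  }
  genes <- models |>
    dplyr::group_by(.data$gene_id, .data$contig, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  exons <- models[models$type == "exon", ]
  if (nrow(exons) == 0) exons <- models[models$type == "CDS", ]
  cds <- models[models$type == "CDS", ]

  ## per-gene CDS machinery, built lazily and cached
  cds_by_gene <- split(cds, cds$gene_id)
  gene_env <- new.env(parent = emptyenv())
  get_cds <- function(gid) {
    if (!is.null(gene_env[[gid]])) return(gene_env[[gid]])
    g <- cds_by_gene[[gid]]
    g <- g[order(g$start), ]
    total <- sum(g$end - g$start + 1L)
    if (total %% 3L != 0L) {
      warn(sprintf("gene '%s': CDS length %d not divisible by 3; coding effects skipped",
                   gid, total))
      gene_env[[gid]] <- list(bad = TRUE)
      return(gene_env[[gid]])
    }
    seqs <- substring(reference[[g$contig[1]]], g$start, g$end)
    cat_seq <- paste(seqs, collapse = "")
    strand <- g$strand[1]
    if (strand == "-") {
      cat_seq <- revcomp_chr(cat_seq)
    }
    gene_env[[gid]] <- list(bad = FALSE, tab = g, seq = cat_seq,
                            strand = strand, total = total)
    gene_env[[gid]]
  }

  region <- character(nrow(calls))
  effect <- rep("none", nrow(calls))
  gene_hit <- rep(NA_character_, nrow(calls))
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(calls))) {
    ctg <- calls$contig[i]
    p <- calls$position[i]
    ex <- exons[exons$contig == ctg & exons$start <= p & exons$end >= p, ]
    if (nrow(ex)) {
      region[i] <- "exonic"
      gene_hit[i] <- ex$gene_id[1]
      if (calls$type[i] == "SNP") {
        cd <- cds[cds$contig == ctg & cds$start <= p & cds$end >= p, ]
        if (nrow(cd)) {
          info <- get_cds(cd$gene_id[1])
          gene_hit[i] <- cd$gene_id[1]
          if (!info$bad) {
            g <- info$tab
            before <- which(g$end < p)
            off <- sum(g$end[before] - g$start[before] + 1L) + (p - g$start[g$start <= p & g$end >= p][1] + 1L)
            if (info$strand == "-") off <- info$total - off + 1L
            alt <- calls$alt_allele[i]
            if (info$strand == "-") alt <- chartr("ACGT", "TGCA", alt)
            ci <- (off - 1L) %/% 3L
            within <- off - ci * 3L
            ref_codon <- substr(info$seq, ci * 3L + 1L, ci * 3L + 3L)
            alt_codon <- ref_codon
            substr(alt_codon, within, within) <- alt
            ref_aa <- code[[ref_codon]]
            alt_aa <- code[[alt_codon]]
            n_codon <- info$total / 3L
            effect[i] <- if (ci == 0L && ref_codon == "ATG" && alt_codon != "ATG") {
              "start_lost"
            } else if (ci == n_codon - 1L && ref_aa == "*" && alt_aa != "*") {
              "stop_lost"
            } else if (alt_aa == "*" && ref_aa != "*") {
              "stop_gained"
            } else if (ref_aa == alt_aa) "synonymous" else "nonsynonymous"
          }
        }
      }
      next
    }
    gi <- genes$contig == ctg & genes$start <= p & genes$end >= p
    if (any(gi)) {
      region[i] <- "intronic"
      gene_hit[i] <- genes$gene_id[which(gi)[1]]
      next
    }
    ## strand-aware flanks
    up <- genes$contig == ctg &
      ((genes$strand == "+" & p >= genes$start - flank_window & p < genes$start) |
         (genes$strand == "-" & p > genes$end & p <= genes$end + flank_window))
    dn <- genes$contig == ctg &
      ((genes$strand == "+" & p > genes$end & p <= genes$end + flank_window) |
         (genes$strand == "-" & p >= genes$start - flank_window & p < genes$start))
    if (any(up)) {
      region[i] <- "upstream"
      gene_hit[i] <- genes$gene_id[which(up)[1]]
    } else if (any(dn)) {
      region[i] <- "downstream"
      gene_hit[i] <- genes$gene_id[which(dn)[1]]
    } else {
      region[i] <- "intergenic"
    }
  }
  dplyr::mutate(calls, region_class = region, coding_effect = effect,
                gene_id = gene_hit)
}

#' Summarise annotated variant calls
#'
#' @param calls annotated calls from [annotate_variants()].
#' @return list of tibbles: `by_region` and `by_effect` (counts and
#'   fractions over all calls; fractions sum to 1 per axis), plus
#'   `by_region_pass`/`by_effect_pass` restricted to pass-filter calls.
#' @export
summarize_effects <- function(calls) {
  tab <- function(df, col) {
    if (nrow(df) == 0) {
      return(tibble(!!col := character(), n = integer(), fraction = double()))
    }
    df |>
      dplyr::count(.data[[col]], name = "n") |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::arrange(dplyr::desc(.data$n))
  }
  pass <- calls[calls$filter == "pass", ]
  list(by_region = tab(calls, "region_class"),
       by_effect = tab(calls, "coding_effect"),
       by_region_pass = tab(pass, "region_class"),
       by_effect_pass = tab(pass, "coding_effect"))
}

#' Marker density per kilobase
#'
#' Converts per-genotype marker counts into densities per 1,000 bases of
#' genome and appends their mean -- the arithmetic behind statements like
#' "2.9 SNPs and 0.22 InDels per 1,000 nt". Full precision is retained in
#' `density`; `density_reported` is rounded to two significant figures for
#' reporting.
#'
#' @param counts numeric vector of marker counts, one per genotype
#'   (optionally named).
#' @param genome_size genome size in bases (> 0).
#' @return tibble with one row per genotype plus a `"mean"` row: `genotype`,
#'   `count`, `density`, `density_reported`.
#' @export
#' @examples
#' marker_density(c(G2 = 698173, G3 = 860215), genome_size = 267e6)
marker_density <- function(counts, genome_size) {
  assert_that_(length(counts) >= 1, "`counts` must be non-empty")
  assert_that_(genome_size > 0, "`genome_size` must be > 0")
  nm <- names(counts) %||% paste0("genotype_", seq_along(counts))
  counts <- unname(counts)
  dens <- counts / genome_size * 1000
  tibble(genotype = c(nm, "mean"),
         count = c(counts, mean(counts)),
         density = c(dens, mean(dens)),
         density_reported = signif(c(dens, mean(dens)), 2))
}

#' Shared and unique gene arithmetic
#'
#' The bookkeeping behind ortholog comparisons: how many genes lack any
#' ortholog, and what percentage are shared with a reference species.
#'
#' @param n_total total predicted genes.
#' @param n_with_orthologs genes with an ortholog in any compared species.
#' @param n_shared genes shared with the reference comparison species.
#' @return one-row tibble: `n_without_orthologs`, `pct_without_orthologs`,
#'   `pct_shared` (percentages rounded to 2 decimals).
#' @export
#' @examples
#' ortholog_summary(44495, 27498, 24216)
ortholog_summary <- function(n_total, n_with_orthologs, n_shared) {
  assert_that_(n_with_orthologs <= n_total && n_shared <= n_total,
               "component counts cannot exceed `n_total`")
  tibble(
    n_without_orthologs = n_total - n_with_orthologs,
    pct_without_orthologs = round((n_total - n_with_orthologs) / n_total * 100, 2),
    pct_shared = round(n_shared / n_total * 100, 2))
}
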
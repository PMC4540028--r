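## Synthetic multi-genotype panel generator.
##
## The reference contig is a chain of rejection-sampled spacers and planted
## SSR tracts; query genotypes are the reference plus an explicit edit script
## (SNPs, InDels, SSR repeat-number changes), so every reference/query
## difference is in the truth tables by construction ("truth closure").

SSR_UNIT_WEIGHTS <- c(0.12, 0.18, 0.40, 0.15, 0.08, 0.07)  # tri-heavy, as in genic SSR tallies
MIN_SPACER <- 120L
EDGE_PAD <- 150L       # variants are planted only where simulated coverage is uniform
TRACT_PAD <- 6L        # no variant within this many bases of an SSR tract

sample_primitive_motif <- function(k) {
  repeat {
    m <- paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
    if (is_primitive_motif(m)) return(m)
  }
}

## Rejection-sample a spacer: no SSR at detection thresholds may overlap the
## spacer, checked on a window that includes up to 12 bases of the adjacent
## tracts so runs crossing a junction are caught. `rewrites` are fixed bases
## (start/stop codons of gene models) applied before the check.
sample_spacer <- function(len, left_ctx, right_ctx, rewrites, thresholds) {
  for (attempt in 1:300) {
    s <- sample(DNA_BASES, len, replace = TRUE)
    if (nrow(rewrites)) s[rewrites$at] <- rewrites$base
    window <- paste0(left_ctx, paste(s, collapse = ""), right_ctx)
    loci <- scan_segment(window, 0L, thresholds$min_repeats)
    lo <- nchar(left_ctx) + 1L
    hi <- nchar(left_ctx) + len
    bad <- length(loci) && any(vapply(loci, function(l) {
      l$start <= hi && l$end >= lo
    }, logical(1)))
    if (!bad) return(paste(s, collapse = ""))
  }
  abort("failed to sample an SSR-free spacer after 300 attempts")
}

## Gene layout on one contig: `n` genes in equal slots, 2-3 exons each, CDS
## length divisible by 3, start/stop codons kept clear of SSR tracts.
layout_genes <- function(contig, contig_length, n, tracts, id_offset) {
  slot <- contig_length %/% n
  assert_that_(slot >= 1600L,
               "contig too short to host its share of gene models (needs >= 1600 bases per gene)")
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    n_ex <- sample(2:3, 1)
    ex_len <- sample(150:500, n_ex, replace = TRUE)
    ex_len[n_ex] <- ex_len[n_ex] - sum(ex_len) %% 3L
    introns <- sample(80:300, n_ex - 1, replace = TRUE)
    span <- sum(ex_len) + sum(introns)
    slot_start <- (i - 1L) * slot + 1L
    gstart <- slot_start + sample.int(max(1L, slot - span - 60L), 1) + 29L
    strand <- sample(c("+", "-"), 1)
    ## shift until the terminal codons avoid SSR tracts
    for (shift in seq(0L, 210L, by = 7L)) {
      s <- gstart + shift
      starts <- s + cumsum(c(0L, head(ex_len, -1) + introns))
      ends <- starts + ex_len - 1L
      cod1 <- if (strand == "+") c(starts[1], starts[1] + 2L) else c(ends[n_ex] - 2L, ends[n_ex])
      cod2 <- if (strand == "+") c(ends[n_ex] - 2L, ends[n_ex]) else c(starts[1], starts[1] + 2L)
      clash <- any(tracts$start <= cod1[2] + 2L & tracts$end >= cod1[1] - 2L) ||
        any(tracts$start <= cod2[2] + 2L & tracts$end >= cod2[1] - 2L)
      if (!clash && ends[n_ex] <= contig_length - 20L) break
    }
    ## transcription-order phases
    ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    phase <- integer(n_ex)
    cum <- 0L
    for (j in ord) {
      phase[j] <- (3L - (cum %% 3L)) %% 3L
      cum <- cum + ex_len[j]
    }
    genes[[i]] <- tibble(
      gene_id = sprintf("Ai02g%05d", id_offset + i),
      contig = contig, strand = strand,
      exon = seq_len(n_ex), start = starts, end = ends, phase = phase)
  }
  list_rbind(genes)
}

## Fixed-base rewrites turning each gene's terminal codons into genuine
## start/stop codons on its coding strand (ATG / TAA).
codon_rewrites <- function(genes) {
  rw <- genes |>
    dplyr::group_by(.data$gene_id, .data$contig, .data$strand) |>
    dplyr::summarise(first = min(.data$start), last = max(.data$end),
                     .groups = "drop")
  list_rbind(pmap(rw, function(gene_id, contig, strand, first, last) {
    if (strand == "+") {
      tibble(contig = contig,
             pos = c(first:(first + 2L), (last - 2L):last),
             base = c("A", "T", "G", "T", "A", "A"))
    } else {
      ## revcomp(ATG) = CAT at the gene 3' end; revcomp(TAA) = TTA at 5' end
      tibble(contig = contig,
             pos = c((last - 2L):last, first:(first + 2L)),
             base = c("C", "A", "T", "T", "T", "A"))
    }
  }))
}

## Left-align an insertion (seq inserted after `anchor`) or a deletion
## (`len` bases deleted starting at `pos`) against `refseq`; the canonical
## representation for both truth tables and calls.
left_align_event <- function(refseq, kind, pos, seq) {
  if (kind == "ins") {
    a <- pos
    s <- strsplit(seq, "")[[1]]
    L <- length(s)
    while (a >= 1L && substr(refseq, a, a) == s[L]) {
      s <- c(s[L], s[-L])
      a <- a - 1L
    }
    list(pos = a, seq = paste(s, collapse = ""))
  } else {
    len <- nchar(seq)
    p <- pos
    d <- strsplit(seq, "")[[1]]
    while (p > 1L && substr(refseq, p - 1L, p - 1L) == d[len]) {
      d <- c(substr(refseq, p - 1L, p - 1L), d[-len])
      p <- p - 1L
    }
    list(pos = p, seq = paste(d, collapse = ""))
  }
}

## Plant SNPs and InDels on one contig. Counts are binomial in the full
## contig length; placement is uniform over the mutable interior (outside
## SSR tracts and contig edges).
plant_variants <- function(refseq, contig_length, tracts, snp_rate, indel_rate) {
  mask <- rep(TRUE, contig_length)
  mask[seq_len(min(EDGE_PAD, contig_length))] <- FALSE
  mask[max(1L, contig_length - EDGE_PAD + 1L):contig_length] <- FALSE
  for (i in seq_len(nrow(tracts))) {
    mask[max(1L, tracts$start[i] - TRACT_PAD):min(contig_length, tracts$end[i] + TRACT_PAD)] <- FALSE
  }
  ops <- list()
  taken <- integer(0)  # indel anchors, for spacing
  n_indel <- stats::rbinom(1, contig_length, indel_rate)
  cand <- which(mask)
  for (i in seq_len(n_indel)) {
    for (try in 1:50) {
      kind <- sample(c("ins", "del"), 1)
      len <- sample.int(10L, 1)
      p <- cand[sample.int(length(cand), 1)]
      span <- if (kind == "del") p:(p + len - 1L) else p
      ok <- max(span) <= contig_length && all(mask[span]) &&
        (!length(taken) || min(abs(taken - p)) > 25L)
      if (ok) {
        seq <- if (kind == "ins") random_dna(len) else substr(refseq, p, p + len - 1L)
        nrm <- left_align_event(refseq, kind, p, seq)
        ops[[length(ops) + 1L]] <- tibble(kind = kind, pos = nrm$pos,
                                          len = len, seq = nrm$seq)
        taken <- c(taken, p, nrm$pos)
        break
      }
    }
  }
  n_snp <- stats::rbinom(1, contig_length, snp_rate)
  snp_cand <- cand[!(cand %in% as.vector(outer(taken, -12:12, `+`)))]
  n_snp <- min(n_snp, length(snp_cand))
  pos <- sort(sample(snp_cand, n_snp))
  for (p in pos) {
    refb <- substr(refseq, p, p)
    ops[[length(ops) + 1L]] <- tibble(kind = "snp", pos = p, len = 1L,
                                      seq = sample(setdiff(DNA_BASES, refb), 1))
  }
  if (!length(ops)) {
    return(tibble(kind = character(), pos = integer(), len = integer(),
                  seq = character()))
  }
  dplyr::arrange(list_rbind(ops), .data$pos)
}

## Apply an edit script to a reference contig: returns the query sequence and
## a query->reference coordinate map (NA over inserted bases).
apply_edits <- function(refseq, ops) {
  L <- nchar(refseq)
  pieces <- character(0)
  maps <- list()
  cur <- 1L
  for (i in seq_len(nrow(ops))) {
    kind <- ops$kind[i]; p <- ops$pos[i]
    if (kind == "snp") {
      if (p > cur) {
        pieces <- c(pieces, substr(refseq, cur, p - 1L))
        maps[[length(maps) + 1L]] <- cur:(p - 1L)
      }
      pieces <- c(pieces, ops$seq[i])
      maps[[length(maps) + 1L]] <- p
      cur <- p + 1L
    } else if (kind == "ins") {
      pieces <- c(pieces, substr(refseq, cur, p), ops$seq[i])
      maps[[length(maps) + 1L]] <- cur:p
      maps[[length(maps) + 1L]] <- rep(NA_integer_, ops$len[i])
      cur <- p + 1L
    } else {  # del
      if (p > cur) {
        pieces <- c(pieces, substr(refseq, cur, p - 1L))
        maps[[length(maps) + 1L]] <- cur:(p - 1L)
      }
      cur <- p + ops$len[i]
    }
  }
  pieces <- c(pieces, substr(refseq, cur, L))
  maps[[length(maps) + 1L]] <- cur:L
  list(seq = paste(pieces, collapse = ""), qmap = unlist(maps))
}

## Expand the layout's exon-indexed spans into the package's standard
## gene-model tibble (exon + CDS rows; panel genes are fully coding).
genes_to_models <- function(layout) {
  dplyr::bind_rows(
    dplyr::transmute(layout, gene_id = .data$gene_id, contig = .data$contig,
                     strand = .data$strand, type = "exon",
                     start = .data$start, end = .data$end,
                     phase = NA_integer_),
    dplyr::transmute(layout, gene_id = .data$gene_id, contig = .data$contig,
                     strand = .data$strand, type = "CDS",
                     start = .data$start, end = .data$end,
                     phase = as.integer(.data$phase))) |>
    dplyr::arrange(.data$contig, .data$gene_id, .data$start, .data$type)
}

## VCF-style truth records (anchor-base representation) from an edit script.
ops_to_truth <- function(refseq, contig, genotype, ops) {
  if (!nrow(ops)) {
    return(tibble(genotype = character(), contig = character(),
                  pos = integer(), ref = character(), alt = character(),
                  type = character()))
  }
  rows <- pmap(ops, function(kind, pos, len, seq) {
    if (kind == "snp") {
      tibble(pos = pos, ref = substr(refseq, pos, pos), alt = seq, type = "SNP")
    } else if (kind == "ins") {
      a <- substr(refseq, pos, pos)
      tibble(pos = pos, ref = a, alt = paste0(a, seq), type = "insertion")
    } else {
      a <- substr(refseq, pos - 1L, pos - 1L)
      tibble(pos = pos - 1L, ref = paste0(a, seq), alt = a, type = "deletion")
    }
  })
  dplyr::mutate(list_rbind(rows), genotype = genotype, contig = contig,
                .before = 1)
}

#' Generate the synthetic three-genotype, multi-assay panel
#'
#' Builds a reference assembly (genotype G1) whose contigs are planted SSR
#' tracts separated by rejection-sampled spacer sequence guaranteed to carry
#' no SSR at detection thresholds, tiles gene models (with genuine start/stop
#' codons and valid CDS phases) across the contigs, and derives two query
#' assemblies (G2, G3) from explicit edit scripts of planted SNPs, InDels and
#' SSR repeat-number changes (+/-1..4 units). Every reference/query
#' difference is recorded in the machine-readable truth tables, including the
#' SSR repeat changes re-expressed as left-normalised InDels.
#'
#' @param config a [panel_config()].
#' @return an object of class `neem_panel`: a list with `config`,
#'   `reference` and `assemblies` ([Biostrings::DNAStringSet]s), `genes`
#'   (tibble of exon/CDS features), `edits` (per-genotype edit scripts and
#'   query-to-reference coordinate maps) and `truth`, a list with tibbles
#'   `ssr` (planted loci with per-genotype repeat counts), `variants`
#'   (VCF-style SNP/InDel records per genotype), `corr_genes` (gene ids
#'   planted to track the metabolite vector) and `metabolite` (per-tissue
#'   concentration, pg per microgram dry tissue).
#' @seealso [simulate_reads()], [simulate_expression()],
#'   [simulate_calibration()], [write_panel()]
#' @export
#' @examples
#' cfg <- panel_config(seed = 7, n_contigs = 1, contig_length = 12000,
#'                     n_genes = 6, n_ssr_planted = 12, n_ssr_polymorphic = 4)
#' panel <- generate_panel(cfg)
#' panel$truth$ssr
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  thresholds <- ssr_thresholds()
  contigs <- sprintf("contig_%02d", seq_len(config$n_contigs))
  ## distribute loci and genes across contigs
  m <- rep(config$n_ssr_planted %/% config$n_contigs, config$n_contigs)
  extra <- config$n_ssr_planted %% config$n_contigs
  if (extra > 0) m[seq_len(extra)] <- m[seq_len(extra)] + 1L
  ng <- rep(config$n_genes %/% config$n_contigs, config$n_contigs)
  extra <- config$n_genes %% config$n_contigs
  if (extra > 0) ng[seq_len(extra)] <- ng[seq_len(extra)] + 1L

  panel <- with_seed_(derive_seed(config$seed, 11), {
    ssr_rows <- list()
    gene_rows <- list()
    seqs <- character(config$n_contigs)
    for (ci in seq_len(config$n_contigs)) {
      mi <- m[ci]
      ## plant SSR loci
      k <- sample(1:6, mi, replace = TRUE, prob = SSR_UNIT_WEIGHTS)
      motif <- vapply(k, sample_primitive_motif, character(1))
      copies <- thresholds$min_repeats[k] + sample(0:6, mi, replace = TRUE)
      tract <- strrep(motif, copies)
      tract_len <- nchar(tract)
      total_spacer <- config$contig_length - sum(tract_len)
      w <- stats::runif(mi + 1L, 0.8, 1.2)
      sp_len <- pmax(MIN_SPACER, as.integer(floor(total_spacer * w / sum(w))))
      sp_len[mi + 1L] <- total_spacer - sum(sp_len[seq_len(mi)])
      assert_that_(sp_len[mi + 1L] >= MIN_SPACER,
                   "contig too short for the requested SSR load")
      tr_start <- cumsum(sp_len[seq_len(mi)] + c(0L, tract_len[-mi])) + 1L
      tr_end <- tr_start + tract_len - 1L
      tracts <- tibble(start = tr_start, end = tr_end)
      ## gene models, then the codon rewrites they impose on the spacers
      genes <- layout_genes(contigs[ci], config$contig_length, ng[ci], tracts,
                            id_offset = (ci - 1L) * max(ng) * 2L)
      rw <- codon_rewrites(genes)
      ## sample spacers left to right
      sp <- character(mi + 1L)
      for (si in seq_len(mi + 1L)) {
        sp_start <- if (si == 1L) 1L else tr_end[si - 1L] + 1L
        ## full adjacent tracts as context: any run that crosses a junction
        ## (including a phase-shifted extension of the tract's own motif)
        ## then overlaps the spacer and forces a resample
        left_ctx <- if (si == 1L) "" else tract[si - 1L]
        right_ctx <- if (si > mi) "" else tract[si]
        local_rw <- rw[rw$pos >= sp_start & rw$pos <= sp_start + sp_len[si] - 1L, ]
        sp[si] <- sample_spacer(sp_len[si], left_ctx, right_ctx,
                                tibble(at = local_rw$pos - sp_start + 1L,
                                       base = local_rw$base), thresholds)
      }
      seqs[ci] <- paste0(paste0(sp[seq_len(mi)], tract, collapse = ""), sp[mi + 1L])
      ssr_rows[[ci]] <- tibble(contig = contigs[ci], start = tr_start,
                               end = tr_end, motif = motif,
                               class = canonical_class(motif),
                               unit_length = nchar(motif),
                               repeat_count = copies)
      gene_rows[[ci]] <- genes
    }
    list(seqs = stats::setNames(seqs, contigs),
         ssr = list_rbind(ssr_rows), genes = list_rbind(gene_rows))
  })

  ssr_truth <- panel$ssr
  genotypes <- c("G2", "G3")
  edits <- list()
  variant_rows <- list()
  for (gi in seq_along(genotypes)) {
    g <- genotypes[gi]
    res <- with_seed_(derive_seed(config$seed, 100 + gi), {
      poly_idx <- if (config$n_ssr_polymorphic > 0) {
        sort(sample.int(nrow(ssr_truth), config$n_ssr_polymorphic))
      } else integer(0)
      delta <- integer(nrow(ssr_truth))
      for (i in poly_idx) {
        repeat {
          d <- sample(c(-4:-1, 1:4), 1)
          if (ssr_truth$repeat_count[i] + d >= 2L) break
        }
        delta[i] <- d
      }
      per_contig <- map(seq_len(config$n_contigs), function(ci) {
        refseq <- panel$seqs[[ci]]
        tr <- ssr_truth[ssr_truth$contig == contigs[ci], ]
        d <- delta[ssr_truth$contig == contigs[ci]]
        ops <- plant_variants(refseq, config$contig_length, tr,
                              config$snp_rate, config$indel_rate)
        ## SSR repeat changes as insertion/deletion ops at the tract end
        ssr_ops <- list()
        for (j in which(d != 0L)) {
          dk <- abs(d[j]) * tr$unit_length[j]
          if (d[j] > 0) {
            nrm <- left_align_event(refseq, "ins", tr$end[j],
                                    strrep(tr$motif[j], d[j]))
            ssr_ops[[length(ssr_ops) + 1L]] <-
              tibble(kind = "ins", pos = nrm$pos, len = dk, seq = nrm$seq)
          } else {
            p <- tr$end[j] - dk + 1L
            nrm <- left_align_event(refseq, "del", p, substr(refseq, p, tr$end[j]))
            ssr_ops[[length(ssr_ops) + 1L]] <-
              tibble(kind = "del", pos = nrm$pos, len = dk, seq = nrm$seq)
          }
        }
        ops <- dplyr::arrange(dplyr::bind_rows(ops, ssr_ops), .data$pos)
        built <- apply_edits(refseq, ops)
        list(ops = ops, seq = built$seq, qmap = built$qmap,
             truth = ops_to_truth(refseq, contigs[ci], g, ops))
      })
      list(delta = delta, per_contig = per_contig)
    })
    ssr_truth[[paste0("repeat_", g)]] <- ssr_truth$repeat_count + res$delta
    edits[[g]] <- stats::setNames(res$per_contig, contigs)
    variant_rows[[g]] <- list_rbind(map(res$per_contig, "truth"))
  }
  names(ssr_truth)[names(ssr_truth) == "repeat_count"] <- "repeat_G1"

  corr_meta <- with_seed_(derive_seed(config$seed, 37), {
    gene_ids <- unique(panel$genes$gene_id)
    corr <- sample(gene_ids, config$n_corr_genes)
    list(corr = corr,
         metab = tibble(tissue = config$tissues,
                        concentration = default_metabolite(config$tissues)))
  })

  reference <- Biostrings::DNAStringSet(panel$seqs)
  assemblies <- list(
    G1 = reference,
    G2 = Biostrings::DNAStringSet(stats::setNames(
      map_chr(edits$G2, "seq"), contigs)),
    G3 = Biostrings::DNAStringSet(stats::setNames(
      map_chr(edits$G3, "seq"), contigs)))
  structure(list(
    config = config, reference = reference, assemblies = assemblies,
    genes = genes_to_models(panel$genes), edits = edits,
    truth = list(ssr = ssr_truth,
                 variants = list_rbind(variant_rows),
                 corr_genes = corr_meta$corr,
                 metabolite = corr_meta$metab)),
    class = "neem_panel")
}

#' @export
print.neem_panel <- function(x, ...) {
  cat("<neem_panel>\n")
  cat(sprintf("  genotypes: %s\n", paste(names(x$assemblies), collapse = ", ")))
  cat(sprintf("  %d contigs, %d planted SSRs, %d gene models\n",
              length(x$reference), nrow(x$truth$ssr),
              dplyr::n_distinct(x$genes$gene_id)))
  cat(sprintf("  %d truth variants (%s)\n", nrow(x$truth$variants),
              paste(sprintf("%s: %d", names(table(x$truth$variants$genotype)),
                            table(x$truth$variants$genotype)), collapse = ", ")))
  invisible(x)
}

#' Write a panel to disk in standard formats
#'
#' Emits per-genotype assemblies (FASTA), gene models (GFF3, 1-based
#' inclusive), and the truth tables (TSV) into `dir`.
#'
#' @param panel a `neem_panel` from [generate_panel()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "neem_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in names(panel$assemblies)) {
    Biostrings::writeXStringSet(panel$assemblies[[g]],
                                file.path(dir, paste0(g, ".fa")))
  }
  write_gff3(panel$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(panel$truth$ssr, file.path(dir, "truth_ssr.tsv"))
  readr::write_tsv(panel$truth$variants, file.path(dir, "truth_variants.tsv"))
  readr::write_tsv(panel$truth$metabolite, file.path(dir, "truth_metabolite.tsv"))
  readr::write_lines(panel$truth$corr_genes, file.path(dir, "truth_corr_genes.txt"))
  invisible(dir)
}
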
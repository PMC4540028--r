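# Synthetic panel generator: determinism, truth closure, planted structure.

test_that("zero-mutation configuration reproduces the reference byte for byte", {
  cfg <- panel_config(seed = 3, n_contigs = 1, contig_length = 20000,
                      n_genes = 5, n_ssr_planted = 15, n_ssr_polymorphic = 0,
                      snp_rate = 0, indel_rate = 0, n_corr_genes = 5)
  p <- generate_panel(cfg)
  expect_identical(as.character(p$assemblies$G2), as.character(p$reference))
  expect_identical(as.character(p$assemblies$G3), as.character(p$reference))
  expect_equal(nrow(p$truth$variants), 0)
})

test_that("generation is deterministic in the seed", {
  cfg <- panel_config(seed = 9, n_contigs = 1, contig_length = 20000,
                      n_genes = 6, n_ssr_planted = 15, n_ssr_polymorphic = 5,
                      n_corr_genes = 6)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(as.character(a$assemblies$G2), as.character(b$assemblies$G2))
  expect_identical(a$truth$variants, b$truth$variants)
  expect_identical(a$truth$ssr, b$truth$ssr)
  c <- generate_panel(panel_config(seed = 10, n_contigs = 1,
                                   contig_length = 20000, n_genes = 6,
                                   n_ssr_planted = 15, n_ssr_polymorphic = 5,
                                   n_corr_genes = 6))
  expect_false(identical(as.character(a$reference), as.character(c$reference)))
})

test_that("undersized contigs are rejected with the sizing constraint named", {
  expect_error(panel_config(n_contigs = 1, contig_length = 5000,
                            n_ssr_planted = 100),
               "too short")
})

test_that("planted SNP counts fall in the central binomial interval", {
  p <- small_panel()
  L <- 2 * 30000
  for (g in c("G2", "G3")) {
    n <- sum(p$truth$variants$genotype == g & p$truth$variants$type == "SNP")
    lim <- qbinom(c(0.005, 0.995), L, 0.003)
    expect_gte(n, lim[1])
    expect_lte(n, lim[2])
  }
})

test_that("truth closure: reference plus truth records rebuilds each query exactly", {
  p <- small_panel()
  for (g in c("G2", "G3")) {
    for (ctg in names(p$reference)) {
      tv <- p$truth$variants[p$truth$variants$genotype == g &
                               p$truth$variants$contig == ctg, ]
      rebuilt <- reconstruct_from_truth(as.character(p$reference[[ctg]]), tv)
      expect_identical(rebuilt, as.character(p$assemblies[[g]][[ctg]]))
    }
  }
})

test_that("planted SSR truth equals what the detector sees on the reference", {
  p <- small_panel()
  det <- scan_ssrs(p$reference)
  tr <- p$truth$ssr
  expect_setequal(paste(det$contig, det$start, det$end, det$motif),
                  paste(tr$contig, tr$start, tr$end, tr$motif))
  expect_false(any(det$compound))
})

test_that("polymorphic SSR truth has >= 2 distinct repeat counts across genotypes", {
  p <- small_panel()
  tr <- p$truth$ssr
  poly <- tr[tr$repeat_G2 != tr$repeat_G1 | tr$repeat_G3 != tr$repeat_G1, ]
  expect_gt(nrow(poly), 0)
  n_distinct <- apply(poly[, c("repeat_G1", "repeat_G2", "repeat_G3")], 1,
                      function(x) length(unique(x)))
  expect_true(all(n_distinct >= 2))
  expect_true(all(tr[, c("repeat_G1", "repeat_G2", "repeat_G3")] >= 2))
})

test_that("gene models have valid phases, start and stop codons", {
  p <- small_panel()
  cds <- p$genes[p$genes$type == "CDS", ]
  for (gid in unique(cds$gene_id)) {
    g <- cds[cds$gene_id == gid, ]
    g <- g[order(g$start), ]
    total <- sum(g$end - g$start + 1)
    expect_equal(total %% 3, 0)
    seqs <- paste(substring(as.character(p$reference[[g$contig[1]]]),
                            g$start, g$end), collapse = "")
    if (g$strand[1] == "-") {
      seqs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs)))
    }
    expect_equal(substr(seqs, 1, 3), "ATG")
    expect_equal(substr(seqs, total - 2, total), "TAA")
    ord <- if (g$strand[1] == "+") seq_len(nrow(g)) else rev(seq_len(nrow(g)))
    cum <- 0
    for (j in ord) {
      expect_equal(g$phase[j], (3 - (cum %% 3)) %% 3)
      cum <- cum + g$end[j] - g$start[j] + 1
    }
  }
})

test_that("panel files round-trip through the standard formats", {
  p <- small_panel()
  dir <- withr::local_tempdir()
  write_panel(p, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "G2.fa"))
  expect_identical(as.character(fa), as.character(p$assemblies$G2))
  models <- read_gff3(file.path(dir, "genes.gff3"))
  expect_setequal(unique(models$gene_id), unique(p$genes$gene_id))
  got <- dplyr::arrange(models[models$type == "CDS",
                               c("gene_id", "contig", "strand", "start", "end", "phase")],
                        contig, gene_id, start)
  want <- dplyr::arrange(p$genes[p$genes$type == "CDS",
                                 c("gene_id", "contig", "strand", "start", "end", "phase")],
                         contig, gene_id, start)
  expect_equal(as.data.frame(got), as.data.frame(want))
})
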
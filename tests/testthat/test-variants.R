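# Pileup variant calling, filters, annotation and density arithmetic.

# tiny hand-built alignment set: n reads covering a 60-base reference
toy_aln <- function(n, seq_fun, pos = 1L, cigar = "60M") {
  tibble::tibble(qname = sprintf("r%03d", seq_len(n)), flag = 0L,
                 rname = "c", pos = pos, mapq = 60L, cigar = cigar,
                 seq = vapply(seq_len(n), seq_fun, character(1)),
                 qual = strrep("I", 60))
}

test_that("reads agreeing with the reference yield zero calls", {
  ref <- c(c = random_dna_str(60))
  aln <- toy_aln(20, function(i) ref[["c"]])
  expect_equal(nrow(pileup_call(aln, ref)), 0)
})

test_that("a homozygous substitution is called pass with alt fraction 1", {
  withr::with_seed(1, {
    ref <- c(c = random_dna_str(60))
    alt <- ref[["c"]]
    old <- substr(alt, 30, 30)
    substr(alt, 30, 30) <- setdiff(c("A", "C", "G", "T"), old)[1]
    calls <- pileup_call(toy_aln(30, function(i) alt), ref)
    expect_equal(nrow(calls), 1)
    expect_equal(calls$position, 30)
    expect_equal(calls$type, "SNP")
    expect_equal(calls$alt_fraction, 1)
    expect_equal(calls$filter, "pass")
    expect_gt(calls$qual, 30)
    # depth 9 fails the depth filter but is still reported
    low <- pileup_call(toy_aln(9, function(i) alt), ref)
    expect_equal(low$filter, "low_depth")
  })
})

test_that("insertions and deletions are taken from gap operations and left-aligned", {
  # reference with a homopolymer so left-alignment is observable
  ref <- c(c = paste0("GATTACA", strrep("A", 6), "CTGCTGACGTTACGGATCCAT",
                      "GGGCCCAAATTT", random_dna_str(14)))
  stopifnot(nchar(ref) == 60)
  q <- ref[["c"]]
  # delete one A from the run (positions 8-13): represent as D at position 11
  del_seq <- paste0(substr(q, 1, 10), substr(q, 12, 60))
  aln <- tibble::tibble(qname = sprintf("r%d", 1:20), flag = 0L, rname = "c",
                        pos = 1L, mapq = 60L, cigar = "10M1D49M",
                        seq = del_seq, qual = strrep("I", 59))
  calls <- pileup_call(aln, ref)
  expect_equal(calls$type, "deletion")
  # the A-run starts at position 7 (GATTACA ends in A); leftmost anchor is 6
  expect_equal(calls$position, 6)
  expect_equal(calls$ref_allele, unname(substr(ref, 6, 7)))
  expect_equal(calls$alt_allele, unname(substr(ref, 6, 6)))
  expect_equal(calls$alt_fraction, 1)

  ins_seq <- paste0(substr(q, 1, 10), "A", substr(q, 11, 59))
  aln2 <- tibble::tibble(qname = sprintf("r%d", 1:20), flag = 0L, rname = "c",
                         pos = 1L, mapq = 60L, cigar = "10M1I49M",
                         seq = ins_seq, qual = strrep("I", 60))
  calls2 <- pileup_call(aln2, ref)
  expect_equal(calls2$type, "insertion")
  expect_equal(calls2$position, 6)
})

test_that("input validation: unknown contigs error, malformed CIGARs are skipped", {
  ref <- c(c = random_dna_str(60))
  aln <- toy_aln(5, function(i) ref[["c"]])
  bad <- aln
  bad$rname <- "nope"
  expect_error(pileup_call(bad, ref), "unknown contig")
  bad2 <- aln
  bad2$cigar[1] <- "60Q"
  expect_warning(pileup_call(bad2, ref), "malformed CIGAR")
})

test_that("raising thresholds never increases pass-filter calls", {
  p <- small_panel()
  reads <- simulate_reads(p, "G2", coverage = 12)
  base <- pileup_call(reads, p$reference)
  n_base <- sum(base$filter == "pass")
  for (md in c(12, 15, 20)) {
    n <- sum(pileup_call(reads, p$reference, min_depth = md)$filter == "pass")
    expect_lte(n, n_base)
    n_base2 <- n
  }
  nq <- sum(pileup_call(reads, p$reference, min_qual = 200)$filter == "pass")
  expect_lte(nq, n_base)
})

test_that("coding effects match the codon table on hand-built models", {
  # one forward gene: ATG GCT TGG TAA  (Met Ala Trp Stop)
  ref <- c(c = paste0("GGGGG", "ATGGCTTGGTAA", "GGGGGGG"))
  models <- tibble::tibble(
    gene_id = "g1", contig = "c", strand = "+",
    type = rep(c("exon", "CDS"), each = 1),
    start = 6L, end = 17L, phase = c(NA, 0L))
  snp <- function(pos, alt) tibble::tibble(
    contig = "c", position = pos, ref_allele = substr(ref, pos, pos),
    alt_allele = alt, type = "SNP", depth = 30L, alt_count = 30L,
    alt_fraction = 1, qual = 600, filter = "pass")
  # GCT (genomic 9-11) -> GCC: Ala/Ala
  ann <- annotate_variants(snp(11L, "C"), models, ref)
  expect_equal(ann$coding_effect, "synonymous")
  # TGG (genomic 12-14) -> TGA: premature stop
  ann2 <- annotate_variants(snp(14L, "A"), models, ref)
  expect_equal(ann2$coding_effect, "stop_gained")
  # ATG -> GTG start lost (genomic 6)
  ann3 <- annotate_variants(snp(6L, "G"), models, ref)
  expect_equal(ann3$coding_effect, "start_lost")
  # TAA -> CAA stop lost (genomic 15+... stop codon at 15:17 -> pos 15)
  ann4 <- annotate_variants(snp(15L, "C"), models, ref)
  expect_equal(ann4$coding_effect, "stop_lost")
})

test_that("region classes follow the exonic > intronic > flank > intergenic priority", {
  ref <- c(c = random_dna_str(30000))
  models <- tibble::tibble(
    gene_id = "g1", contig = "c", strand = "-",
    type = c("exon", "exon", "CDS", "CDS"),
    start = c(10000L, 10500L, 10000L, 10500L),
    end = c(10299L, 10799L, 10299L, 10799L),
    phase = c(NA, NA, 0L, 0L))
  mk <- function(pos) tibble::tibble(
    contig = "c", position = pos, ref_allele = "A", alt_allele = "G",
    type = "SNP", depth = 30L, alt_count = 30L, alt_fraction = 1,
    qual = 600, filter = "pass")
  cls <- function(pos) annotate_variants(mk(pos), models, ref)$region_class
  expect_equal(cls(10100L), "exonic")
  expect_equal(cls(10400L), "intronic")
  # strand is "-": upstream lies beyond the gene end, downstream before start
  expect_equal(cls(11000L), "upstream")
  expect_equal(cls(9000L), "downstream")
  expect_equal(cls(25000L), "intergenic")
})

test_that("a CDS not divisible by three is reported once and skipped", {
  ref <- c(c = paste0("GGGGG", "ATGGCTTGGTA", "AGGGGGGG"))
  models <- tibble::tibble(gene_id = "g1", contig = "c", strand = "+",
                           type = c("exon", "CDS"), start = 6L, end = 16L,
                           phase = c(NA, 0L))
  call <- tibble::tibble(contig = "c", position = 13L, ref_allele = "T",
                         alt_allele = "C", type = "SNP", depth = 30L,
                         alt_count = 30L, alt_fraction = 1, qual = 600,
                         filter = "pass")
  expect_warning(ann <- annotate_variants(call, models, ref),
                 "not divisible by 3")
  expect_equal(ann$coding_effect, "none")
})

test_that("effect summaries normalise within each axis", {
  p <- small_panel()
  reads <- simulate_reads(p, "G2", coverage = 12)
  calls <- annotate_variants(pileup_call(reads, p$reference), p$genes,
                             p$reference)
  sm <- summarize_effects(calls)
  expect_equal(sum(sm$by_region$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(sm$by_effect$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(sm$by_region$n), nrow(calls))
  empty <- summarize_effects(calls[0, ])
  expect_equal(nrow(empty$by_region), 0)
})

test_that("marker densities reproduce the published per-kb arithmetic", {
  snp <- marker_density(c(G2 = 698173, G3 = 860215), 267e6)
  expect_equal(snp$density_reported[snp$genotype == "mean"], 2.9)
  ind <- marker_density(c(G2 = 53508, G3 = 66171), 267e6)
  expect_equal(ind$density_reported[ind$genotype == "mean"], 0.22)
  z <- marker_density(c(g = 0), 1e6)
  expect_equal(z$density, c(0, 0))
  expect_error(marker_density(numeric(0), 1e6), "non-empty")
  expect_error(marker_density(c(1), 0), "> 0")
})

test_that("ortholog arithmetic matches the published shared/unique split", {
  o <- ortholog_summary(44495, 27498, 24216)
  expect_equal(o$n_without_orthologs, 16997)
  expect_equal(o$pct_shared, 54.42)
})
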
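# Flank-anchored cross-genotype SSR polymorphism calling.

# a tiny two-locus assembly built by hand
toy_assembly <- function(seed = 21) {
  withr::with_seed(seed, {
    sp <- replicate(3, random_dna_str(150))
    list(seq = c(c1 = paste0(sp[1], strrep("AT", 8), sp[2],
                             strrep("AAG", 7), sp[3])),
         spacers = sp)
  })
}

test_that("regions carry 100 bp flanks and truncation flags", {
  toy <- toy_assembly()
  loci <- scan_ssrs(toy$seq)
  reg <- extract_ssr_regions(toy$seq, loci)
  expect_true(all(nchar(reg$left_flank) == 100))
  expect_true(all(nchar(reg$right_flank) == 100))
  expect_false(any(reg$flank_truncated))
  # locus at the very start of a contig: empty left flank, truncated
  edge <- c(c1 = paste0(strrep("AT", 8), random_dna_str(200)))
  lo <- scan_ssrs(edge)
  r2 <- extract_ssr_regions(edge, lo)
  expect_equal(nchar(r2$left_flank), 0)
  expect_true(r2$flank_truncated)
  bad <- loci
  bad$end <- bad$end + 10000L
  expect_error(extract_ssr_regions(toy$seq, bad), "out of contig bounds")
})

test_that("self-mapping recovers every locus exactly with zero mismatches", {
  p <- small_panel()
  loci <- scan_ssrs(p$reference)
  calls <- ssr_polymorphism(p$reference, p$reference, loci = loci)
  ok <- calls[!calls$flank_truncated & !calls$compound, ]
  expect_true(all(ok$unique))
  expect_true(all(ok$left_mismatch == 0 & ok$right_mismatch == 0))
  expect_true(all(ok$inter_flank_span == ok$end - ok$start + 1))
  expect_true(all(ok$status == "monomorphic"))
  expect_equal(sum(calls$status == "polymorphic"), 0)
})

test_that("a duplicated flank makes placement ambiguous and blocks the call", {
  toy <- toy_assembly()
  loci <- scan_ssrs(toy$seq)
  reg <- extract_ssr_regions(toy$seq, loci)
  # query duplicates the whole first region -> both flanks multi-hit
  dup <- c(q1 = paste0(toy$seq[[1]], substr(toy$seq[[1]], 1, 480)))
  m <- match_ssr_regions(reg[1, ], dup)
  expect_true(m$matched)
  expect_false(m$unique)
  calls <- call_ssr_polymorphism(m)
  expect_equal(calls$status, "unresolved")
})

test_that("repeat-number changes shift the inter-flank span by the unit arithmetic", {
  toy <- toy_assembly()
  loci <- scan_ssrs(toy$seq)
  reg <- extract_ssr_regions(toy$seq, loci)
  at <- reg[reg$motif == "AT", ]
  # +2 AT units planted in the query
  q <- c(c1 = sub(strrep("AT", 8), strrep("AT", 10), toy$seq[[1]], fixed = TRUE))
  m <- match_ssr_regions(at, q)
  expect_true(m$unique)
  expect_equal(m$inter_flank_span, (at$end - at$start + 1) + 4)
  calls <- call_ssr_polymorphism(m)
  expect_equal(calls$status, "polymorphic")
  expect_equal(calls$query_repeat_count, 10L)
  expect_equal(calls$ref_repeat_count, 8L)
})

test_that("a deleted locus is reported absent and polymorphic", {
  toy <- toy_assembly()
  loci <- scan_ssrs(toy$seq)
  reg <- extract_ssr_regions(toy$seq, loci)
  at <- reg[reg$motif == "AT", ]
  q <- c(c1 = sub(strrep("AT", 8), "", toy$seq[[1]], fixed = TRUE))
  calls <- call_ssr_polymorphism(match_ssr_regions(at, q))
  expect_equal(calls$query_class, "absent")
  expect_equal(calls$status, "polymorphic")
})

test_that("loci are found on the reverse strand of a rearranged query", {
  toy <- toy_assembly()
  loci <- scan_ssrs(toy$seq)
  reg <- extract_ssr_regions(toy$seq, loci)
  q <- c(c1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toy$seq[[1]]))))
  calls <- call_ssr_polymorphism(match_ssr_regions(reg, q))
  expect_true(all(calls$orientation == "reverse"))
  expect_true(all(calls$status == "monomorphic"))
  expect_equal(calls$query_repeat_count, calls$ref_repeat_count)
})

test_that("an N in the inter-flank sequence leaves the locus unresolved", {
  toy <- toy_assembly()
  loci <- scan_ssrs(toy$seq)
  reg <- extract_ssr_regions(toy$seq, loci)
  at <- reg[reg$motif == "AT", ]
  q <- c(c1 = sub(strrep("AT", 8), paste0(strrep("AT", 4), "NN", strrep("AT", 4)),
                  toy$seq[[1]], fixed = TRUE))
  calls <- call_ssr_polymorphism(match_ssr_regions(at, q))
  expect_equal(calls$status, "unresolved")
})

test_that("swapping reference and query preserves status and flips the count difference", {
  toy <- toy_assembly()
  q <- c(c1 = sub(strrep("AT", 8), strrep("AT", 10), toy$seq[[1]], fixed = TRUE))
  fwd <- ssr_polymorphism(toy$seq, q)
  bwd <- ssr_polymorphism(q, toy$seq)
  f <- fwd[fwd$motif == "AT", ]
  b <- bwd[bwd$motif == "AT", ]
  expect_equal(f$status, "polymorphic")
  expect_equal(b$status, "polymorphic")
  expect_equal(f$query_repeat_count - f$ref_repeat_count,
               -(b$query_repeat_count - b$ref_repeat_count))
  expect_equal(fwd[fwd$motif == "AAG", ]$status, "monomorphic")
  expect_equal(bwd[bwd$motif == "AAG", ]$status, "monomorphic")
})

test_that("the concordance shortlist is the intersection of polymorphic calls", {
  p <- small_panel()
  loci <- scan_ssrs(p$reference)
  c2 <- ssr_polymorphism(p$reference, p$assemblies$G2, loci = loci)
  c3 <- ssr_polymorphism(p$reference, p$assemblies$G3, loci = loci)
  sl <- concordant_polymorphic(c2, c3)
  k2 <- locus_key(c2[c2$status == "polymorphic", ])
  k3 <- locus_key(c3[c3$status == "polymorphic", ])
  expect_setequal(locus_key(sl), intersect(k2, k3))
  # subset property
  expect_true(all(locus_key(sl) %in% k2))
  expect_true(all(locus_key(sl) %in% k3))
  # intersection with an empty call set is empty
  empty <- c3[c3$status == "monomorphic" & FALSE, ]
  expect_equal(nrow(concordant_polymorphic(c2, c2[0, ])), 0)
  # differing reference locus lists are rejected
  expect_error(concordant_polymorphic(c2, c3[-1, ]),
               "reference locus list")
  # sorted by contig then start
  expect_false(is.unsorted(order(sl$contig, sl$start)))
})
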
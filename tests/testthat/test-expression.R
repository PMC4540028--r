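# RPKM, tissue partitioning, the metabolite correlation screen, and ddCt.

mini_cfg <- function(...) {
  panel_config(seed = 5, n_contigs = 1, contig_length = 20000, n_genes = 120,
               n_ssr_planted = 10, n_ssr_polymorphic = 0, n_corr_genes = 20, ...)
}

test_that("rpkm applies the reads-per-kilobase-per-million formula", {
  counts <- tibble::tibble(gene_id = "g1", length = 1000, leaf = 1000)
  m <- rpkm(counts, totals = c(leaf = 1e6))
  expect_equal(m$leaf, 1000)
  # doubling counts and totals leaves RPKM unchanged
  c2 <- tibble::tibble(gene_id = c("a", "b"), length = c(500, 2000),
                       leaf = c(10, 40), root = c(5, 80))
  m1 <- rpkm(c2)
  c3 <- dplyr::mutate(c2, leaf = leaf * 2, root = root * 2)
  m2 <- rpkm(c3)
  expect_equal(m1$leaf, m2$leaf)
  expect_equal(m1$root, m2$root)
  # random matrix equals the direct per-cell computation
  withr::with_seed(2, {
    cc <- tibble::tibble(gene_id = paste0("g", 1:30),
                         length = sample(200:3000, 30),
                         t1 = runif(30, 0, 500), t2 = runif(30, 0, 500))
    mm <- rpkm(cc)
    expect_equal(mm$t1, cc$t1 * 1e9 / (cc$length * sum(cc$t1)))
    expect_equal(mm$t2, cc$t2 * 1e9 / (cc$length * sum(cc$t2)))
  })
  expect_error(rpkm(dplyr::select(counts, -length)), "length")
  expect_error(rpkm(counts, gene_lengths = c(gX = 100)), "no length")
})

test_that("expression summaries are monotone in the threshold", {
  sim <- simulate_expression(mini_cfg())
  mat <- rpkm(sim$counts)
  sm <- expression_summary(mat)
  wide <- tidyr::pivot_wider(sm, names_from = threshold, values_from = n_genes)
  expect_true(all(wide$`1` >= wide$`5` & wide$`5` >= wide$`10`))
  zero <- mat
  zero[setdiff(names(zero), c("gene_id", "length"))] <- 0
  expect_true(all(expression_summary(zero)$n_genes == 0))
})

test_that("tissue partition separates ubiquitous and tissue-specific genes", {
  mat <- tibble::tibble(gene_id = c("ubi", "spec", "off", "mid"),
                        length = 1000,
                        t1 = c(2, 3, 0, 2), t2 = c(5, 0, 0, 0),
                        t3 = c(2, 0, 0, 3))
  pt <- tissue_partition(mat)
  expect_equal(pt$category, c("ubiquitous", "tissue_specific", "other", "other"))
  expect_error(tissue_partition(mat[, 1:3]), ">= 2 tissues")
})

test_that("correlations match direct computation and flag undefined cases", {
  withr::with_seed(3, {
    mat <- tibble::tibble(gene_id = paste0("g", 1:20), length = 1000)
    for (t in paste0("t", 1:7)) mat[[t]] <- runif(20, 0, 100)
    prof <- tibble::tibble(tissue = paste0("t", 1:7),
                           concentration = runif(7, 1, 50))
    r <- metabolite_correlation(mat, prof)
    direct <- apply(as.matrix(mat[paste0("t", 1:7)]), 1,
                    function(x) cor(x, prof$concentration))
    expect_equal(r$r, unname(direct), tolerance = 1e-12)
    expect_true(all(r$r >= -1 & r$r <= 1))
    # perfectly tracking and anti-tracking genes
    mat$t1 <- NULL  # rebuild with exact profiles
    mat2 <- tibble::tibble(gene_id = c("pos", "neg", "flat"), length = 1000)
    for (i in 1:7) {
      mat2[[paste0("t", i)]] <- c(prof$concentration[i] * 3,
                                  100 - prof$concentration[i], 5)
    }
    r2 <- metabolite_correlation(mat2, prof)
    expect_equal(r2$r[1:2], c(1, -1), tolerance = 1e-12)
    expect_true(r2$undefined[3])
    expect_true(is.na(r2$r[3]))
    # constant metabolite vector: flagged, not an error
    flatprof <- dplyr::mutate(prof, concentration = 4)
    expect_warning(r3 <- metabolite_correlation(mat2, flatprof), "zero variance")
    expect_true(all(r3$undefined))
    # mismatched tissue sets name the difference
    expect_error(metabolite_correlation(mat2, prof[-1, ]), "t1")
  })
})

test_that("screen tiers use inclusive thresholds and the tissue contrast", {
  prof <- tibble::tibble(tissue = c("developing_endosperm", "mature_leaf", "t3"),
                         concentration = c(100, 1, 10))
  mat <- tibble::tibble(gene_id = "exact08", length = 1000,
                        developing_endosperm = 0, mature_leaf = 0, t3 = 0)
  # construct a profile with r exactly 0.8 against prof via projection
  x <- prof$concentration
  xc <- x - mean(x)
  y <- 0.8 * xc / sqrt(sum(xc^2))
  resid <- c(1, 1, -2)
  resid <- resid - mean(resid)
  resid <- resid - sum(resid * xc) / sum(xc^2) * xc
  y <- y + sqrt(1 - 0.8^2) * resid / sqrt(sum(resid^2))
  v <- y + 1  # shift positive; Pearson is location-invariant
  stopifnot(abs(cor(v, x) - 0.8) < 1e-12)
  mat[1, c("developing_endosperm", "mature_leaf", "t3")] <- as.list(v)
  sc <- candidate_screen(mat, prof)
  expect_equal(sc$tier, "r08")  # inclusive at the 0.8 boundary
  expect_equal(nrow(candidate_screen(mat[0, ], prof)), 0)
  expect_error(candidate_screen(mat, prof, contrast = c("nope", "mature_leaf")),
               "nope")
})

test_that("noise-free planted genes correlate perfectly and all reach tier r09", {
  cfg <- mini_cfg(expression_noise_cv = 0)
  sim <- simulate_expression(cfg)
  mat <- rpkm(sim$counts)
  sc <- candidate_screen(mat, sim$metabolite)
  planted <- sc[sc$gene_id %in% sim$corr_genes, ]
  expect_true(all(abs(planted$r - 1) < 1e-9))
  expect_true(all(planted$tier == "r09"))
})

test_that("simulated expression conserves library sizes and is deterministic", {
  cfg <- mini_cfg()
  sim <- simulate_expression(cfg)
  tissues <- cfg$tissues
  expect_equal(colSums(as.matrix(sim$counts[tissues])), 
               stats::setNames(sim$totals$total, tissues))
  sim2 <- simulate_expression(cfg)
  expect_identical(sim$counts, sim2$counts)
})

test_that("ddCt fold changes follow 2^-ddCt with replicate averaging", {
  ct <- tibble::tibble(sample = c("cal", "s1", "s2"),
                       ct_target = c(25, 24, 25 + 3.32),
                       ct_reference = c(20, 20, 20))
  f <- ddct_fold_change(ct, "cal")
  expect_equal(f$fold_change[f$sample == "cal"], 1)
  expect_equal(f$fold_change[f$sample == "s1"], 2)
  expect_equal(f$fold_change[f$sample == "s2"], 2^-3.32, tolerance = 1e-12)
  # replicates averaged on the Ct scale
  ct2 <- dplyr::bind_rows(ct, tibble::tibble(sample = "s1", ct_target = 22,
                                             ct_reference = 20))
  f2 <- ddct_fold_change(ct2, "cal")
  expect_equal(f2$fold_change[f2$sample == "s1"], 2^-(23 - 25))
  expect_error(ddct_fold_change(dplyr::mutate(ct, ct_reference = NA), "cal"),
               "non-finite")
  expect_error(ddct_fold_change(ct, "nope"), "calibrator")
})

test_that("tissue clustering returns a dendrogram over tissues", {
  sim <- simulate_expression(mini_cfg())
  hc <- cluster_tissues(rpkm(sim$counts))
  expect_s3_class(hc, "hclust")
  expect_setequal(hc$labels, mini_cfg()$tissues)
})
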
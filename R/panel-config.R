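#' Configuration for the synthetic multi-genotype panel
#'
#' Describes the full study design emulated by [generate_panel()]: a
#' reference genotype (G1) plus two query genotypes (G2, G3) derived from it
#' by planted SSR repeat-number changes, SNPs and small InDels; simulated
#' short reads; a multi-tissue expression matrix with a planted set of genes
#' tracking a planted metabolite concentration vector; and two-fold dilution
#' calibration standards. All randomness derives from `seed`.
#'
#' Defaults mirror the emulated study: three genotypes, 30x coverage of
#' 2x100-style 100 nt reads, an SSR panel large enough for marker work
#' (550 loci, 60 polymorphic per query genotype), a SNP rate of 3 per kb with
#' an InDel rate about 13-fold lower (the genome-wide SNP:InDel ratio
#' observed in the study), the seven tissues used for the pathway screen,
#' 50 metabolite-tracking genes at 10% expression noise, and 1% multiplicative
#' calibration noise.
#'
#' @param seed integer master seed; all submodule seeds are derived from it
#'   by fixed offsets.
#' @param n_contigs,contig_length number and size (bases) of reference
#'   contigs.
#' @param n_genes total number of gene models tiled across the contigs.
#' @param n_ssr_planted total SSR loci planted into the reference.
#' @param n_ssr_polymorphic loci per query genotype given a +/-1..4
#'   repeat-unit change.
#' @param snp_rate,indel_rate per-base substitution and InDel event rates in
#'   `[0, 1)`.
#' @param read_length,coverage simulated read length (bases) and mean fold
#'   coverage.
#' @param tissues ordered character vector of tissue names (unique,
#'   non-empty).
#' @param n_corr_genes number of genes planted to track the metabolite
#'   vector.
#' @param expression_noise_cv,calib_noise_cv coefficients of variation of the
#'   multiplicative (log-normal) noise applied to expression counts and
#'   calibration response ratios.
#' @return a list of class `panel_config`.
#' @export
panel_config <- function(seed = 1L,
                         n_contigs = 6L,
                         contig_length = 75000L,
                         n_genes = 250L,
                         n_ssr_planted = 550L,
                         n_ssr_polymorphic = 60L,
                         snp_rate = 0.003,
                         indel_rate = 0.00023,
                         read_length = 100L,
                         coverage = 30,
                         tissues = c("developing_endosperm", "mature_leaf",
                                     "mature_fruit", "seedling_root",
                                     "fruit_coat_and_pulp", "seedling_shoot",
                                     "flower_and_bud"),
                         n_corr_genes = 50L,
                         expression_noise_cv = 0.1,
                         calib_noise_cv = 0.01) {
  assert_that_(n_ssr_polymorphic <= n_ssr_planted,
               "`n_ssr_polymorphic` must be <= `n_ssr_planted`")
  assert_that_(snp_rate >= 0 && snp_rate < 1 && indel_rate >= 0 && indel_rate < 1,
               "mutation rates must lie in [0, 1)")
  assert_that_(coverage > 0, "`coverage` must be > 0")
  assert_that_(length(tissues) >= 1 && !anyDuplicated(tissues),
               "`tissues` must be non-empty and unique")
  assert_that_(n_corr_genes <= n_genes,
               "`n_corr_genes` must be <= `n_genes`")
  assert_that_(read_length >= 20, "`read_length` must be >= 20 bases")
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              n_genes = as.integer(n_genes),
              n_ssr_planted = as.integer(n_ssr_planted),
              n_ssr_polymorphic = as.integer(n_ssr_polymorphic),
              snp_rate = snp_rate, indel_rate = indel_rate,
              read_length = as.integer(read_length), coverage = coverage,
              tissues = tissues, n_corr_genes = as.integer(n_corr_genes),
              expression_noise_cv = expression_noise_cv,
              calib_noise_cv = calib_noise_cv)
  ## sizing check: every contig must host its share of SSR loci with
  ## non-repetitive spacer on both sides of each locus
  m_max <- ceiling(n_ssr_planted / n_contigs)
  min_spacer <- 120L
  need <- m_max * 70L + (m_max + 1L) * min_spacer
  if (contig_length < need) {
    abort(sprintf(paste0(
      "contig_length (%d) too short to host %d SSR loci per contig: ",
      "needs >= %d bases (70 per locus plus %d bases of spacer around each)"),
      contig_length, m_max, need, min_spacer))
  }
  structure(cfg, class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config>\n")
  cat(sprintf("  %d contigs x %d b, %d genes, %d SSRs (%d polymorphic/genotype)\n",
              x$n_contigs, x$contig_length, x$n_genes, x$n_ssr_planted,
              x$n_ssr_polymorphic))
  cat(sprintf("  snp_rate %g, indel_rate %g, reads %d b at %gx\n",
              x$snp_rate, x$indel_rate, x$read_length, x$coverage))
  cat(sprintf("  tissues: %s\n", paste(x$tissues, collapse = ", ")))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
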
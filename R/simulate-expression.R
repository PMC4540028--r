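#' Simulate the multi-tissue expression and metabolite dataset
#'
#' Emulates the tissue design of the expression survey: a planted set of
#' metabolite-tracking genes whose *expected RPKM is exactly proportional to
#' the planted metabolite concentration vector* across tissues, against a
#' background of genes whose tissue profiles are independent of it.
#' Backgrounds get a gene-specific scale (lognormal, sdlog 1.2) modulated by
#' independent per-tissue factors (lognormal, sdlog 0.3 -- the modest
#' variation expected of a pathway-prefiltered candidate pool rather than a
#' whole transcriptome). Counts are real-valued expected read counts; when
#' `expression_noise_cv > 0` each cell is multiplied by mean-1 lognormal
#' noise with that coefficient of variation.
#'
#' The planted proportionality is achieved exactly in the noise-free case by
#' solving the self-consistent library size: planted counts are chosen so
#' that `count * 1e9 / (length * colsum)` equals `scale_g * concentration_t`
#' once the planted counts themselves are included in the column sum.
#'
#' @param config a [panel_config()]; uses `tissues`, `n_genes`,
#'   `n_corr_genes`, `expression_noise_cv` and the seed.
#' @param truth optional truth list from [generate_panel()] supplying
#'   `corr_genes` and `metabolite`; synthesised from the config when absent.
#' @param gene_ids optional gene universe (must contain the planted genes);
#'   synthetic ids are generated when absent.
#' @return list with `counts` (tibble: `gene_id`, `length`, tissue columns),
#'   `totals` (tibble: `tissue`, `total` -- the column sums, i.e. recorded
#'   library sizes), `metabolite` (tibble: `tissue`, `concentration`) and
#'   `corr_genes` (planted gene ids).
#' @export
simulate_expression <- function(config, truth = NULL, gene_ids = NULL) {
  stopifnot(inherits(config, "panel_config"))
  tissues <- config$tissues
  n <- config$n_genes
  nc <- config$n_corr_genes
  assert_that_(nc <= n, "more planted genes than genes")
  with_seed_(derive_seed(config$seed, 300), {
    metab <- if (!is.null(truth)) {
      truth$metabolite
    } else {
      tibble(tissue = tissues, concentration = default_metabolite(tissues))
    }
    assert_that_(setequal(metab$tissue, tissues),
                 "metabolite profile tissues must match the configured tissues")
    conc <- stats::setNames(metab$concentration, metab$tissue)[tissues]
    corr <- if (!is.null(truth)) truth$corr_genes else NULL
    if (is.null(gene_ids)) {
      gene_ids <- sprintf("gene_%05d", seq_len(n))
      if (!is.null(corr)) {
        gene_ids[seq_along(corr)] <- corr
        gene_ids <- sample(gene_ids)  # don't leave planted genes first
      }
    }
    assert_that_(length(gene_ids) == n, "`gene_ids` must have `n_genes` entries")
    if (is.null(corr)) corr <- sample(gene_ids, nc)
    assert_that_(all(corr %in% gene_ids),
                 "planted genes must be part of the gene universe")
    nT <- length(tissues)
    len <- sample(300:3000, n, replace = TRUE)
    names(len) <- gene_ids
    is_corr <- gene_ids %in% corr
    ## background: gene scale x independent tissue factors
    base <- stats::rlnorm(n, log(20), 1.2)
    bg_rpkm <- base * matrix(stats::rlnorm(n * nT, 0, 0.3), n, nT)
    ## target library scale per tissue (reads mapped to the gene set)
    S <- round(stats::runif(nT, 5e6, 3e7))
    counts <- sweep(bg_rpkm * len, 2, S, "*") / 1e9
    counts[is_corr, ] <- 0
    B <- colSums(counts)
    ## planted genes: expected RPKM = scale_g * concentration_t, exactly,
    ## via the self-consistent column sum C_t = B_t / (1 - A * conc_t)
    cg <- stats::runif(sum(is_corr), 20, 80) / max(conc)
    A <- sum(cg * len[is_corr]) / 1e9
    assert_that_(all(A * conc < 1),
                 "planted expression load too high for a consistent library size")
    Ct <- B / (1 - A * conc)
    counts[is_corr, ] <- (cg * len[is_corr]) %o% (conc * Ct) / 1e9
    cv <- config$expression_noise_cv
    if (cv > 0) {
      sdl <- sqrt(log(1 + cv^2))
      counts <- counts * matrix(stats::rlnorm(n * nT, -sdl^2 / 2, sdl), n, nT)
    }
    colnames(counts) <- tissues
    list(counts = dplyr::bind_cols(tibble(gene_id = gene_ids,
                                          length = as.numeric(len)),
                                   as_tibble(counts)),
         totals = tibble(tissue = tissues, total = colSums(counts)),
         metabolite = tibble(tissue = tissues, concentration = unname(conc)),
         corr_genes = corr)
  })
}

## Default azadirachtin-like concentration profile (pg per microgram dry
## tissue): highest in developing endosperm, lowest in mature leaf, matching
## the tissue ordering reported for the real metabolite survey.
default_metabolite <- function(tissues) {
  known <- c(developing_endosperm = 2500, mature_leaf = 5, mature_fruit = 90,
             seedling_root = 120, fruit_coat_and_pulp = 60,
             seedling_shoot = 180, flower_and_bud = 30)
  if (all(tissues %in% names(known))) {
    unname(known[tissues])
  } else {
    stats::rlnorm(length(tissues), log(100), 1.2)
  }
}
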
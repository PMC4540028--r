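#' RPKM expression matrix from read counts
#'
#' Reads per kilobase of gene model per million mapped reads:
#' `RPKM = count * 1e9 / (gene_length * total_mapped)`. The denominator is
#' the total reads mapped to the gene set per tissue (the matrix is
#' self-contained: by default totals are the column sums of `counts`).
#'
#' @param counts tibble with a `gene_id` column, a `length` column (or
#'   lengths supplied separately) and one numeric column per tissue.
#' @param gene_lengths optional named vector of gene lengths (bases),
#'   overriding the `length` column.
#' @param totals optional named vector of per-tissue mapped-read totals;
#'   defaults to column sums.
#' @return tibble of RPKM values (`gene_id`, `length`, tissue columns) with
#'   the totals used recorded in the `"totals"` attribute.
#' @export
#' @examples
#' rpkm(tibble::tibble(gene_id = "g1", length = 1000, leaf = 1000),
#'      totals = c(leaf = 1e6))
rpkm <- function(counts, gene_lengths = NULL, totals = NULL) {
  assert_that_("gene_id" %in% names(counts), "`counts` needs a `gene_id` column")
  if (!is.null(gene_lengths)) {
    missing <- setdiff(counts$gene_id, names(gene_lengths))
    if (length(missing)) {
      abort(sprintf("no length for counted gene(s): %s",
                    paste(utils::head(missing, 5), collapse = ", ")))
    }
    len <- unname(gene_lengths[counts$gene_id])
  } else {
    assert_that_("length" %in% names(counts),
                 "`counts` needs a `length` column (or pass `gene_lengths`)")
    len <- counts$length
  }
  assert_that_(all(len > 0), "gene lengths must be > 0")
  tissues <- setdiff(names(counts), c("gene_id", "length"))
  assert_that_(length(tissues) >= 1, "no tissue columns found")
  m <- as.matrix(counts[tissues])
  if (is.null(totals)) {
    totals <- colSums(m)
  } else {
    assert_that_(all(tissues %in% names(totals)),
                 "`totals` must name every tissue column")
    totals <- totals[tissues]
  }
  assert_that_(all(totals > 0), "per-tissue totals must be > 0")
  r <- sweep(m * 1e9 / len, 2, totals, "/")
  out <- dplyr::bind_cols(tibble(gene_id = counts$gene_id, length = len),
                          as_tibble(r))
  attr(out, "totals") <- totals
  out
}

#' Genes expressed above RPKM thresholds, per tissue
#'
#' @param mat RPKM tibble from [rpkm()].
#' @param thresholds RPKM cutoffs.
#' @return long tibble `tissue`, `threshold`, `n_genes` (count of genes with
#'   RPKM strictly above the threshold); counts are non-increasing in the
#'   threshold within each tissue.
#' @export
expression_summary <- function(mat, thresholds = c(1, 5, 10)) {
  tissues <- setdiff(names(mat), c("gene_id", "length"))
  assert_that_(nrow(mat) > 0 && length(tissues) > 0, "empty expression matrix")
  m <- as.matrix(mat[tissues])
  tidyr::expand_grid(tissue = tissues, threshold = thresholds) |>
    dplyr::mutate(n_genes = purrr::map2_int(
      .data$tissue, .data$threshold, ~ sum(m[, .x] > .y)))
}

#' Partition genes by tissue specificity
#'
#' `ubiquitous` genes are expressed (RPKM >= `min_rpkm`) in every tissue;
#' `tissue_specific` genes in exactly one; everything else (including genes
#' expressed nowhere) is `other`.
#'
#' @param mat RPKM tibble from [rpkm()].
#' @param min_rpkm expression floor.
#' @return tibble `gene_id`, `n_expressed`, `category`.
#' @export
tissue_partition <- function(mat, min_rpkm = 1) {
  tissues <- setdiff(names(mat), c("gene_id", "length"))
  assert_that_(length(tissues) >= 2, "tissue partition needs >= 2 tissues")
  m <- as.matrix(mat[tissues])
  n_exp <- rowSums(m >= min_rpkm)
  tibble(gene_id = mat$gene_id, n_expressed = as.integer(n_exp),
         category = dplyr::case_when(
           n_exp == length(tissues) ~ "ubiquitous",
           n_exp == 1 ~ "tissue_specific",
           TRUE ~ "other"))
}

#' Pearson correlation of each gene's expression with a metabolite profile
#'
#' Standard product-moment correlation of each gene's RPKM profile across
#' tissues against the per-tissue metabolite concentration. Genes with zero
#' expression variance -- or a zero-variance metabolite profile -- yield an
#' undefined correlation, which is flagged (`undefined = TRUE`, `r = NA`)
#' rather than silently zeroed.
#'
#' @param mat RPKM tibble from [rpkm()].
#' @param profile metabolite profile: tibble with `tissue` and
#'   `concentration` columns, or a named numeric vector.
#' @return tibble `gene_id`, `r`, `undefined`.
#' @export
metabolite_correlation <- function(mat, profile) {
  if (is.data.frame(profile)) {
    profile <- stats::setNames(profile$concentration, profile$tissue)
  }
  tissues <- setdiff(names(mat), c("gene_id", "length"))
  assert_that_(length(tissues) >= 3, "need >= 3 shared tissues")
  extra <- setdiff(tissues, names(profile))
  missing <- setdiff(names(profile), tissues)
  if (length(extra) || length(missing)) {
    abort(sprintf(
      "tissue sets differ: %s%s",
      if (length(extra)) paste0("no concentration for [",
                                paste(extra, collapse = ", "), "] ") else "",
      if (length(missing)) paste0("no expression for [",
                                  paste(missing, collapse = ", "), "]") else ""))
  }
  conc <- profile[tissues]
  m <- as.matrix(mat[tissues])
  cc <- conc - mean(conc)
  if (sum(cc^2) == 0) {
    warn("metabolite profile has zero variance; all correlations undefined")
    return(tibble(gene_id = mat$gene_id, r = NA_real_, undefined = TRUE))
  }
  mc <- m - rowMeans(m)
  den2 <- rowSums(mc^2) * sum(cc^2)
  r <- as.vector(mc %*% cc) / sqrt(den2)
  undef <- rowSums(mc^2) == 0
  r[undef] <- NA_real_
  tibble(gene_id = mat$gene_id, r = r, undefined = undef)
}

#' Metabolite-correlated candidate gene screen
#'
#' Ranks genes by Pearson correlation with the metabolite profile and
#' assigns candidate tiers using the contrasting-tissue rule: tier `r08`
#' requires `r >= r_min` and higher expression in `contrast[1]` than in
#' `contrast[2]` (e.g. developing endosperm vs mature leaf for azadirachtin);
#' tier `r09` additionally requires `r >= r_strict`. Thresholds are
#' inclusive and configurable.
#'
#' @param mat RPKM tibble from [rpkm()].
#' @param profile metabolite profile (see [metabolite_correlation()]).
#' @param r_min,r_strict correlation thresholds for the two tiers.
#' @param contrast length-2 character vector `(high_tissue, low_tissue)`.
#' @param rpkm_thresholds expression floors at which per-gene expressed
#'   tissue counts are reported.
#' @return tibble of class `candidate_screen`, sorted by `r` descending
#'   (ties by `gene_id`): `gene_id`, `r`, `undefined`, per-threshold
#'   expressed-tissue counts, contrast RPKMs, `contrast_pass`, `tier`.
#' @export
candidate_screen <- function(mat, profile, r_min = 0.8, r_strict = 0.9,
                             contrast = c("developing_endosperm", "mature_leaf"),
                             rpkm_thresholds = c(1, 5, 10)) {
  tissues <- setdiff(names(mat), c("gene_id", "length"))
  if (nrow(mat) == 0) {
    out <- tibble(gene_id = character(), r = double(), undefined = logical(),
                  contrast_pass = logical(), tier = character())
    class(out) <- c("candidate_screen", class(out))
    return(out)
  }
  assert_that_(all(contrast %in% tissues),
               sprintf("contrast tissue(s) absent from the matrix: %s",
                       paste(setdiff(contrast, tissues), collapse = ", ")))
  cors <- metabolite_correlation(mat, profile)
  m <- as.matrix(mat[tissues])
  out <- cors
  for (t in rpkm_thresholds) {
    out[[sprintf("n_tissues_rpkm%g", t)]] <- as.integer(rowSums(m > t))
  }
  out$rpkm_high <- mat[[contrast[1]]]
  out$rpkm_low <- mat[[contrast[2]]]
  out$contrast_pass <- out$rpkm_high > out$rpkm_low
  out$tier <- dplyr::case_when(
    !is.na(out$r) & out$r >= r_strict & out$contrast_pass ~ "r09",
    !is.na(out$r) & out$r >= r_min & out$contrast_pass ~ "r08",
    TRUE ~ "none")
  out <- dplyr::arrange(out, dplyr::desc(.data$r), .data$gene_id)
  class(out) <- c("candidate_screen", class(out))
  out
}

#' Cluster tissues on expression profiles
#'
#' Average-linkage hierarchical clustering of tissues on Euclidean distance
#' between log2(RPKM + 1) profiles -- the sample dendrogram used to check
#' that tissue relationships mirror metabolite load.
#'
#' @param mat RPKM tibble from [rpkm()].
#' @return an [stats::hclust] object over tissues.
#' @export
cluster_tissues <- function(mat) {
  tissues <- setdiff(names(mat), c("gene_id", "length"))
  m <- as.matrix(mat[tissues])
  stats::hclust(stats::dist(t(log2(m + 1))), method = "average")
}

#' qPCR relative quantification (delta-delta-Ct)
#'
#' Fold change of a target gene relative to a reference gene and a
#' calibrator sample: `fold = 2^-(dCt_sample - dCt_calibrator)` with
#' `dCt = Ct_target - Ct_reference`. Replicate wells are averaged on the Ct
#' scale before the differences are taken.
#'
#' @param ct tibble with columns `sample`, `ct_target`, `ct_reference`
#'   (one row per well; replicates share a sample name).
#' @param calibrator name of the calibrator sample.
#' @return tibble `sample`, `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @export
#' @examples
#' ddct_fold_change(
#'   tibble::tibble(sample = c("leaf", "seed"), ct_target = c(30, 24),
#'                  ct_reference = c(20, 19)), calibrator = "leaf")
ddct_fold_change <- function(ct, calibrator) {
  assert_that_(all(c("sample", "ct_target", "ct_reference") %in% names(ct)),
               "`ct` needs columns sample, ct_target, ct_reference")
  if (!all(is.finite(ct$ct_target)) || !all(is.finite(ct$ct_reference))) {
    abort("non-finite Ct value (missing reference or target Ct)")
  }
  assert_that_(calibrator %in% ct$sample,
               sprintf("calibrator '%s' not among the samples", calibrator))
  d <- ct |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(delta_ct = mean(.data$ct_target) - mean(.data$ct_reference),
                     .groups = "drop")
  cal <- d$delta_ct[d$sample == calibrator]
  dplyr::mutate(d, delta_delta_ct = .data$delta_ct - cal,
                fold_change = 2^(-.data$delta_delta_ct))
}
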
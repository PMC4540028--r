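#' @importFrom rlang abort warn %||% := .data
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int pmap imap list_rbind
#' @importFrom stringr str_sub
#' @importFrom utils head
#' @importFrom dplyr mutate arrange bind_rows bind_cols
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' Thin vectorised wrapper used throughout for motif arithmetic. For long
#' sequences the package works with [Biostrings::DNAStringSet] objects
#' instead.
#'
#' @param x character vector of sequences over A/C/G/T (and N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp_chr <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

## Run body with a temporary RNG state seeded from `seed`, restoring the
## caller's stream afterwards. Keeps every simulator a pure function of its
## seed without clobbering user RNG.
with_seed_ <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

## Deterministic sub-seed derivation: one global seed, fixed offsets per
## submodule so regenerating one assay never perturbs another.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + offset) %% 2147483647
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

assert_that_ <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
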
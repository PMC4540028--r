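#' SSR detection thresholds
#'
#' Minimum number of repeat units per motif length for a tandem run to be
#' reported, plus the maximum interruption (in bases) for two neighbouring
#' loci to be flagged as a compound SSR. Defaults are the MISA tool's
#' shipped configuration: mono >= 10, di >= 6, tri/tetra/penta/hexa >= 5,
#' compound interruption 100 bases.
#'
#' @param min_repeats integer vector of length 6; `min_repeats[k]` is the
#'   minimum copy number for motifs of length `k`.
#' @param max_interruption maximum number of bases between two reported loci
#'   for them to be merged into a compound SSR annotation.
#' @return a list of class `ssr_thresholds`.
#' @export
#' @examples
#' ssr_thresholds()
ssr_thresholds <- function(min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
                           max_interruption = 100L) {
  assert_that_(length(min_repeats) == 6 && all(min_repeats >= 2),
               "`min_repeats` must give six minimums, all >= 2")
  assert_that_(max_interruption >= 0, "`max_interruption` must be >= 0")
  structure(list(min_repeats = as.integer(min_repeats),
                 max_interruption = as.integer(max_interruption)),
            class = "ssr_thresholds")
}

## Is a motif primitive (not a whole-number repetition of a shorter unit)?
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    for (d in seq_len(k - 1)) {
      if (k %% d == 0 && strrep(substr(m, 1, d), k / d) == m) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonical motif class of an SSR unit
#'
#' Groups a repeat unit with all of its cyclic rotations and their reverse
#' complements, and labels the group `"X/revcomp(X)"` where `X` is the
#' lexicographically smallest member. This is the convention behind class
#' names such as `"AAG/CTT"` or the mononucleotide class `"A/T"`; it makes
#' class assignment independent of which strand or phase a locus was
#' detected on.
#'
#' @param motif character vector of primitive repeat units (length 1-6, over
#'   A/C/G/T).
#' @return character vector of class labels.
#' @export
#' @examples
#' canonical_class(c("CTT", "T", "TA"))
canonical_class <- function(motif) {
  assert_that_(all(nchar(motif) >= 1 & nchar(motif) <= 6),
               "motifs must have length 1-6")
  assert_that_(!any(grepl("[^ACGT]", motif)),
               "motifs must be over the A/C/G/T alphabet")
  assert_that_(all(is_primitive_motif(motif)),
               "motifs must be primitive (not a repetition of a shorter unit)")
  vapply(motif, function(m) {
    k <- nchar(m)
    doubled <- paste0(m, m)
    rot <- substring(doubled, seq_len(k), seq_len(k) + k - 1)
    rc <- revcomp_chr(m)
    doubled_rc <- paste0(rc, rc)
    rot_rc <- substring(doubled_rc, seq_len(k), seq_len(k) + k - 1)
    x <- min(c(rot, rot_rc))
    paste0(x, "/", revcomp_chr(x))
  }, character(1), USE.NAMES = FALSE)
}

## Scan one N-free segment (offset = 0-based position of segment start on the
## contig) for maximal tandem runs of primitive units of length 1..6.
## Within a unit length, scanning is greedy left-to-right: once a run meeting
## the copy threshold is emitted (or consumed as a non-primitive repetition of
## a shorter unit), the next run of the same unit length starts strictly after
## it, mirroring how a leftmost-greedy enumeration walks the sequence.
scan_segment <- function(seg, offset, min_repeats) {
  n <- nchar(seg)
  raw <- charToRaw(seg)
  out <- vector("list", 6L)
  for (k in 1:6) {
    min_rep <- min_repeats[k]
    if (n < k * 2L) next
    eq <- raw[seq_len(n - k)] == raw[(k + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= (min_rep - 1L) * k
    if (!any(keep)) next
    starts <- starts[keep]
    ends <- ends[keep]
    last_end <- 0L
    rows <- list()
    for (j in seq_along(starts)) {
      i <- max(starts[j], last_end + 1L)
      region_len <- ends[j] + k - i + 1L
      copies <- region_len %/% k
      if (copies < min_rep) next
      tract_end <- i + copies * k - 1L
      motif <- substr(seg, i, i + k - 1L)
      last_end <- tract_end
      if (!is_primitive_motif(motif)) next  # reported under the shorter unit
      rows[[length(rows) + 1L]] <-
        list(start = offset + i, end = offset + tract_end,
             motif = motif, unit_length = k, repeat_count = copies)
    }
    if (length(rows)) out[[k]] <- rows
  }
  unlist(out, recursive = FALSE)
}

## Flag compound loci: sorted loci on one contig whose gap to a neighbour is
## <= max_interruption belong to a compound group; `interruption` records the
## gap to the previous locus of the same group (0 for the first member and
## for simple loci).
flag_compound <- function(df, max_interruption) {
  if (nrow(df) == 0) {
    df$compound <- logical(0)
    df$interruption <- integer(0)
    return(df)
  }
  df <- dplyr::arrange(df, .data$start, .data$end)
  gap_prev <- c(NA_integer_, df$start[-1] - df$end[-nrow(df)] - 1L)
  linked_prev <- !is.na(gap_prev) & gap_prev <= max_interruption
  linked_next <- c(linked_prev[-1], FALSE)
  df$compound <- linked_prev | linked_next
  df$interruption <- ifelse(linked_prev, gap_prev, 0L)
  df
}

#' Detect simple sequence repeats
#'
#' Scans nucleotide sequence for maximal perfect tandem repeats of primitive
#' units of length 1-6 (microsatellites). A run divisible into several unit
#' lengths (e.g. `AAAA` as `A` x4 or `AA` x2) is reported only under its
#' shortest, primitive unit. Runs containing `N` are split at the `N`;
#' reported spans never overlap an `N`. Loci closer together than
#' `thresholds$max_interruption` bases are flagged as compound.
#'
#' @param x sequences to scan: a (optionally named) character vector, a
#'   [Biostrings::DNAStringSet], or a single string. Names become the
#'   `contig` column (`"seq_1"`, ... when absent).
#' @param thresholds an [ssr_thresholds()] object.
#' @return a tibble with one row per locus: `contig`, `start`, `end`
#'   (1-based inclusive), `motif` (unit as first encountered), `class`
#'   (canonical motif class), `unit_length`, `repeat_count`, `compound`,
#'   `interruption`.
#' @export
#' @examples
#' scan_ssrs(c(chr1 = paste0(strrep("GTCAC", 4), strrep("A", 12), "GTCCATG")))
scan_ssrs <- function(x, thresholds = ssr_thresholds()) {
  stopifnot(inherits(thresholds, "ssr_thresholds"))
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  assert_that_(is.character(x), "`x` must be character or a DNAStringSet")
  if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
  res <- imap(x, function(seq, contig) {
    seq <- toupper(seq)
    bad <- regexpr("[^ACGTN]", seq)
    if (bad > 0) {
      abort(sprintf("invalid character '%s' at position %d of '%s'",
                    substr(seq, bad, bad), bad, contig))
    }
    if (nchar(seq) == 0) return(NULL)
    ## split at N: scan each N-free segment independently
    segs <- gregexpr("[ACGT]+", seq)[[1]]
    if (segs[1] == -1) return(NULL)
    loci <- list()
    for (si in seq_along(segs)) {
      s0 <- segs[si]
      len <- attr(segs, "match.length")[si]
      seg <- substr(seq, s0, s0 + len - 1L)
      loci <- c(loci, scan_segment(seg, s0 - 1L, thresholds$min_repeats))
    }
    if (!length(loci)) return(NULL)
    df <- tibble(
      contig = contig,
      start = map_int(loci, ~ as.integer(.x$start)),
      end = map_int(loci, ~ as.integer(.x$end)),
      motif = map_chr(loci, "motif"),
      unit_length = map_int(loci, ~ as.integer(.x$unit_length)),
      repeat_count = map_int(loci, ~ as.integer(.x$repeat_count))
    )
    df$class <- canonical_class(df$motif)
    flag_compound(df, thresholds$max_interruption)
  })
  out <- list_rbind(res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  motif = character(), class = character(),
                  unit_length = integer(), repeat_count = integer(),
                  compound = logical(), interruption = integer()))
  }
  dplyr::select(out, "contig", "start", "end", "motif", "class",
                "unit_length", "repeat_count", "compound", "interruption")
}

#' Summarise detected SSR loci
#'
#' Tabulates loci per canonical motif class and per unit length, optionally
#' split into genic vs non-genic by overlap (>= 1 base) with gene spans.
#'
#' @param loci tibble from [scan_ssrs()].
#' @param gene_models optional tibble of gene features with columns `contig`,
#'   `start`, `end` (any rows; gene spans are taken as the per-gene range when
#'   a `gene_id` column is present).
#' @return a list with tibbles `by_class` (class, n), `by_unit_length`
#'   (unit_length, n) and, when gene models are given, `genic` (genic flag
#'   added per locus plus counts). Totals are conserved: class counts sum to
#'   the number of loci.
#' @export
summarize_ssrs <- function(loci, gene_models = NULL) {
  by_class <- loci |>
    dplyr::count(.data$class, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$class)
  by_unit <- loci |>
    dplyr::count(.data$unit_length, name = "n") |>
    dplyr::arrange(.data$unit_length)
  out <- list(by_class = by_class, by_unit_length = by_unit,
              n_loci = nrow(loci))
  if (!is.null(gene_models) && nrow(loci) > 0) {
    spans <- gene_models
    if ("gene_id" %in% names(spans)) {
      spans <- spans |>
        dplyr::group_by(.data$gene_id, .data$contig) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end),
                         .groups = "drop")
    }
    genic <- vapply(seq_len(nrow(loci)), function(i) {
      any(spans$contig == loci$contig[i] &
            spans$start <= loci$end[i] & spans$end >= loci$start[i])
    }, logical(1))
    out$genic <- tibble(genic = c(TRUE, FALSE),
                        n = c(sum(genic), sum(!genic)))
    out$loci_genic <- dplyr::mutate(loci, genic = genic)
  }
  out
}
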
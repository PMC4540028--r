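## Cross-genotype SSR polymorphism: each reference locus is anchored in a
## query assembly by its two 100 bp flanks (exact 31-mer seeding + full-flank
## extension with a mismatch budget), and the inter-flank query sequence is
## re-scanned to compare repeat structure.

#' Extract SSR loci with flanking sequence
#'
#' @param assembly [Biostrings::DNAStringSet] or named character vector the
#'   loci were detected on.
#' @param loci tibble from [scan_ssrs()].
#' @param flank_len target flank length in bases (100 by convention).
#' @return `loci` with `left_flank`, `right_flank` and `flank_truncated`
#'   (true when the locus is nearer than `flank_len` to a contig end)
#'   appended.
#' @export
extract_ssr_regions <- function(assembly, loci, flank_len = 100L) {
  if (inherits(assembly, "DNAStringSet")) {
    assembly <- stats::setNames(as.character(assembly), names(assembly))
  }
  assert_that_(all(loci$contig %in% names(assembly)),
               "loci reference contigs absent from the assembly")
  lens <- nchar(assembly)[loci$contig]
  if (any(loci$start < 1 | loci$end > lens)) {
    abort("locus coordinates out of contig bounds")
  }
  ls <- pmax(1L, loci$start - flank_len)
  re <- pmin(lens, loci$end + flank_len)
  seqs <- assembly[loci$contig]
  dplyr::mutate(loci,
                left_flank = unname(substr(seqs, ls, loci$start - 1L)),
                right_flank = unname(substr(seqs, loci$end + 1L, re)),
                flank_truncated = nchar(.data$left_flank) < flank_len |
                  nchar(.data$right_flank) < flank_len)
}

count_mismatch <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

seed_offsets <- function(fl, k = 31L) {
  if (fl < k) return(integer(0))
  unique(as.integer(c(1L, max(1L, (fl - k) %/% 2L + 1L), fl - k + 1L)))
}

## Locate a set of flank strings in the query: exact 31-mer seeds on both
## strands, then full-string verification with <= max_mismatch mismatches.
## Returns, per flank, the deduplicated verified placements in "strand space"
## (coordinates on the searched strand's string).
locate_flanks <- function(flanks, subjects_fwd, subjects_rev, max_mismatch,
                          k = 31L) {
  seed_tab <- list()
  for (i in seq_along(flanks)) {
    fl <- nchar(flanks[i])
    for (o in seed_offsets(fl, k)) {
      s <- substr(flanks[i], o, o + k - 1L)
      if (!grepl("N", s, fixed = TRUE)) {
        seed_tab[[length(seed_tab) + 1L]] <- list(flank = i, offset = o, seed = s)
      }
    }
  }
  placements <- vector("list", length(flanks))
  if (!length(seed_tab)) return(placements)
  seeds <- map_chr(seed_tab, "seed")
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  search_one <- function(subjects, strand) {
    subj_chrs <- vapply(subjects, as.character, character(1))
    for (ctg in names(subjects)) {
      hits <- Biostrings::matchPDict(pd, subjects[[ctg]])
      n_hit <- S4Vectors::elementNROWS(hits)
      subj_chr <- subj_chrs[[ctg]]
      for (si in which(n_hit > 0)) {
        fi <- seed_tab[[si]]$flank
        off <- seed_tab[[si]]$offset
        fl <- nchar(flanks[fi])
        for (hs in IRanges::start(hits[[si]])) {
          ps <- hs - off + 1L
          pe <- ps + fl - 1L
          if (ps < 1L || pe > nchar(subj_chr)) next
          mm <- count_mismatch(substr(subj_chr, ps, pe), flanks[fi])
          if (mm <= max_mismatch) {
            placements[[fi]] <<- c(placements[[fi]],
                                   list(list(contig = ctg, strand = strand,
                                             start = ps, end = pe, mismatch = mm)))
          }
        }
      }
    }
  }
  search_one(subjects_fwd, "forward")
  search_one(subjects_rev, "reverse")
  ## dedupe placements found via several seeds
  map(placements, function(pl) {
    if (is.null(pl)) return(NULL)
    key <- map_chr(pl, ~ paste(.x$contig, .x$strand, .x$start))
    pl[!duplicated(key)]
  })
}

## Gap-tolerant boundary recovery for a flank whose seeds all failed: align
## the full flank (global on the flank, local on the subject) inside the
## window implied by the other, uniquely anchored flank. The recovered
## boundary is pulled back from the locus by a 13-base pad so a small
## deletion between the last aligned base and the locus cannot clip the
## repeat tract. Returns a placement list or NULL.
align_flank_boundary <- function(flank, side, anchor, subjects_fwd,
                                 subjects_rev, win) {
  pad <- 13L
  strand_str <- if (anchor$strand == "forward") {
    as.character(subjects_fwd[[anchor$contig]])
  } else {
    as.character(subjects_rev[[anchor$contig]])
  }
  L <- nchar(strand_str)
  if (side == "left") {
    ws <- max(1L, anchor$start - win)
    we <- anchor$start - 1L
  } else {
    ws <- anchor$end + 1L
    we <- min(L, anchor$end + win)
  }
  if (we - ws + 1L < nchar(flank) %/% 2L) return(NULL)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(flank),
    Biostrings::DNAString(substr(strand_str, ws, we)),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
    gapOpening = 5, gapExtension = 2)
  lesions <- Biostrings::nmismatch(al) +
    sum(IRanges::width(Biostrings::deletion(al)[[1L]])) +
    sum(IRanges::width(Biostrings::insertion(al)[[1L]]))
  if (lesions > 10L) return(NULL)
  subj <- Biostrings::subject(al)
  if (side == "left") {
    list(contig = anchor$contig, strand = anchor$strand,
         start = ws + Biostrings::start(subj) - 1L,
         end = ws + Biostrings::end(subj) - 1L - pad,
         mismatch = NA_integer_)
  } else {
    list(contig = anchor$contig, strand = anchor$strand,
         start = ws + Biostrings::start(subj) - 1L + pad,
         end = ws + Biostrings::end(subj) - 1L,
         mismatch = NA_integer_)
  }
}

#' Anchor SSR regions in a query assembly
#'
#' Each non-truncated, non-compound region's two flanks are located in the
#' query by exact 31-mer seeding (three staggered seeds per flank, so a flank
#' with up to two mismatches always retains an exact seed) followed by
#' full-flank verification allowing `max_mismatch_per_flank` mismatches, on
#' both strands. A locus is matched only when both flanks place uniquely, on
#' one contig, in consistent orientation and order, with an inter-flank span
#' of at most locus length + `max_span_extra`. When a full flank fails to
#' place (e.g. an InDel disrupted its outer half), a nested rescue with the
#' 50 inner bases and a 1-mismatch budget is attempted.
#'
#' @param regions tibble from [extract_ssr_regions()].
#' @param query query assembly ([Biostrings::DNAStringSet] or named
#'   character).
#' @param max_mismatch_per_flank mismatch budget per 100 bp flank.
#' @param max_span_extra allowed inter-flank span inflation over the
#'   reference locus length, in bases.
#' @param rescue attempt the inner-flank rescue pass.
#' @return `regions` with match columns appended: `matched`, `unique`,
#'   `query_contig`, `orientation`, `left_mismatch`, `right_mismatch`,
#'   `inter_flank_span`, `query_ssr_seq` (inter-flank sequence on the locus
#'   strand) and `skip_reason` for regions never attempted or failed.
#' @export
match_ssr_regions <- function(regions, query, max_mismatch_per_flank = 2L,
                              max_span_extra = 200L, rescue = TRUE) {
  if (!inherits(query, "DNAStringSet")) {
    query <- Biostrings::DNAStringSet(query)
  }
  subjects_fwd <- stats::setNames(as.list(query), names(query))
  subjects_rev <- stats::setNames(as.list(Biostrings::reverseComplement(query)),
                                  names(query))
  n <- nrow(regions)
  res <- tibble(matched = rep(FALSE, n), unique = rep(FALSE, n),
                query_contig = NA_character_, orientation = NA_character_,
                left_mismatch = NA_integer_, right_mismatch = NA_integer_,
                inter_flank_span = NA_integer_, query_ssr_seq = NA_character_,
                skip_reason = NA_character_)
  eligible <- which(!regions$flank_truncated & !regions$compound)
  res$skip_reason[regions$flank_truncated] <- "truncated_flank"
  res$skip_reason[!regions$flank_truncated & regions$compound] <- "compound_locus"
  if (!length(eligible)) return(dplyr::bind_cols(regions, res))

  find_side <- function(flanks, budget, k = 31L) {
    locate_flanks(flanks, subjects_fwd, subjects_rev, budget, k)
  }
  left <- find_side(regions$left_flank[eligible], max_mismatch_per_flank)
  right <- find_side(regions$right_flank[eligible], max_mismatch_per_flank)
  if (rescue) {
    miss_l <- which(vapply(left, function(x) length(x) == 0L, logical(1)))
    if (length(miss_l)) {
      inner <- str_sub(regions$left_flank[eligible][miss_l], -50L)
      ## k = 25 gives two disjoint seeds over 50 bases, so a single mismatch
      ## anywhere still leaves an exact seed
      resc <- find_side(inner, 1L, k = 25L)
      ## inner left flank: only its end coordinate is used downstream
      left[miss_l] <- resc
    }
    miss_r <- which(vapply(right, function(x) length(x) == 0L, logical(1)))
    if (length(miss_r)) {
      inner <- substr(regions$right_flank[eligible][miss_r], 1L, 50L)
      resc <- find_side(inner, 1L, k = 25L)
      right[miss_r] <- resc
    }
    ## rung 3: exact 25-base innermost anchor (for an InDel in the inner
    ## half of a flank); still subject to the uniqueness requirement
    miss_l <- which(vapply(left, function(x) length(x) == 0L, logical(1)))
    if (length(miss_l)) {
      inner <- str_sub(regions$left_flank[eligible][miss_l], -25L)
      left[miss_l] <- find_side(inner, 0L, k = 25L)
    }
    miss_r <- which(vapply(right, function(x) length(x) == 0L, logical(1)))
    if (length(miss_r)) {
      inner <- substr(regions$right_flank[eligible][miss_r], 1L, 25L)
      right[miss_r] <- find_side(inner, 0L, k = 25L)
    }
    ## rung 4: exact 25-mer from bases -50..-26 (left) / 26..50 (right) of
    ## the flank, for an InDel inside the innermost 25 bases. The flank
    ## boundary is inferred from the reference distance, pulled back by a
    ## 13-base pad so a <=10-base deletion between anchor and locus cannot
    ## clip the repeat tract; the relaxed re-scan absorbs the extra window.
    pad <- 13L
    miss_l <- which(vapply(left, function(x) length(x) == 0L, logical(1)))
    if (length(miss_l)) {
      seg <- str_sub(regions$left_flank[eligible][miss_l], -50L, -26L)
      found <- find_side(seg, 0L, k = 25L)
      left[miss_l] <- map(found, function(pl) {
        map(pl, function(p) { p$end <- p$end + 25L - pad; p })
      })
    }
    miss_r <- which(vapply(right, function(x) length(x) == 0L, logical(1)))
    if (length(miss_r)) {
      seg <- substr(regions$right_flank[eligible][miss_r], 26L, 50L)
      found <- find_side(seg, 0L, k = 25L)
      right[miss_r] <- map(found, function(pl) {
        map(pl, function(p) { p$start <- p$start - 25L + pad; p })
      })
    }
  }

  for (j in seq_along(eligible)) {
    i <- eligible[j]
    lp <- left[[j]]
    rp <- right[[j]]
    ## rung 5: one flank anchored uniquely, the other damaged beyond seeding
    ## (e.g. SNP + InDel in the same flank) -- align it within the window the
    ## anchored flank implies, tolerant to gaps, as an aligner would
    if (rescue && xor(length(lp) == 0L, length(rp) == 0L)) {
      locus_len <- regions$end[i] - regions$start[i] + 1L
      win <- locus_len + max_span_extra + 120L
      if (!length(lp) && length(rp) == 1L) {
        lp <- align_flank_boundary(regions$left_flank[i], "left", rp[[1L]],
                                   subjects_fwd, subjects_rev, win)
        if (!is.null(lp)) left[[j]] <- lp <- list(lp)
      } else if (!length(rp) && length(lp) == 1L) {
        rp <- align_flank_boundary(regions$right_flank[i], "right", lp[[1L]],
                                   subjects_fwd, subjects_rev, win)
        if (!is.null(rp)) right[[j]] <- rp <- list(rp)
      }
    }
    if (!length(lp) || !length(rp)) {
      res$skip_reason[i] <- "flank_not_found"
      next
    }
    if (length(lp) > 1L || length(rp) > 1L) {
      res$matched[i] <- TRUE
      res$unique[i] <- FALSE
      res$skip_reason[i] <- "ambiguous_placement"
      next
    }
    lp <- lp[[1L]]
    rp <- rp[[1L]]
    locus_len <- regions$end[i] - regions$start[i] + 1L
    ok <- lp$contig == rp$contig && lp$strand == rp$strand &&
      rp$start > lp$end &&
      (rp$start - lp$end - 1L) <= locus_len + max_span_extra
    if (!ok) {
      res$skip_reason[i] <- "inconsistent_anchors"
      next
    }
    strand_str <- if (lp$strand == "forward") {
      as.character(subjects_fwd[[lp$contig]])
    } else {
      as.character(subjects_rev[[lp$contig]])
    }
    res$matched[i] <- TRUE
    res$unique[i] <- TRUE
    res$query_contig[i] <- lp$contig
    res$orientation[i] <- lp$strand
    res$left_mismatch[i] <- lp$mismatch
    res$right_mismatch[i] <- rp$mismatch
    res$inter_flank_span[i] <- rp$start - lp$end - 1L
    res$query_ssr_seq[i] <- substr(strand_str, lp$end + 1L, rp$start - 1L)
  }
  dplyr::bind_cols(regions, res)
}

#' Call SSR polymorphism from anchored regions
#'
#' Re-scans each uniquely anchored inter-flank query sequence (with all
#' repeat-count minimums relaxed to 2, so shrunken tracts are still counted)
#' and compares repeat structure with the reference locus:
#' `polymorphic` when the canonical class is conserved but the repeat count
#' differs, or when the locus is absent from the query; `monomorphic` when
#' class and count agree; `class_changed` when only a different class is
#' found; `unresolved` when the locus could not be anchored or the query
#' sequence contains `N`.
#'
#' @param matches tibble from [match_ssr_regions()].
#' @return `matches` with `ref_repeat_count`, `query_repeat_count`,
#'   `query_class` and `status` appended.
#' @export
call_ssr_polymorphism <- function(matches) {
  relaxed <- ssr_thresholds(min_repeats = rep(2L, 6L))
  n <- nrow(matches)
  status <- rep("unresolved", n)
  q_count <- rep(NA_integer_, n)
  q_class <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!isTRUE(matches$unique[i])) next
    seq <- matches$query_ssr_seq[i]
    if (grepl("N", seq, fixed = TRUE)) next
    hit_class <- NA_character_
    hit_count <- NA_integer_
    other_class <- NA_character_
    if (nchar(seq) >= 2L) {
      loci <- scan_ssrs(c(q = seq), relaxed)
      if (nrow(loci)) {
        same <- loci[loci$class == matches$class[i], ]
        if (nrow(same)) {
          hit_class <- matches$class[i]
          hit_count <- max(same$repeat_count)
        } else {
          other_class <- loci$class[which.max(loci$repeat_count)]
        }
      }
    }
    if (!is.na(hit_class)) {
      q_class[i] <- hit_class
      q_count[i] <- hit_count
      status[i] <- if (hit_count != matches$repeat_count[i]) "polymorphic" else "monomorphic"
    } else if (!is.na(other_class)) {
      q_class[i] <- other_class
      status[i] <- "class_changed"
    } else {
      q_class[i] <- "absent"
      status[i] <- "polymorphic"
    }
  }
  dplyr::mutate(matches, ref_repeat_count = .data$repeat_count,
                query_repeat_count = q_count, query_class = q_class,
                status = status)
}

#' Full SSR polymorphism pipeline for one genome pair
#'
#' Convenience wrapper: scan the reference for SSR loci (unless supplied),
#' extract 100 bp flanked regions, anchor them in the query, and call
#' polymorphism status.
#'
#' @param reference,query assemblies ([Biostrings::DNAStringSet] or named
#'   character).
#' @param loci optional pre-computed [scan_ssrs()] tibble for the reference.
#' @param thresholds detection thresholds for the reference scan.
#' @param flank_len,max_mismatch_per_flank,max_span_extra see
#'   [extract_ssr_regions()] and [match_ssr_regions()].
#' @return the [call_ssr_polymorphism()] tibble.
#' @export
ssr_polymorphism <- function(reference, query, loci = NULL,
                             thresholds = ssr_thresholds(), flank_len = 100L,
                             max_mismatch_per_flank = 2L,
                             max_span_extra = 200L) {
  if (is.null(loci)) loci <- scan_ssrs(reference, thresholds)
  regions <- extract_ssr_regions(reference, loci, flank_len)
  matches <- match_ssr_regions(regions, query, max_mismatch_per_flank,
                               max_span_extra)
  call_ssr_polymorphism(matches)
}

#' Concordantly polymorphic loci across genotype comparisons
#'
#' Intersects two polymorphism call sets computed against the same reference
#' locus list and returns the loci called `polymorphic` in both -- the
#' shortlist of marker-grade SSRs segregating in all genotypes.
#'
#' @param calls_a,calls_b tibbles from [call_ssr_polymorphism()] (or
#'   [ssr_polymorphism()]) against the same reference.
#' @return tibble of shared polymorphic loci (reference locus columns plus
#'   per-comparison repeat counts), sorted by contig then start.
#' @export
concordant_polymorphic <- function(calls_a, calls_b) {
  key <- c("contig", "start", "end", "motif")
  if (nrow(calls_a) && nrow(calls_b)) {
    ka <- do.call(paste, calls_a[key])
    kb <- do.call(paste, calls_b[key])
    if (!setequal(ka, kb)) {
      abort("call sets do not share a reference locus list")
    }
  }
  pa <- calls_a[calls_a$status == "polymorphic",
                c(key, "class", "unit_length", "ref_repeat_count",
                  "query_repeat_count")]
  pb <- calls_b[calls_b$status == "polymorphic",
                c(key, "query_repeat_count")]
  dplyr::inner_join(pa, pb, by = key, suffix = c("_a", "_b")) |>
    dplyr::arrange(.data$contig, .data$start)
}
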
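#' Indel filtering parameters
#'
#' Defaults implement the WGS indel-confidence filter used for off-target
#' inference: drop calls with fewer than 4 supporting reads, mapping
#' quality below 30, QUAL below 20 or length of 50 bp and over, plus calls
#' near other variants or inside exclusion intervals (e.g. the
#' pseudoautosomal regions).
#'
#' @param min_support Minimum supporting reads (calls with fewer are dropped).
#' @param min_mq Minimum mapping quality.
#' @param min_qual Minimum site QUAL.
#' @param max_indel_len Exclusive upper bound on indel length in bp.
#' @param near_variant_dist Drop calls with another variant within this many
#'   bp (only applied when `all_variants` is supplied to [filter_indels()]).
#' @param exclusion_bed Optional tibble of 0-based half-open intervals
#'   (`chrom`, `start`, `end`) to exclude, e.g. from [read_exclusion_bed()].
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_support = 4, min_mq = 30, min_qual = 20,
                          max_indel_len = 50, near_variant_dist = 10,
                          exclusion_bed = NULL) {
  stopifnot(min_support >= 0, min_mq >= 0, min_qual >= 0,
            max_indel_len >= 0, near_variant_dist >= 0)
  structure(
    list(min_support = min_support, min_mq = min_mq, min_qual = min_qual,
         max_indel_len = max_indel_len, near_variant_dist = near_variant_dist,
         exclusion_bed = exclusion_bed),
    class = "filter_params"
  )
}

#' Filter indel calls to the high-confidence set
#'
#' Applies, in order: supporting-read, mapping-quality, QUAL and
#' indel-length thresholds; proximity to other variants; exclusion
#' intervals. Removed calls are returned in the `"removed"` attribute with
#' the first failing rule, so filter provenance can be reported.
#'
#' @param calls Call tibble (see [read_indel_vcf()]).
#' @param params A [filter_params()].
#' @param all_variants Optional tibble (`chrom`, `pos`) of all variant
#'   positions (SNVs and indels) used for the near-variant rule; a call is
#'   never compared against its own position.
#' @return The surviving calls; attribute `"removed"` holds the rest with a
#'   `removed_by` column.
#' @export
filter_indels <- function(calls, params = filter_params(), all_variants = NULL) {
  if (nrow(calls) == 0L) {
    out <- calls
    attr(out, "removed") <- dplyr::mutate(calls, removed_by = character(0))
    return(out)
  }
  if (any(grepl(",", calls$alt, fixed = TRUE))) {
    abort("multi-allelic record(s) present: split them before filtering")
  }
  fail <- rep(NA_character_, nrow(calls))
  mark <- function(fail, bad, rule) ifelse(is.na(fail) & bad, rule, fail)
  fail <- mark(fail, calls$support < params$min_support, "support")
  fail <- mark(fail, calls$mq < params$min_mq, "mq")
  fail <- mark(fail, calls$qual < params$min_qual, "qual")
  fail <- mark(fail, calls$indel_len >= params$max_indel_len, "indel_len")
  if (!is.null(all_variants) && nrow(all_variants)) {
    near <- purrr::map_lgl(seq_len(nrow(calls)), function(i) {
      same <- all_variants$chrom == calls$chrom[i] &
        !(all_variants$pos == calls$pos[i])
      any(same & abs(all_variants$pos - calls$pos[i]) <= params$near_variant_dist)
    })
    fail <- mark(fail, near, "near_variant")
  }
  if (!is.null(params$exclusion_bed) && nrow(params$exclusion_bed)) {
    iv <- indel_intervals(calls)
    excl <- purrr::map_lgl(seq_len(nrow(calls)), function(i) {
      b <- params$exclusion_bed
      any(b$chrom == calls$chrom[i] & b$start < iv$end[i] + (iv$end[i] == iv$start[i]) &
            b$end > iv$start[i] - 0)
    })
    fail <- mark(fail, excl, "exclusion_bed")
  }
  out <- calls[is.na(fail), , drop = FALSE]
  removed <- calls[!is.na(fail), , drop = FALSE]
  removed$removed_by <- fail[!is.na(fail)]
  attr(out, "removed") <- removed
  out
}

#' Edited-exclusive indels
#'
#' Returns the edited-sample calls with no matching control call. `exact`
#' matching requires identical (chrom, pos, ref, alt); `windowed` matching
#' treats a control call as matching when it is on the same chromosome,
#' has the same indel length, and lies within `window` bp.
#'
#' @param edited,control Filtered call tibbles, single sample label each.
#' @param match_mode `"exact"` (default) or `"windowed"`.
#' @param window Position tolerance for `"windowed"` mode (bp).
#' @return The edited-exclusive calls.
#' @export
exclusive_indels <- function(edited, control, match_mode = c("exact", "windowed"),
                             window = 3) {
  match_mode <- match.arg(match_mode)
  for (x in list(edited, control)) {
    if (nrow(x) && length(unique(x$sample)) > 1L) {
      abort("mixed sample labels within one call list")
    }
  }
  if (nrow(edited) == 0L) return(edited)
  if (nrow(control) == 0L) return(edited)
  if (match_mode == "exact") {
    dplyr::anti_join(edited, control, by = c("chrom", "pos", "ref", "alt"))
  } else {
    matched <- purrr::map_lgl(seq_len(nrow(edited)), function(i) {
      any(control$chrom == edited$chrom[i] &
            control$indel_len == edited$indel_len[i] &
            abs(control$pos - edited$pos[i]) <= window)
    })
    edited[!matched, , drop = FALSE]
  }
}

# 0-based half-open reference interval affected by each indel:
# deletion of r-1 bases anchored at 1-based pos -> [pos, pos + r - 1);
# insertion -> zero-width point at `pos` (0-based boundary after the anchor).
indel_intervals <- function(calls) {
  r <- nchar(calls$ref)
  a <- nchar(calls$alt)
  del <- r > a
  start <- ifelse(del, calls$pos, calls$pos)
  end <- ifelse(del, calls$pos + (r - a), calls$pos)
  tibble::tibble(start = start, end = end)
}

#' Intersect candidate sites with indel calls by distance windows
#'
#' For every (site, indel) pair on the same chromosome, the distance is 0
#' when the indel's affected reference interval overlaps the site interval
#' and otherwise the gap between nearest boundaries. One hit row is emitted
#' per pair per satisfied window class (`within_<w>` for each radius in
#' `windows`); a smaller window implies every larger one.
#'
#' @param sites Sites tibble ([scan_offtargets()] / [read_sites_bed()]).
#' @param indels Call tibble.
#' @param windows Window radii in bp (default `c(15, 200)`).
#' @return Tibble of hits (`chrom`, site coords, indel pos/alleles,
#'   `distance`, `window_class`); attribute `"summary"` is a tibble with
#'   per-window counts of distinct sites hit.
#' @export
intersect_windows <- function(sites, indels, windows = c(15, 200)) {
  if (any(windows < 0)) abort("window radii must be >= 0")
  windows <- sort(unique(windows))
  empty <- tibble::tibble(
    chrom = character(), site_start = integer(), site_end = integer(),
    strand = character(), penalty = integer(), pos = integer(),
    ref = character(), alt = character(), distance = double(),
    window_class = character())
  if (nrow(sites) == 0L || nrow(indels) == 0L) {
    attr(empty, "summary") <- tibble::tibble(
      window = windows, sites_hit = 0L, indels_hit = 0L)
    return(empty)
  }
  iv <- indel_intervals(indels)
  ind <- dplyr::mutate(indels, iv_start = iv$start, iv_end = iv$end,
                       .indel_id = dplyr::row_number())
  st <- dplyr::mutate(sites, .site_id = dplyr::row_number())
  pairs <- dplyr::inner_join(
    dplyr::select(st, ".site_id", "chrom", site_start = "start",
                  site_end = "end", "strand", "penalty"),
    dplyr::select(ind, ".indel_id", "chrom", "pos", "ref", "alt",
                  "iv_start", "iv_end"),
    by = "chrom", relationship = "many-to-many")
  pairs$distance <- pmax(0, pairs$site_start - pairs$iv_end,
                         pairs$iv_start - pairs$site_end)
  hits <- purrr::map_dfr(windows, function(w) {
    h <- dplyr::filter(pairs, .data$distance <= w)
    h$window_class <- rep(paste0("within_", w), nrow(h))
    h
  })
  summary <- purrr::map_dfr(windows, function(w) {
    h <- dplyr::filter(pairs, .data$distance <= w)
    tibble::tibble(window = w,
                   sites_hit = dplyr::n_distinct(h$.site_id),
                   indels_hit = dplyr::n_distinct(h$.indel_id))
  })
  hits <- dplyr::select(hits, -".site_id", -".indel_id", -"iv_start", -"iv_end")
  attr(hits, "summary") <- summary
  hits
}

#' Per-window summary of a window intersection
#'
#' @param hits Output of [intersect_windows()].
#' @return Tibble with `window`, `sites_hit`, `indels_hit`.
#' @export
window_summary <- function(hits) {
  attr(hits, "summary")
}

#' Run the full edited-vs-control cross-reference
#'
#' Filter both samples, derive edited-exclusive indels, and intersect them
#' with windows around candidate sites.
#'
#' @param edited,control Unfiltered call tibbles.
#' @param sites Candidate-site tibble.
#' @param params A [filter_params()].
#' @param windows Window radii in bp.
#' @param match_mode,window Passed to [exclusive_indels()].
#' @param all_variants Optional variant-position table for the near-variant
#'   rule.
#' @return A list with `exclusive` (the edited-exclusive calls), `hits`
#'   and `summary`.
#' @export
crossref_indels <- function(edited, control, sites, params = filter_params(),
                            windows = c(15, 200), match_mode = "exact",
                            window = 3, all_variants = NULL) {
  fe <- filter_indels(edited, params, all_variants)
  fc <- filter_indels(control, params, all_variants)
  excl <- exclusive_indels(fe, fc, match_mode = match_mode, window = window)
  hits <- intersect_windows(offtarget_candidates_safe(sites), excl, windows)
  list(exclusive = excl, hits = hits, summary = window_summary(hits))
}

offtarget_candidates_safe <- function(sites) {
  if ("on_target_region" %in% names(sites)) offtarget_candidates(sites) else sites
}
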
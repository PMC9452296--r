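#' Enumerate candidate off-target sites for a guide
#'
#' Scans every sequence in `genome` on both strands for protospacer matches
#' whose minimal alignment penalty (substitution = 1, each bulged base =
#' `bulge_cost_per_base`) is within `max_penalty` and that are followed
#' (3' on the protospacer strand) by a PAM matching the IUPAC pattern.
#' Both DNA bulges (extra target base) and RNA bulges (extra guide base)
#' are modelled; bulge runs are internal to the alignment, at most
#' `max_bulge_len` bases long, and separate runs must be split by at least
#' one aligned base. Overlapping alignments of the same locus on the same
#' strand are collapsed to the minimal-penalty representative (ties: fewer
#' bulge bases, then leftmost start). Alignments whose target segment or
#' PAM contains a non-ACGT base are never reported.
#'
#' @param genome A named character vector / `DNAStringSet` of chromosome
#'   sequences, or the path to a FASTA file (gzip allowed).
#' @param guide A [guide_spec()] (or a bare protospacer string).
#' @param params A [scan_params()].
#' @return A tibble with one row per candidate site: `chrom`, `start`,
#'   `end` (0-based half-open protospacer interval), `strand`, `penalty`,
#'   `mismatches`, `dna_bulge_bases`, `rna_bulge_bases`, `aligned_guide`,
#'   `aligned_target` (gapped strings in protospacer orientation),
#'   `pam_observed`, `guide_name` and `on_target_region` (TRUE for sites
#'   within `exclude_on_target_radius` of the guide's on-target locus;
#'   these are reported but not counted as candidates).
#' @examples
#' g <- guide_spec("ACGTACGTACGTACGTACGT", name = "demo")
#' genome <- c(chrT = paste0(strrep("T", 30), "ACGTACGTACGTACGTACGT", "AGG",
#'                           strrep("C", 30)))
#' scan_offtargets(genome, g)
#' @export
scan_offtargets <- function(genome, guide, params = scan_params()) {
  scan_impl(genome, guide, params, engine = "dp")
}

#' Brute-force reference off-target scan
#'
#' Same site model and output contract as [scan_offtargets()], computed by
#' an exhaustive enumeration: every alignment shape (placement of bulge
#' runs up to `max_bulge_len`) is tried at every window start on both
#' strands and the penalty evaluated explicitly. Exponentially slower than
#' the anchored dynamic program but algorithmically independent of it; used
#' as the reference implementation in verification and by the synthetic
#' genome generator to certify planted penalties.
#'
#' @inheritParams scan_offtargets
#' @return A tibble, see [scan_offtargets()].
#' @export
scan_offtargets_brute <- function(genome, guide, params = scan_params()) {
  scan_impl(genome, guide, params, engine = "brute")
}

scan_impl <- function(genome, guide, params, engine) {
  genome <- as_genome(genome)
  if (length(genome) == 0L || all(Biostrings::width(genome) == 0L)) {
    abort("empty genome")
  }
  if (is.character(guide)) guide <- guide_spec(guide)
  stopifnot(inherits(guide, "guide_spec"), inherits(params, "scan_params"))
  pam <- params$pam_pattern %||% guide$pam_pattern
  fun <- if (engine == "dp") cpp_scan_oriented else cpp_scan_brute_oriented
  res <- purrr::map(names(genome), function(chrom) {
    s <- as.character(genome[[chrom]])
    L <- nchar(s)
    plus <- fun(s, guide$protospacer, pam, params$max_penalty,
                params$bulge_cost_per_base, params$max_bulge_len)
    minus <- fun(as.character(Biostrings::reverseComplement(genome[[chrom]])),
                 guide$protospacer, pam, params$max_penalty,
                 params$bulge_cost_per_base, params$max_bulge_len)
    plus <- tibble::as_tibble(plus)
    minus <- tibble::as_tibble(minus)
    plus$strand <- rep("+", nrow(plus))
    if (nrow(minus)) {
      new_start <- L - minus$end
      minus$end <- L - minus$start
      minus$start <- new_start
    }
    minus$strand <- rep("-", nrow(minus))
    out <- dplyr::bind_rows(plus, minus)
    out$chrom <- rep(chrom, nrow(out))
    out
  })
  sites <- dplyr::bind_rows(res)
  if (nrow(sites) == 0L) {
    sites <- empty_sites()
  } else {
    sites <- dedupe_sites(sites)
  }
  sites$guide_name <- rep(guide$name, nrow(sites))
  sites$on_target_region <- rep(FALSE, nrow(sites))
  ot <- guide$on_target
  if (!is.null(ot) && nrow(sites)) {
    r <- params$exclude_on_target_radius
    p0 <- ot$pos - 1  # 0-based
    gap <- pmax(0, sites$start - 1 - p0, p0 - sites$end)
    sites$on_target_region <- sites$chrom == ot$chrom & gap <= r
  }
  dplyr::arrange(sites, .data$chrom, .data$start, .data$strand)
}

# one representative per locus: chain-overlapping intervals on the same
# chrom+strand form a locus; keep min (penalty, bulge bases, start, end)
dedupe_sites <- function(sites) {
  sites %>%
    dplyr::group_by(.data$chrom, .data$strand) %>%
    dplyr::arrange(.data$start, .data$end, .by_group = TRUE) %>%
    dplyr::mutate(.grp = cumsum(.data$start >= dplyr::lag(cummax(.data$end),
                                                          default = -1L))) %>%
    dplyr::group_by(.data$.grp, .add = TRUE) %>%
    dplyr::arrange(.data$penalty,
                   .data$dna_bulge_bases + .data$rna_bulge_bases,
                   .data$start, .data$end, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::select(-".grp")
}

empty_sites <- function() {
  tibble::tibble(
    start = integer(), end = integer(), penalty = integer(),
    mismatches = integer(), dna_bulge_bases = integer(),
    rna_bulge_bases = integer(), aligned_guide = character(),
    aligned_target = character(), pam_observed = character(),
    strand = character(), chrom = character()
  )
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    gs <- genome
  } else if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
             file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
    names(gs) <- sub("\\s.*$", "", names(gs))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome sequences must be named")
    gs <- Biostrings::DNAStringSet(toupper(genome))
  } else {
    abort("`genome` must be a DNAStringSet, a named character vector, or a FASTA path")
  }
  if (anyDuplicated(names(gs))) abort("duplicate sequence names in genome")
  gs
}

#' Candidate sites excluding the on-target region
#'
#' @param sites Output of [scan_offtargets()].
#' @return `sites` without rows flagged `on_target_region`.
#' @export
offtarget_candidates <- function(sites) {
  dplyr::filter(sites, !.data$on_target_region)
}

#' Plot the penalty spectrum of a site scan
#'
#' Bar chart of candidate-site counts by penalty, split by whether the site
#' carries any bulge.
#'
#' @param sites Output of [scan_offtargets()].
#' @return A ggplot object.
#' @export
plot_site_penalties <- function(sites) {
  df <- dplyr::mutate(
    sites,
    class = ifelse(.data$dna_bulge_bases + .data$rna_bulge_bases > 0,
                   "with bulge", "mismatch only"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$penalty), fill = .data$class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "alignment penalty (mismatch-equivalents)",
                  y = "candidate sites", fill = NULL) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
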
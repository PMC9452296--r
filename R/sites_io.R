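#' Write candidate sites to BED6
#'
#' 0-based half-open BED with `name` =
#' `<guide>|mm<mismatches>|db<dna bulges>|rb<rna bulges>`, `score` = penalty
#' and the site strand. A companion TSV written next to it (same path with
#' `.tsv` appended) carries the gapped alignment strings and full penalty
#' decomposition; [read_sites_bed()] restores the full table from the pair,
#' or the BED alone if the TSV is absent.
#'
#' @param sites Tibble from [scan_offtargets()].
#' @param path Output BED path.
#' @param tsv Also write the companion TSV (default TRUE).
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, tsv = TRUE) {
  sites <- dplyr::arrange(sites, .data$chrom, .data$start, .data$strand)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("# editqc candidate sites (BED6: chrom start end name score=penalty strand)", con)
  if (nrow(sites)) {
    nm <- sprintf("%s|mm%d|db%d|rb%d",
                  sites$guide_name %||% "site", sites$mismatches,
                  sites$dna_bulge_bases, sites$rna_bulge_bases)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", sites$chrom, sites$start,
                       sites$end, nm, sites$penalty, sites$strand), con)
  }
  if (tsv) {
    readr::write_tsv(sites, paste0(path, ".tsv"))
  }
  invisible(path)
}

#' Read candidate sites written by [write_sites_bed()]
#'
#' @param path BED path; if `<path>.tsv` exists the full table (alignment
#'   strings, on-target flag) is restored from it.
#' @return A sites tibble.
#' @export
read_sites_bed <- function(path) {
  tsv <- paste0(path, ".tsv")
  if (file.exists(tsv)) {
    out <- readr::read_tsv(tsv, show_col_types = FALSE)
    for (col in c("start", "end", "penalty", "mismatches",
                  "dna_bulge_bases", "rna_bulge_bases")) {
      if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
    }
    return(out)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    out <- empty_sites()
    out$guide_name <- character()
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(f, `[`, "", 4L)
  dec <- regmatches(nm, regexec("^(.*)\\|mm(\\d+)\\|db(\\d+)\\|rb(\\d+)$", nm))
  tibble::tibble(
    chrom = vapply(f, `[`, "", 1L),
    start = as.integer(vapply(f, `[`, "", 2L)),
    end = as.integer(vapply(f, `[`, "", 3L)),
    strand = vapply(f, `[`, "", 6L),
    penalty = as.integer(vapply(f, `[`, "", 5L)),
    mismatches = as.integer(vapply(dec, `[`, "", 3L)),
    dna_bulge_bases = as.integer(vapply(dec, `[`, "", 4L)),
    rna_bulge_bases = as.integer(vapply(dec, `[`, "", 5L)),
    guide_name = vapply(dec, `[`, "", 2L)
  )
}

#' Read a BED file of exclusion intervals
#'
#' Minimal 3+ column BED reader for exclusion masks such as the
#' pseudoautosomal regions. Coordinates stay 0-based half-open.
#'
#' @param path BED path.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_exclusion_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)]
  if (!length(lines)) return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    chrom = vapply(f, `[`, "", 1L),
    start = as.integer(vapply(f, `[`, "", 2L)),
    end = as.integer(vapply(f, `[`, "", 3L))
  )
}
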
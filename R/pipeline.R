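#' Run the end-to-end editing-QC pipeline
#'
#' Orchestrates the stages — off-target scan, edited-vs-control indel
#' cross-reference, amplicon editing-outcome quantification, and knock-in
#' genotype deconvolution — in dependency order. Any subset of stages may
#' be configured; the cross-reference can consume a sites BED from an
#' earlier run instead of a scan stage. Stage outputs are serialized to
#' standard formats (BED/TSV/JSON) in `out_dir` and summarized in a QC
#' report (`report.json` + `report.md`) whose every number is re-derivable
#' from the stage outputs written beside it.
#'
#' @param config Path to a YAML file or an equivalent nested list with
#'   optional blocks:
#'   \describe{
#'     \item{guide}{`protospacer`, `pam_pattern`, `name`, `on_target`
#'       (`chrom`, `pos`).}
#'     \item{scan}{`genome` (FASTA path), plus any [scan_params()] fields.}
#'     \item{crossref}{`edited`, `control` (VCF paths), `sites` (BED path;
#'       defaults to the scan stage output), `exclude` (BED), `windows`,
#'       `match_mode`, plus any [filter_params()] fields.}
#'     \item{amplicon}{`reads` (FASTQ), `reference`/`amplicon_fasta`,
#'       `cut_site`, `hdr_signature`, `quant_window`, `min_read_len`.}
#'     \item{genotype}{`bands` (TSV with columns sample, A, B, C, D).}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return The QC report as a list (invisibly returns it; also written to
#'   `out_dir/report.json` and `out_dir/report.md`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(meta = list(
    package = "editqc",
    version = as.character(utils::packageVersion("editqc")),
    parameter_hash = rlang::hash(config)))
  log_stage <- function(stage, msg) {
    message(sprintf("[editqc:%s] %s", stage, msg))
  }

  guide <- NULL
  if (!is.null(config$guide)) {
    guide <- guide_spec(
      protospacer = config$guide$protospacer,
      pam_pattern = config$guide$pam_pattern %||% "NRG",
      name = config$guide$name %||% "guide",
      on_target = config$guide$on_target)
    report$guide <- list(name = guide$name, protospacer = guide$protospacer,
                         pam_pattern = guide$pam_pattern)
  }

  sites <- NULL
  if (!is.null(config$scan)) {
    if (is.null(guide)) abort("scan stage configured but no guide block given")
    if (is.null(config$scan$genome)) abort("scan stage needs `genome` (FASTA path)")
    sp <- scan_params(
      max_penalty = config$scan$max_penalty %||% 5L,
      bulge_cost_per_base = config$scan$bulge_cost_per_base %||% 2L,
      max_bulge_len = config$scan$max_bulge_len %||% 2L,
      pam_pattern = config$scan$pam_pattern,
      exclude_on_target_radius = config$scan$exclude_on_target_radius %||% 1000L)
    log_stage("scan", paste("scanning", config$scan$genome))
    sites <- scan_offtargets(config$scan$genome, guide, sp)
    write_sites_bed(offtarget_candidates(sites), file.path(out_dir, "sites.bed"))
    ot <- dplyr::filter(sites, .data$on_target_region)
    if (nrow(ot)) write_sites_bed(ot, file.path(out_dir, "sites_on_target.bed"))
    report$scan <- list(
      n_candidate_sites = nrow(offtarget_candidates(sites)),
      n_on_target_excluded = nrow(ot),
      max_penalty = sp$max_penalty)
  }

  if (!is.null(config$crossref)) {
    cc <- config$crossref
    if (is.null(sites)) {
      if (is.null(cc$sites)) abort("crossref stage needs `sites` (no scan stage output available)")
      sites <- read_sites_bed(cc$sites)
    }
    if (is.null(cc$edited) || is.null(cc$control)) {
      abort("crossref stage needs `edited` and `control` VCF paths")
    }
    log_stage("crossref", "filtering and intersecting indel calls")
    fp <- filter_params(
      min_support = cc$min_support %||% 4,
      min_mq = cc$min_mq %||% 30,
      min_qual = cc$min_qual %||% 20,
      max_indel_len = cc$max_indel_len %||% 50,
      near_variant_dist = cc$near_variant_dist %||% 10,
      exclusion_bed = if (!is.null(cc$exclude)) read_exclusion_bed(cc$exclude))
    windows <- as.numeric(cc$windows %||% c(15, 200))
    edited <- read_indel_vcf(cc$edited, sample = "edited")
    control <- read_indel_vcf(cc$control, sample = "control")
    res <- crossref_indels(edited, control, sites, fp, windows,
                           match_mode = cc$match_mode %||% "exact")
    readr::write_tsv(res$exclusive, file.path(out_dir, "exclusive_indels.tsv"))
    readr::write_tsv(res$hits, file.path(out_dir, "proximity_hits.tsv"))
    smry <- stats::setNames(as.list(res$summary$sites_hit),
                            paste0("sites_within_", res$summary$window))
    jsonlite::write_json(smry, file.path(out_dir, "crossref_summary.json"),
                         auto_unbox = TRUE)
    report$crossref <- c(smry, list(n_exclusive = nrow(res$exclusive)))
  }

  if (!is.null(config$amplicon)) {
    loci <- config$amplicon
    if (!is.null(loci$reads)) loci <- list(loci)  # single locus block
    report$amplicon <- purrr::map(loci, function(am) {
      ref <- am$reference %||% {
        fa <- Biostrings::readDNAStringSet(am$amplicon_fasta)
        as.character(fa[[1]])
      }
      spec <- amplicon_spec(ref, am$cut_site,
                            hdr_signature = am$hdr_signature,
                            quant_window = am$quant_window %||% 2L,
                            min_read_len = am$min_read_len %||% 50L)
      log_stage("amplicon", paste("quantifying", am$reads))
      q <- quantify_amplicon(am$reads, spec)
      nm <- am$name %||% "locus"
      jsonlite::write_json(
        c(list(locus = nm), unclass(glance(q))),
        file.path(out_dir, paste0("quant_", nm, ".json")), auto_unbox = TRUE,
        digits = NA)
      list(locus = nm, n_total = q$n_total, n_pass = q$n_pass,
           indel_pct = q$indel_pct, hdr_pct = q$hdr_pct,
           indel_ci95 = q$indel_ci95, hdr_ci95 = q$hdr_ci95)
    })
  }

  if (!is.null(config$genotype)) {
    log_stage("genotype", "deconvolving band intensities")
    bands <- readr::read_tsv(config$genotype$bands, show_col_types = FALSE)
    geno <- deconvolve_genotypes(bands)
    readr::write_tsv(geno, file.path(out_dir, "genotypes.tsv"))
    report$genotype <- purrr::transpose(as.list(geno))
  }

  if (is.null(report$scan) && is.null(report$crossref) &&
      is.null(report$amplicon) && is.null(report$genotype)) {
    abort("configuration names no stage to run")
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report_md(report), file.path(out_dir, "report.md"))
  invisible(report)
}

render_report_md <- function(report) {
  out <- c("# editqc QC report", "",
           sprintf("- package: editqc %s", report$meta$version),
           sprintf("- parameter hash: %s", report$meta$parameter_hash), "")
  if (!is.null(report$guide)) {
    out <- c(out, "## Guide",
             sprintf("- %s: %s (PAM %s)", report$guide$name,
                     report$guide$protospacer, report$guide$pam_pattern), "")
  }
  if (!is.null(report$scan)) {
    out <- c(out, "## Off-target scan",
             sprintf("- candidate sites (penalty <= %d): %d",
                     report$scan$max_penalty, report$scan$n_candidate_sites),
             sprintf("- excluded on-target-region sites: %d",
                     report$scan$n_on_target_excluded), "")
  }
  if (!is.null(report$crossref)) {
    cr <- report$crossref
    wins <- grep("^sites_within_", names(cr), value = TRUE)
    out <- c(out, "## Edited-vs-control cross-reference",
             sprintf("- edited-exclusive indels: %d", cr$n_exclusive),
             sprintf("- %s: %d sites", sub("sites_within_", "sites with hits within +/-",
                                           wins), unlist(cr[wins])), "")
  }
  if (!is.null(report$amplicon)) {
    out <- c(out, "## Amplicon quantification")
    for (am in report$amplicon) {
      out <- c(out, sprintf(
        "- %s: indel %.2f%% [%.2f, %.2f], HDR %.2f%% [%.2f, %.2f] (n pass = %d)",
        am$locus, am$indel_pct, am$indel_ci95[1], am$indel_ci95[2],
        am$hdr_pct, am$hdr_ci95[1], am$hdr_ci95[2], am$n_pass))
    }
    out <- c(out, "")
  }
  if (!is.null(report$genotype)) {
    out <- c(out, "## Knock-in genotypes")
    for (gr in report$genotype) {
      lab <- gr$sample %||% "sample"
      out <- c(out, sprintf(
        "- %s: WT/indel %.1f%%, heterozygous %.1f%%, homozygous %.1f%%%s",
        lab, gr$wt_indel_pct, gr$het_pct, gr$homo_pct,
        if (isTRUE(gr$consistent)) "" else " [INCONSISTENT LANE]"))
    }
    out <- c(out, "")
  }
  out
}
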
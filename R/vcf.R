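#' Read indel calls from a VCF
#'
#' Parses a VCF (v4.x, plain or bgzipped) via \pkg{vcfR} and returns the
#' pure indel records as a normalized call table. Multi-allelic records are
#' refused: split them upstream (e.g. `bcftools norm -m-`) so that filtering
#' never has to pick an allele silently. Site quality comes from QUAL;
#' mapping quality and supporting-read count come from INFO keys
#' (configurable, defaults `MQ` and `DP`).
#'
#' @param path VCF path.
#' @param sample Label attached to every call (e.g. `"edited"`, `"control"`).
#' @param mq_key,support_key INFO keys for mapping quality and supporting
#'   reads.
#' @param keep_snvs Keep non-indel records too (default FALSE).
#' @return Tibble with `chrom`, `pos` (1-based), `ref`, `alt`, `indel_len`,
#'   `qual`, `mq`, `support`, `sample`.
#' @export
read_indel_vcf <- function(path, sample = "sample", mq_key = "MQ",
                           support_key = "DP", keep_snvs = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    abort(paste0("multi-allelic record(s) in ", path,
                 ": split them first (e.g. `bcftools norm -m-`)"))
  }
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = mq_key)))
  support <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = support_key)))
  calls <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = alt,
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    mq = mq,
    support = support,
    sample = sample
  )
  calls$indel_len <- abs(nchar(calls$alt) - nchar(calls$ref))
  if (!keep_snvs) calls <- dplyr::filter(calls, .data$indel_len >= 1L)
  dplyr::select(calls, "chrom", "pos", "ref", "alt", "indel_len",
                "qual", "mq", "support", "sample")
}

#' Write an indel call table as an uncompressed VCFv4.2 file
#'
#' Emitter for the synthetic-data generators and for round-tripping filtered
#' call sets; the output is readable by [read_indel_vcf()] and standard
#' tools. QUAL, INFO/MQ and INFO/DP carry site quality, mapping quality and
#' supporting reads.
#'
#' @param calls Call tibble (columns as in [read_indel_vcf()]).
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_indel_vcf <- function(calls, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=editqc",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Supporting reads">'
  )
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  calls <- dplyr::arrange(calls, .data$chrom, .data$pos)
  body <- if (nrow(calls)) {
    sprintf("%s\t%d\t.\t%s\t%s\t%.2f\t.\tMQ=%.2f;DP=%d",
            calls$chrom, calls$pos, calls$ref, calls$alt, calls$qual,
            calls$mq, as.integer(calls$support))
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
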
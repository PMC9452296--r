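#' Define an sgRNA guide
#'
#' A guide is the protospacer sequence matched by the sgRNA spacer plus the
#' PAM pattern required 3' of it. RNA alphabet is accepted and normalized
#' (U -> T). An optional on-target locus lets the scanner flag (and exclude
#' from counting) candidate sites around the intended cut site.
#'
#' @param protospacer Protospacer sequence, 18-24 nt, A/C/G/T/U only
#'   (canonically 20 nt for SpCas9).
#' @param pam_pattern IUPAC PAM pattern required immediately 3' of the
#'   protospacer (default `"NRG"`, the relaxed SpCas9 motif; R = A/G).
#' @param name Label used in outputs.
#' @param on_target Optional on-target locus: a list or named vector with
#'   `chrom`, `pos` (1-based) and optionally `strand`.
#' @return An object of class `guide_spec`.
#' @examples
#' guide_spec("CGACUGGCCAGGGCGCCUGU", name = "PD1-site1",
#'            on_target = list(chrom = "chr2", pos = 241858824))
#' @export
guide_spec <- function(protospacer, pam_pattern = "NRG", name = "guide",
                       on_target = NULL) {
  if (!is.character(protospacer) || length(protospacer) != 1L) {
    abort("`protospacer` must be a single string")
  }
  ps <- chartr("u", "t", toupper(protospacer))
  ps <- chartr("U", "T", ps)
  if (!grepl("^[ACGT]+$", ps)) {
    abort("protospacer contains ambiguous or non-nucleotide bases (only A/C/G/T/U allowed)")
  }
  if (nchar(ps) < 18L || nchar(ps) > 24L) {
    abort("protospacer length must be 18-24 nt")
  }
  check_iupac(pam_pattern)
  if (!is.null(on_target)) {
    on_target <- as.list(on_target)
    if (is.null(on_target$chrom) || is.null(on_target$pos)) {
      abort("`on_target` needs `chrom` and `pos`")
    }
    on_target$pos <- as.numeric(on_target$pos)
  }
  structure(
    list(protospacer = ps, pam_pattern = toupper(pam_pattern),
         name = name, on_target = on_target),
    class = "guide_spec"
  )
}

#' @export
print.guide_spec <- function(x, ...) {
  cat("<guide_spec> ", x$name, "\n", sep = "")
  cat("  protospacer: ", x$protospacer, " (", nchar(x$protospacer), " nt)\n", sep = "")
  cat("  PAM pattern: ", x$pam_pattern, "\n", sep = "")
  if (!is.null(x$on_target)) {
    cat("  on-target:   ", x$on_target$chrom, ":", format(x$on_target$pos, scientific = FALSE),
        "\n", sep = "")
  }
  invisible(x)
}

#' Off-target scan parameters
#'
#' The penalty model prices a substitution at 1 and each bulged
#' (unpaired) base at `bulge_cost_per_base`; a site is a candidate when its
#' minimal alignment penalty is at most `max_penalty` and the adjacent
#' PAM-side bases match `pam_pattern`. Defaults implement the screen used to
#' qualify edited cell products: up to five mismatch-equivalents with a
#' bulge penalty equal to two base mismatches, NRG PAM.
#'
#' @param max_penalty Maximum total penalty in mismatch-equivalents.
#' @param bulge_cost_per_base Penalty per bulged base (DNA or RNA bulge).
#' @param max_bulge_len Maximum contiguous bulge run length, in bases.
#' @param pam_pattern IUPAC PAM pattern (overrides the guide's if given here).
#' @param exclude_on_target_radius Sites within this many bases of the
#'   guide's on-target locus are flagged `on_target_region` and excluded
#'   from candidate counts.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(max_penalty = 5L, bulge_cost_per_base = 2L,
                        max_bulge_len = 2L, pam_pattern = NULL,
                        exclude_on_target_radius = 1000L) {
  stopifnot(max_penalty >= 0, bulge_cost_per_base >= 1, max_bulge_len >= 0,
            exclude_on_target_radius >= 0)
  if (!is.null(pam_pattern)) check_iupac(pam_pattern)
  structure(
    list(max_penalty = as.integer(max_penalty),
         bulge_cost_per_base = as.integer(bulge_cost_per_base),
         max_bulge_len = as.integer(max_bulge_len),
         pam_pattern = if (is.null(pam_pattern)) NULL else toupper(pam_pattern),
         exclude_on_target_radius = as.integer(exclude_on_target_radius)),
    class = "scan_params"
  )
}

check_iupac <- function(pam_pattern) {
  if (!is.character(pam_pattern) || length(pam_pattern) != 1L ||
      nchar(pam_pattern) < 1L ||
      !grepl("^[ACGTURYSWKMBDHVNacgturyswkmbdhvn]+$", pam_pattern)) {
    abort("`pam_pattern` must be a non-empty IUPAC nucleotide string")
  }
  invisible(pam_pattern)
}

#' Bundled guide and primer sequences
#'
#' sgRNA protospacers (with their published on-target loci, GRCh38 1-based
#' coordinates) and genotyping primers used in non-viral CAR-T manufacture:
#' the AAVS1 safe-harbour guide, two PD1 exon-1 guides, TRAC and B2M guides,
#' and the three-primer set for CAR knock-in genotyping at PD1 (the forward
#' primer binding inside the anti-CD19 CAR cassette, a genomic reverse
#' primer outside the right homology arm, and a genomic forward primer in
#' the left homology arm).
#'
#' @return A list with two tibbles: `guides` (name, protospacer, chrom, pos,
#'   note) and `primers` (name, sequence, binds).
#' @export
example_guides <- function() {
  guides <- tibble::tribble(
    ~name,        ~protospacer,             ~chrom,  ~pos,       ~note,
    "AAVS1",      "AGAGCUAGCACAGACUAGAG",   "chr19", 55115996,   "intron 1 of PPP1R12C",
    "PD1-site1",  "CGACUGGCCAGGGCGCCUGU",   "chr2",  241858824,  "exon 1 of PD1",
    "PD1-site2",  "GGGCGGUGCUACAACUGGGC",   "chr2",  241858788,  "exon 1 of PD1",
    "TRAC",       "AGAGCAACAGTGCTGTGGCC",   "chr14", 22547693,   "exon 1 of TRAC",
    "B2M",        "GAGTAGCGCGAGCACAGCTA",   "chr15", 44711569,   "exon 1 of B2M"
  )
  primers <- tibble::tribble(
    ~name,            ~sequence,              ~binds,
    "CAR-forward",    "CCCTGCAACTGATGGTGACT", "anti-CD19 CAR cassette",
    "genomic-reverse","TCACAGTGTACACAGAGGGC", "outside right homology arm",
    "genomic-forward","GACAGTTTCCCTTCCGCTCA", "left homology arm",
    "PD1-amp-F",      "CCACGTGGATGTGGAGGAAG", "PD1 amplicon forward",
    "PD1-amp-R",      "CCACACAGCTCAGGGTAAGG", "PD1 amplicon reverse"
  )
  list(guides = guides, primers = primers)
}
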
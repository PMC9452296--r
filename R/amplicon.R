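#' Describe an amplicon for editing-outcome quantification
#'
#' @param reference Amplicon reference sequence (string).
#' @param cut_site 0-based offset of the blunt Cas9 cut in `reference`
#'   (the cut falls between positions `cut_site - 1` and `cut_site`;
#'   for SpCas9 this is 3 bp 5' of the PAM, between protospacer positions
#'   17 and 18).
#' @param hdr_signature Donor-specific subsequence diagnostic of the
#'   knock-in junction (default length 30 in the simulators); must not occur
#'   in `reference`.
#' @param quant_window Radius in bp around `cut_site` within which an
#'   alignment gap is attributed to editing (default 2).
#' @param min_read_len Reads shorter than this after quality trimming FAIL.
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(reference, cut_site, hdr_signature = NULL,
                          quant_window = 2L, min_read_len = 50L) {
  reference <- toupper(reference)
  stopifnot(is.character(reference), length(reference) == 1L)
  if (!(cut_site > 0 && cut_site < nchar(reference))) {
    abort("`cut_site` must lie strictly inside the reference")
  }
  if (!is.null(hdr_signature)) {
    hdr_signature <- toupper(hdr_signature)
    if (grepl(hdr_signature, reference, fixed = TRUE)) {
      abort("`hdr_signature` must not be a substring of the reference")
    }
  }
  structure(
    list(reference = reference, cut_site = as.integer(cut_site),
         hdr_signature = hdr_signature, quant_window = as.integer(quant_window),
         min_read_len = as.integer(min_read_len)),
    class = "amplicon_spec"
  )
}

#' Alignment parameters for read classification
#'
#' @param match,mismatch,gap_opening,gap_extension Scoring (signs as usual:
#'   positive match reward, negative penalties).
#' @param min_identity_wt Identity (matches / read length) at or above which
#'   a gap-free-window read is WT.
#' @param min_identity_pass Identity below which a read FAILs.
#' @param hdr_max_mismatch Mismatches tolerated when searching for the HDR
#'   signature (forward or reverse complement).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_opening = -4,
                         gap_extension = -1, min_identity_wt = 0.9,
                         min_identity_pass = 0.6, hdr_max_mismatch = 1L) {
  structure(list(match = match, mismatch = mismatch, gap_opening = gap_opening,
                 gap_extension = gap_extension, min_identity_wt = min_identity_wt,
                 min_identity_pass = min_identity_pass,
                 hdr_max_mismatch = as.integer(hdr_max_mismatch)),
            class = "align_params")
}

#' Classify amplicon reads by editing outcome
#'
#' Each read is labelled `HDR` when the donor signature (or its reverse
#' complement) occurs with at most `hdr_max_mismatch` mismatches; otherwise
#' the read is globally aligned to the amplicon reference (read global,
#' reference ends free) and labelled `INDEL` when an alignment gap overlaps
#' the quantification window around the cut site, `WT` when no window gap
#' exists and identity >= `min_identity_wt`, `FAIL` when identity <
#' `min_identity_pass` (or the read is shorter than `min_read_len`), and
#' `AMBIGUOUS` otherwise.
#'
#' @param reads Character vector, `DNAStringSet`, or FASTQ path.
#' @param spec An [amplicon_spec()].
#' @param params An [align_params()].
#' @param trim_quality Phred threshold for 3' quality trimming when reads
#'   carry qualities (default 20; set NULL to skip).
#' @return Tibble with `read_id`, `label`, `indel_len` (signed net bases of
#'   window-overlapping gaps; 0 unless INDEL), `identity`,
#'   `alignment_score`.
#' @export
classify_reads <- function(reads, spec, params = align_params(),
                           trim_quality = 20) {
  reads <- as_reads(reads, trim_quality)
  n <- length(reads)
  ids <- names(reads) %||% as.character(seq_len(n))
  out <- tibble::tibble(read_id = ids, label = rep("AMBIGUOUS", n),
                        indel_len = rep(0L, n), identity = rep(NA_real_, n),
                        alignment_score = rep(NA_real_, n))
  if (n == 0L) return(out)
  too_short <- Biostrings::width(reads) < spec$min_read_len
  out$label[too_short] <- "FAIL"
  todo <- which(!too_short)
  if (!length(todo)) return(out)
  # HDR: signature k-mer (or its reverse complement) with <= 1 mismatch
  if (!is.null(spec$hdr_signature)) {
    sig <- Biostrings::DNAString(spec$hdr_signature)
    hits <- Biostrings::vcountPattern(sig, reads[todo],
                                      max.mismatch = params$hdr_max_mismatch) +
      Biostrings::vcountPattern(Biostrings::reverseComplement(sig), reads[todo],
                                max.mismatch = params$hdr_max_mismatch)
    is_hdr <- hits > 0
    out$label[todo[is_hdr]] <- "HDR"
    todo <- todo[!is_hdr]
  }
  if (!length(todo)) return(out)
  ref <- Biostrings::DNAString(spec$reference)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                  mismatch = params$mismatch)
  aln <- Biostrings::pairwiseAlignment(
    reads[todo], ref, type = "global-local", substitutionMatrix = mat,
    gapOpening = abs(params$gap_opening), gapExtension = abs(params$gap_extension))
  idf <- Biostrings::nmatch(aln) / Biostrings::width(reads[todo])
  out$identity[todo] <- idf
  out$alignment_score[todo] <- Biostrings::score(aln)
  pat <- as.character(Biostrings::pattern(aln))
  sub <- as.character(Biostrings::subject(aln))
  ref_off <- Biostrings::start(Biostrings::subject(aln)) - 1L  # 0-based ref offset
  w_lo <- spec$cut_site - spec$quant_window
  w_hi <- spec$cut_site + spec$quant_window
  gapped <- grepl("-", pat, fixed = TRUE) | grepl("-", sub, fixed = TRUE)
  net <- integer(length(todo))
  has_window_gap <- logical(length(todo))
  for (ii in which(gapped)) {
    g <- gap_runs(pat[ii], sub[ii], ref_off[ii], spec$reference)
    # a gap counts when any equivalent placement (same alternate sequence,
    # gap slid along flanking repeats) touches the window: deletions by
    # interval overlap with [w_lo, w_hi), insertion points within
    # [w_lo, w_hi]
    in_win <- ifelse(g$type == "del",
                     g$lo < w_hi & g$hi > w_lo,
                     g$lo <= w_hi & g$hi >= w_lo)
    if (any(in_win)) {
      has_window_gap[ii] <- TRUE
      net[ii] <- sum(ifelse(g$type[in_win] == "ins", g$len[in_win], -g$len[in_win]))
    }
  }
  lab <- rep("AMBIGUOUS", length(todo))
  lab[has_window_gap & net != 0L] <- "INDEL"
  lab[!has_window_gap & idf >= params$min_identity_wt] <- "WT"
  lab[idf < params$min_identity_pass] <- "FAIL"
  out$label[todo] <- lab
  out$indel_len[todo[lab == "INDEL"]] <- net[lab == "INDEL"]
  out
}

# gap runs of one alignment, in 0-based reference coordinates, with the
# equivalence range each run can slide over along flanking repeats
gap_runs <- function(pat, sub, ref_off, ref) {
  p <- strsplit(pat, "", fixed = TRUE)[[1]]
  s <- strsplit(sub, "", fixed = TRUE)[[1]]
  rch <- strsplit(ref, "", fixed = TRUE)[[1]]
  Lr <- length(rch)
  ref_pos <- ref_off + cumsum(s != "-")  # ref coord AFTER each column (1-based count)
  runs <- rle(paste0(ifelse(p == "-", "D", ""), ifelse(s == "-", "I", "")))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values %in% c("D", "I")
  if (!any(keep)) {
    return(tibble::tibble(type = character(), start = integer(),
                          end = integer(), len = integer(),
                          lo = integer(), hi = integer()))
  }
  type <- ifelse(runs$values[keep] == "D", "del", "ins")
  cs <- starts[keep]; ce <- ends[keep]; lens <- runs$lengths[keep]
  start <- ifelse(type == "del", ref_pos[cs] - 1L, ref_pos[cs])
  end <- ifelse(type == "del", ref_pos[ce], ref_pos[cs])
  lo <- integer(length(cs)); hi <- integer(length(cs))
  for (i in seq_along(cs)) {
    if (type[i] == "del") {
      a <- start[i]; b <- end[i]          # deleted ref bases, 0-based [a, b)
      la <- a; lb <- b
      while (la > 0 && rch[la] == rch[lb]) { la <- la - 1L; lb <- lb - 1L }
      ra <- a; rb <- b
      while (rb < Lr && rch[rb + 1L] == rch[ra + 1L]) { ra <- ra + 1L; rb <- rb + 1L }
      lo[i] <- la; hi[i] <- rb
    } else {
      ins <- p[cs[i]:ce[i]]               # inserted read bases
      pt <- start[i]                      # 0-based insertion boundary
      lpt <- pt; v <- ins
      while (lpt > 0 && rch[lpt] == v[length(v)]) {
        v <- c(v[length(v)], v[-length(v)]); lpt <- lpt - 1L
      }
      rpt <- pt; v <- ins
      while (rpt < Lr && rch[rpt + 1L] == v[1L]) {
        v <- c(v[-1L], v[1L]); rpt <- rpt + 1L
      }
      lo[i] <- lpt; hi[i] <- rpt
    }
  }
  tibble::tibble(type = type, start = as.integer(start),
                 end = as.integer(end), len = as.integer(lens),
                 lo = as.integer(lo), hi = as.integer(hi))
}

#' Quantify editing outcomes over an amplicon read set
#'
#' Aggregates [classify_reads()] into per-locus percentages. `FAIL` reads
#' are excluded from denominators; percentages are of passing reads, with
#' Clopper-Pearson 95% binomial confidence intervals.
#'
#' @inheritParams classify_reads
#' @param min_pass Minimum passing reads required (default 100).
#' @return An object of class `amplicon_quant` with counts, percentages,
#'   confidence intervals and the per-read table.
#' @export
quantify_amplicon <- function(reads, spec, params = align_params(),
                              trim_quality = 20, min_pass = 100L) {
  cls <- classify_reads(reads, spec, params, trim_quality)
  n_total <- nrow(cls)
  counts <- table(factor(cls$label, levels = c("WT", "INDEL", "HDR", "AMBIGUOUS", "FAIL")))
  n_pass <- n_total - counts[["FAIL"]]
  if (n_pass == 0L) abort("zero passing reads: nothing to quantify")
  if (n_pass < min_pass) {
    warning(sprintf("only %d passing reads (< %d): confidence intervals will be wide",
                    n_pass, min_pass))
  }
  ci <- function(k) as.numeric(stats::binom.test(k, n_pass)$conf.int) * 100
  res <- structure(
    list(n_total = n_total, n_pass = n_pass,
         n_wt = counts[["WT"]], n_indel = counts[["INDEL"]],
         n_hdr = counts[["HDR"]], n_ambiguous = counts[["AMBIGUOUS"]],
         n_fail = counts[["FAIL"]],
         indel_pct = 100 * counts[["INDEL"]] / n_pass,
         hdr_pct = 100 * counts[["HDR"]] / n_pass,
         indel_ci95 = ci(counts[["INDEL"]]),
         hdr_ci95 = ci(counts[["HDR"]]),
         reads = cls, spec = spec),
    class = "amplicon_quant"
  )
  res
}

#' @export
print.amplicon_quant <- function(x, ...) {
  cat("<amplicon_quant> ", x$n_total, " reads (", x$n_pass, " passing)\n", sep = "")
  cat(sprintf("  indel: %5.2f%%  [95%% CI %5.2f-%5.2f]  (n = %d)\n",
              x$indel_pct, x$indel_ci95[1], x$indel_ci95[2], x$n_indel))
  cat(sprintf("  HDR:   %5.2f%%  [95%% CI %5.2f-%5.2f]  (n = %d)\n",
              x$hdr_pct, x$hdr_ci95[1], x$hdr_ci95[2], x$n_hdr))
  cat(sprintf("  WT: %d  ambiguous: %d  fail: %d\n", x$n_wt, x$n_ambiguous, x$n_fail))
  invisible(x)
}

#' @rdname quantify_amplicon
#' @param x An `amplicon_quant` object.
#' @param ... Unused.
#' @export
tidy.amplicon_quant <- function(x, ...) {
  tibble::tibble(
    outcome = c("WT", "INDEL", "HDR", "AMBIGUOUS"),
    n = c(x$n_wt, x$n_indel, x$n_hdr, x$n_ambiguous),
    pct = 100 * c(x$n_wt, x$n_indel, x$n_hdr, x$n_ambiguous) / x$n_pass,
    conf.low = c(NA, x$indel_ci95[1], x$hdr_ci95[1], NA),
    conf.high = c(NA, x$indel_ci95[2], x$hdr_ci95[2], NA)
  )
}

#' @rdname quantify_amplicon
#' @export
glance.amplicon_quant <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_pass = x$n_pass,
                 indel_pct = x$indel_pct, hdr_pct = x$hdr_pct,
                 n_fail = x$n_fail)
}

#' @rdname quantify_amplicon
#' @param object An `amplicon_quant` object.
#' @export
autoplot.amplicon_quant <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "% of passing reads") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

as_reads <- function(reads, trim_quality) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fq|fastq)(\\.gz)?$", reads)) {
    # the reader warns about dropping its own internal metadata columns
    qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(reads))
    return(trim_reads(qs, trim_quality))
  }
  if (inherits(reads, "QualityScaledDNAStringSet")) return(trim_reads(reads, trim_quality))
  if (inherits(reads, "DNAStringSet")) return(reads)
  if (is.character(reads)) return(Biostrings::DNAStringSet(toupper(reads)))
  abort("`reads` must be a FASTQ path, a DNAStringSet, or a character vector")
}

# fixed 3'-end quality trim: cut after the last base meeting the threshold
trim_reads <- function(qs, trim_quality) {
  plain <- Biostrings::DNAStringSet(as.character(qs))  # drop quality mcols
  if (is.null(trim_quality)) return(plain)
  qm <- methods::as(Biostrings::quality(qs), "IntegerList")
  keep <- vapply(qm, function(q) {
    ok <- which(q >= trim_quality)
    if (length(ok)) max(ok) else 0L
  }, integer(1))
  out <- Biostrings::subseq(plain, start = 1L,
                            end = pmin(keep, Biostrings::width(plain)))
  names(out) <- names(qs)
  out
}
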
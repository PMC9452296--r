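#' Generate a synthetic genome with planted near-match protospacers
#'
#' Builds a random background genome and plants, at the requested offsets,
#' protospacer variants realizing an exact mismatch/bulge/PAM description,
#' so scanner output can be compared against known truth. Each planted
#' locus is certified with the brute-force reference scanner
#' ([scan_offtargets_brute()]) to guarantee that its minimal alignment
#' penalty equals the intended one (background bases are resampled locally
#' until it does), so a site intended to exceed the budget can never
#' admit a cheaper alignment by accident.
#'
#' @param guide A [guide_spec()].
#' @param sites Tibble describing the planted sites, one row each:
#'   `offset` (0-based start of the planted cassette), `strand` (`"+"`/
#'   `"-"`), `mismatches`, `dna_bulge` (extra target bases, one run),
#'   `rna_bulge` (unpaired guide bases, one run), `pam_ok` (logical:
#'   plant a matching PAM or a deliberately failing one).
#' @param genome_len Background genome length (bases).
#' @param gc_content Background GC fraction (default 0.5, uniform).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param chrom Chromosome name.
#' @param params [scan_params()] used for penalty bookkeeping/certification.
#' @param fasta,truth_bed Optional output paths (FASTA genome, BED6 truth).
#' @return List with `genome` (a `DNAStringSet`) and `truth` (tibble:
#'   `chrom`, `start`, `end` of the protospacer alignment, `strand`,
#'   `mismatches`, `dna_bulge`, `rna_bulge`, `pam_ok`, `penalty`).
#' @export
make_genome <- function(guide, sites, genome_len, gc_content = 0.5,
                        seed = NULL, chrom = "chrS", params = scan_params(),
                        fasta = NULL, truth_bed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(guide, "guide_spec"))
  sites <- tibble::as_tibble(sites)
  defaults <- list(strand = "+", mismatches = 0L, dna_bulge = 0L,
                   rna_bulge = 0L, pam_ok = TRUE)
  for (nm in names(defaults)) {
    if (!nm %in% names(sites)) sites[[nm]] <- rep(defaults[[nm]], nrow(sites))
  }
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
             (1 - gc_content) / 2)
  g <- sample(bases, genome_len, replace = TRUE, prob = probs)
  pam <- params$pam_pattern %||% guide$pam_pattern
  m <- nchar(guide$protospacer)
  bc <- params$bulge_cost_per_base

  cassette_len <- function(i) {
    m + sites$dna_bulge[i] - sites$rna_bulge[i] + nchar(pam)
  }
  # planted cassettes must not overlap (and must fit)
  if (nrow(sites)) {
    iv <- cbind(sites$offset, sites$offset + vapply(seq_len(nrow(sites)),
                                                    cassette_len, numeric(1)))
    if (any(iv[, 1] < 0) || any(iv[, 2] > genome_len)) {
      abort("planted site extends outside the genome")
    }
    o <- order(iv[, 1])
    if (nrow(sites) > 1 && any(iv[o[-1], 1] < iv[o[-nrow(sites)], 2])) {
      abort("planted sites overlap")
    }
  }

  truth <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    intended <- sites$mismatches[i] + bc * (sites$dna_bulge[i] + sites$rna_bulge[i])
    for (attempt in 1:50) {
      cass <- build_cassette(guide$protospacer, pam,
                             sites$mismatches[i], sites$dna_bulge[i],
                             sites$rna_bulge[i], sites$pam_ok[i])
      planted_seq <- if (sites$strand[i] == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cass$seq)))
      } else cass$seq
      gg <- g
      idxs <- sites$offset[i] + seq_len(nchar(planted_seq))
      gg[idxs] <- strsplit(planted_seq, "")[[1]]
      # certify against the reference scanner on a local window
      tlen <- nchar(cass$seq) - nchar(pam)
      lo <- max(0, sites$offset[i] - (m + 5))
      hi <- min(genome_len, sites$offset[i] + nchar(cass$seq) + m + 5)
      local <- paste(gg[(lo + 1):hi], collapse = "")
      chk <- scan_offtargets_brute(
        stats::setNames(local, "w"), guide,
        scan_params(max_penalty = max(params$max_penalty, intended),
                    bulge_cost_per_base = bc,
                    max_bulge_len = max(params$max_bulge_len,
                                        sites$dna_bulge[i], sites$rna_bulge[i])))
      cass_off <- sites$offset[i] - lo +
        (if (sites$strand[i] == "-") nchar(pam) else 0L)
      here <- dplyr::filter(chk, .data$start < cass_off + tlen,
                            .data$end > cass_off,
                            .data$strand == sites$strand[i])
      ok <- if (sites$pam_ok[i]) {
        # the locus representative (minimal penalty, then fewer bulges,
        # then leftmost) must realize the planted description exactly
        if (nrow(here) == 0) FALSE else {
          best <- here[order(here$penalty,
                             here$dna_bulge_bases + here$rna_bulge_bases,
                             here$start, here$end), ][1, ]
          best$penalty == intended &&
            best$mismatches == sites$mismatches[i] &&
            best$dna_bulge_bases == sites$dna_bulge[i] &&
            best$rna_bulge_bases == sites$rna_bulge[i]
        }
      } else {
        nrow(here) == 0
      }
      if (ok) {
        g <- gg
        break
      }
      if (attempt == 50) abort("could not realize a planted site at its intended penalty")
    }
    truth[[i]] <- tibble::tibble(
      chrom = chrom,
      start = sites$offset[i] + if (sites$strand[i] == "-") nchar(pam) else 0L,
      end = sites$offset[i] + if (sites$strand[i] == "-") nchar(cass$seq) else
        nchar(cass$seq) - nchar(pam),
      strand = sites$strand[i],
      mismatches = sites$mismatches[i],
      dna_bulge = sites$dna_bulge[i], rna_bulge = sites$rna_bulge[i],
      pam_ok = sites$pam_ok[i], penalty = intended)
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   strand = character(), mismatches = integer(),
                   dna_bulge = integer(), rna_bulge = integer(),
                   pam_ok = logical(), penalty = integer())
  genome <- Biostrings::DNAStringSet(stats::setNames(paste(g, collapse = ""), chrom))
  if (!is.null(fasta)) Biostrings::writeXStringSet(genome, fasta)
  if (!is.null(truth_bed)) {
    writeLines(c("# planted truth sites",
                 sprintf("%s\t%d\t%d\tplanted%d|pen%d\t%d\t%s", truth$chrom,
                         truth$start, truth$end, seq_len(nrow(truth)),
                         truth$penalty, truth$penalty, truth$strand)),
               truth_bed)
  }
  list(genome = genome, truth = truth)
}

# concrete planted cassette (protospacer variant + PAM), plus orientation;
# minus-strand sites are planted as the reverse complement
build_cassette <- function(protospacer, pam, mismatches, dna_bulge, rna_bulge,
                           pam_ok) {
  m <- nchar(protospacer)
  gch <- strsplit(protospacer, "")[[1]]
  bases <- c("A", "C", "G", "T")
  # guide positions kept aligned (1-based); carve one internal RNA-bulge run
  aligned <- seq_len(m)
  if (rna_bulge > 0) {
    i0 <- sample(2:(m - rna_bulge), 1)  # run at guide pos i0..i0+rb-1, internal
    aligned <- setdiff(aligned, i0:(i0 + rna_bulge - 1))
  }
  tch <- gch[aligned]
  t_of_g <- stats::setNames(seq_along(aligned), aligned)
  # mismatches at aligned positions
  if (mismatches > 0) {
    mm_at <- sample(seq_along(tch), mismatches)
    tch[mm_at] <- vapply(tch[mm_at], function(b) sample(setdiff(bases, b), 1), "")
  }
  # one internal DNA-bulge run: insert between two aligned guide bases,
  # separated from the RNA bulge by >= 1 aligned base
  if (dna_bulge > 0) {
    bnd <- which(diff(aligned) == 1)  # insertion between aligned[k], aligned[k+1]
    if (!length(bnd)) abort("infeasible bulge specification")
    k <- sample(bnd, 1)
    ins <- sample(bases, dna_bulge, replace = TRUE)
    tch <- append(tch, ins, after = k)
  }
  pam_seq <- realize_pam(pam, pam_ok)
  tibble::lst(seq = paste(c(tch, strsplit(pam_seq, "")[[1]]), collapse = ""))
}

realize_pam <- function(pattern, ok) {
  sets <- iupac_sets()
  ch <- strsplit(toupper(pattern), "")[[1]]
  draw <- vapply(ch, function(x) sample(sets[[x]], 1), "")
  if (!ok) {
    # violate the most constrained position
    sizes <- vapply(ch, function(x) length(sets[[x]]), numeric(1))
    if (all(sizes == 4)) abort("cannot plant a PAM failing an all-N pattern")
    j <- which.min(sizes)
    draw[j] <- sample(setdiff(c("A", "C", "G", "T"), sets[[ch[j]]]), 1)
  }
  paste(draw, collapse = "")
}

iupac_sets <- function() {
  list(A = "A", C = "C", G = "G", T = c("T"), U = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

#' Random plant-site specifications
#'
#' Convenience sampler for [make_genome()]: draws non-overlapping offsets
#' and random mismatch/bulge/PAM descriptions with penalties spanning the
#' requested range.
#'
#' @param n Number of sites.
#' @param genome_len Genome length the sites must fit in.
#' @param guide_len Protospacer length (default 20).
#' @param penalties Pool of intended penalties to draw from.
#' @param bulge_cost Penalty per bulge base (to translate penalties into
#'   mismatch/bulge splits).
#' @param pam_len PAM length (default 3).
#' @param margin Bases left free at both genome ends (default 300), so
#'   downstream simulators can place indels within the widest proximity
#'   window of any site.
#' @param seed Optional seed.
#' @return A `sites` tibble for [make_genome()].
#' @export
sample_plant_sites <- function(n, genome_len, guide_len = 20, penalties = 0:6,
                               bulge_cost = 2, pam_len = 3, margin = 300,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slot_w <- guide_len + 2 + pam_len + 10
  max_slots <- floor((genome_len - 2 * margin) / slot_w) - 1
  if (n > max_slots) abort("genome too small for that many non-overlapping sites")
  slots <- sort(sample(max_slots, n))
  pen <- sample(penalties, n, replace = TRUE)
  db <- integer(n); rb <- integer(n)
  for (i in seq_len(n)) {
    nb <- sample(0:(pen[i] %/% bulge_cost), 1)
    if (nb > 0) {
      if (sample(c(TRUE, FALSE), 1)) db[i] <- nb else rb[i] <- nb
    }
  }
  tibble::tibble(
    offset = margin + slots * slot_w,
    strand = sample(c("+", "-"), n, replace = TRUE),
    mismatches = pen - bulge_cost * (db + rb),
    dna_bulge = db, rna_bulge = rb,
    pam_ok = TRUE)
}

#' Generate a synthetic amplicon and donor signature
#'
#' Random amplicon reference and donor-junction signature with homopolymer
#' runs capped at 2 bases, mirroring the primer/amplicon design practice of
#' avoiding homopolymer stretches; this keeps indel placement unambiguous
#' under left-aligning gap placement, so a lesion planted at the cut site
#' cannot slide outside the quantification window.
#'
#' @param length Amplicon length (default 240).
#' @param cut_site 0-based cut offset (default the midpoint).
#' @param sig_len Donor signature length (default 30).
#' @param seed Optional seed.
#' @param ... Passed to [amplicon_spec()].
#' @return An [amplicon_spec()].
#' @export
synthetic_amplicon <- function(length = 240, cut_site = length %/% 2,
                               sig_len = 30, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) {
    bases <- c("A", "C", "G", "T")
    out <- character(n)
    for (i in seq_len(n)) {
      avoid <- if (i > 2 && out[i - 1] == out[i - 2]) out[i - 1] else NULL
      out[i] <- sample(setdiff(bases, avoid), 1)
    }
    paste(out, collapse = "")
  }
  ref <- draw(length)
  repeat {
    sig <- draw(sig_len)
    if (!grepl(sig, ref, fixed = TRUE)) break
  }
  amplicon_spec(ref, cut_site, hdr_signature = sig, ...)
}

#' Simulate an edited/control VCF pair with planted exclusive indels
#'
#' The control sample carries background indels; the edited sample carries
#' the same background plus planted edited-exclusive indels at requested
#' distances from planted candidate sites. Support, MQ and QUAL are drawn
#' from a model that straddles the default filter thresholds
#' (support ~ Poisson(30), MQ ~ 60 - Exp(5), QUAL ~ Gamma(4, scale 10)), so
#' filters are exercised on both sides; each background record reuses one
#' quality draw in both samples so that shared calls stay shared after
#' filtering. The truth table records, per planted indel, whether it
#' survives the supplied filter parameters and its window classes.
#'
#' @param truth_sites Truth tibble from [make_genome()] (or any sites
#'   table with `chrom`, `start`, `end`).
#' @param genome `DNAStringSet` the positions refer to.
#' @param planted Tibble with one row per planted exclusive indel:
#'   `site_index` (row of `truth_sites`), `distance` (bp gap to the site
#'   interval; 0 = overlapping), `indel_len` (signed: negative deletion,
#'   positive insertion), optional `side` (`"right"` default, or
#'   `"left"`), optional `force_pass` (draw qualities that pass filters).
#' @param background_rate Background indels per bp (default 2e-4).
#' @param seed Optional seed.
#' @param params [filter_params()] used for the truth bookkeeping.
#' @param windows Window radii for the truth summary.
#' @param edited_vcf,control_vcf Optional output VCF paths.
#' @return List with `edited`, `control` (call tibbles), `truth` (planted
#'   indels with `survives_filter` and per-window flags) and
#'   `summary_truth` (expected distinct-site counts per window).
#' @export
make_vcf_pair <- function(truth_sites, genome, planted,
                          background_rate = 2e-4, seed = NULL,
                          params = filter_params(), windows = c(15, 200),
                          edited_vcf = NULL, control_vcf = NULL) {
  if (!is.null(seed)) set.seed(seed)
  planted <- tibble::as_tibble(planted)
  if (nrow(planted) && !"side" %in% names(planted)) {
    planted$side <- rep("right", nrow(planted))
  }
  if (nrow(planted) && !"force_pass" %in% names(planted)) {
    planted$force_pass <- rep(FALSE, nrow(planted))
  }
  if (nrow(planted) && any(planted$distance < 0)) abort("distances must be >= 0")
  chrom <- names(genome)[1]
  seq1 <- as.character(genome[[1]])
  L <- nchar(seq1)

  qdraw <- function(n, force_pass = FALSE) {
    out <- tibble::tibble(
      support = stats::rpois(n, 30),
      mq = pmax(0, 60 - stats::rexp(n, 1 / 5)),
      qual = stats::rgamma(n, shape = 4, scale = 10))
    if (force_pass) {
      out$support <- pmax(out$support, params$min_support)
      out$mq <- pmax(out$mq, params$min_mq)
      out$qual <- pmax(out$qual, params$min_qual)
    }
    out
  }
  mk_record <- function(pos1, len) {
    # pos1: 1-based anchor; len < 0 deletion of |len| bases after the anchor
    if (len < 0) {
      ref <- substr(seq1, pos1, pos1 - len)
      alt <- substr(seq1, pos1, pos1)
    } else {
      ref <- substr(seq1, pos1, pos1)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                               collapse = ""))
    }
    list(ref = ref, alt = alt)
  }

  # planted exclusives at exact gap distances from the site interval
  planted_calls <- NULL
  if (nrow(planted)) {
    rows <- purrr::map(seq_len(nrow(planted)), function(i) {
      site <- truth_sites[planted$site_index[i], ]
      d <- planted$distance[i]
      len <- planted$indel_len[i]
      alen <- abs(len)
      if (planted$side[i] == "right") {
        # affected interval starts at site$end + d (0-based)
        pos1 <- site$end + d            # deletion: 0-based del start == pos1
        if (d == 0) pos1 <- site$start + 1  # overlap the site itself
      } else {
        pos1 <- site$start - d - (if (len < 0) alen else 0L)
        if (d == 0) pos1 <- site$start + 1
      }
      if (pos1 < 1 || pos1 + alen + 1 > L) abort("planted indel falls off the genome")
      rec <- mk_record(pos1, len)
      tibble::tibble(chrom = chrom, pos = as.integer(pos1), ref = rec$ref,
                     alt = rec$alt, indel_len = alen,
                     site_index = planted$site_index[i],
                     distance = d)
    })
    planted_calls <- dplyr::bind_rows(rows)
    q <- qdraw(nrow(planted_calls), force_pass = FALSE)
    fp <- planted$force_pass
    qf <- qdraw(nrow(planted_calls), force_pass = TRUE)
    for (col in c("support", "mq", "qual")) {
      q[[col]] <- ifelse(fp, qf[[col]], q[[col]])
    }
    planted_calls <- dplyr::bind_cols(planted_calls, q)
  }

  # shared background, away from planted positions
  n_bg <- stats::rpois(1, background_rate * L)
  bg <- NULL
  if (n_bg > 0) {
    avoid <- if (!is.null(planted_calls)) planted_calls$pos else integer()
    pos1 <- sample(seq(10, L - 20), n_bg)
    pos1 <- pos1[!pos1 %in% outer(avoid, -12:12, `+`)]
    if (length(pos1)) {
      lens <- sample(c(-1, 1, -2, 2, -3), length(pos1), replace = TRUE)
      recs <- purrr::map2(pos1, lens, mk_record)
      bg <- tibble::tibble(
        chrom = chrom, pos = as.integer(pos1),
        ref = purrr::map_chr(recs, "ref"), alt = purrr::map_chr(recs, "alt"),
        indel_len = abs(lens))
      bg <- dplyr::bind_cols(bg, qdraw(nrow(bg)))
    }
  }

  std <- function(x, sample) {
    if (is.null(x) || nrow(x) == 0L) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            indel_len = integer(), qual = double(),
                            mq = double(), support = double(),
                            sample = character()))
    }
    dplyr::mutate(
      dplyr::select(x, "chrom", "pos", "ref", "alt", "indel_len",
                    "qual", "mq", "support"),
      sample = sample)
  }
  edited <- dplyr::arrange(dplyr::bind_rows(std(bg, "edited"),
                                            std(planted_calls, "edited")),
                           .data$pos)
  control <- dplyr::arrange(std(bg, "control"), .data$pos)

  truth <- if (!is.null(planted_calls)) {
    tr <- planted_calls
    tr$survives_filter <- tr$support >= params$min_support &
      tr$mq >= params$min_mq & tr$qual >= params$min_qual &
      tr$indel_len < params$max_indel_len
    for (w in windows) {
      tr[[paste0("within_", w)]] <- tr$survives_filter & tr$distance <= w
    }
    tr
  } else {
    tibble::tibble(site_index = integer(), distance = double(),
                   survives_filter = logical())
  }
  # distinct truth sites per window, counting each surviving indel against
  # EVERY site (a planted indel may fall inside a neighbouring site's
  # window too); explicit double loop kept independent of the pipeline
  summary_truth <- purrr::map_dfr(windows, function(w) {
    hit <- logical(nrow(truth_sites))
    if (!is.null(planted_calls)) {
      surv <- truth[truth$survives_filter, , drop = FALSE]
      for (s in seq_len(nrow(truth_sites))) {
        for (k in seq_len(nrow(surv))) {
          del <- nchar(surv$ref[k]) > nchar(surv$alt[k])
          iv0 <- surv$pos[k]
          iv1 <- if (del) surv$pos[k] + surv$indel_len[k] else surv$pos[k]
          gap <- max(0, truth_sites$start[s] - iv1, iv0 - truth_sites$end[s])
          if (surv$chrom[k] == truth_sites$chrom[s] && gap <= w) {
            hit[s] <- TRUE
            break
          }
        }
      }
    }
    tibble::tibble(window = w, sites_hit = sum(hit))
  })
  contigs <- stats::setNames(L, chrom)
  if (!is.null(edited_vcf)) write_indel_vcf(edited, edited_vcf, contigs)
  if (!is.null(control_vcf)) write_indel_vcf(control, control_vcf, contigs)
  list(edited = edited, control = control, truth = truth,
       summary_truth = summary_truth)
}

#' Simulate amplicon reads with known editing outcomes
#'
#' Draws reads per class (WT / INDEL / HDR) at the requested true
#' fractions. Indel reads carry a lesion overlapping the cut site, with
#' sizes from the default spectrum 60% 1-bp deletion, 20% 1-bp insertion,
#' 20% 2-10-bp deletion; HDR reads carry the donor signature inserted at
#' the cut; uniform substitution errors are applied to every read. Reads
#' are windows of the edited molecule covering the cut region, with
#' constant Phred 37 qualities.
#'
#' @param spec An [amplicon_spec()] (must have `hdr_signature` when
#'   `hdr_fraction > 0`).
#' @param n_reads Number of reads.
#' @param indel_fraction,hdr_fraction True outcome fractions (sum <= 1;
#'   remainder is WT).
#' @param read_len Read length (default 150; must fit the signature plus
#'   10 bp of context).
#' @param substitution_error_rate Per-base substitution error probability.
#' @param seed Optional seed; fixed seed gives byte-identical reads.
#' @param fastq,truth_json Optional output paths (FASTQ and per-read truth
#'   labels as JSON).
#' @return List with `reads` (`QualityScaledDNAStringSet`) and `truth`
#'   (tibble `read_id`, `label`, `indel_len`).
#' @export
make_reads <- function(spec, n_reads, indel_fraction = 0.6, hdr_fraction = 0.2,
                       read_len = 150, substitution_error_rate = 0.001,
                       seed = NULL, fastq = NULL, truth_json = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "amplicon_spec"), n_reads > 0,
            indel_fraction >= 0, hdr_fraction >= 0,
            indel_fraction + hdr_fraction <= 1)
  ref <- spec$reference
  L <- nchar(ref)
  if (read_len > L) abort("read_len exceeds the amplicon length")
  sig <- spec$hdr_signature
  if (hdr_fraction > 0 && is.null(sig)) abort("hdr_fraction > 0 needs an hdr_signature")
  if (!is.null(sig) && nchar(sig) + 10 > read_len) {
    abort("hdr_signature (plus context) longer than read_len")
  }
  cut <- spec$cut_site
  bases <- c("A", "C", "G", "T")
  labels <- sample(c("INDEL", "HDR", "WT"), n_reads, replace = TRUE,
                   prob = c(indel_fraction, hdr_fraction,
                            1 - indel_fraction - hdr_fraction))
  draw_indel_len <- function() {
    u <- stats::runif(1)
    if (u < 0.6) -1L else if (u < 0.8) 1L else -sample(2:10, 1)
  }
  seqs <- character(n_reads)
  lens <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    lab <- labels[i]
    if (lab == "WT") {
      mol <- ref; core_lo <- cut - 12; core_hi <- cut + 12
    } else if (lab == "INDEL") {
      len <- draw_indel_len()
      lens[i] <- len
      if (len < 0) {
        al <- -len
        off <- sample.int(al, 1) - 1L  # deletion covers the cut boundary
        dstart <- cut - off            # 0-based start of deleted run
        dstart <- max(1, min(dstart, L - al - 1))
        mol <- paste0(substr(ref, 1, dstart), substr(ref, dstart + al + 1, L))
        core_lo <- dstart - 12; core_hi <- dstart + 12
      } else {
        ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
        mol <- paste0(substr(ref, 1, cut), ins, substr(ref, cut + 1, L))
        core_lo <- cut - 12; core_hi <- cut + len + 12
      }
    } else {
      mol <- paste0(substr(ref, 1, cut), sig, substr(ref, cut + 1, L))
      core_lo <- cut - 5; core_hi <- cut + nchar(sig) + 5
    }
    ml <- nchar(mol)
    lo <- max(0, min(core_hi, ml) - read_len)
    hi <- min(max(core_lo, 0), ml - read_len)
    if (hi < lo) { lo <- max(0, ml - read_len); hi <- lo }
    st <- sample(seq(lo, hi), 1)
    rd <- substr(mol, st + 1, st + read_len)
    nerr <- stats::rbinom(1, read_len, substitution_error_rate)
    if (nerr > 0) {
      at <- sample(read_len, nerr)
      ch <- strsplit(rd, "")[[1]]
      ch[at] <- vapply(ch[at], function(b) sample(setdiff(bases, b), 1), "")
      rd <- paste(ch, collapse = "")
    }
    seqs[i] <- rd
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
    Biostrings::PhredQuality(rep(paste(rep("F", read_len), collapse = ""),
                                 n_reads)))
  truth <- tibble::tibble(read_id = ids, label = labels, indel_len = lens)
  if (!is.null(fastq)) {
    Biostrings::writeQualityScaledXStringSet(reads, fastq)
  }
  if (!is.null(truth_json)) {
    jsonlite::write_json(truth, truth_json, auto_unbox = FALSE)
  }
  list(reads = reads, truth = truth)
}
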
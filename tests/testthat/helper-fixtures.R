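# shared fixtures and small independent oracles used across test files

demo_guide <- function() {
  guide_spec("ACGTTGCAACGGTCAGTCAA", name = "demo")
}

# comparable identity of a site row (alignment strings excluded: gap
# placement may differ between equally-scored layouts)
site_key <- function(x) {
  paste(x$chrom, x$start, x$end, x$strand, x$penalty, x$mismatches,
        x$dna_bulge_bases, x$rna_bulge_bases, sep = "|")
}

# random indel call table straddling the filter thresholds
random_calls <- function(n, seed, sample = "edited", chroms = c("chr1", "chr2")) {
  set.seed(seed)
  is_del <- sample(c(TRUE, FALSE), n, replace = TRUE)
  len <- sample(c(1:10, 45:55), n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  anchor <- sample(bases, n, replace = TRUE)
  tail <- vapply(len, function(l) paste(sample(bases, l, replace = TRUE),
                                        collapse = ""), "")
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample(1e6, n),
    ref = ifelse(is_del, paste0(anchor, tail), anchor),
    alt = ifelse(is_del, anchor, paste0(anchor, tail)),
    indel_len = len,
    qual = stats::runif(n, 0, 60),
    mq = stats::runif(n, 0, 60),
    support = sample(0:60, n, replace = TRUE),
    sample = sample)
}

# independent per-record filter predicate (plain logic, no shared code path)
predicate_keep <- function(calls, params, all_variants = NULL) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    k <- calls$support[i] >= params$min_support &&
      calls$mq[i] >= params$min_mq &&
      calls$qual[i] >= params$min_qual &&
      calls$indel_len[i] < params$max_indel_len
    if (k && !is.null(all_variants)) {
      for (j in seq_len(nrow(all_variants))) {
        if (all_variants$chrom[j] == calls$chrom[i] &&
            all_variants$pos[j] != calls$pos[i] &&
            abs(all_variants$pos[j] - calls$pos[i]) <= params$near_variant_dist) {
          k <- FALSE
          break
        }
      }
    }
    if (k && !is.null(params$exclusion_bed)) {
      r <- nchar(calls$ref[i]); a <- nchar(calls$alt[i])
      iv0 <- calls$pos[i]
      iv1 <- if (r > a) calls$pos[i] + (r - a) else calls$pos[i]
      for (j in seq_len(nrow(params$exclusion_bed))) {
        b <- params$exclusion_bed[j, ]
        hit <- if (iv1 > iv0) (b$start < iv1 && b$end > iv0)
               else (b$start <= iv0 && b$end > iv0)
        if (b$chrom == calls$chrom[i] && hit) { k <- FALSE; break }
      }
    }
    keep[i] <- k
  }
  keep
}

# all-pairs site/indel distance by double loop (oracle for intersect_windows)
allpairs_distance <- function(sites, indels) {
  out <- NULL
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(indels))) {
      if (sites$chrom[i] != indels$chrom[j]) next
      r <- nchar(indels$ref[j]); a <- nchar(indels$alt[j])
      iv0 <- indels$pos[j]
      iv1 <- if (r > a) indels$pos[j] + (r - a) else indels$pos[j]
      d <- max(0, sites$start[i] - iv1, iv0 - sites$end[i])
      out <- rbind(out, data.frame(site = i, indel = j, distance = d))
    }
  }
  out
}
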
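test_that("an exact protospacer with a valid PAM is found once at penalty 0", {
  g <- demo_guide()
  set.seed(1)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  genome <- c(chrT = paste0(pad(50), g$protospacer, "AGG", pad(50)))
  sites <- scan_offtargets(genome, g)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 50L)
  expect_equal(sites$end, 70L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$penalty, 0L)
  expect_equal(sites$mismatches, 0L)
  expect_equal(sites$dna_bulge_bases + sites$rna_bulge_bases, 0L)
  expect_equal(sites$pam_observed, "AGG")
})

test_that("a PAM failing the pattern suppresses the site", {
  g <- demo_guide()
  set.seed(1)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  genome <- c(chrT = paste0(pad(50), g$protospacer, "ATT", pad(50)))
  expect_equal(nrow(scan_offtargets(genome, g)), 0L)
})

test_that("penalty budget is respected: 5 substitutions in, bulge + 4 out", {
  g <- demo_guide()
  sites <- tibble::tibble(
    offset = c(500, 1500),
    strand = "+",
    mismatches = c(5L, 4L),
    dna_bulge = c(0L, 1L),
    rna_bulge = 0L,
    pam_ok = TRUE)
  gen <- make_genome(g, sites, 5000, seed = 42)
  expect_equal(gen$truth$penalty, c(5, 6))
  found <- scan_offtargets(gen$genome, g)
  hit5 <- dplyr::filter(found, .data$start == gen$truth$start[1])
  expect_equal(hit5$penalty, 5L)
  expect_equal(hit5$mismatches, 5L)
  # the penalty-6 bulged variant must be absent
  expect_false(any(found$start < gen$truth$end[2] & found$end > gen$truth$start[2]))
  # and the brute-force oracle agrees exactly
  brute <- scan_offtargets_brute(gen$genome, g)
  expect_setequal(site_key(found), site_key(brute))
})

test_that("scanner equals the exhaustive oracle on seeded planted genomes", {
  g <- demo_guide()
  for (seed in c(7, 19, 33)) {
    plant <- sample_plant_sites(12, 12000, seed = seed)
    gen <- make_genome(g, plant, 12000, seed = seed)
    fast <- scan_offtargets(gen$genome, g)
    brute <- scan_offtargets_brute(gen$genome, g)
    expect_setequal(site_key(fast), site_key(brute))
    # planted-site recall: everything <= budget recovered at its penalty
    # (the reported representative may be an equal-penalty alignment of the
    # same locus, so sites are matched by overlap on the planted strand)
    tr <- gen$truth
    for (i in seq_len(nrow(tr))) {
      hit <- dplyr::filter(fast, .data$start < tr$end[i],
                           .data$end > tr$start[i],
                           .data$strand == tr$strand[i])
      if (tr$penalty[i] <= 5) {
        expect_equal(hit$penalty, tr$penalty[i])
      } else {
        expect_equal(nrow(hit), 0L)
      }
    }
  }
})

test_that("strand symmetry: scanning the reverse complement mirrors sites", {
  g <- demo_guide()
  plant <- sample_plant_sites(8, 6000, seed = 7)
  gen <- make_genome(g, plant, 6000, seed = 7)
  fwd <- scan_offtargets(gen$genome, g)
  rc <- Biostrings::reverseComplement(gen$genome)
  names(rc) <- names(gen$genome)
  rev <- scan_offtargets(rc, g)
  L <- Biostrings::width(gen$genome)[1]
  mirrored <- paste(rev$chrom, L - rev$end, L - rev$start,
                    ifelse(rev$strand == "+", "-", "+"), rev$penalty,
                    rev$mismatches, rev$dna_bulge_bases, rev$rna_bulge_bases,
                    sep = "|")
  expect_setequal(site_key(fwd), mirrored)
})

test_that("site sets are monotone in the penalty budget", {
  g <- demo_guide()
  plant <- sample_plant_sites(10, 8000, penalties = 0:6, seed = 11)
  gen <- make_genome(g, plant, 8000, seed = 11)
  prev <- character()
  for (k in 0:6) {
    cur <- site_key(scan_offtargets(gen$genome, g,
                                    scan_params(max_penalty = k)))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("penalty decomposition identity holds for every emitted site", {
  g <- demo_guide()
  plant <- sample_plant_sites(12, 9000, seed = 13)
  gen <- make_genome(g, plant, 9000, seed = 13)
  p <- scan_params()
  sites <- scan_offtargets(gen$genome, g, p)
  expect_gt(nrow(sites), 0)
  expect_equal(sites$penalty,
               sites$mismatches + p$bulge_cost_per_base *
                 (sites$dna_bulge_bases + sites$rna_bulge_bases))
  # aligned strings are consistent with the decomposition
  for (i in seq_len(nrow(sites))) {
    ag <- strsplit(sites$aligned_guide[i], "")[[1]]
    at <- strsplit(sites$aligned_target[i], "")[[1]]
    expect_equal(sum(ag == "-"), sites$dna_bulge_bases[i])
    expect_equal(sum(at == "-"), sites$rna_bulge_bases[i])
    both <- ag != "-" & at != "-"
    expect_equal(sum(ag[both] != at[both]), sites$mismatches[i])
  }
})

test_that("sites near a declared on-target locus are flagged, not counted", {
  g <- guide_spec("ACGTTGCAACGGTCAGTCAA", name = "demo",
                  on_target = list(chrom = "chrT", pos = 51))
  set.seed(2)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  genome <- c(chrT = paste0(pad(50), g$protospacer, "AGG", pad(2000),
                            g$protospacer, "TGG", pad(50)))
  sites <- scan_offtargets(genome, g)
  expect_equal(nrow(sites), 2L)
  expect_equal(sum(sites$on_target_region), 1L)
  expect_equal(nrow(offtarget_candidates(sites)), 1L)
  expect_true(offtarget_candidates(sites)$start > 1000)
})

test_that("invalid guides, PAMs and genomes are refused", {
  expect_error(guide_spec("ACGTNCGTACGTACGTACGT"), "ambiguous")
  expect_error(guide_spec("ACGT"), "18-24")
  expect_error(guide_spec("ACGTACGTACGTACGTACGT", pam_pattern = "NQG"), "IUPAC")
  expect_error(scan_offtargets(character(), demo_guide()), "named|empty")
  expect_error(scan_offtargets(c(chrT = ""), demo_guide()), "empty")
})

test_that("windows containing N never yield sites", {
  g <- demo_guide()
  set.seed(3)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  ps <- g$protospacer
  substr(ps, 10, 10) <- "N"
  genome <- c(chrT = paste0(pad(40), ps, "AGG", pad(40)))
  expect_equal(nrow(scan_offtargets(genome, g)), 0L)
  expect_equal(nrow(scan_offtargets_brute(genome, g)), 0L)
})

test_that("candidate sites round-trip through BED", {
  g <- demo_guide()
  plant <- sample_plant_sites(10, 9000, seed = 23)
  gen <- make_genome(g, plant, 9000, seed = 23)
  sites <- scan_offtargets(gen$genome, g)
  expect_gt(nrow(sites), 5)
  path <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, path)
  back <- read_sites_bed(path)
  expect_equal(as.data.frame(back[names(sites)]), as.data.frame(sites))
  # BED-only round trip preserves coordinates and decomposition
  file.remove(paste0(path, ".tsv"))
  bed_only <- read_sites_bed(path)
  expect_setequal(site_key(bed_only), site_key(sites))
  # empty input round-trips to an empty table
  write_sites_bed(sites[0, ], path, tsv = FALSE)
  expect_equal(nrow(read_sites_bed(path)), 0L)
})
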
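test_that("filtering matches an independent per-record predicate", {
  calls <- random_calls(200, seed = 7)
  excl <- tibble::tibble(chrom = "chr1", start = c(0L, 500000L),
                         end = c(1000L, 600000L))
  params <- filter_params(exclusion_bed = excl)
  av <- dplyr::bind_rows(
    dplyr::select(calls, "chrom", "pos"),
    tibble::tibble(chrom = "chr2", pos = calls$pos[1:50] + 5L))
  kept <- filter_indels(calls, params, all_variants = av)
  oracle <- predicate_keep(calls, params, all_variants = av)
  expect_equal(nrow(kept), sum(oracle))
  expect_equal(paste(kept$chrom, kept$pos, kept$ref, kept$alt),
               paste(calls$chrom[oracle], calls$pos[oracle],
                     calls$ref[oracle], calls$alt[oracle]))
  removed <- attr(kept, "removed")
  expect_equal(nrow(removed) + nrow(kept), nrow(calls))
  expect_true(all(removed$removed_by %in%
                    c("support", "mq", "qual", "indel_len",
                      "near_variant", "exclusion_bed")))
})

test_that("single threshold failures remove a call with the right rule", {
  call <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "AT", alt = "A",
                         indel_len = 1L, qual = 50, mq = 60, support = 3,
                         sample = "edited")
  kept <- filter_indels(call)
  expect_equal(nrow(kept), 0L)
  expect_equal(attr(kept, "removed")$removed_by, "support")
  expect_equal(nrow(filter_indels(call[0, ])), 0L)
})

test_that("raising any threshold never enlarges the surviving set", {
  calls <- random_calls(300, seed = 17)
  base <- filter_params()
  base_set <- paste(filter_indels(calls, base)$pos)
  bumps <- list(
    filter_params(min_support = 10),
    filter_params(min_mq = 45),
    filter_params(min_qual = 35),
    filter_params(max_indel_len = 20))
  for (p in bumps) {
    s <- paste(filter_indels(calls, p)$pos)
    expect_true(all(s %in% base_set))
  }
})

test_that("exclusive_indels finds edited-only calls in both match modes", {
  a <- random_calls(60, seed = 11, sample = "edited")
  # identical sets -> empty; empty control -> identity
  ctrl <- dplyr::mutate(a, sample = "control")
  expect_equal(nrow(exclusive_indels(a, ctrl)), 0L)
  expect_equal(exclusive_indels(a, ctrl[0, ]), a)
  # one unique edited call comes back
  extra <- tibble::tibble(chrom = "chr1", pos = 424242L, ref = "A", alt = "AGG",
                          indel_len = 2L, qual = 50, mq = 60, support = 30,
                          sample = "edited")
  expect_equal(exclusive_indels(dplyr::bind_rows(a, extra), ctrl)$pos, 424242L)
  # windowed mode equals a brute-force pairwise matcher
  b <- random_calls(60, seed = 12, sample = "control")
  w <- 3
  excl <- exclusive_indels(a, b, match_mode = "windowed", window = w)
  matched <- vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$indel_len == a$indel_len[i] &
          abs(b$pos - a$pos[i]) <= w)
  }, logical(1))
  expect_equal(excl$pos, a$pos[!matched])
  expect_error(exclusive_indels(dplyr::bind_rows(a, ctrl), b), "mixed sample")
})

test_that("window intersection honours the boundary at exactly 15 bp", {
  site <- tibble::tibble(chrom = "chrS", start = 1000L, end = 1020L,
                         strand = "+", penalty = 0L)
  mk <- function(pos, ref, alt) {
    tibble::tibble(chrom = "chrS", pos = pos, ref = ref, alt = alt,
                   indel_len = abs(nchar(ref) - nchar(alt)),
                   qual = 50, mq = 60, support = 30, sample = "edited")
  }
  # insertion points at gaps 15 and 16 to the right of the site
  hits15 <- intersect_windows(site, mk(1035L, "A", "AT"))
  expect_setequal(hits15$window_class, c("within_15", "within_200"))
  hits16 <- intersect_windows(site, mk(1036L, "A", "AT"))
  expect_equal(hits16$window_class, "within_200")
  # deletion overlapping the site -> distance 0
  hits0 <- intersect_windows(site, mk(1010L, "ATT", "A"))
  expect_equal(unique(hits0$distance), 0)
  # no indels -> zero hits with zero summary
  none <- intersect_windows(site, mk(1035L, "A", "AT")[0, ])
  expect_equal(nrow(none), 0L)
  expect_equal(window_summary(none)$sites_hit, c(0L, 0L))
  expect_error(intersect_windows(site, mk(1035L, "A", "AT"), windows = -5),
               ">= 0")
})

test_that("window intersection equals the all-pairs distance oracle", {
  set.seed(29)
  n <- 60
  sites <- tibble::tibble(
    chrom = sample(c("c1", "c2"), n, TRUE),
    start = sample(1e5, n), strand = "+", penalty = 0L)
  sites$end <- sites$start + 20L
  indels <- random_calls(n, seed = 31)
  indels$chrom <- sample(c("c1", "c2"), n, TRUE)
  indels$pos <- sample(1e5, n)
  hits <- intersect_windows(sites, indels, windows = c(15, 200))
  oracle <- allpairs_distance(sites, indels)
  for (w in c(15, 200)) {
    expect_equal(
      sum(hits$window_class == paste0("within_", w)),
      sum(oracle$distance <= w))
    expect_equal(
      window_summary(hits)$sites_hit[window_summary(hits)$window == w],
      length(unique(oracle$site[oracle$distance <= w])))
  }
  # window nesting: within_15 sites are a subset of within_200 sites
  in15 <- unique(paste(hits$chrom, hits$site_start)[hits$window_class == "within_15"])
  in200 <- unique(paste(hits$chrom, hits$site_start)[hits$window_class == "within_200"])
  expect_true(all(in15 %in% in200))
})

test_that("VCF writing and reading round-trips indel calls", {
  calls <- random_calls(50, seed = 41)
  calls <- dplyr::arrange(calls, .data$chrom, .data$pos)
  calls$qual <- round(calls$qual, 2)
  calls$mq <- round(calls$mq, 2)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_indel_vcf(calls, path, contigs = c(chr1 = 2e6, chr2 = 2e6))
  back <- read_indel_vcf(path, sample = "edited")
  expect_equal(nrow(back), nrow(calls))
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$qual, calls$qual, tolerance = 1e-6)
  expect_equal(back$mq, calls$mq, tolerance = 1e-6)
  expect_equal(back$support, as.numeric(calls$support))
  # multi-allelic records are refused, not silently split
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tAT,ATT\t50\t.\tMQ=60;DP=30"), path)
  expect_error(read_indel_vcf(path), "multi-allelic")
})

test_that("synthetic VCF pairs drive the pipeline to their planted truth", {
  g <- demo_guide()
  plant <- sample_plant_sites(6, 9000, penalties = 0:4, seed = 19)
  gen <- make_genome(g, plant, 9000, seed = 19)
  planted <- tibble::tibble(
    site_index = c(1, 2, 3, 4, 5, 6),
    distance = c(0, 10, 15, 16, 120, 300),
    indel_len = c(-2, 1, -1, 3, -4, -1),
    force_pass = TRUE)
  vp <- make_vcf_pair(gen$truth, gen$genome, planted, seed = 19)
  res <- crossref_indels(vp$edited, vp$control, gen$truth)
  expect_equal(res$summary$sites_hit, vp$summary_truth$sites_hit)
  expect_equal(res$summary$sites_hit, c(3L, 5L))
  # no planted exclusives -> no hits anywhere
  vp0 <- make_vcf_pair(gen$truth, gen$genome, planted[0, ], seed = 19)
  res0 <- crossref_indels(vp0$edited, vp0$control, gen$truth)
  expect_equal(res0$summary$sites_hit, c(0L, 0L))
  # randomized spec: pipeline summary equals the generator truth table
  for (seed in c(5, 6)) {
    set.seed(seed)
    pl <- tibble::tibble(
      site_index = sample(nrow(gen$truth), 4),
      distance = sample(0:250, 4),
      indel_len = sample(c(-3:-1, 1:3), 4),
      force_pass = sample(c(TRUE, FALSE), 4, TRUE))
    vpr <- make_vcf_pair(gen$truth, gen$genome, pl, seed = seed * 100)
    resr <- crossref_indels(vpr$edited, vpr$control, gen$truth)
    expect_equal(resr$summary$sites_hit, vpr$summary_truth$sites_hit)
  }
})
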
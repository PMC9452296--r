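test_that("genome generation is seed-deterministic down to bytes", {
  g <- demo_guide()
  plant <- sample_plant_sites(5, 4000, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  gen1 <- make_genome(g, plant, 4000, seed = 3, fasta = f1)
  gen2 <- make_genome(g, plant, 4000, seed = 3, fasta = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(gen1$truth, gen2$truth)
})

test_that("planted descriptions are realized exactly", {
  g <- demo_guide()
  sites <- tibble::tibble(
    offset = c(200, 400, 600, 800, 1000),
    strand = c("+", "-", "+", "-", "+"),
    mismatches = c(0L, 2L, 1L, 0L, 3L),
    dna_bulge = c(0L, 0L, 1L, 2L, 0L),
    rna_bulge = c(0L, 1L, 0L, 0L, 1L),
    pam_ok = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  gen <- make_genome(g, sites, 1500, seed = 8)
  found <- scan_offtargets(gen$genome, g, scan_params(max_penalty = 6))
  for (i in 1:4) {
    hit <- dplyr::filter(found, .data$start == gen$truth$start[i],
                         .data$strand == gen$truth$strand[i])
    expect_equal(hit$penalty, gen$truth$penalty[i])
    expect_equal(hit$mismatches, gen$truth$mismatches[i])
    expect_equal(hit$dna_bulge_bases, gen$truth$dna_bulge[i])
    expect_equal(hit$rna_bulge_bases, gen$truth$rna_bulge[i])
  }
  # pam_ok = FALSE site is never reported on its strand
  expect_false(any(found$start < gen$truth$end[5] &
                     found$end > gen$truth$start[5] &
                     found$strand == gen$truth$strand[5]))
  # overlapping plants are refused
  expect_error(make_genome(g, tibble::tibble(offset = c(100, 110)), 1000,
                           seed = 1), "overlap")
  expect_error(make_genome(g, tibble::tibble(offset = 990), 1000, seed = 1),
               "outside")
})

test_that("VCF pair generation is deterministic and respects distances", {
  g <- demo_guide()
  plant <- sample_plant_sites(4, 5000, penalties = 0:3, seed = 9)
  gen <- make_genome(g, plant, 5000, seed = 9)
  planted <- tibble::tibble(site_index = c(1, 3), distance = c(7, 40),
                            indel_len = c(-2, 2), force_pass = TRUE)
  v1 <- make_vcf_pair(gen$truth, gen$genome, planted, seed = 5)
  v2 <- make_vcf_pair(gen$truth, gen$genome, planted, seed = 5)
  expect_identical(v1$edited, v2$edited)
  expect_identical(v1$control, v2$control)
  # background is shared; planted records are edited-only
  expect_true(all(paste(v1$control$pos, v1$control$ref, v1$control$alt) %in%
                    paste(v1$edited$pos, v1$edited$ref, v1$edited$alt)))
  expect_equal(nrow(v1$edited) - nrow(v1$control), nrow(planted))
  # realized gap distances match the request
  oracle <- allpairs_distance(gen$truth[c(1, 3), ], v1$truth)
  expect_equal(oracle$distance[oracle$site == 1 & oracle$indel == 1], 7)
  expect_equal(oracle$distance[oracle$site == 2 & oracle$indel == 2], 40)
  expect_error(
    make_vcf_pair(gen$truth, gen$genome,
                  tibble::tibble(site_index = 4, distance = 6000,
                                 indel_len = -1)),
    "off the genome")
})

test_that("truth tables flag which planted indels survive default filters", {
  g <- demo_guide()
  plant <- sample_plant_sites(3, 4000, penalties = 0:2, seed = 15)
  gen <- make_genome(g, plant, 4000, seed = 15)
  set.seed(2)
  planted <- tibble::tibble(site_index = rep(1:3, 5),
                            distance = sample(0:250, 15),
                            indel_len = sample(c(-2, -1, 1, 2), 15, TRUE),
                            force_pass = FALSE)
  vp <- make_vcf_pair(gen$truth, gen$genome, planted, seed = 2)
  expect_equal(
    vp$truth$survives_filter,
    vp$truth$support >= 4 & vp$truth$mq >= 30 & vp$truth$qual >= 20)
  res <- crossref_indels(vp$edited, vp$control, gen$truth)
  expect_equal(res$summary$sites_hit, vp$summary_truth$sites_hit)
})

test_that("synthetic amplicons avoid homopolymer runs over 2 bases", {
  spec <- synthetic_amplicon(300, 150, seed = 42)
  expect_false(grepl("AAA|CCC|GGG|TTT", spec$reference))
  expect_false(grepl(spec$hdr_signature, spec$reference, fixed = TRUE))
  expect_equal(nchar(spec$hdr_signature), 30L)
})
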
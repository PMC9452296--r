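test_that("constructed reads classify as expected", {
  spec <- synthetic_amplicon(240, 120, seed = 5)
  ref <- spec$reference
  wt <- ref
  del3 <- paste0(substr(ref, 1, 118), substr(ref, 122, 240))    # 3-bp del over cut
  ins2 <- paste0(substr(ref, 1, 120), "AC", substr(ref, 121, 240))
  hdr <- paste0(substr(ref, 1, 120), spec$hdr_signature, substr(ref, 121, 240))
  far_del <- paste0(substr(ref, 1, 30), substr(ref, 34, 240))   # 3-bp del far from cut
  cls <- classify_reads(c(wt, del3, ins2, hdr, far_del), spec)
  expect_equal(cls$label, c("WT", "INDEL", "INDEL", "HDR", "WT"))
  expect_equal(cls$indel_len[2], -3L)
  expect_equal(cls$indel_len[3], 2L)
  # HDR tolerated with one mismatch and on the reverse complement
  hdr1 <- hdr
  substr(hdr1, 125, 125) <- if (substr(hdr1, 125, 125) == "A") "C" else "A"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(hdr)))
  expect_equal(classify_reads(c(hdr1, rc), spec)$label, c("HDR", "HDR"))
  # short and garbage reads fail
  junk <- paste(rep("ACGT", 40), collapse = "")
  cls2 <- classify_reads(c(substr(ref, 1, 30), junk), spec)
  expect_equal(cls2$label, c("FAIL", "FAIL"))
})

test_that("quantification is exact on constructed mixtures and order-invariant", {
  spec <- synthetic_amplicon(240, 120, seed = 5)
  ref <- spec$reference
  del1 <- paste0(substr(ref, 1, 119), substr(ref, 121, 240))
  reads <- c(rep(ref, 100), rep(del1, 100))
  q <- quantify_amplicon(reads, spec)
  expect_equal(q$indel_pct, 50)
  expect_equal(q$hdr_pct, 0)
  expect_equal(q$n_pass, q$n_wt + q$n_indel + q$n_hdr + q$n_ambiguous)
  expect_equal(q$n_total, q$n_pass + q$n_fail)
  # permuting reads leaves the result unchanged
  set.seed(1)
  q2 <- quantify_amplicon(sample(reads), spec)
  expect_equal(glance(q2), glance(q))
  # all-WT set: both percentages zero
  q3 <- quantify_amplicon(rep(ref, 120), spec)
  expect_equal(q3$indel_pct, 0)
  expect_equal(q3$hdr_pct, 0)
  expect_error(quantify_amplicon(rep(substr(ref, 1, 20), 150), spec),
               "zero passing")
})

test_that("simulated truth is recovered within the binomial CI", {
  spec <- synthetic_amplicon(240, 120, seed = 5)
  sim <- make_reads(spec, 4000, indel_fraction = 0.6, hdr_fraction = 0.2,
                    substitution_error_rate = 0.001, seed = 3)
  q <- quantify_amplicon(sim$reads, spec)
  truth_indel <- 100 * mean(sim$truth$label == "INDEL")
  truth_hdr <- 100 * mean(sim$truth$label == "HDR")
  expect_gte(truth_indel, q$indel_ci95[1])
  expect_lte(truth_indel, q$indel_ci95[2])
  expect_gte(truth_hdr, q$hdr_ci95[1])
  expect_lte(truth_hdr, q$hdr_ci95[2])
  # per-read agreement on error-free reads
  sim0 <- make_reads(spec, 2000, indel_fraction = 0.6, hdr_fraction = 0.2,
                     substitution_error_rate = 0, seed = 4)
  cls <- classify_reads(sim0$reads, spec)
  expect_gte(mean(cls$label == sim0$truth$label), 0.99)
})

test_that("pure-WT reads at 0.5% substitution error stay below 1% false indels", {
  spec <- synthetic_amplicon(240, 120, seed = 5)
  sim <- make_reads(spec, 2000, indel_fraction = 0, hdr_fraction = 0,
                    substitution_error_rate = 0.005, seed = 9)
  q <- quantify_amplicon(sim$reads, spec)
  expect_lt(100 * q$n_indel / q$n_pass, 1)
})

test_that("read generation is seed-deterministic and validates inputs", {
  spec <- synthetic_amplicon(240, 120, seed = 5)
  a <- make_reads(spec, 50, seed = 77)
  b <- make_reads(spec, 50, seed = 77)
  expect_identical(as.character(a$reads), as.character(b$reads))
  expect_identical(a$truth, b$truth)
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  make_reads(spec, 50, seed = 77, fastq = f1)
  make_reads(spec, 50, seed = 77, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  # FASTQ path input works
  q <- quantify_amplicon(f1, spec, min_pass = 10)
  expect_equal(q$n_total, 50L)
  expect_error(make_reads(spec, 10, read_len = 30), "longer than read_len")
  expect_error(amplicon_spec(spec$reference, 120,
                             hdr_signature = substr(spec$reference, 50, 70)),
               "substring")
})

test_that("tidy, glance and autoplot expose the quantification", {
  spec <- synthetic_amplicon(240, 120, seed = 5)
  sim <- make_reads(spec, 300, seed = 13)
  q <- quantify_amplicon(sim$reads, spec)
  td <- tidy(q)
  expect_equal(td$outcome, c("WT", "INDEL", "HDR", "AMBIGUOUS"))
  expect_equal(sum(td$n), q$n_pass)
  gl <- glance(q)
  expect_equal(gl$indel_pct, q$indel_pct)
  expect_s3_class(autoplot(q), "ggplot")
})
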
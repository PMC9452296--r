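#' Deconvolve knock-in genotype fractions from three-primer PCR bands
#'
#' A single semiquantitative PCR with three primers produces a
#' cassette-specific (CAR) band and a wild-type/indel band. Densitometry on
#' sorted (CAR+) and unsorted cells yields four intensities: `A`, the
#' wild-type/indel band percentage in sorted cells; `B`, the CAR band
#' percentage in sorted cells; `C` and `D`, the same two percentages in
#' unsorted cells. Assuming unbiased allelic amplification, the cell-level
#' genotype fractions follow in closed form:
#' \deqn{wt = (B C - A D)/B, \quad het = 2 A D / B, \quad homo = (B - A) D / B}
#' (all in percent). The three outputs always sum to `C + D` exactly.
#' Physically inconsistent inputs (negative components) are flagged, never
#' clamped, so downstream QC can reject lanes.
#'
#' @param bands Data frame with numeric columns `A`, `B`, `C`, `D` in
#'   `[0, 100]` (one row per sample; extra columns such as `sample` are
#'   carried through).
#' @return Tibble with `wt_indel_pct`, `het_pct`, `homo_pct` and a logical
#'   `consistent` flag appended to the input columns.
#' @examples
#' deconvolve_genotypes(data.frame(A = 30, B = 70, C = 65, D = 35))
#' @export
deconvolve_genotypes <- function(bands) {
  bands <- tibble::as_tibble(bands)
  need <- c("A", "B", "C", "D")
  if (!all(need %in% names(bands))) {
    abort("`bands` needs numeric columns A, B, C, D")
  }
  vals <- as.matrix(bands[need])
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100)) {
    abort("band percentages must be finite and within [0, 100]")
  }
  if (any(vals[, "B"] == 0)) {
    abort("B = 0 (no CAR band in sorted cells): deconvolution undefined")
  }
  A <- bands$A; B <- bands$B; C <- bands$C; D <- bands$D
  out <- dplyr::mutate(
    bands,
    wt_indel_pct = (B * C - A * D) / B,
    het_pct = 2 * A * D / B,
    homo_pct = (B - A) * D / B)
  out$consistent <- out$wt_indel_pct >= 0 & out$het_pct >= 0 & out$homo_pct >= 0
  if (any(!out$consistent)) {
    warning("physically inconsistent lane(s): negative genotype component (flagged, not clamped)")
  }
  out
}

#' Simulate three-primer PCR band intensities from a genotype mix
#'
#' Forward model inverted by [deconvolve_genotypes()]. For a cell mix with
#' `wt_indel_pct` (no cassette), `het_pct` (cassette on one allele) and
#' `homo_pct` (both alleles), unbiased allelic amplification gives
#' `A = het / (2 (het + homo))`, `B = (het + 2 homo)/(2 (het + homo))` in
#' the sorted (CAR+) lane and `C = (2 wt + het)/2`, `D = (het + 2 homo)/2`
#' unsorted (all in percent). Multiplicative Gaussian intensity noise is
#' applied per band and each lane renormalized to 100%.
#'
#' @param mix Data frame with columns `wt_indel_pct`, `het_pct`,
#'   `homo_pct` summing to 100 per row.
#' @param noise_sd Relative (multiplicative) intensity noise s.d.
#'   (0 = exact).
#' @return Tibble with columns `A`, `B`, `C`, `D` appended to the input.
#' @examples
#' simulate_bands(data.frame(wt_indel_pct = 50, het_pct = 30, homo_pct = 20))
#' @export
simulate_bands <- function(mix, noise_sd = 0) {
  mix <- tibble::as_tibble(mix)
  need <- c("wt_indel_pct", "het_pct", "homo_pct")
  if (!all(need %in% names(mix))) {
    abort("`mix` needs columns wt_indel_pct, het_pct, homo_pct")
  }
  stopifnot(noise_sd >= 0)
  w <- mix$wt_indel_pct; h <- mix$het_pct; m <- mix$homo_pct
  if (any(w < 0 | h < 0 | m < 0) || any(abs(w + h + m - 100) > 1e-6)) {
    abort("mix fractions must be non-negative and sum to 100")
  }
  if (any(h + m == 0)) {
    abort("het + homo = 0: no CAR+ cells, the sorted lane does not exist")
  }
  A <- 100 * h / (2 * (h + m))
  B <- 100 * (h + 2 * m) / (2 * (h + m))
  C <- (2 * w + h) / 2
  D <- (h + 2 * m) / 2
  if (noise_sd > 0) {
    jitter <- function(x) x * stats::rnorm(length(x), 1, noise_sd)
    A <- pmax(jitter(A), 0); B <- pmax(jitter(B), 0)
    C <- pmax(jitter(C), 0); D <- pmax(jitter(D), 0)
    sAB <- A + B; sCD <- C + D
    A <- 100 * A / sAB; B <- 100 * B / sAB
    C <- 100 * C / sCD; D <- 100 * D / sCD
  }
  dplyr::bind_cols(mix, tibble::tibble(A = A, B = B, C = C, D = D))
}

#' Plot deconvolved genotype fractions
#'
#' Stacked bar of wild-type/indel, heterozygous and homozygous knock-in
#' fractions per sample.
#'
#' @param genotypes Output of [deconvolve_genotypes()].
#' @param sample_col Column holding sample labels (default `"sample"`; row
#'   numbers are used when absent).
#' @return A ggplot object.
#' @export
plot_genotype_fractions <- function(genotypes, sample_col = "sample") {
  df <- genotypes
  if (!sample_col %in% names(df)) df[[sample_col]] <- as.character(seq_len(nrow(df)))
  long <- tidyr::pivot_longer(
    df, c("wt_indel_pct", "het_pct", "homo_pct"),
    names_to = "genotype", values_to = "pct")
  long$genotype <- factor(long$genotype,
                          levels = c("wt_indel_pct", "het_pct", "homo_pct"),
                          labels = c("WT/indel", "heterozygous", "homozygous"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[sample_col]], y = .data$pct,
                                     fill = .data$genotype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of cells", fill = NULL) +
    ggplot2::theme_minimal()
}
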
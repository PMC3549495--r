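#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided test for departure from Hardy-Weinberg proportions at a
#' biallelic marker, by enumeration over all heterozygote counts compatible
#' with the observed allele counts. The p-value is the total probability of
#' all tables whose conditional probability does not exceed that of the
#' observed table.
#'
#' @param n_aa,n_ab,n_bb genotype counts (either homozygote may be the rare
#'   one; the test is orientation-invariant).
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_rare <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  het_obs <- n_ab
  # heterozygote counts share the parity of the rare-allele count
  hs <- seq(n_rare %% 2, n_rare, by = 2)
  probs <- numeric(length(hs))
  mid <- which.min(abs(hs - n_rare * (2 * n - n_rare) / (2 * n - 1)))
  probs[mid] <- 1
  # upward recurrence: P(h+2)/P(h) = 4*homr*homc / ((h+1)(h+2))
  if (mid < length(hs)) {
    for (k in mid:(length(hs) - 1)) {
      h <- hs[k]
      homr <- (n_rare - h) / 2
      homc <- n - h - homr
      probs[k + 1] <- probs[k] * 4 * homr * homc / ((h + 1) * (h + 2))
    }
  }
  # downward recurrence: P(h-2)/P(h) = h(h-1) / (4*(homr+1)(homc+1))
  if (mid > 1) {
    for (k in mid:2) {
      h <- hs[k]
      homr <- (n_rare - h) / 2
      homc <- n - h - homr
      probs[k - 1] <- probs[k] * h * (h - 1) / (4 * (homr + 1) * (homc + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(het_obs, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Removes SNPs in four sequential passes: non-autosomal markers, genotyping
#' call rate below `call_rate_min`, exact Hardy-Weinberg p-value below
#' `hwe_p_min`, and minor allele frequency below `maf_min`. Each SNP is
#' attributed to the first filter that removes it. Surviving columns are
#' re-oriented so the counted allele has frequency at most 0.5, making the
#' MAF filter idempotent.
#'
#' @param g a [genotype_data()] object.
#' @param call_rate_min minimum per-SNP genotyping rate (default 0.95).
#' @param hwe_p_min exact HWE p-value below which a SNP is removed
#'   (default 5e-7).
#' @param maf_min minimum minor allele frequency (default 0.1; must be
#'   at most 0.5).
#' @param autosomes_only drop SNPs on non-autosomal chromosomes (default TRUE).
#' @return A list with `genotypes` (filtered [genotype_data()]) and `report`,
#'   a tibble with one row per filter (`filter`, `threshold`, `n_removed`)
#'   plus attributes `n_input` and `n_surviving`.
#' @export
qc_filter <- function(g, call_rate_min = 0.95, hwe_p_min = 5e-7,
                      maf_min = 0.1, autosomes_only = TRUE) {
  stopifnot(inherits(g, "genotype_data"))
  if (maf_min < 0 || maf_min > 0.5) {
    stop("`maf_min` must lie in [0, 0.5]: minor allele frequency cannot exceed 0.5.")
  }
  if (call_rate_min < 0 || call_rate_min > 1) stop("`call_rate_min` must lie in [0, 1].")
  counts <- g$counts
  p <- ncol(counts)
  removed_by <- rep(NA_character_, p)

  if (autosomes_only) {
    non_auto <- !(g$snps$chromosome %in% as.character(1:22))
    removed_by[non_auto] <- "non_autosomal"
  }
  call_rate <- colMeans(!is.na(counts))
  low_call <- call_rate < call_rate_min
  removed_by[is.na(removed_by) & low_call] <- "call_rate"

  n0 <- colSums(counts == 0, na.rm = TRUE)
  n1 <- colSums(counts == 1, na.rm = TRUE)
  n2 <- colSums(counts == 2, na.rm = TRUE)
  hwe_p <- vapply(seq_len(p), function(j) hwe_exact_test(n0[j], n1[j], n2[j]),
                  numeric(1))
  removed_by[is.na(removed_by) & hwe_p < hwe_p_min] <- "hwe"

  f <- colMeans(counts, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  removed_by[is.na(removed_by) & maf < maf_min] <- "maf"

  keep <- which(is.na(removed_by))
  report <- tibble::tibble(
    filter = c("non_autosomal", "call_rate", "hwe", "maf"),
    threshold = c(NA, call_rate_min, hwe_p_min, maf_min),
    n_removed = vapply(
      c("non_autosomal", "call_rate", "hwe", "maf"),
      function(f) sum(removed_by == f, na.rm = TRUE), integer(1)
    )
  )
  attr(report, "n_input") <- p
  attr(report, "n_surviving") <- length(keep)
  if (!length(keep)) {
    warning("All SNPs were removed by QC filtering; returning an empty genotype set.")
  }
  out <- subset_genotypes(g, snps = keep)
  # orient to the minor allele: flip columns where the counted allele is major
  flip <- which(colMeans(out$counts, na.rm = TRUE) / 2 > 0.5)
  if (length(flip)) out$counts[, flip] <- 2 - out$counts[, flip]
  list(genotypes = out, report = report)
}

#' Impute missing genotypes by the per-SNP rounded mean count
#'
#' A deliberately simple rule for post-QC data: each missing call is replaced
#' by the column mean of the observed counts, rounded to the nearest integer
#' count (ties to even, as in [round()]). A column with no observed calls
#' cannot be imputed and raises an error.
#'
#' @param g a [genotype_data()] object that has passed QC.
#' @return A `genotype_data` with no missing entries.
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "genotype_data"))
  counts <- g$counts
  miss <- is.na(counts)
  if (!any(miss)) return(g)
  all_missing <- colSums(!miss) == 0
  if (any(all_missing)) {
    stop("Cannot impute SNP(s) with no observed genotypes: ",
         paste(head(g$snps$snp_id[all_missing], 5), collapse = ", "))
  }
  fill <- round(colMeans(counts, na.rm = TRUE))
  idx <- which(miss, arr.ind = TRUE)
  counts[idx] <- fill[idx[, 2]]
  g$counts <- counts
  g
}
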
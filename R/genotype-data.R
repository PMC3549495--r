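#' Genotype container
#'
#' Holds an N x P matrix of minor-allele counts together with per-SNP
#' metadata. Entries are 0, 1, 2 or `NA` (missing call). Rows are samples,
#' columns are SNPs.
#'
#' @param counts numeric matrix of allele counts in \{0, 1, 2, NA\}.
#' @param sample_ids character vector, length `nrow(counts)`.
#' @param snp_ids character vector, length `ncol(counts)`.
#' @param chromosome per-SNP chromosome labels (e.g. `"1"`..`"22"`, `"X"`).
#' @param position_bp per-SNP 1-based base-pair positions.
#'
#' @return An object of class `genotype_data`: a list with elements
#'   `counts`, `sample_ids`, and a `snps` tibble (`snp_id`, `chromosome`,
#'   `position_bp`).
#' @export
genotype_data <- function(counts, sample_ids = NULL, snp_ids = NULL,
                          chromosome = NULL, position_bp = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  p <- ncol(counts)
  if (is.null(sample_ids)) sample_ids <- rownames(counts) %||% paste0("S", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- colnames(counts) %||% paste0("snp", seq_len(p))
  if (is.null(chromosome)) chromosome <- rep("1", p)
  if (is.null(position_bp)) position_bp <- seq_len(p)
  if (length(sample_ids) != n) stop("`sample_ids` must have one entry per row of `counts`.")
  if (length(snp_ids) != p) stop("`snp_ids` must have one entry per column of `counts`.")
  if (length(chromosome) != p || length(position_bp) != p) {
    stop("SNP metadata must have one entry per column of `counts`.")
  }
  bad <- counts[!is.na(counts)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("Non-missing genotype entries must be 0, 1 or 2.")
  }
  if (any(position_bp < 0)) stop("`position_bp` must be non-negative.")
  dimnames(counts) <- list(sample_ids, snp_ids)
  structure(
    list(
      counts = counts,
      sample_ids = as.character(sample_ids),
      snps = tibble::tibble(
        snp_id = as.character(snp_ids),
        chromosome = as.character(chromosome),
        position_bp = as.integer(round(position_bp))
      )
    ),
    class = "genotype_data"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf(
    "<genotype_data> %d samples x %d SNPs (%.2f%% missing)\n",
    nrow(x$counts), ncol(x$counts),
    100 * mean(is.na(x$counts))
  ))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$counts)

#' Subset a genotype object by samples and/or SNPs
#'
#' @param g a [genotype_data()] object.
#' @param samples row indices (or logical mask) of samples to keep.
#' @param snps column indices (or logical mask) of SNPs to keep.
#' @return A `genotype_data` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  stopifnot(inherits(g, "genotype_data"))
  if (is.null(samples)) samples <- seq_len(nrow(g$counts))
  if (is.null(snps)) snps <- seq_len(ncol(g$counts))
  snp_meta <- g$snps[snps, , drop = FALSE]
  genotype_data(
    g$counts[samples, snps, drop = FALSE],
    sample_ids = g$sample_ids[samples],
    snp_ids = snp_meta$snp_id,
    chromosome = snp_meta$chromosome,
    position_bp = snp_meta$position_bp
  )
}

#' Per-SNP minor allele frequency
#'
#' Frequency of the counted allele among non-missing calls. After
#' [qc_filter()] re-orientation the counted allele is the minor allele, so
#' this is the MAF.
#'
#' @param g a [genotype_data()] object.
#' @return Numeric vector of length P.
#' @export
allele_frequency <- function(g) {
  stopifnot(inherits(g, "genotype_data"))
  colMeans(g$counts, na.rm = TRUE) / 2
}
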
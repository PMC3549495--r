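#' Write genotypes as a PLINK bed/bim/fam triple
#'
#' SNP-major 2-bit encoding; the counted allele is written as A1 so that
#' reading the triple back reproduces the count matrix exactly.
#'
#' @param g a [genotype_data()] object.
#' @param prefix output path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_data"))
  n <- nrow(g$counts)
  p <- ncol(g$counts)
  # counts -> 2-bit codes: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code_of <- function(x) {
    out <- integer(length(x))
    out[is.na(x)] <- 1L
    out[!is.na(x) & x == 1] <- 2L
    out[!is.na(x) & x == 0] <- 3L
    out
  }
  bps <- ceiling(n / 4)
  pad <- 4 * bps - n
  codes <- apply(g$counts, 2, code_of)
  codes <- rbind(matrix(codes, nrow = n), matrix(0L, nrow = pad, ncol = p))
  i1 <- seq(1, 4 * bps, by = 4)
  bytes <- codes[i1, , drop = FALSE] +
    4L * codes[i1 + 1, , drop = FALSE] +
    16L * codes[i1 + 2, , drop = FALSE] +
    64L * codes[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.integer(bytes)), con)
  readr::write_tsv(
    tibble::tibble(
      chromosome = g$snps$chromosome, snp_id = g$snps$snp_id, cm = 0,
      position_bp = g$snps$position_bp, a1 = "A", a2 = "B"
    ),
    paste0(prefix, ".bim"), col_names = FALSE
  )
  readr::write_tsv(
    tibble::tibble(fid = g$sample_ids, iid = g$sample_ids, pat = "0",
                   mat = "0", sex = 0, phenotype = -9),
    paste0(prefix, ".fam"), col_names = FALSE
  )
  invisible(prefix)
}

#' Write a result table as TSV
#'
#' Numeric columns are rounded to 6 significant digits; column order is
#' preserved as-is, so writes are byte-stable for identical inputs.
#'
#' @param obj a data frame (QC report, ranking table, weight schedule, ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) {
  obj <- tibble::as_tibble(obj)
  obj <- dplyr::mutate(obj, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 6)))
  readr::write_tsv(obj, path)
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
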
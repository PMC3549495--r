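#' Read genotypes from PLINK or delimited formats
#'
#' Supported formats: a PLINK bed/bim/fam triple (pass the `.bed` path or the
#' common prefix), a PLINK `.raw` export (whitespace-delimited, header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP), or a
#' delimited count matrix with a header row of SNP identifiers. Missing
#' genotypes are kept as `NA`, never imputed here.
#'
#' @param path file path (for PLINK, the `.bed` file or prefix).
#' @param format one of `"auto"`, `"bed"`, `"raw"`, `"matrix"`.
#' @param snp_info optional SNP metadata for `"raw"`/`"matrix"` input: a data
#'   frame (or TSV path) with columns `snp_id`, `chromosome`, `position_bp`.
#' @return A [genotype_data()] object.
#' @export
read_genotypes <- function(path, format = c("auto", "bed", "raw", "matrix"),
                           snp_info = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <-
      if (grepl("\\.bed$", path) || file.exists(paste0(path, ".bed"))) "bed"
      else if (grepl("\\.raw$", path)) "raw"
      else "matrix"
  }
  g <- switch(format,
    bed = read_plink(path),
    raw = read_plink_raw(path),
    matrix = read_count_matrix(path)
  )
  if (!is.null(snp_info) && format != "bed") {
    if (is.character(snp_info)) {
      snp_info <- readr::read_tsv(snp_info, show_col_types = FALSE)
    }
    snp_info <- tibble::as_tibble(snp_info)
    need <- c("snp_id", "chromosome", "position_bp")
    if (!all(need %in% names(snp_info))) {
      stop("`snp_info` must have columns snp_id, chromosome, position_bp.")
    }
    idx <- match(g$snps$snp_id, snp_info$snp_id)
    if (anyNA(idx)) {
      stop("dimension error: `snp_info` is missing metadata for SNP(s): ",
           paste(head(g$snps$snp_id[is.na(idx)], 5), collapse = ", "))
    }
    g$snps$chromosome <- as.character(snp_info$chromosome[idx])
    g$snps$position_bp <- as.integer(snp_info$position_bp[idx])
  }
  g
}

read_count_matrix <- function(path) {
  tab <- tryCatch(
    readr::read_table(path, show_col_types = FALSE),
    error = function(e) stop("parse error reading count matrix '", path, "': ",
                             conditionMessage(e))
  )
  if (!ncol(tab)) stop("parse error: '", path, "' has no columns.")
  first <- names(tab)[1]
  ids <- NULL
  if (tolower(first) %in% c("sample_id", "iid", "id")) {
    ids <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
  }
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab, is.numeric, logical(1)))[1]
    stop("parse error in '", path, "': column '", names(tab)[bad],
         "' is not numeric.")
  }
  genotype_data(m, sample_ids = ids, snp_ids = names(tab))
}

read_plink_raw <- function(path) {
  tab <- tryCatch(
    readr::read_table(path, show_col_types = FALSE, na = c("NA", "-9", "")),
    error = function(e) stop("parse error reading .raw file '", path, "': ",
                             conditionMessage(e))
  )
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(tab)[seq_along(fixed)])) {
    stop("parse error: '", path, "' lacks the PLINK .raw header ",
         paste(fixed, collapse = " "), ".")
  }
  snp_cols <- setdiff(names(tab), fixed)
  m <- as.matrix(tab[, snp_cols, drop = FALSE])
  # .raw columns carry the counted allele as a suffix, e.g. rs123_A
  snp_ids <- sub("_[ACGT0-9]+$", "", snp_cols)
  genotype_data(m, sample_ids = as.character(tab$IID), snp_ids = snp_ids)
}

# ---- PLINK bed/bim/fam ------------------------------------------------------

plink_paths <- function(path) {
  prefix <- sub("\\.(bed|bim|fam)$", "", path)
  list(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
       fam = paste0(prefix, ".fam"))
}

read_plink <- function(path) {
  p <- plink_paths(path)
  for (f in unlist(p)) if (!file.exists(f)) stop("PLINK file not found: ", f)
  bim <- readr::read_tsv(
    p$bim,
    col_names = c("chromosome", "snp_id", "cm", "position_bp", "a1", "a2"),
    col_types = "ccdicc"
  )
  fam <- readr::read_table(
    p$fam,
    col_names = c("fid", "iid", "pat", "mat", "sex", "phenotype"),
    col_types = "ccccdd"
  )
  n <- nrow(fam)
  p_snp <- nrow(bim)
  raw <- readBin(p$bed, what = "raw", n = file.size(p$bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("parse error: '", p$bed, "' lacks the PLINK bed magic number.")
  }
  if (raw[3] != as.raw(0x01)) {
    stop("parse error: '", p$bed, "' is not in SNP-major order.")
  }
  bps <- ceiling(n / 4) # bytes per SNP
  body <- raw[-(1:3)]
  if (length(body) != bps * p_snp) {
    stop("dimension error: '", p$bed, "' holds ", length(body),
         " data bytes; expected ", bps * p_snp, " for ", n, " samples x ",
         p_snp, " SNPs.")
  }
  ints <- as.integer(body)
  # unpack 4 two-bit codes per byte, low bits first
  codes <- matrix(NA_integer_, nrow = 4 * bps, ncol = p_snp)
  bytes <- matrix(ints, nrow = bps, ncol = p_snp)
  codes[seq(1, 4 * bps, by = 4), ] <- bytes %% 4L
  codes[seq(2, 4 * bps, by = 4), ] <- (bytes %/% 4L) %% 4L
  codes[seq(3, 4 * bps, by = 4), ] <- (bytes %/% 16L) %% 4L
  codes[seq(4, 4 * bps, by = 4), ] <- bytes %/% 64L
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1 (counted allele), 01 -> missing, 10 -> 1, 11 -> 0
  lookup <- c(2, NA, 1, 0)
  counts <- matrix(lookup[codes + 1L], nrow = n, ncol = p_snp)
  genotype_data(counts, sample_ids = fam$iid, snp_ids = bim$snp_id,
                chromosome = bim$chromosome, position_bp = bim$position_bp)
}

# ---- Covariates, genes, pathways -------------------------------------------

#' Read a subject covariate table
#'
#' Expects a TSV with columns `sample_id`, `age`, `sex`, `diagnosis`. Sex may
#' be coded 0/1 already or as two labels (e.g. `F`/`M`), in which case the
#' first label sorted alphabetically becomes 0 and the mapping is recorded in
#' the `sex_coding` attribute. Diagnosis must be `AD` or `CN` with no missing
#' values.
#'
#' @param path TSV file path.
#' @return A tibble with attribute `sex_coding`.
#' @export
read_covariates <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "age", "sex", "diagnosis")
  if (!all(need %in% names(tab))) {
    stop("Covariate table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyNA(tab$diagnosis)) stop("Missing diagnosis is not allowed.")
  if (!all(tab$diagnosis %in% c("AD", "CN"))) {
    stop("`diagnosis` must be 'AD' or 'CN'.")
  }
  coding <- NULL
  if (!is.numeric(tab$sex)) {
    lev <- sort(unique(as.character(tab$sex)))
    if (length(lev) > 2) stop("`sex` must be binary.")
    coding <- stats::setNames(seq_along(lev) - 1L, lev)
    tab$sex <- as.numeric(coding[as.character(tab$sex)])
  } else if (!all(tab$sex %in% c(0, 1))) {
    stop("Numeric `sex` must be coded 0/1.")
  }
  tab$sample_id <- as.character(tab$sample_id)
  attr(tab, "sex_coding") <- coding
  tab
}

#' Read gene locations
#'
#' Either a TSV with columns `gene_id`, `chromosome`, `start_bp`, `end_bp`
#' (1-based, inclusive) or a 4+-column BED file (`chrom start end name`,
#' 0-based half-open, converted to 1-based inclusive).
#'
#' @param path file path.
#' @param format `"auto"` (BED iff the extension is `.bed`), `"tsv"` or `"bed"`.
#' @return A tibble with columns `gene_id`, `chromosome`, `start_bp`, `end_bp`.
#' @export
read_gene_table <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.bed$", path)) "bed" else "tsv"
  if (format == "bed") {
    tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
    if (ncol(tab) < 4) stop("parse error: BED gene file needs >= 4 columns.")
    genes <- tibble::tibble(
      gene_id = as.character(tab[[4]]),
      chromosome = sub("^chr", "", as.character(tab[[1]])),
      start_bp = as.integer(tab[[2]]) + 1L,
      end_bp = as.integer(tab[[3]])
    )
  } else {
    genes <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("gene_id", "chromosome", "start_bp", "end_bp")
    if (!all(need %in% names(genes))) {
      stop("Gene table must have columns: ", paste(need, collapse = ", "))
    }
    genes <- tibble::as_tibble(genes[need])
    genes$gene_id <- as.character(genes$gene_id)
    genes$chromosome <- as.character(genes$chromosome)
  }
  if (anyDuplicated(genes$gene_id)) stop("`gene_id` values must be unique.")
  if (any(genes$start_bp > genes$end_bp)) {
    stop("Gene intervals must satisfy start_bp <= end_bp.")
  }
  genes
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then member gene symbols.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of gene ids, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("parse error: '", path, "' is empty.")
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("parse error at line ", i, " of '", path,
           "': need name, description and >= 1 gene.")
    }
    nm <- fields[1]
    if (nm %in% names(out)) stop("Duplicate pathway name '", nm, "'.")
    out[[nm]] <- unique(fields[-(1:2)])
  }
  out
}
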
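#' Map SNPs to genes within a window
#'
#' A SNP maps to a gene when both lie on the same chromosome and the SNP
#' position falls within `window_bp` base pairs of the gene body, i.e. in
#' `[start_bp - window_bp, end_bp + window_bp]` with inclusive boundaries.
#' SNPs may map to several genes; SNPs mapping to none are absent from the
#' result.
#'
#' @param g a [genotype_data()] object.
#' @param genes a gene table as returned by [read_gene_table()].
#' @param window_bp mapping window in base pairs (default 10000).
#' @return A tibble with columns `snp_id`, `gene_id`, carrying attributes
#'   `window_bp` and `snp_ids` (all genotype SNP ids, in column order).
#' @export
map_snps_to_genes <- function(g, genes, window_bp = 10000) {
  stopifnot(inherits(g, "genotype_data"))
  if (window_bp < 0) stop("`window_bp` must be non-negative.")
  snps <- g$snps
  pairs <- dplyr::inner_join(
    snps, tibble::as_tibble(genes),
    by = "chromosome", relationship = "many-to-many"
  )
  hits <- dplyr::filter(
    pairs,
    .data$position_bp >= .data$start_bp - window_bp,
    .data$position_bp <= .data$end_bp + window_bp
  )
  out <- dplyr::distinct(dplyr::select(hits, "snp_id", "gene_id"))
  out <- dplyr::arrange(
    out,
    match(.data$snp_id, snps$snp_id), .data$gene_id
  )
  attr(out, "window_bp") <- window_bp
  attr(out, "snp_ids") <- snps$snp_id
  out
}

#' Build the pathway mapping and expanded-column index
#'
#' Assigns to each pathway the union of SNPs mapped (via [map_snps_to_genes()])
#' to any of its genes, drops pathways with no mapped SNPs, optionally drops
#' the single largest pathway by mapped-SNP count, and lays out the expanded
#' design index in which overlapping pathways become disjoint blocks: pathway
#' order follows the gene-set file, SNP order within a pathway follows
#' genotype column order.
#'
#' @param snp_gene_map result of [map_snps_to_genes()].
#' @param pathway_db named list of gene-id vectors, e.g. from [read_gmt()].
#' @param drop_largest drop the pathway with the most mapped SNPs
#'   (ties broken by the lexicographically first name)? Default TRUE.
#' @return An object of class `pathway_mapping`: a list with `pathways`
#'   (names, length L), `groups` (list of original SNP column indices),
#'   `sizes` (group sizes S_l), `expansion_index` (tibble: `expanded_col`,
#'   `pathway_index`, `pathway`, `snp_index`, `snp_id`), `gene_membership`
#'   (pathway -> genes with >= 1 mapped SNP), `snp_ids`, and
#'   `dropped_pathway` (NULL or the removed name).
#' @export
build_pathway_mapping <- function(snp_gene_map, pathway_db, drop_largest = TRUE) {
  snp_ids <- attr(snp_gene_map, "snp_ids")
  if (is.null(snp_ids)) {
    stop("`snp_gene_map` must come from map_snps_to_genes() (missing snp_ids).")
  }
  gene_to_snps <- split(snp_gene_map$snp_id, snp_gene_map$gene_id)
  groups <- list()
  membership <- list()
  for (nm in names(pathway_db)) {
    genes_here <- intersect(pathway_db[[nm]], names(gene_to_snps))
    snps_here <- unique(unlist(gene_to_snps[genes_here], use.names = FALSE))
    idx <- sort(match(snps_here, snp_ids))
    if (length(idx)) {
      groups[[nm]] <- idx
      membership[[nm]] <- genes_here
    }
  }
  if (!length(groups)) stop("No pathway maps to any SNP; mapping is empty.")
  dropped <- NULL
  if (drop_largest && length(groups) > 1) {
    sizes <- lengths(groups)
    biggest <- sort(names(groups)[sizes == max(sizes)])[1]
    dropped <- biggest
    message("Dropping largest pathway by mapped SNPs: '", biggest,
            "' (", max(sizes), " SNPs).")
    groups[[biggest]] <- NULL
    membership[[biggest]] <- NULL
  }
  if (!length(groups)) stop("Pathway mapping is empty after dropping the largest pathway.")
  sizes <- lengths(groups)
  expansion <- tibble::tibble(
    expanded_col = seq_len(sum(sizes)),
    pathway_index = rep(seq_along(groups), sizes),
    pathway = rep(names(groups), sizes),
    snp_index = unlist(groups, use.names = FALSE)
  )
  expansion$snp_id <- snp_ids[expansion$snp_index]
  structure(
    list(
      pathways = names(groups),
      groups = unname(groups),
      sizes = unname(sizes),
      expansion_index = expansion,
      gene_membership = membership,
      snp_ids = snp_ids,
      dropped_pathway = dropped
    ),
    class = "pathway_mapping"
  )
}

#' @export
print.pathway_mapping <- function(x, ...) {
  cat(sprintf(
    "<pathway_mapping> %d pathways, %d expanded columns over %d distinct SNPs\n",
    length(x$pathways), sum(x$sizes),
    length(unique(x$expansion_index$snp_index))
  ))
  invisible(x)
}

#' Expand a design matrix into disjoint pathway blocks
#'
#' Column `k` of the result is the design column of the SNP recorded at row
#' `k` of `mapping$expansion_index`, so each SNP column appears once per
#' pathway that contains it and `X = [X_1, ..., X_L]`.
#'
#' @param X standardised N x P matrix whose columns follow genotype order.
#' @param mapping a [build_pathway_mapping()] result.
#' @return An N x P* matrix.
#' @export
expand_design <- function(X, mapping) {
  stopifnot(inherits(mapping, "pathway_mapping"))
  idx <- mapping$expansion_index$snp_index
  if (max(idx) > ncol(X)) {
    stop("Mapping refers to SNP column ", max(idx), " but the design has only ",
         ncol(X), " columns: mapping/genotype mismatch.")
  }
  out <- X[, idx, drop = FALSE]
  colnames(out) <- mapping$expansion_index$snp_id
  out
}

#' Summarise a pathway mapping
#'
#' @param mapping a [build_pathway_mapping()] result.
#' @return A list with `pathways` (tibble: `pathway`, `n_snps`, `n_genes`),
#'   `snps` (tibble: `snp_id`, `n_pathways` overlap counts) and `summary`
#'   (tibble of min/mean/max for both).
#' @export
pathway_summary <- function(mapping) {
  stopifnot(inherits(mapping, "pathway_mapping"))
  pw <- tibble::tibble(
    pathway = mapping$pathways,
    n_snps = mapping$sizes,
    n_genes = lengths(mapping$gene_membership)
  )
  ov <- dplyr::count(mapping$expansion_index, .data$snp_id, name = "n_pathways")
  summ <- tibble::tibble(
    quantity = c("pathway_size", "snp_overlap"),
    min = c(min(pw$n_snps), min(ov$n_pathways)),
    mean = c(mean(pw$n_snps), mean(ov$n_pathways)),
    max = c(max(pw$n_snps), max(ov$n_pathways))
  )
  list(pathways = pw, snps = ov, summary = summ)
}

#' Serialise a pathway mapping to two TSV files
#'
#' Writes `<prefix>_snp_gene.tsv` (the SNP-gene membership implied by
#' `gene_membership`) and `<prefix>_pathway_snps.tsv` (the expansion index),
#' enough to reconstruct the expanded design deterministically.
#'
#' @param mapping a [build_pathway_mapping()] result.
#' @param snp_gene_map the [map_snps_to_genes()] tibble used to build it.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_pathway_mapping <- function(mapping, snp_gene_map, prefix) {
  write_table(snp_gene_map, paste0(prefix, "_snp_gene.tsv"))
  write_table(mapping$expansion_index, paste0(prefix, "_pathway_snps.tsv"))
  invisible(prefix)
}
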
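#' Second-stage lasso sparse reduced-rank regression
#'
#' Rank-1 alternating estimation as in [fit_psrrr()], but with an ordinary
#' lasso penalty `lambda * ||beta||_1` (every SNP its own group, unit
#' weight) on a reduced design of distinct SNPs. `lambda = gamma *
#' lambda_max` is computed on the reduced design at the initial phenotype
#' direction.
#'
#' @param X N x Z standardised reduced design (distinct SNP columns).
#' @param Y N x Q phenotype matrix.
#' @param gamma fraction of `lambda_max` (default 0.8).
#' @param outer_tol,max_outer,bcd_tol alternation controls.
#' @return List with `beta`, `a`, `selected` (column indices with non-zero
#'   coefficient), `lambda`, `lambda_max`.
#' @export
stage2_lasso_srrr <- function(X, Y, gamma = 0.8, outer_tol = 1e-4,
                              max_outer = 100, bcd_tol = 1e-5) {
  Y <- as.matrix(Y)
  p <- ncol(X)
  if (p == 0) {
    return(list(beta = numeric(0), a = NULL, selected = integer(0),
                lambda = 0, lambda_max = 0))
  }
  sizes <- rep(1L, p)
  w <- rep(1, p)
  a <- initial_a(Y)
  lmax <- lambda_max(X, Y, a, w, sizes)
  lam <- gamma * lmax
  beta <- numeric(p)
  beta_prev <- beta
  a_prev <- a
  for (it in seq_len(max_outer)) {
    y <- as.numeric(Y %*% a)
    beta <- as.numeric(group_lasso_bcd(X, y, sizes, w, lam, tol = bcd_tol))
    if (!any(beta != 0)) break
    bu <- beta / sqrt(sum(beta^2))
    a <- update_a(X, Y, bu)
    if (max(abs(c(bu - beta_prev, a - a_prev))) < outer_tol) break
    beta_prev <- bu
    a_prev <- a
  }
  list(beta = beta, a = a, selected = which(beta != 0),
       lambda = lam, lambda_max = lmax)
}

# stratified half-sample indices: floor(n/2) subjects, allocated across
# strata by largest remainder so the overall size is exact
half_sample <- function(n, strata = NULL) {
  target <- n %/% 2L
  if (is.null(strata)) return(sort(sample.int(n, target)))
  strata <- as.factor(strata)
  groups <- split(seq_len(n), strata)
  quota <- lengths(groups) * target / n
  base <- floor(quota)
  short <- target - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  sort(unlist(mapply(function(g, k) sample(g, k), groups, base,
                     SIMPLIFY = FALSE), use.names = FALSE))
}

#' Rank pathways (and SNPs/genes) by selection frequency over subsamples
#'
#' Repeats, for `b = 1, ..., B`: draw `floor(N/2)` subjects without
#' replacement (stratified by diagnosis when given), restandardise genotypes
#' and recentre phenotypes within the subsample, fit the PsRRR model at
#' `lambda = gamma * lambda_max` (with `lambda_max` recomputed per
#' subsample), and record the selected pathway set. When `stage2 = TRUE`, a
#' second-stage lasso ([stage2_lasso_srrr()]) on the distinct SNPs of the
#' selected pathways records selected SNPs. Selection frequencies are exact
#' fractions of `B`. Subsample `b` uses RNG seed `seed + b`, so results are
#' independent of execution order.
#'
#' @param genotypes a [genotype_data()] (imputed, post-QC) or a complete
#'   N x P count matrix in genotype column order.
#' @param Y N x Q phenotype matrix.
#' @param mapping a [build_pathway_mapping()] object.
#' @param weights pathway weights (tuned, or `sqrt(S_l)`).
#' @param gamma penalty fraction (default 0.8).
#' @param B number of half-sample subsamples (default 1000).
#' @param seed master integer seed.
#' @param diagnosis optional per-subject labels for stratified subsampling.
#' @param stage2 run the second-stage lasso per subsample (default TRUE).
#' @param max_outer alternations per fit (default 25).
#' @return An object of class `psrrr_ranking`: list with `pathway_freq`
#'   (tibble: pathway, n_snps, freq, rank — ties get average ranks),
#'   `records` (tibble: one row per subsample with list-columns
#'   `sample_indices`, `selected_pathways`, `selected_snps`, and `z_b`),
#'   `B`, `gamma`, `seed`.
#' @export
rank_pathways <- function(genotypes, Y, mapping, weights = NULL,
                          gamma = 0.8, B = 1000, seed = 1,
                          diagnosis = NULL, stage2 = TRUE, max_outer = 25) {
  counts <- if (inherits(genotypes, "genotype_data")) genotypes$counts else as.matrix(genotypes)
  if (anyNA(counts)) stop("Genotypes must be complete; run impute_missing() first.")
  Y <- as.matrix(Y)
  n <- nrow(counts)
  if (nrow(Y) != n) stop("Genotypes and phenotypes must cover the same subjects.")
  if (is.null(weights)) weights <- initial_weights(mapping)
  if (B < 1) stop("`B` must be at least 1.")
  L <- length(mapping$pathways)

  records <- vector("list", B)
  for (b in seq_len(B)) {
    records[[b]] <- withr::with_seed(seed + b, {
      idx <- half_sample(n, diagnosis)
      Xs <- suppressWarnings(
        standardise_design(counts[idx, , drop = FALSE], drop_constant = FALSE)
      )
      n_constant <- length(attr(Xs, "dropped_columns"))
      Ys <- scale(Y[idx, , drop = FALSE], center = TRUE, scale = FALSE)
      Xe <- expand_design(Xs, mapping)
      fit <- fit_psrrr(Xe, Ys, mapping, weights, gamma = gamma,
                       max_outer = max_outer)
      sel <- fit$selected_index
      snp_cols <- sort(unique(unlist(mapping$groups[sel], use.names = FALSE)))
      sel_snps <- character(0)
      if (stage2 && length(snp_cols)) {
        s2 <- stage2_lasso_srrr(Xs[, snp_cols, drop = FALSE], Ys, gamma = gamma)
        sel_snps <- mapping$snp_ids[snp_cols[s2$selected]]
      }
      tibble::tibble(
        b_index = b,
        sample_indices = list(idx),
        selected_pathways = list(mapping$pathways[sel]),
        z_b = length(snp_cols),
        selected_snps = list(sel_snps),
        n_constant_snps = n_constant,
        seed = seed + b
      )
    })
  }
  records <- dplyr::bind_rows(records)
  sel_counts <- table(factor(unlist(records$selected_pathways),
                             levels = mapping$pathways))
  pathway_freq <- tibble::tibble(
    pathway = mapping$pathways,
    n_snps = mapping$sizes,
    freq = as.numeric(sel_counts) / B
  )
  pathway_freq$rank <- rank(-pathway_freq$freq, ties.method = "average")
  pathway_freq <- dplyr::arrange(pathway_freq, .data$rank)
  structure(
    list(pathway_freq = pathway_freq, records = records, B = B,
         gamma = gamma, seed = seed),
    class = "psrrr_ranking"
  )
}

#' @export
print.psrrr_ranking <- function(x, ...) {
  cat(sprintf("<psrrr_ranking> B = %d subsamples, gamma = %.2f\n", x$B, x$gamma))
  print(head(x$pathway_freq, 10))
  invisible(x)
}

#' SNP and gene selection frequencies from subsample records
#'
#' A SNP's frequency is the fraction of subsamples in which the second-stage
#' lasso selected it; a gene counts as selected in a subsample whenever any
#' SNP mapped to it was selected.
#'
#' @param ranking a [rank_pathways()] result (with `stage2 = TRUE`), or its
#'   `records` tibble.
#' @param snp_gene_map a [map_snps_to_genes()] tibble.
#' @return List of two tibbles, `snps` (`snp_id`, `freq`, `rank`) and
#'   `genes` (`gene_id`, `freq`, `rank`), ranked by descending frequency
#'   with average ranks for ties.
#' @export
snp_gene_frequencies <- function(ranking, snp_gene_map) {
  records <- if (inherits(ranking, "psrrr_ranking")) ranking$records else ranking
  B <- nrow(records)
  snp_ids <- unique(snp_gene_map$snp_id)
  snp_counts <- stats::setNames(integer(length(snp_ids)), snp_ids)
  gene_ids <- unique(snp_gene_map$gene_id)
  gene_counts <- stats::setNames(integer(length(gene_ids)), gene_ids)
  snp_to_genes <- split(snp_gene_map$gene_id, snp_gene_map$snp_id)
  for (b in seq_len(B)) {
    sel <- intersect(records$selected_snps[[b]], snp_ids)
    snp_counts[sel] <- snp_counts[sel] + 1L
    g <- unique(unlist(snp_to_genes[sel], use.names = FALSE))
    gene_counts[g] <- gene_counts[g] + 1L
  }
  rank_tbl <- function(ids, counts, id_col) {
    out <- tibble::tibble(id = ids, freq = as.numeric(counts) / B)
    names(out)[1] <- id_col
    out$rank <- rank(-out$freq, ties.method = "average")
    dplyr::arrange(out, .data$rank)
  }
  list(
    snps = rank_tbl(snp_ids, snp_counts, "snp_id"),
    genes = rank_tbl(gene_ids, gene_counts, "gene_id")
  )
}

#' Permutation enrichment test for an a priori gene list
#'
#' Each listed gene receives the mean rank of the pathways containing it;
#' the observed enrichment score is the sum of those mean ranks over the
#' listed genes present in at least one ranked pathway (low score = listed
#' genes sit in high-ranking pathways). The null distribution permutes the
#' pathway rank vector uniformly; the p-value is the proportion of permuted
#' scores strictly below the observed score.
#'
#' @param pathway_ranks named numeric vector of pathway ranks (1 = best),
#'   e.g. from `tidy()` of a [rank_pathways()] result.
#' @param gene_membership named list pathway -> member genes (e.g. the
#'   `gene_membership` element of a [build_pathway_mapping()] object).
#' @param gene_list character vector of genes of interest.
#' @param n_perm number of rank-vector permutations (default 100000).
#' @param seed integer seed.
#' @return An object of class `enrichment_result`: list with
#'   `observed_score`, `p_value`, `n_perm`, `genes_used`,
#'   `permuted_summary` (tibble), `degenerate` (TRUE when the score is
#'   invariant under permutation).
#' @export
enrichment_test <- function(pathway_ranks, gene_membership, gene_list,
                            n_perm = 100000, seed = 1) {
  pathways <- names(pathway_ranks)
  if (is.null(pathways)) stop("`pathway_ranks` must be named by pathway.")
  gene_membership <- gene_membership[intersect(names(gene_membership), pathways)]
  genes_used <- intersect(gene_list,
                          unique(unlist(gene_membership, use.names = FALSE)))
  if (!length(genes_used)) {
    stop("None of the listed genes occurs in any ranked pathway.")
  }
  # score is linear in the rank vector: score(r) = sum(contrib * r)
  L <- length(pathway_ranks)
  contrib <- numeric(L)
  for (g in genes_used) {
    member <- which(vapply(gene_membership, function(gs) g %in% gs, logical(1)))
    member_idx <- match(names(gene_membership)[member], pathways)
    contrib[member_idx] <- contrib[member_idx] + 1 / length(member_idx)
  }
  ranks <- as.numeric(pathway_ranks)
  observed <- sum(contrib * ranks)
  perm_scores <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sum(contrib * ranks[sample.int(L)]),
           numeric(1))
  })
  degenerate <- all(abs(perm_scores - observed) < 1e-12)
  structure(
    list(
      observed_score = observed,
      p_value = mean(perm_scores < observed),
      n_perm = n_perm,
      genes_used = genes_used,
      permuted_summary = tibble::tibble(
        min = min(perm_scores), mean = mean(perm_scores),
        median = stats::median(perm_scores), max = max(perm_scores),
        sd = stats::sd(perm_scores)
      ),
      degenerate = degenerate
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> observed score %.4g over %d gene(s); p = %.4g (%d permutations)%s\n",
    x$observed_score, length(x$genes_used), x$p_value, x$n_perm,
    if (x$degenerate) " [degenerate: score invariant under permutation]" else ""
  ))
  invisible(x)
}
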
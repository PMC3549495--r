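make_map_fixture <- function() {
  # genes A (snps s1, s2), B (s3), far apart on chromosome 1
  g <- genotype_data(
    matrix(rbinom(5 * 3, 2, 0.4), 5, 3),
    snp_ids = c("s1", "s2", "s3"),
    chromosome = rep("1", 3),
    position_bp = c(1000L, 1500L, 100000L)
  )
  genes <- tibble::tibble(
    gene_id = c("A", "B"), chromosome = "1",
    start_bp = c(900L, 99500L), end_bp = c(2000L, 100500L)
  )
  db <- list(pw1 = "A", pw2 = c("A", "B"))
  list(g = g, genes = genes, db = db)
}

test_that("SNP-to-gene mapping honours inclusive window boundaries", {
  g <- genotype_data(matrix(0:2, 3, 2), snp_ids = c("in", "out"),
                     chromosome = c("1", "1"),
                     position_bp = c(990L, 12001L))
  genes <- tibble::tibble(gene_id = "G", chromosome = "1",
                          start_bp = 1000L, end_bp = 2000L)
  sg <- map_snps_to_genes(g, genes, window_bp = 10000)
  expect_equal(sg$snp_id, "in")       # 990 is inside [start - w, end + w]
  # distance 10,001 beyond the gene end is excluded; exactly 10,000 is kept
  g2 <- genotype_data(matrix(0:2, 3, 2), snp_ids = c("edge", "past"),
                      chromosome = c("1", "1"),
                      position_bp = c(12000L, 12001L))
  sg2 <- map_snps_to_genes(g2, genes, window_bp = 10000)
  expect_equal(sg2$snp_id, "edge")
  expect_error(map_snps_to_genes(g, genes, window_bp = -1), "non-negative")
})

test_that("random mappings equal a brute-force all-pairs distance scan", {
  withr::with_seed(31, {
    p <- 200
    g <- genotype_data(
      matrix(rbinom(10 * p, 2, 0.3), 10, p),
      chromosome = sample(c("1", "2"), p, replace = TRUE),
      position_bp = sample.int(5e5, p)
    )
    genes <- tibble::tibble(
      gene_id = paste0("g", 1:20),
      chromosome = sample(c("1", "2"), 20, replace = TRUE),
      start_bp = sample.int(4e5, 20)
    )
    genes$end_bp <- genes$start_bp + sample.int(2e4, 20)
  })
  w <- 10000
  sg <- map_snps_to_genes(g, genes, window_bp = w)
  brute <- list()
  for (i in seq_len(nrow(g$snps))) {
    for (k in seq_len(nrow(genes))) {
      if (g$snps$chromosome[i] == genes$chromosome[k] &&
          g$snps$position_bp[i] >= genes$start_bp[k] - w &&
          g$snps$position_bp[i] <= genes$end_bp[k] + w) {
        brute[[length(brute) + 1]] <- c(g$snps$snp_id[i], genes$gene_id[k])
      }
    }
  }
  brute <- do.call(rbind, brute)
  got <- dplyr::arrange(sg, .data$snp_id, .data$gene_id)
  want <- dplyr::arrange(
    tibble::tibble(snp_id = brute[, 1], gene_id = brute[, 2]),
    .data$snp_id, .data$gene_id
  )
  expect_equal(tibble::as_tibble(got)[c("snp_id", "gene_id")], want,
               ignore_attr = TRUE)
})

test_that("widening the window never removes a SNP-gene pair", {
  fx <- make_map_fixture()
  narrow <- map_snps_to_genes(fx$g, fx$genes, window_bp = 100)
  wide <- map_snps_to_genes(fx$g, fx$genes, window_bp = 50000)
  narrow_pairs <- paste(narrow$snp_id, narrow$gene_id)
  wide_pairs <- paste(wide$snp_id, wide$gene_id)
  expect_true(all(narrow_pairs %in% wide_pairs))
})

test_that("overlapping pathways expand into disjoint duplicated blocks", {
  fx <- make_map_fixture()
  sg <- map_snps_to_genes(fx$g, fx$genes)
  pm <- build_pathway_mapping(sg, fx$db, drop_largest = FALSE)
  expect_equal(pm$pathways, c("pw1", "pw2"))
  expect_equal(pm$groups[[1]], c(1L, 2L))
  expect_equal(pm$groups[[2]], c(1L, 2L, 3L))
  expect_equal(sum(pm$sizes), 5L) # P* = S1 + S2
  # dropping the largest leaves the single smaller group
  pm2 <- suppressMessages(build_pathway_mapping(sg, fx$db, drop_largest = TRUE))
  expect_equal(pm2$pathways, "pw1")
  expect_equal(sum(pm2$sizes), 2L)
  expect_equal(pm2$dropped_pathway, "pw2")
})

test_that("per-SNP overlap counts match direct set arithmetic", {
  scn <- psrrr_scenario(n = 30, n_genes = 15, snps_per_gene = 2, l = 6,
                        genes_per_pathway = c(1, 5), overlap_rate = 0.5,
                        seed = 8)
  pw <- simulate_pathways(scn)
  pm <- pw$mapping
  # oracle: for each SNP, count pathways whose gene set contains a gene the
  # SNP maps to
  sg <- pw$snp_gene_map
  snp_genes <- split(sg$gene_id, sg$snp_id)
  ov_oracle <- vapply(names(snp_genes), function(s) {
    sum(vapply(pm$gene_membership, function(gs) {
      any(snp_genes[[s]] %in% gs)
    }, logical(1)))
  }, numeric(1))
  ov_pkg <- table(pm$expansion_index$snp_id)
  mapped <- names(ov_oracle)[ov_oracle > 0]
  expect_equal(as.numeric(ov_pkg[mapped]), unname(ov_oracle[mapped]))
  # conservation
  expect_equal(sum(pm$sizes), nrow(pm$expansion_index))
  expect_lte(length(unique(pm$expansion_index$snp_index)), nrow(pw$snp_gene_map))
})

test_that("design expansion duplicates columns losslessly", {
  fx <- make_map_fixture()
  sg <- map_snps_to_genes(fx$g, fx$genes)
  pm <- build_pathway_mapping(sg, fx$db, drop_largest = FALSE)
  X <- oracle_standardise(fx$g$counts)
  Xe <- expand_design(X, pm)
  expect_equal(ncol(Xe), 5L)
  # s1 appears in both pathways, bit-identical
  expect_identical(Xe[, 1], Xe[, 3])
  # every original column is recoverable from any copy
  for (k in seq_len(ncol(Xe))) {
    expect_identical(unname(Xe[, k]), unname(X[, pm$expansion_index$snp_index[k]]))
  }
  # column sums scatter correctly
  expect_equal(colSums(Xe), colSums(X)[pm$expansion_index$snp_index],
               ignore_attr = TRUE)
  # disjoint pathways covering all SNPs give a column permutation
  db_disjoint <- list(p1 = "A", p2 = "B")
  pmd <- build_pathway_mapping(sg, db_disjoint, drop_largest = FALSE)
  Xd <- expand_design(X, pmd)
  expect_equal(ncol(Xd), ncol(X))
  expect_equal(sort(pmd$expansion_index$snp_index), 1:3)
})

test_that("pathway summaries report sizes, overlaps and the mean identity", {
  fx <- make_map_fixture()
  sg <- map_snps_to_genes(fx$g, fx$genes)
  pm <- build_pathway_mapping(sg, fx$db, drop_largest = FALSE)
  s <- pathway_summary(pm)
  expect_equal(s$pathways$n_snps, c(2L, 3L))
  expect_equal(sort(s$snps$n_pathways, decreasing = TRUE), c(2L, 2L, 1L))
  # mean overlap = P* / #distinct mapped SNPs
  expect_equal(s$summary$mean[s$summary$quantity == "snp_overlap"],
               sum(pm$sizes) / dplyr::n_distinct(pm$expansion_index$snp_id))
})

test_that("degenerate mappings raise errors", {
  fx <- make_map_fixture()
  sg <- map_snps_to_genes(fx$g, fx$genes)
  expect_error(build_pathway_mapping(sg, list(pwZ = "nogene")), "empty")
})
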
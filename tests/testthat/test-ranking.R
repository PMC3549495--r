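make_rank_fixture <- function(seed = 1, l = 5, n = 120) {
  scn <- psrrr_scenario(n = n, n_genes = 15, snps_per_gene = 3, l = l,
                        genes_per_pathway = c(2, 4), overlap_rate = 0.1,
                        n_causal_pathways = 2, seed = seed)
  g <- simulate_genotypes(scn)
  pw <- simulate_pathways(scn, g)
  X <- standardise_design(g)
  ph <- simulate_phenotype(scn, X, pw$mapping)
  list(g = g, pw = pw, Y = ph$Y, truth = ph$truth)
}

test_that("a single subsample gives 0/1 selection frequencies", {
  fx <- make_rank_fixture(2)
  rk <- rank_pathways(fx$g, fx$Y, fx$pw$mapping, B = 1, seed = 5,
                      stage2 = FALSE)
  expect_true(all(rk$pathway_freq$freq %in% c(0, 1)))
  sel <- rk$records$selected_pathways[[1]]
  expect_equal(sort(rk$pathway_freq$pathway[rk$pathway_freq$freq == 1]),
               sort(sel))
})

test_that("frequencies are exact multiples of 1/B and replayable from records", {
  fx <- make_rank_fixture(3)
  rk <- rank_pathways(fx$g, fx$Y, fx$pw$mapping, B = 12, seed = 7)
  expect_true(all(abs(rk$pathway_freq$freq * rk$B -
                        round(rk$pathway_freq$freq * rk$B)) < 1e-12))
  recount <- table(factor(unlist(rk$records$selected_pathways),
                          levels = fx$pw$mapping$pathways))
  expect_identical(as.numeric(recount) / 12,
                   rk$pathway_freq$freq[match(fx$pw$mapping$pathways,
                                              rk$pathway_freq$pathway)])
})

test_that("subsample records are deterministic in the master seed, per index", {
  fx <- make_rank_fixture(4)
  r1 <- rank_pathways(fx$g, fx$Y, fx$pw$mapping, B = 5, seed = 42)
  r2 <- rank_pathways(fx$g, fx$Y, fx$pw$mapping, B = 5, seed = 42)
  expect_identical(r1$records, r2$records)
  # per-subsample seeds derive from seed + b: a shorter run is a prefix
  r3 <- rank_pathways(fx$g, fx$Y, fx$pw$mapping, B = 3, seed = 42)
  expect_identical(r3$records, r1$records[1:3, ])
})

test_that("stratified half-samples preserve the diagnosis ratio", {
  fx <- make_rank_fixture(5, n = 121)
  diagnosis <- rep(c("AD", "CN"), c(44, 77))
  rk <- rank_pathways(fx$g, fx$Y, fx$pw$mapping, B = 4, seed = 2,
                      diagnosis = diagnosis, stage2 = FALSE)
  for (idx in rk$records$sample_indices) {
    expect_equal(length(idx), 60L) # floor(121/2)
    expect_equal(sum(diagnosis[idx] == "AD"), 22L) # 44 * 60/121, rounded
  }
})

test_that("known causal pathways rank on top over B = 100 subsamples", {
  fx <- make_rank_fixture(6, l = 8, n = 200)
  rk <- rank_pathways(fx$g, fx$Y, fx$pw$mapping, B = 100, seed = 11,
                      stage2 = FALSE)
  top2 <- rk$pathway_freq$pathway[1:2]
  expect_setequal(top2, fx$truth$causal_pathways)
})

test_that("stage-2 lasso behaves at the penalty extremes and on orthonormal designs", {
  fx <- make_rank_fixture(7)
  X <- standardise_design(fx$g)
  # gamma = 1: empty support
  s_empty <- stage2_lasso_srrr(X[, 1:6], fx$Y, gamma = 1)
  expect_equal(s_empty$selected, integer(0))
  # single strong SNP is selected
  withr::with_seed(3, {
    x <- oracle_standardise(matrix(rnorm(80), 80, 1))
    Ys <- as.numeric(x) %*% t(c(2, 1)) + matrix(rnorm(160, sd = 0.1), 80, 2)
  })
  s_one <- stage2_lasso_srrr(x, Ys, gamma = 0.8)
  expect_equal(s_one$selected, 1L)
  # orthonormal reduced design: support equals the soft-threshold support
  withr::with_seed(4, {
    Q <- qr.Q(qr(matrix(rnorm(60 * 8), 60, 8)))
    Yq <- matrix(rnorm(60 * 3), 60, 3)
  })
  a0 <- psrrr:::initial_a(Yq)
  z <- as.numeric(crossprod(Q, Yq %*% a0))
  lam <- 0.8 * max(abs(z))
  beta <- as.numeric(group_lasso_bcd(Q, as.numeric(Yq %*% a0),
                                     rep(1L, 8), rep(1, 8), lam))
  expect_equal(which(beta != 0), which(abs(z) > lam))
  expect_equal(beta[beta != 0],
               (abs(z) - lam)[abs(z) > lam] * sign(z)[abs(z) > lam],
               tolerance = 1e-10)
})

test_that("SNP and gene frequencies follow the indicator algebra", {
  sg <- tibble::tibble(
    snp_id = c("rs1", "rs2", "rs2", "rs3"),
    gene_id = c("gA", "gA", "gB", "gC")
  )
  B <- 1000
  sel <- c(rep(list("rs1"), 451), rep(list(c("rs2", "rs3")), 100),
           rep(list(character(0)), B - 551))
  records <- tibble::tibble(
    b_index = seq_len(B),
    selected_snps = sel
  )
  fr <- snp_gene_frequencies(records, sg)
  expect_equal(fr$snps$freq[fr$snps$snp_id == "rs1"], 0.451)
  # rs2 maps to two genes: both indicators fire when rs2 is selected
  expect_equal(fr$genes$freq[fr$genes$gene_id == "gB"], 0.1)
  expect_equal(fr$genes$freq[fr$genes$gene_id == "gC"], 0.1)
  # gA fires for rs1 or rs2 selections
  expect_equal(fr$genes$freq[fr$genes$gene_id == "gA"], 0.551)
  # a gene dominates any SNP mapped only to it
  expect_gte(fr$genes$freq[fr$genes$gene_id == "gA"],
             fr$snps$freq[fr$snps$snp_id == "rs1"])
})

test_that("the three-pathway enrichment example is reproduced exactly", {
  ranks <- c(p1 = 1, p2 = 2, p3 = 3)
  membership <- list(p1 = "geneA", p2 = "geneB", p3 = "geneZ")
  res <- enrichment_test(ranks, membership, c("geneA", "geneB"),
                         n_perm = 600, seed = 1)
  expect_equal(res$observed_score, 3)
  # exhaustive permutations give scores {3,3,4,4,5,5}: nothing below 3
  expect_equal(res$p_value, 0)
  expect_equal(sort(unique(res$permuted_summary$min)), 3)
})

test_that("Monte-Carlo enrichment p-values sit within 3 SDs of exhaustive", {
  withr::with_seed(10, {
    L <- 6
    ranks <- stats::setNames(sample(1:L), paste0("pw", 1:L))
    membership <- lapply(1:L, function(i) {
      sample(paste0("g", 1:8), 3)
    })
    names(membership) <- paste0("pw", 1:L)
    gene_list <- c("g1", "g2", "g3")
  })
  # exhaustive p over all 720 permutations of the rank vector
  perms <- gtools_permutations <- NULL
  all_perm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  genes_used <- intersect(gene_list, unique(unlist(membership)))
  score_of <- function(r) {
    sum(vapply(genes_used, function(g) {
      mean(r[vapply(membership, function(gs) g %in% gs, logical(1))])
    }, numeric(1)))
  }
  obs <- score_of(ranks)
  exh <- vapply(all_perm(as.numeric(ranks)), function(r) {
    score_of(stats::setNames(r, names(ranks)))
  }, numeric(1))
  p_exact <- mean(exh < obs)
  res <- enrichment_test(ranks, membership, gene_list, n_perm = 4000, seed = 3)
  expect_equal(res$observed_score, obs)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_value - p_exact), max(3 * se, 1e-9))
})

test_that("degenerate and empty enrichment inputs are handled", {
  ranks <- c(p1 = 1, p2 = 2)
  membership <- list(p1 = c("gA", "gB"), p2 = c("gA", "gB"))
  res <- enrichment_test(ranks, membership, "gA", n_perm = 50, seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 0) # strict inequality on an invariant score
  expect_error(
    enrichment_test(ranks, membership, "absent_gene", n_perm = 10),
    "None of the listed genes"
  )
})
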
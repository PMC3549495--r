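test_that("standardisation centres and scales to unit sum of squares", {
  m <- matrix(c(0, 1, 2, 5, 5, 5), 3, 2)
  expect_warning(s <- standardise_design(m), "constant")
  expect_equal(s[, 1], c(-1, 0, 1) / sqrt(2), ignore_attr = TRUE)
  expect_equal(ncol(s), 1L)
  # idempotence
  s2 <- standardise_design(s)
  expect_equal(unname(s2), unname(s), tolerance = 1e-12, ignore_attr = TRUE)
  # random matrix: direct recomputation
  withr::with_seed(7, x <- matrix(rnorm(200), 20, 10))
  sx <- standardise_design(x)
  expect_lt(max(abs(colMeans(sx))), 1e-12)
  expect_lt(max(abs(colSums(sx^2) - 1)), 1e-12)
  expect_equal(unname(sx), unname(oracle_standardise(x)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardise_design(x[1, , drop = FALSE]), "two samples")
})

test_that("the phenotype update matches per-column OLS on the latent factor", {
  withr::with_seed(11, {
    X <- oracle_standardise(matrix(rnorm(40 * 6), 40, 6))
    b <- rnorm(6)
    Y <- matrix(rnorm(40 * 5), 40, 5)
  })
  a <- update_a(X, Y, b)
  expect_equal(sum(a^2), 1)
  xb <- as.numeric(X %*% b)
  ols <- vapply(seq_len(5), function(q) {
    coef(lm(Y[, q] ~ xb - 1))[[1]]
  }, numeric(1))
  expect_equal(a, ols / sqrt(sum(ols^2)), tolerance = 1e-10)
  # noiseless inversion up to sign
  a0 <- c(3, 4) / 5
  Yn <- xb %*% t(a0)
  expect_equal(abs(sum(update_a(X, Yn, b) * a0)), 1, tolerance = 1e-12)
  # degenerate cases raise
  expect_error(update_a(X, Y, numeric(6)), "X b = 0")
  Yorth <- qr.resid(qr(xb), Y)
  expect_error(update_a(X, Yorth, b), "orthogonal")
})

test_that("lambda_max is the exact zero-solution threshold", {
  withr::with_seed(13, {
    X <- oracle_standardise(matrix(rnorm(40 * 30), 40, 30))
    Y <- matrix(rnorm(40 * 4), 40, 4)
  })
  sizes <- c(8, 5, 7, 6, 4)
  w <- sqrt(sizes)
  a <- psrrr:::initial_a(Y)
  lm0 <- lambda_max(X, Y, a, w, sizes)
  y <- as.numeric(Y %*% a)
  b_at <- group_lasso_bcd(X, y, sizes, w, lm0)
  expect_true(all(b_at == 0))
  b_above <- group_lasso_bcd(X, y, sizes, w, lm0 * 1.5)
  expect_true(all(b_above == 0))
  b_below <- group_lasso_bcd(X, y, sizes, w, lm0 * 0.99)
  expect_gt(sum(b_below != 0), 0)
  # single group, unit weight: definitionally ||X'Ya||
  expect_equal(lambda_max(X, Y, a, 1, ncol(X)),
               sqrt(sum((crossprod(X, y))^2)))
  # orthogonal case
  expect_equal(lambda_max(X, matrix(0, 40, 4), a, w, sizes), 0)
  expect_error(lambda_max(X, Y, a, c(-1, w[-1]), sizes), "positive")
})

test_that("unpenalised BCD recovers OLS and orthonormal designs soft-threshold", {
  withr::with_seed(17, {
    X <- oracle_standardise(matrix(rnorm(50 * 6), 50, 6))
    y <- rnorm(50)
  })
  b <- group_lasso_bcd(X, y, 6, 1, 0)
  expect_equal(as.numeric(b), as.numeric(qr.coef(qr(X), y)), tolerance = 1e-6)

  # orthonormal single group: block soft-threshold closed form
  Q <- qr.Q(qr(matrix(rnorm(50 * 5), 50, 5)))
  z <- as.numeric(crossprod(Q, y))
  for (lam in c(0.2, 0.8) * sqrt(sum(z^2))) {
    b_hat <- as.numeric(group_lasso_bcd(Q, y, 5, 1, lam, tol = 1e-10))
    b_closed <- max(0, 1 - lam / sqrt(sum(z^2))) * z
    expect_equal(b_hat, b_closed, tolerance = 1e-7)
  }
})

test_that("BCD matches the proximal-gradient oracle and certifies KKT", {
  for (seed in 1:8) {
    sizes <- withr::with_seed(seed, sample(2:6, sample(3:5, 1), replace = TRUE))
    inst <- make_grouped_instance(n = 35, sizes = sizes, seed = 100 + seed)
    a_dummy <- 1
    lmax <- max(vapply(seq_along(sizes), function(l) {
      idx <- cumsum(c(0, sizes[-length(sizes)]))[l] + seq_len(sizes[l])
      sqrt(sum(crossprod(inst$X[, idx], inst$y)^2)) / inst$w[l]
    }, numeric(1)))
    lam <- 0.3 * lmax
    b_bcd <- as.numeric(group_lasso_bcd(inst$X, inst$y, sizes, inst$w, lam,
                                        tol = 1e-8))
    b_ora <- oracle_group_lasso(inst$X, inst$y, sizes, inst$w, lam)
    f_bcd <- oracle_gl_objective(inst$X, inst$y, b_bcd, sizes, inst$w, lam)
    f_ora <- oracle_gl_objective(inst$X, inst$y, b_ora, sizes, inst$w, lam)
    expect_lt(abs(f_bcd - f_ora) / abs(f_ora), 1e-4)
    kk <- kkt_check(inst$X, inst$y, b_bcd, sizes, inst$w, lam, tol = 1e-4)
    expect_true(kk$ok)
  }
})

test_that("active-set screening reproduces the full solve", {
  sizes <- c(5, 4, 6, 3, 5)
  inst <- make_grouped_instance(n = 40, sizes = sizes, seed = 77)
  lmax <- max(vapply(seq_along(sizes), function(l) {
    idx <- cumsum(c(0, sizes[-length(sizes)]))[l] + seq_len(sizes[l])
    sqrt(sum(crossprod(inst$X[, idx], inst$y)^2)) / inst$w[l]
  }, numeric(1)))
  for (gamma in c(0.95, 0.5, 0.2)) {
    lam <- gamma * lmax
    b_full <- as.numeric(group_lasso_bcd(inst$X, inst$y, sizes, inst$w, lam,
                                         tol = 1e-8))
    b_act <- as.numeric(active_set_fit(inst$X, inst$y, sizes, inst$w, lam,
                                       tol = 1e-8))
    expect_equal(b_act, b_full, tolerance = 1e-6)
  }
})

test_that("screening violations are detected and repaired", {
  # force the screen to exclude truly active groups by raising kappa far
  # above 1: the initial candidate set collapses to the top-scoring group,
  # and the KKT re-check must detect the excluded violators, add them and
  # re-solve until the certificate is clean
  sizes <- c(2L, 3L, 2L, 3L)
  inst <- make_grouped_instance(n = 45, sizes = sizes, seed = 301, snr = 2)
  starts <- cumsum(c(0L, sizes[-4]))
  scores <- vapply(1:4, function(l) {
    sqrt(sum(crossprod(inst$X[, starts[l] + seq_len(sizes[l])], inst$y)^2))
  }, numeric(1)) / inst$w
  lam <- 0.3 * max(scores)
  b_full <- as.numeric(group_lasso_bcd(inst$X, inst$y, sizes, inst$w, lam,
                                       tol = 1e-9))
  active <- vapply(1:4, function(l) {
    any(b_full[starts[l] + seq_len(sizes[l])] != 0)
  }, logical(1))
  expect_gt(sum(active), 1) # several active groups to recover
  # set the screen just below the top score so only the strongest group
  # survives it: every other active group is provably excluded at first
  kappa <- 0.999 * max(scores) / lam
  expect_true(any(active & scores < kappa * lam))
  b_act <- as.numeric(active_set_fit(inst$X, inst$y, sizes, inst$w, lam,
                                     tol = 1e-9, kappa = kappa))
  expect_equal(b_act, b_full, tolerance = 1e-5)
  kk <- kkt_check(inst$X, inst$y, b_act, sizes, inst$w, lam, tol = 1e-5)
  expect_true(kk$ok)
})

make_fit_fixture <- function(seed, l = 6, n = 120) {
  # disjoint pathways isolate the solver's selection behaviour from
  # overlap-induced competition
  scn <- psrrr_scenario(n = n, n_genes = 18, snps_per_gene = 3, l = l,
                        genes_per_pathway = c(2, 3), overlap_rate = 0,
                        n_causal_pathways = 1, seed = seed)
  g <- simulate_genotypes(scn)
  pw <- simulate_pathways(scn, g)
  X <- standardise_design(g)
  ph <- simulate_phenotype(scn, X, pw$mapping)
  list(Xe = expand_design(X, pw$mapping), Y = ph$Y, pm = pw$mapping,
       truth = ph$truth)
}

test_that("gamma = 1 yields the empty model by construction", {
  fx <- make_fit_fixture(5)
  fit <- fit_psrrr(fx$Xe, fx$Y, fx$pm, gamma = 1)
  expect_equal(fit$selected, character(0))
  expect_true(all(fit$b == 0))
})

test_that("a single causal pathway is recovered across seeds", {
  hits <- 0
  for (seed in 1:20) {
    fx <- make_fit_fixture(seed)
    fit <- fit_psrrr(fx$Xe, fx$Y, fx$pm, gamma = 0.8)
    hits <- hits + (fx$truth$causal_pathways %in% fit$selected)
  }
  expect_gte(hits, 19) # >= 95% of seeds
})

test_that("the objective trace is non-increasing across outer iterations", {
  for (seed in 21:40) {
    fx <- make_fit_fixture(seed, l = 4, n = 60)
    fit <- fit_psrrr(fx$Xe, fx$Y, fx$pm, gamma = 0.6)
    tr <- fit$diagnostics$objective
    if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-8))
  }
})

test_that("identical duplicated pathways are exchangeable in the fitted model", {
  # with two bit-identical groups and equal weights the minimiser is not
  # unique (mass can sit in either copy), but the problem is symmetric:
  # swapping the two blocks of any solution changes neither the objective
  # nor the KKT certificate
  withr::with_seed(55, {
    X0 <- oracle_standardise(matrix(rnorm(60 * 8), 60, 8))
    Y <- matrix(rnorm(60 * 4), 60, 4)
    u <- as.numeric(X0 %*% c(1, 1, 1, 1, 0, 0, 0, 0))
    Y <- Y + u %*% t(c(1, 0, 0, 0))
  })
  Xe <- cbind(X0[, 1:4], X0[, 1:4]) # two identical groups
  sizes <- c(4L, 4L)
  a <- psrrr:::initial_a(Y)
  y <- as.numeric(Y %*% a)
  lam <- 0.5 * lambda_max(Xe, Y, a, c(2, 2), sizes)
  b <- as.numeric(group_lasso_bcd(Xe, y, sizes, c(2, 2), lam, tol = 1e-9))
  b_swap <- c(b[5:8], b[1:4])
  f <- group_lasso_objective(Xe, y, b, sizes, c(2, 2), lam)
  f_swap <- group_lasso_objective(Xe, y, b_swap, sizes, c(2, 2), lam)
  expect_equal(f, f_swap, tolerance = 1e-12)
  expect_true(kkt_check(Xe, y, b_swap, sizes, c(2, 2), lam, tol = 1e-5)$ok)
})

test_that("selection is monotone along a shared-initialisation lambda path", {
  fx <- make_fit_fixture(3)
  a <- psrrr:::initial_a(fx$Y)
  y <- as.numeric(fx$Y %*% a)
  w <- initial_weights(fx$pm)
  lmax <- lambda_max(fx$Xe, fx$Y, a, w, fx$pm)
  n_sel <- vapply(c(0.95, 0.8, 0.6, 0.4, 0.2), function(gam) {
    b <- group_lasso_bcd(fx$Xe, y, fx$pm, w, gam * lmax)
    length(psrrr:::selected_groups(as.numeric(b), fx$pm))
  }, numeric(1))
  expect_true(all(diff(n_sel) >= 0))
})

test_that("fit diagnostics expose a clean KKT certificate", {
  fx <- make_fit_fixture(9)
  fit <- fit_psrrr(fx$Xe, fx$Y, fx$pm, gamma = 0.7)
  expect_true(all(fit$diagnostics$kkt_max <= 1e-4))
  expect_true(fit$diagnostics$converged)
  # glance/tidy surfaces
  gl <- glance(fit)
  expect_equal(gl$n_selected, length(fit$selected))
  td <- tidy(fit)
  expect_equal(nrow(td), ncol(fx$Xe))
  expect_equal(td$estimate, fit$b)
})
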
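# Independent oracles and fixture builders used across the suite.

# Proximal-gradient (ISTA) solver for the weighted group lasso: an algorithm
# independent of the package's block coordinate descent. Fixed step 1/L with
# L the largest eigenvalue of X'X; prox is the blockwise soft-threshold.
oracle_group_lasso <- function(X, y, sizes, w, lam,
                               max_iter = 50000, tol = 1e-11) {
  starts <- cumsum(c(0, sizes[-length(sizes)]))
  lip <- max(eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / lip
  b <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    grad <- -as.numeric(crossprod(X, y - X %*% b))
    u <- b - step * grad
    bn <- u
    for (l in seq_along(sizes)) {
      idx <- starts[l] + seq_len(sizes[l])
      nrm <- sqrt(sum(u[idx]^2))
      thr <- step * lam * w[l]
      bn[idx] <- if (nrm <= thr) 0 else (1 - thr / nrm) * u[idx]
    }
    if (max(abs(bn - b)) < tol) {
      b <- bn
      break
    }
    b <- bn
  }
  b
}

oracle_gl_objective <- function(X, y, b, sizes, w, lam) {
  starts <- cumsum(c(0, sizes[-length(sizes)]))
  pen <- sum(vapply(seq_along(sizes), function(l) {
    w[l] * sqrt(sum(b[starts[l] + seq_len(sizes[l])]^2))
  }, numeric(1)))
  0.5 * sum((y - X %*% b)^2) + lam * pen
}

# Direct log-multinomial exact HWE p-value (independent of the package's
# recurrence implementation): P(n_ab | n, n_rare) via factorials.
oracle_hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_rare <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  hs <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hs, function(h) {
    homr <- (n_rare - h) / 2
    homc <- n - h - homr
    lfactorial(n) - lfactorial(homr) - lfactorial(h) - lfactorial(homc) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Random grouped regression instance with overlapping groups realised as
# duplicated columns (the expanded-design construction).
make_grouped_instance <- function(n, sizes, seed, snr = 1) {
  withr::with_seed(seed, {
    p <- sum(sizes)
    X <- matrix(rnorm(n * p), n, p)
    X <- scale(X, center = TRUE, scale = FALSE)
    X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
    b0 <- numeric(p)
    act <- seq_len(sizes[1])
    b0[act] <- rnorm(sizes[1])
    y <- as.numeric(X %*% b0) * snr + rnorm(n)
    y <- y - mean(y)
    list(X = X, y = y, sizes = sizes, w = sqrt(sizes))
  })
}

# Standardise columns the long way, for cross-checks.
oracle_standardise <- function(m) {
  m <- apply(m, 2, function(x) x - mean(x))
  apply(m, 2, function(x) x / sqrt(sum(x^2)))
}

# Tiny genotype fixture with known metadata.
make_geno_fixture <- function(n = 12, p = 6, seed = 1, missing_rate = 0) {
  withr::with_seed(seed, {
    counts <- matrix(rbinom(n * p, 2, 0.35), n, p)
    if (missing_rate > 0) {
      counts[runif(n * p) < missing_rate] <- NA
    }
    genotype_data(
      counts,
      sample_ids = paste0("s", seq_len(n)),
      snp_ids = paste0("rs", seq_len(p)),
      chromosome = rep("1", p),
      position_bp = seq_len(p) * 1000L
    )
  })
}
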
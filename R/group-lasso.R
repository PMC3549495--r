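#' Standardise a design matrix
#'
#' Mean-centres every column and scales it to unit sum of squares
#' (`sum(x^2) == 1`), the scaling under which the group-lasso penalty and
#' `lambda_max` are defined. Constant columns carry no information and are
#' either dropped (default) or kept as all-zero columns (needed when a
#' pathway mapping indexes the original column layout).
#'
#' @param x a numeric matrix or a [genotype_data()] object (no missing
#'   entries; run [impute_missing()] first).
#' @param drop_constant drop zero-variance columns (TRUE, with a warning) or
#'   zero them in place (FALSE).
#' @return The standardised matrix; attribute `dropped_columns` lists any
#'   removed/zeroed column indices.
#' @export
standardise_design <- function(x, drop_constant = TRUE) {
  if (inherits(x, "genotype_data")) x <- x$counts
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("At least two samples are required to standardise.")
  if (anyNA(x)) stop("Design has missing entries; impute before standardising.")
  x <- sweep(x, 2, colMeans(x), "-")
  ss <- sqrt(colSums(x^2))
  zero <- which(ss == 0)
  nz <- which(ss > 0)
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, ss[nz], "/")
  if (length(zero)) {
    if (drop_constant) {
      warning(length(zero), " constant column(s) dropped during standardisation.")
      x <- x[, nz, drop = FALSE]
    }
  }
  attr(x, "dropped_columns") <- zero
  x
}

as_group_layout <- function(groups) {
  # groups: a pathway_mapping (contiguous expanded blocks) or a list of sizes
  if (inherits(groups, "pathway_mapping")) {
    sizes <- groups$sizes
  } else if (is.list(groups)) {
    sizes <- lengths(groups)
  } else {
    sizes <- as.integer(groups)
  }
  list(start = cumsum(c(0L, sizes[-length(sizes)])), size = as.integer(sizes))
}

#' Weighted group-lasso solver (block coordinate descent)
#'
#' Minimises `0.5 * ||y - X b||^2 + lambda * sum_l w_l ||b_l||_2` over
#' contiguous column blocks by cycling over groups: a group is set to zero
#' when the norm of its gradient at the residual excluding the group falls
#' below `lambda * w_l`; otherwise its coefficients are updated coordinate
#' by coordinate with a local quadratic (Taylor) approximation of the
#' penalty at the current group norm. Singleton groups use the exact lasso
#' soft-threshold.
#'
#' @param X N x P* design, columns standardised to unit sum of squares
#'   (all-zero columns are tolerated and stay at coefficient zero).
#' @param y length-N response.
#' @param groups a [build_pathway_mapping()] object, a list of index vectors,
#'   or an integer vector of block sizes (blocks must be contiguous in `X`).
#' @param weights positive group weights `w_l`.
#' @param lambda penalty level.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_sweeps maximum full cycles over groups.
#' @param b_init optional warm start.
#' @return The coefficient vector `b`, with attributes `sweeps` and
#'   `converged`. Warns (with diagnostics) if not converged.
#' @export
group_lasso_bcd <- function(X, y, groups, weights, lambda,
                            tol = 1e-5, max_sweeps = 1000, b_init = NULL) {
  lay <- as_group_layout(groups)
  p <- ncol(X)
  if (sum(lay$size) != p) {
    stop("Group sizes sum to ", sum(lay$size), " but X has ", p, " columns.")
  }
  if (length(weights) != length(lay$size)) stop("One weight per group is required.")
  if (any(weights <= 0)) stop("Group weights must be strictly positive.")
  if (lambda < 0) stop("`lambda` must be non-negative.")
  if (is.null(b_init)) b_init <- numeric(p)
  fit <- bcd_group_lasso(X, as.numeric(y), lay$start, lay$size,
                         as.numeric(weights), lambda, tol,
                         as.integer(max_sweeps), as.numeric(b_init))
  if (!fit$converged) {
    warning("group_lasso_bcd did not converge in ", max_sweeps,
            " sweeps (returning best iterate).")
  }
  structure(fit$b, sweeps = fit$sweeps, converged = fit$converged)
}

#' KKT certificate for a group-lasso solution
#'
#' For the objective of [group_lasso_bcd()], a solution must satisfy
#' `||X_l'r|| <= lambda * w_l` for zero groups and
#' `X_l'r = lambda * w_l * b_l / ||b_l||` for active groups, with
#' `r = y - X b`.
#'
#' @inheritParams group_lasso_bcd
#' @param b candidate coefficient vector.
#' @return A list with `max_zero_violation`, `max_active_violation` and
#'   `ok` (both below `tol`).
#' @param tol certification tolerance (default 1e-4).
#' @export
kkt_check <- function(X, y, b, groups, weights, lambda, tol = 1e-4) {
  lay <- as_group_layout(groups)
  r <- as.numeric(y - X %*% b)
  g <- as.numeric(crossprod(X, r))
  viol_zero <- 0
  viol_active <- 0
  for (l in seq_along(lay$size)) {
    idx <- lay$start[l] + seq_len(lay$size[l])
    bl <- b[idx]
    gl <- g[idx]
    if (all(bl == 0)) {
      viol_zero <- max(viol_zero, sqrt(sum(gl^2)) - lambda * weights[l])
    } else {
      want <- lambda * weights[l] * bl / sqrt(sum(bl^2))
      viol_active <- max(viol_active, max(abs(gl - want)))
    }
  }
  list(
    max_zero_violation = max(0, viol_zero),
    max_active_violation = viol_active,
    ok = max(0, viol_zero) <= tol && viol_active <= tol
  )
}

#' Group-lasso objective value
#'
#' @inheritParams kkt_check
#' @return `0.5 * ||y - X b||^2 + lambda * sum_l w_l ||b_l||`.
#' @export
group_lasso_objective <- function(X, y, b, groups, weights, lambda) {
  lay <- as_group_layout(groups)
  pen <- sum(vapply(seq_along(lay$size), function(l) {
    idx <- lay$start[l] + seq_len(lay$size[l])
    weights[l] * sqrt(sum(b[idx]^2))
  }, numeric(1)))
  0.5 * sum((y - X %*% b)^2) + lambda * pen
}

#' Active-set group-lasso fit
#'
#' Screens groups by the gradient of the empty model, solves the restricted
#' problem on the candidate set `{l : ||X_l'y|| / w_l >= kappa * lambda}`
#' (plus any warm-start-active groups), then verifies the KKT conditions on
#' the excluded groups, adding violators and re-solving until the
#' certificate is clean. The result solves the full problem.
#'
#' @inheritParams group_lasso_bcd
#' @param kappa screening multiplier in (0, 1]; candidates score at least
#'   `kappa * lambda` (default 0.9).
#' @param max_rounds violation-resolution rounds before falling back to a
#'   full solve with a warning (default 20).
#' @return As [group_lasso_bcd()].
#' @export
active_set_fit <- function(X, y, groups, weights, lambda,
                           tol = 1e-5, max_sweeps = 1000, b_init = NULL,
                           kappa = 0.9, max_rounds = 20) {
  lay <- as_group_layout(groups)
  L <- length(lay$size)
  p <- ncol(X)
  if (is.null(b_init)) b_init <- numeric(p)
  grp_cols <- lapply(seq_len(L), function(l) lay$start[l] + seq_len(lay$size[l]))
  g0 <- as.numeric(crossprod(X, y))
  scores <- vapply(seq_len(L), function(l) sqrt(sum(g0[grp_cols[[l]]]^2)), numeric(1)) / weights
  active0 <- vapply(seq_len(L), function(l) any(b_init[grp_cols[[l]]] != 0), logical(1))
  cand <- which(scores >= kappa * lambda | active0)
  if (!length(cand)) cand <- which.max(scores)
  b <- b_init
  for (round in seq_len(max_rounds)) {
    cols <- unlist(grp_cols[cand], use.names = FALSE)
    sub <- group_lasso_bcd(X[, cols, drop = FALSE], y, lay$size[cand],
                           weights[cand], lambda, tol, max_sweeps,
                           b_init = b[cols])
    b <- numeric(p)
    b[cols] <- as.numeric(sub)
    r <- as.numeric(y - X[, cols, drop = FALSE] %*% b[cols])
    g <- as.numeric(crossprod(X, r))
    out <- setdiff(seq_len(L), cand)
    if (!length(out)) {
      return(structure(b, sweeps = attr(sub, "sweeps"),
                       converged = attr(sub, "converged")))
    }
    viol <- out[vapply(out, function(l) {
      sqrt(sum(g[grp_cols[[l]]]^2)) > lambda * weights[l] + 1e-8
    }, logical(1))]
    if (!length(viol)) {
      return(structure(b, sweeps = attr(sub, "sweeps"),
                       converged = attr(sub, "converged")))
    }
    cand <- sort(c(cand, viol))
  }
  warning("Active-set screening failed to stabilise; falling back to a full solve.")
  group_lasso_bcd(X, y, groups, weights, lambda, tol, max_sweeps, b_init = b)
}
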
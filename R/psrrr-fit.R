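#' Closed-form update of the phenotype coefficient vector
#'
#' For fixed SNP coefficients `b`, the least-squares phenotype vector is
#' `a = (b'X'Y) / (b'X'Xb)`, rescaled to unit Euclidean norm for the
#' following genotype step.
#'
#' @param X N x P* design.
#' @param Y N x Q phenotype matrix.
#' @param b SNP coefficient vector.
#' @return Unit-norm length-Q vector.
#' @export
update_a <- function(X, Y, b) {
  xb <- as.numeric(X %*% b)
  denom <- sum(xb^2)
  if (denom == 0) stop("Degenerate latent factor: X b = 0.")
  a <- as.numeric(crossprod(Y, xb)) / denom
  na <- sqrt(sum(a^2))
  # cosine between Xb and its projection onto the span of Y's columns
  align <- na * sqrt(denom) / sqrt(sum(Y^2))
  if (na == 0 || align < 1e-10) {
    stop("Degenerate latent factor: Y is orthogonal to X b.")
  }
  a / na
}

#' Smallest penalty at which no pathway is selected
#'
#' `lambda_max = max_l ||X_l'(Y a)|| / w_l`; fitting the group lasso with
#' response `Y a` at any `lambda >= lambda_max` yields `b = 0`.
#'
#' @param X N x P* expanded design.
#' @param Y N x Q phenotype matrix.
#' @param a unit-norm phenotype coefficient vector.
#' @param weights positive pathway weights.
#' @param mapping a [build_pathway_mapping()] object (or group sizes).
#' @return The scalar `lambda_max`.
#' @export
lambda_max <- function(X, Y, a, weights, mapping) {
  if (any(weights <= 0)) stop("Group weights must be strictly positive.")
  lay <- as_group_layout(mapping)
  g <- as.numeric(crossprod(X, Y %*% a))
  scores <- vapply(seq_along(lay$size), function(l) {
    sqrt(sum(g[lay$start[l] + seq_len(lay$size[l])]^2))
  }, numeric(1))
  max(scores / weights)
}

# deterministic initial phenotype direction: dominant right singular vector
# of Y, sign fixed so its largest-magnitude entry is positive
initial_a <- function(Y) {
  v <- svd(Y, nu = 0, nv = 1)$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Fit the rank-1 pathway sparse reduced-rank regression model
#'
#' Alternates (i) a weighted group-lasso fit of the SNP coefficient vector
#' `b` against the current latent phenotype `Y a` and (ii) the closed-form
#' phenotype update `a`, each normalised to unit norm for the other's step,
#' until the coefficients stabilise. The penalty is held at
#' `lambda = gamma * lambda_max`, with `lambda_max` computed once at the
#' initial `a` (the dominant right singular vector of `Y`). Pathways with a
#' non-zero coefficient block form the selected set.
#'
#' @param X N x P* expanded standardised design (see [expand_design()]).
#' @param Y N x Q phenotype matrix (columns mean-centred).
#' @param mapping a [build_pathway_mapping()] object.
#' @param weights pathway weights (default `sqrt(S_l)`, see
#'   [initial_weights()]).
#' @param gamma fraction of `lambda_max` in (0, 1] (default 0.8).
#' @param outer_tol convergence tolerance on the maximum change of the
#'   normalised `(b, a)` pair (default 1e-4).
#' @param max_outer maximum alternations (default 100).
#' @param bcd_tol,max_sweeps tolerances of the inner group-lasso solver.
#' @param use_active_set solve each b-step through [active_set_fit()]
#'   (default TRUE).
#' @return An object of class `psrrr_fit`: list with `b` (expanded, as
#'   returned by the final group-lasso step), `a` (unit norm), `selected`
#'   (pathway names), `gamma`, `lambda`, `lambda_max`, `weights`, `mapping`,
#'   and `diagnostics` (objective trace, sweeps, active-set sizes, KKT
#'   violations, convergence flag, tolerances).
#' @export
fit_psrrr <- function(X, Y, mapping, weights = NULL, gamma = 0.8,
                      outer_tol = 1e-4, max_outer = 100,
                      bcd_tol = 1e-5, max_sweeps = 1000,
                      use_active_set = TRUE) {
  stopifnot(inherits(mapping, "pathway_mapping"))
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have matching sample rows.")
  if (is.null(weights)) weights <- initial_weights(mapping)
  if (gamma <= 0 || gamma > 1) stop("`gamma` must lie in (0, 1].")

  a <- initial_a(Y)
  lam_max <- lambda_max(X, Y, a, weights, mapping)
  lam <- gamma * lam_max

  L <- length(mapping$sizes)
  obj_trace <- numeric(0)
  sweeps <- integer(0)
  active_sizes <- integer(0)
  kkt_max <- numeric(0)
  b <- numeric(ncol(X))
  b_unit_prev <- b
  a_prev <- a
  converged <- FALSE

  for (it in seq_len(max_outer)) {
    y <- as.numeric(Y %*% a)
    b <- if (use_active_set) {
      active_set_fit(X, y, mapping, weights, lam, tol = bcd_tol,
                     max_sweeps = max_sweeps, b_init = b)
    } else {
      group_lasso_bcd(X, y, mapping, weights, lam, tol = bcd_tol,
                      max_sweeps = max_sweeps, b_init = b)
    }
    sweeps <- c(sweeps, attr(b, "sweeps"))
    b <- as.numeric(b)
    sel <- selected_groups(b, mapping)
    active_sizes <- c(active_sizes, length(sel))
    if (!any(b != 0)) {
      obj_trace <- c(obj_trace, 0.5 * sum(Y^2))
      converged <- TRUE
      break
    }
    b_unit <- b / sqrt(sum(b^2))
    a <- update_a(X, Y, b_unit)
    obj_trace <- c(
      obj_trace,
      0.5 * sum((Y - (X %*% b) %*% t(a))^2) +
        lam * group_penalty(b, mapping, weights)
    )
    kk <- kkt_check(X, y, b, mapping, weights, lam, tol = 1e-4)
    kkt_max <- c(kkt_max, max(kk$max_zero_violation, kk$max_active_violation))
    delta <- max(abs(c(b_unit - b_unit_prev, a - a_prev)))
    b_unit_prev <- b_unit
    a_prev <- a
    if (delta < outer_tol) {
      converged <- TRUE
      break
    }
  }
  sel <- selected_groups(b, mapping)
  structure(
    list(
      b = b, a = a, selected = mapping$pathways[sel],
      selected_index = sel, gamma = gamma, lambda = lam,
      lambda_max = lam_max, weights = weights, mapping = mapping,
      diagnostics = list(
        objective = obj_trace, sweeps = sweeps,
        active_set_sizes = active_sizes, kkt_max = kkt_max,
        converged = converged, n_outer = length(obj_trace),
        outer_tol = outer_tol, bcd_tol = bcd_tol
      )
    ),
    class = "psrrr_fit"
  )
}

selected_groups <- function(b, mapping) {
  lay <- as_group_layout(mapping)
  norms <- vapply(seq_along(lay$size), function(l) {
    sqrt(sum(b[lay$start[l] + seq_len(lay$size[l])]^2))
  }, numeric(1))
  # relative floor guards against numerically negligible boundary leakage
  # (a group sitting exactly at its KKT threshold)
  which(norms > 1e-8 * max(norms, 0))
}

group_penalty <- function(b, mapping, weights) {
  lay <- as_group_layout(mapping)
  sum(vapply(seq_along(lay$size), function(l) {
    weights[l] * sqrt(sum(b[lay$start[l] + seq_len(lay$size[l])]^2))
  }, numeric(1)))
}

#' @export
print.psrrr_fit <- function(x, ...) {
  cat(sprintf(
    "<psrrr_fit> gamma = %.2f, lambda = %.4g (lambda_max = %.4g)\n",
    x$gamma, x$lambda, x$lambda_max
  ))
  if (length(x$selected)) {
    cat("selected pathways:", paste(x$selected, collapse = ", "), "\n")
  } else {
    cat("no pathway selected (empty model)\n")
  }
  cat(sprintf("converged: %s after %d outer iteration(s)\n",
              x$diagnostics$converged, x$diagnostics$n_outer))
  invisible(x)
}
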
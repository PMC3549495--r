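#' Initial pathway weights
#'
#' `w0_l = sqrt(S_l)`, the size correction for the group lasso: larger
#' pathways would otherwise be favoured purely because their coefficient
#' blocks have more entries.
#'
#' @param mapping a [build_pathway_mapping()] object (or a vector of group
#'   sizes).
#' @return Numeric weight vector, named by pathway where available.
#' @export
initial_weights <- function(mapping) {
  if (inherits(mapping, "pathway_mapping")) {
    stats::setNames(sqrt(mapping$sizes), mapping$pathways)
  } else {
    sqrt(as.numeric(mapping))
  }
}

#' Empirical pathway selection frequencies under the permutation null
#'
#' For each permutation, subject rows of `Y` are jointly permuted (breaking
#' the genotype-phenotype link while preserving voxel correlation), and the
#' model is fitted with `lambda` calibrated by bisection in
#' `(0, lambda_max)` so that exactly one pathway is selected. The selection
#' fraction per pathway estimates the null selection distribution
#' `Pi*_l(w)`; without biasing factors it is uniform at `1/L`.
#'
#' @param X expanded standardised design.
#' @param Y phenotype matrix.
#' @param mapping a [build_pathway_mapping()] object.
#' @param weights pathway weights.
#' @param n_perm number of permutations; at least L is recommended (a
#'   warning is raised otherwise).
#' @param seed integer seed; permutation `t` uses `seed + t`.
#' @param max_bisect bisection iterations per permutation (default 40).
#' @param max_outer alternations per calibration fit (default 1: the
#'   calibration only needs the identity of the single selected pathway,
#'   which is determined by the group-lasso step at the initial phenotype
#'   direction; more alternations change the frequencies only marginally at
#'   several times the cost).
#' @return Numeric vector `Pi*` of length L (named by pathway), with
#'   attributes `n_valid` (fits that isolated one pathway) and `counts`.
#' @export
null_selection_frequencies <- function(X, Y, mapping, weights, n_perm,
                                       seed = 1, max_bisect = 40,
                                       max_outer = 1) {
  L <- length(mapping$sizes)
  if (n_perm < L) {
    warning("n_perm (", n_perm, ") is below the number of pathways (", L,
            "); frequency estimates will be coarse.")
  }
  counts <- integer(L)
  n_valid <- 0L
  n <- nrow(Y)
  for (t in seq_len(n_perm)) {
    Yp <- withr::with_seed(seed + t, Y[sample.int(n), , drop = FALSE])
    sel <- calibrate_single_selection(X, Yp, mapping, weights,
                                      max_bisect = max_bisect,
                                      max_outer = max_outer)
    if (length(sel) == 1) {
      counts[sel] <- counts[sel] + 1L
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid < n_perm) {
    warning(n_perm - n_valid, " of ", n_perm,
            " null fits failed to isolate a single pathway and were dropped.")
  }
  if (n_valid == 0) stop("No null fit isolated a single pathway.")
  structure(stats::setNames(counts / n_valid, mapping$pathways),
            n_valid = n_valid, counts = counts)
}

# bisection on lambda so that exactly one pathway is selected; returns the
# selected group index (length 1), or the set found when bisection exhausts.
# The empty-model group scores bracket the answer for near-orthogonal
# groups, so bisection starts between the two largest scores and widens to
# [0, lambda_max] only if that bracket fails.
calibrate_single_selection <- function(X, Y, mapping, weights,
                                       max_bisect = 40, max_outer = 1) {
  a0 <- initial_a(Y)
  lay <- as_group_layout(mapping)
  g <- as.numeric(crossprod(X, Y %*% a0))
  scores <- vapply(seq_along(lay$size), function(l) {
    sqrt(sum(g[lay$start[l] + seq_len(lay$size[l])]^2))
  }, numeric(1)) / weights
  ord <- order(scores, decreasing = TRUE)
  lmax <- scores[ord[1]]
  fit_sel <- function(lam) {
    fit <- fit_psrrr(X, Y, mapping, weights, gamma = min(lam / lmax, 1),
                     max_outer = max_outer, use_active_set = TRUE)
    fit$selected_index
  }
  lo <- if (length(scores) > 1) scores[ord[2]] else 0
  hi <- lmax
  sel <- integer(0)
  widened <- FALSE
  for (k in seq_len(max_bisect)) {
    mid <- (lo + hi) / 2
    sel <- fit_sel(mid)
    if (length(sel) == 1) return(sel)
    if (length(sel) == 0) hi <- mid else lo <- mid
    if (!widened && hi - lo < 1e-12 * lmax) {
      # informed bracket failed (correlated groups); restart on [0, lmax]
      lo <- 0
      hi <- lmax
      widened <- TRUE
    }
  }
  sel
}

#' Iterative pathway weight tuning against selection bias
#'
#' Starting from `w0 = sqrt(S_l)`, repeatedly measures the empirical null
#' selection distribution `Pi*` ([null_selection_frequencies()]) and adjusts
#' each weight by the multiplicative factor of
#' [weight_adjustment_factor()], `w_l <- w_l * (1 - sign(d_l) *
#' eta)^(-L^2 d_l^2)`, where `d_l = Pi*_l - 1/L` (no change when
#' `d_l = 0`). A pathway selected with zero frequency (`d_l = -1/L`)
#' receives the maximal single-iteration reduction `1/(1 + eta)`.
#' Iterations stop when `sum(|d_l|) < epsilon`.
#'
#' @inheritParams null_selection_frequencies
#' @param eta adjustment rate in (0, 1) (default 0.2; larger values
#'   overshoot and can oscillate once deviations reach the 1/L scale).
#' @param epsilon convergence bound on `sum(|d_l|)` (default 0.1).
#' @param n_perm permutations per iteration (default `max(200, 2L)`).
#' @param max_iter maximum tuning iterations (default 20).
#' @param evaluate also measure the tuned weights on an independent
#'   (held-out) permutation set (default TRUE).
#' @param eval_n_perm held-out permutations used when `evaluate = TRUE`
#'   (default `n_perm`).
#'
#' @details The same permutation set (derived from `seed`) is re-used at
#' every iteration — common random numbers — so the convergence signal is
#' not drowned by permutation-sampling noise: over a fixed set, selection
#' is deterministic given the weights, and `sum(|d_l|)` can be driven to
#' the granularity of `1/n_perm`. Because the in-loop deviations are then
#' an optimistic measure, the tuned weights are re-evaluated on a fresh
#' permutation set (`evaluation` element) when `evaluate = TRUE`.
#'
#' @return An object of class `weight_schedule`: list with `iterations`
#'   (tibble: iteration, pathway, weight, pi_star, d, count, n_valid),
#'   `sum_abs_d` per iteration, `final_w`, `eta`, `epsilon`, `n_perm`,
#'   `converged`, and `evaluation` (held-out tibble: pathway, pi_star, d,
#'   count, n_valid, plus attribute `sum_abs_d`).
#' @export
tune_weights <- function(X, Y, mapping, eta = 0.2, epsilon = 0.1,
                         n_perm = NULL, max_iter = 20, seed = 1,
                         max_outer = 1, evaluate = TRUE,
                         eval_n_perm = NULL) {
  if (eta <= 0 || eta >= 1) stop("`eta` must lie strictly in (0, 1).")
  L <- length(mapping$sizes)
  if (is.null(n_perm)) n_perm <- max(200, 2 * L)
  if (is.null(eval_n_perm)) eval_n_perm <- n_perm
  w <- initial_weights(mapping)
  pi_target <- 1 / L
  rows <- list()
  sum_abs_d <- numeric(0)
  converged <- FALSE
  n_increase <- 0L
  for (tau in seq_len(max_iter)) {
    pi_star <- null_selection_frequencies(
      X, Y, mapping, w, n_perm = n_perm, seed = seed,
      max_outer = max_outer
    )
    d <- as.numeric(pi_star) - pi_target
    s <- sum(abs(d))
    sel_counts <- attr(pi_star, "counts")
    n_valid <- attr(pi_star, "n_valid")
    rows[[tau]] <- tibble::tibble(
      iteration = tau, pathway = mapping$pathways, weight = as.numeric(w),
      pi_star = as.numeric(pi_star), d = d,
      count = sel_counts, n_valid = n_valid
    )
    sum_abs_d <- c(sum_abs_d, s)
    if (s < epsilon) {
      converged <- TRUE
      break
    }
    if (tau > 1 && s > sum_abs_d[tau - 1]) n_increase <- n_increase + 1L
    else n_increase <- 0L
    if (n_increase >= 5L) {
      warning("Weight tuning aborted: sum(|d|) increased for 5 consecutive ",
              "iterations (last value ", signif(s, 4), ").")
      break
    }
    w <- w * weight_adjustment_factor(d, eta, L)
  }
  evaluation <- NULL
  if (evaluate) {
    pi_eval <- null_selection_frequencies(
      X, Y, mapping, w, n_perm = eval_n_perm, seed = seed + 777777L,
      max_outer = max_outer
    )
    d_eval <- as.numeric(pi_eval) - pi_target
    evaluation <- tibble::tibble(
      pathway = mapping$pathways, pi_star = as.numeric(pi_eval), d = d_eval,
      count = attr(pi_eval, "counts"), n_valid = attr(pi_eval, "n_valid")
    )
    attr(evaluation, "sum_abs_d") <- sum(abs(d_eval))
  }
  structure(
    list(
      iterations = dplyr::bind_rows(rows), sum_abs_d = sum_abs_d,
      final_w = w, eta = eta, epsilon = epsilon, n_perm = n_perm,
      converged = converged, evaluation = evaluation
    ),
    class = "weight_schedule"
  )
}

#' Multiplicative weight adjustment factor
#'
#' `(1 - sign(d) * eta)^(-L^2 d^2)`, with `d = 0` leaving the weight
#' unchanged (factor 1). An over-selected pathway (`d > 0`) has its weight
#' raised, an under-selected one lowered; the squared deviation makes larger
#' `|d|` produce larger adjustments, and a pathway selected with zero
#' frequency (`d = -1/L`, the most negative value possible) receives the
#' maximal single-iteration reduction, `1/(1 + eta)`, controlled by `eta`.
#' Unlike update rules whose adjustment decays super-exponentially in
#' `1/d^2`, this factor has no dead zone near `d = 0`, so the iteration can
#' refine weights all the way to a uniform null selection distribution.
#' Exposed so the update rule can be inspected and tested directly.
#'
#' @param d per-pathway deviation `Pi*_l - 1/L`, in `[-1/L, 1 - 1/L]`.
#' @param eta adjustment rate in (0, 1).
#' @param L number of pathways.
#' @return Vector of positive factors.
#' @export
weight_adjustment_factor <- function(d, eta, L) {
  (1 - sign(d) * eta)^(-L^2 * d^2)
}

#' @export
print.weight_schedule <- function(x, ...) {
  cat(sprintf(
    "<weight_schedule> %d iteration(s), final sum|d| = %.4g (epsilon = %g), converged: %s\n",
    length(x$sum_abs_d), x$sum_abs_d[length(x$sum_abs_d)], x$epsilon,
    x$converged
  ))
  invisible(x)
}
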
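#' Tidy a PsRRR fit
#'
#' One row per expanded design column, with its pathway, SNP and estimated
#' coefficient.
#'
#' @param x a [fit_psrrr()] result.
#' @param ... unused.
#' @return A tibble: `expanded_col`, `pathway`, `snp_id`, `estimate`,
#'   `selected`.
#' @export
tidy.psrrr_fit <- function(x, ...) {
  out <- x$mapping$expansion_index
  out$estimate <- x$b
  out$selected <- out$pathway %in% x$selected
  dplyr::select(out, "expanded_col", "pathway", "snp_id", "estimate", "selected")
}

#' One-row model summary of a PsRRR fit
#'
#' @inheritParams tidy.psrrr_fit
#' @return A tibble with `gamma`, `lambda`, `lambda_max`, `n_selected`,
#'   `n_outer`, `converged`, `objective`.
#' @export
glance.psrrr_fit <- function(x, ...) {
  obj <- x$diagnostics$objective
  tibble::tibble(
    gamma = x$gamma, lambda = x$lambda, lambda_max = x$lambda_max,
    n_selected = length(x$selected), n_outer = x$diagnostics$n_outer,
    converged = x$diagnostics$converged,
    objective = if (length(obj)) obj[length(obj)] else NA_real_
  )
}

#' Tidy a pathway ranking
#'
#' @param x a [rank_pathways()] result.
#' @param ... unused.
#' @return The pathway frequency tibble (`pathway`, `n_snps`, `freq`,
#'   `rank`).
#' @export
tidy.psrrr_ranking <- function(x, ...) x$pathway_freq

#' One-row summary of a pathway ranking
#'
#' @inheritParams tidy.psrrr_ranking
#' @return A tibble with `B`, `gamma`, `mean_selected` (average number of
#'   selected pathways per subsample), `mean_z` (average stage-2 SNP count).
#' @export
glance.psrrr_ranking <- function(x, ...) {
  tibble::tibble(
    B = x$B, gamma = x$gamma,
    mean_selected = mean(lengths(x$records$selected_pathways)),
    mean_z = mean(x$records$z_b)
  )
}

#' Tidy a weight-tuning schedule
#'
#' @param x a [tune_weights()] result.
#' @param ... unused.
#' @return Long tibble: `iteration`, `pathway`, `weight`, `pi_star`, `d`.
#' @export
tidy.weight_schedule <- function(x, ...) x$iterations

#' One-row summary of a weight-tuning schedule
#'
#' @inheritParams tidy.weight_schedule
#' @return A tibble with `n_iterations`, `final_sum_abs_d`, `epsilon`,
#'   `eta`, `n_perm`, `converged`.
#' @export
glance.weight_schedule <- function(x, ...) {
  tibble::tibble(
    n_iterations = length(x$sum_abs_d),
    final_sum_abs_d = x$sum_abs_d[length(x$sum_abs_d)],
    holdout_sum_abs_d = if (is.null(x$evaluation)) NA_real_ else
      attr(x$evaluation, "sum_abs_d"),
    epsilon = x$epsilon, eta = x$eta, n_perm = x$n_perm,
    converged = x$converged
  )
}

#' Tidy an enrichment test
#'
#' @param x an [enrichment_test()] result.
#' @param ... unused.
#' @return A tibble with `observed_score`, `p_value`, `n_perm`, `n_genes`,
#'   `degenerate`.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    observed_score = x$observed_score, p_value = x$p_value,
    n_perm = x$n_perm, n_genes = length(x$genes_used),
    degenerate = x$degenerate
  )
}

#' @rdname tidy.enrichment_result
#' @export
glance.enrichment_result <- tidy.enrichment_result
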
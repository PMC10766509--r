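#' Permutation importance of committor-model inputs
#'
#' For each input `i`, the training-set loss is re-evaluated on copies of
#' the data with column `i` randomly permuted across records (shuffling
#' in the batch dimension), averaged over `n_perms` shuffles:
#' \deqn{\Delta l_i = \langle l(w, \tilde\theta_i) \rangle - l_{ref}.}
#' Inputs that strongly influence the model prediction get large
#' \eqn{\Delta l_i}; inputs the model ignores get exactly zero. The raw
#' (unnormalized) difference is reported, ranked descending -- the
#' ranking is what downstream symbolic regression consumes.
#'
#' @param model a trained [predict_q()]-capable model.
#' @param data a [training_set()] tibble (>= 2 records).
#' @param n_perms number of permuted copies per input (default 100).
#' @param seed seed for the shuffles.
#' @param inputs input names to score (default: all feature columns).
#' @return tibble with `input`, `delta_l`, `mc_se` (Monte-Carlo standard
#'   error over shuffles), `rank`; attribute `"l_ref"` holds the
#'   unperturbed reference loss.
#' @export
permutation_importance <- function(model, data, n_perms = 100L, seed = 1L,
                                   inputs = NULL) {
  data <- as_tibble(data)
  if (nrow(data) < 2) abort("permutation importance needs >= 2 records")
  if (n_perms < 1) abort("n_perms must be >= 1")
  fn <- if (inherits(model, "committor_net")) model$feature_names else NULL
  X <- feature_matrix(data, fn)
  inputs <- inputs %||% colnames(X)
  l_ref <- nll_loss(predict_q(model, X), data)
  set.seed(seed)
  res <- purrr::map(inputs, function(nm) {
    j <- match(nm, colnames(X))
    losses <- vapply(seq_len(n_perms), function(r) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      nll_loss(predict_q(model, Xp), data)
    }, numeric(1))
    tibble(input = nm, delta_l = mean(losses) - l_ref,
           mc_se = sd(losses) / sqrt(n_perms))
  })
  out <- dplyr::bind_rows(res) |>
    dplyr::arrange(dplyr::desc(.data$delta_l)) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "l_ref") <- l_ref
  out
}

#' Region-restricted permutation importance
#'
#' [permutation_importance()] computed on the subset of records selected
#' by `region_filter` -- for example restricting to training points close
#' to one of the metastable states, where different inputs may control
#' the prediction.
#'
#' @inheritParams permutation_importance
#' @param region_filter logical vector over records, or a predicate
#'   function taking the data tibble and returning one; must keep >= 2
#'   records.
#' @export
restricted_importance <- function(model, data, region_filter,
                                  n_perms = 100L, seed = 1L,
                                  inputs = NULL) {
  data <- as_tibble(data)
  keep <- if (is.function(region_filter)) region_filter(data) else
    region_filter
  if (!is.logical(keep) || length(keep) != nrow(data)) {
    abort("region_filter must select rows of data")
  }
  if (sum(keep) < 2) abort("region filter keeps fewer than 2 records")
  permutation_importance(model, data[keep, , drop = FALSE],
                         n_perms = n_perms, seed = seed, inputs = inputs)
}

#' @rdname permutation_importance
#' @param importance a [permutation_importance()] result.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = stats::reorder(.data$input,
                                                  .data$delta_l),
                               y = .data$delta_l)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$delta_l - .data$mc_se,
      ymax = .data$delta_l + .data$mc_se), width = 0.2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(Delta * l)) +
    ggplot2::theme_minimal()
}
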
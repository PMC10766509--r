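#' Reactive probability of a two-way shot
#'
#' For Markovian time-reversible dynamics, the probability that a two-way
#' shot from a point with committor `p` yields a transition path:
#' \eqn{P(TP|x) = 2 p (1 - p)}. Maximal (1/2) at the transition state
#' `p = 1/2`, symmetric under `p -> 1 - p`.
#'
#' @param p committor value(s) in `[0, 1]`.
#' @export
reactive_probability <- function(p) {
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  2 * p * (1 - p)
}

#' Expected transition-path count over a validation window
#'
#' \deqn{n_{TP}^{exp} = \sum_{i=1}^{k} 2 (1 - p_B(x_i, i)) p_B(x_i, i)}
#' over the `k` most recent shooting attempts, each term using the model
#' prediction recorded before observing that shot's outcome. The window
#' is truncated at the start of the history; void shots (no outcome)
#' carry `NA` and are skipped.
#'
#' @param ledger a run ledger tibble with column `p_pred` (see
#'   [run_guided_sampling()]), or a numeric vector of pre-shot committor
#'   predictions.
#' @param window window length k (default 100 TPS steps).
#' @export
expected_tp_count <- function(ledger, window = 100L) {
  p <- if (is.numeric(ledger)) ledger else {
    if (!"p_pred" %in% names(ledger)) abort("ledger lacks p_pred")
    ledger$p_pred
  }
  if (length(p) == 0) abort("empty ledger")
  p <- tail(p, window)
  sum(reactive_probability(p[!is.na(p)]))
}

#' Efficiency factor of the committor prediction
#'
#' \deqn{\alpha_{eff} = \min(1, (1 - n^{gen}_{TP} / n^{exp}_{TP})^2)}
#' in `[0, 1]`; zero iff the generated count matches the expected count
#' exactly (perfect prediction). A zero expected count is treated as
#' maximal mismatch (`alpha_eff = 1`, with a warning).
#'
#' @param n_gen generated TP count.
#' @param n_exp expected TP count, > 0.
#' @export
efficiency_factor <- function(n_gen, n_exp) {
  if (n_exp <= 0) {
    warn("expected TP count is zero; alpha_eff set to 1")
    return(1)
  }
  min(1, (1 - n_gen / n_exp)^2)
}

#' Learning-rate gate driven by the efficiency factor
#'
#' The efficiency factor scales the base learning rate,
#' `lr = alpha_eff * base_lr`, and training is skipped entirely when the
#' scaled rate falls below `floor` (for the defaults
#' \eqn{10^{-3}, 10^{-4}} this is the same as requiring
#' \eqn{\alpha_{eff} \ge 0.1}). Training only when prediction is poor
#' avoids overfitting to already-explained outcomes.
#'
#' @param alpha_eff efficiency factor in `[0, 1]`.
#' @param base_lr base learning rate, > 0.
#' @param floor minimum admissible learning rate.
#' @return list with `should_train` and `lr`.
#' @export
training_gate <- function(alpha_eff, base_lr = 1e-3, floor = 1e-4) {
  if (base_lr <= 0) abort("base_lr must be > 0")
  lr <- alpha_eff * base_lr
  list(should_train = lr >= floor, lr = lr)
}

#' Estimate the committor by repeated shooting
#'
#' Shoots `n_shots` independent one-way trajectories (fresh
#' Maxwell--Boltzmann velocities each) from a configuration and estimates
#' the committor as the fraction entering the second state ("B") first.
#' Uncommitted trials are discarded; an error is raised if no trial
#' commits.
#'
#' @param point a [phase_point()].
#' @param engine,potential,states simulation setup (second state = "B").
#' @param n_shots number of trials.
#' @param seed optional seed.
#' @return tibble with `p_hat` (= n_B / n), `n_B`, `n_A`, `n`
#'   (committed trials) and the binomial standard error `se`.
#' @export
sample_committor <- function(point, engine, potential, states, n_shots,
                             seed = NULL) {
  if (n_shots < 1) abort("n_shots must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  labs <- character(n_shots)
  for (i in seq_len(n_shots)) {
    pt <- if (engine$kind == "underdamped") {
      draw_maxwell_boltzmann(point, engine$kT)
    } else point
    tr <- tryCatch(propagate_committed(engine, potential, pt, states,
                                       record = FALSE),
                   guidedtps_uncommitted = function(e) NULL)
    labs[i] <- if (is.null(tr)) NA_character_ else tr$label
  }
  labs <- labs[!is.na(labs)]
  if (length(labs) == 0) abort("all trials uncommitted")
  n <- length(labs)
  n_B <- sum(labs == states[[2]]$label)
  p <- n_B / n
  tibble(p_hat = p, n_B = n_B, n_A = n - n_B, n = n,
         se = sqrt(p * (1 - p) / n))
}

#' Cross-validate predicted against sampled committors in bins
#'
#' Bins held-out configurations by their model-predicted committor and
#' summarizes the independently sampled committor within each bin: for a
#' calibrated model the bin means fall on the identity line. Empty bins
#' are absent from the output, not zero.
#'
#' @param predicted model committor values for configurations not used in
#'   training.
#' @param sampled shooting-estimated committors for the same
#'   configurations.
#' @param bin_edges committor bin edges (default ten equal bins).
#' @return tibble with per-bin `bin_mid`, `n`, `mean_sampled`,
#'   `sd_sampled`; attribute `"max_deviation"` holds
#'   \eqn{\max_b |mean_b - mid_b|}.
#' @export
crossval_bins <- function(predicted, sampled,
                          bin_edges = seq(0, 1, by = 0.1)) {
  if (length(predicted) != length(sampled)) abort("length mismatch")
  bin <- cut(predicted, bin_edges, include.lowest = TRUE)
  mids <- (head(bin_edges, -1) + tail(bin_edges, -1)) / 2
  out <- tibble(bin = bin, mid = mids[as.integer(bin)],
                sampled = sampled) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .data$mid) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_sampled = mean(.data$sampled),
                     sd_sampled = sd(.data$sampled), .groups = "drop") |>
    dplyr::rename(bin_mid = "mid")
  attr(out, "max_deviation") <- max(abs(out$mean_sampled - out$bin_mid))
  out
}

#' Self-consistency and calibration plots
#'
#' `plot_ledger()` shows the cumulative generated and expected TP counts
#' and their cumulative difference as the run proceeds; a plateauing
#' difference signals a converged committor. `plot_crossval()` shows the
#' binned sampled committor against the predicted committor with the
#' identity line.
#'
#' @param run a `guided_tps_run` (or its ledger tibble).
#' @export
plot_ledger <- function(run) {
  led <- if (inherits(run, "guided_tps_run")) run$ledger else run
  p <- ifelse(is.na(led$p_pred), 0, led$p_pred)
  df <- tibble(step = led$step,
               generated = cumsum(led$generated),
               expected = cumsum(reactive_probability(p)))
  df$difference <- df$generated - df$expected
  long <- tidyr_pivot(df)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$count,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "TPS step", y = "cumulative TP count",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format helper (avoids a tidyr dependency for one reshape)
tidyr_pivot <- function(df) {
  dplyr::bind_rows(
    tibble(step = df$step, count = df$generated, curve = "generated"),
    tibble(step = df$step, count = df$expected, curve = "expected"),
    tibble(step = df$step, count = df$difference, curve = "difference")
  )
}

#' @rdname plot_ledger
#' @param bins a [crossval_bins()] result.
#' @export
plot_crossval <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_mid,
                                     y = .data$mean_sampled)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_sampled - .data$sd_sampled,
      ymax = .data$mean_sampled + .data$sd_sampled)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "predicted committor", y = "sampled committor") +
    ggplot2::theme_minimal()
}
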
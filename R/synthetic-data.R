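#' Synthetic fixtures for every stage of the pipeline
#'
#' Programmatic stand-ins for the molecular datasets the method is
#' normally run on, each emulating the statistical structure the
#' corresponding module consumes.
#'
#' `generate_point_cloud()` draws an ideal-gas (uniform Poisson) 3D point
#' cloud of density `rho` in a cubic box centred on the origin -- the
#' reference distribution of the symmetry-function normalizers.
#'
#' `generate_logistic_records()` draws feature vectors and Bernoulli
#' shooting outcomes from a planted committor
#' \eqn{p_B(x) = \sigma(q(x))}: the outcome is `s = -1` (enters B first)
#' with probability \eqn{p_B} -- exactly the likelihood the committor
#' loss maximizes, so planted parameters are recoverable.
#'
#' `generate_planted_polylines()` draws noisy polylines around bundle
#' template curves, the planted-cluster input for DTW clustering.
#'
#' `generate_shooting_table()` emulates a pre-existing offline shooting
#' dataset (features concentrated around the transition region, outcomes
#' from a planted nonlinear committor) for offline training and
#' distillation.
#'
#' @param rho number density of the cloud.
#' @param box_half half edge length of the cubic box.
#' @param seed integer seed.
#' @return a tibble (records, cloud) or list of matrices (polylines).
#' @export
generate_point_cloud <- function(rho = 1, box_half = 2.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vol <- (2 * box_half)^3
  n <- stats::rpois(1, rho * vol)
  tibble(x = runif(n, -box_half, box_half),
         y = runif(n, -box_half, box_half),
         z = runif(n, -box_half, box_half))
}

#' @rdname generate_point_cloud
#' @param n number of records.
#' @param q_fun planted log-predictor: function of a feature matrix.
#' @param d number of features.
#' @param x_range uniform sampling range of each feature.
#' @export
generate_logistic_records <- function(n, q_fun, d = 1L,
                                      x_range = c(0, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(runif(n * d, x_range[1], x_range[2]), n, d)
  colnames(X) <- paste0("x", seq_len(d))
  p_B <- sigmoid_link(q_fun(X))
  s <- ifelse(runif(n) < p_B, -1, 1)
  training_set(X, s = s, step_index = seq_len(n))
}

#' @rdname generate_point_cloud
#' @param n_per_bundle polylines per bundle.
#' @param templates list of template matrices (one per bundle).
#' @param noise_sd Gaussian jitter around the template.
#' @param len_jitter maximal fraction of frames dropped at either end.
#' @export
generate_planted_polylines <- function(n_per_bundle = 20,
                                       templates = default_bundles(),
                                       noise_sd = 0.05, len_jitter = 0.2,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  labels <- integer(0)
  for (b in seq_along(templates)) {
    tpl <- templates[[b]]
    for (i in seq_len(n_per_bundle)) {
      drop_head <- sample.int(max(1, round(len_jitter * nrow(tpl))), 1) - 1L
      drop_tail <- sample.int(max(1, round(len_jitter * nrow(tpl))), 1) - 1L
      keep <- seq(1 + drop_head, nrow(tpl) - drop_tail)
      m <- tpl[keep, , drop = FALSE] +
        matrix(rnorm(length(keep) * ncol(tpl), sd = noise_sd),
               ncol = ncol(tpl))
      out[[length(out) + 1]] <- m
      labels <- c(labels, b)
    }
  }
  attr(out, "bundle") <- labels
  out
}

default_bundles <- function(n_frames = 50) {
  t <- seq(0, 1, length.out = n_frames)
  list(cbind(t, 0.5 * sin(pi * t)),    # upper channel
       cbind(t, -0.5 * sin(pi * t)))   # lower channel
}

#' @rdname generate_point_cloud
#' @param potential,engine,states simulation setup for the planted
#'   committor (defaults: the 1D quartic double well study system).
#' @param sp_sd spread of shooting points around the barrier top.
#' @export
generate_shooting_table <- function(n, potential = potential_spec(),
                                    engine = engine_params(),
                                    states = default_states_1d(),
                                    sp_sd = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- states[[1]]$upper[1]; b <- states[[2]]$lower[1]
  x <- pmin(pmax(rnorm(n, 0, sp_sd), a), b)
  p <- analytic_committor_1d(potential, engine$kT, a, b, x)
  s <- ifelse(runif(n) < p, -1, 1)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x1"))
  training_set(X, s = s, step_index = seq_len(n))
}

#' Default study system: the 1D quartic double well
#'
#' States `A` (`x <= -0.9`) and `B` (`x >= 0.9`) of the
#' `double_well_1d` potential with its default barrier `h = 4` and well
#' separation `x0 = 1` -- the smallest system exercising every stage of
#' the algorithm.
#'
#' @param edge state boundary position.
#' @export
default_states_1d <- function(edge = 0.9) {
  list(state_def("A", -Inf, -edge), state_def("B", edge, Inf))
}

#' @rdname default_states_1d
#' @param edge_x state boundary along the channel coordinate.
#' @export
default_states_2d <- function(edge_x = 0.9) {
  list(state_def("A", c(-Inf, -Inf), c(-edge_x, Inf)),
       state_def("B", c(edge_x, -Inf), c(Inf, Inf)))
}
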
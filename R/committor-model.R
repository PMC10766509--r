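#' Sigmoid link between log-predictor and committor
#'
#' \eqn{p_B = 1/(1 + e^{-q})}: strictly increasing, `p_B(0) = 1/2`,
#' `p_B(-q) = 1 - p_B(q)`; overflow-safe for arbitrarily large `|q|`.
#'
#' @param q log-predictor value(s).
#' @export
sigmoid_link <- function(q) plogis(q)

#' Softmax link for N-state committors
#'
#' Normalized state probabilities from a real log-predictor vector;
#' invariant to adding a constant to all components. With two components
#' `(q, 0)` the second probability equals `sigmoid_link(-q)`, i.e. the
#' two-state parameterization is recovered.
#'
#' @param q_vec numeric vector (length >= 2) or matrix (one row per point).
#' @export
softmax_link <- function(q_vec) {
  if (is.matrix(q_vec)) {
    z <- exp(q_vec - apply(q_vec, 1, max))
    return(z / rowSums(z))
  }
  z <- exp(q_vec - max(q_vec))
  z / sum(z)
}

#' Pyramidal network architecture
#'
#' Hidden-layer widths decay geometrically from `input_width` to
#' `final_width` over `n_blocks` blocks with ratio
#' \eqn{f = (final/input)^{1/(n_{blocks}-1)}}; the dropout schedule is
#' `dropout0 * f^i` for block `i = 0, ..., n_blocks - 1`. The final layer
#' is always a single linear neuron, the log-predictor. `n_blocks = 0`
#' yields a purely linear (logistic-regression) model.
#'
#' @param input_width width of the first hidden block (>= `final_width`).
#' @param n_blocks number of hidden blocks (>= 0).
#' @param final_width width of the last hidden block (>= 1).
#' @param dropout0 dropout probability of the first block.
#' @param activation hidden activation, `"tanh"` or `"relu"`.
#' @return a list of class `pyramid_arch` with `widths`, `dropout`,
#'   `decay_factor` and `activation`.
#' @export
build_pyramid <- function(input_width, n_blocks, final_width = input_width,
                          dropout0 = 0, activation = c("tanh", "relu")) {
  activation <- match.arg(activation)
  if (n_blocks == 0) {
    return(structure(list(widths = integer(0), dropout = numeric(0),
                          decay_factor = 1, activation = activation),
                     class = "pyramid_arch"))
  }
  if (final_width < 1 || input_width < final_width) {
    abort("need input_width >= final_width >= 1")
  }
  f <- if (n_blocks == 1) 1 else (final_width / input_width)^(1 / (n_blocks - 1))
  i <- seq_len(n_blocks) - 1
  widths <- round(input_width * f^i)
  widths[n_blocks] <- final_width
  structure(list(widths = as.integer(widths), dropout = dropout0 * f^i,
                 decay_factor = f, activation = activation),
            class = "pyramid_arch")
}

#' Parametric committor model
#'
#' A feed-forward network \eqn{q(x|w)} modelling the committor through a
#' sigmoid (two-state) or softmax (N-state) link. Weights are initialized
#' with Glorot-uniform scaling; training is full-batch Adam on the
#' shooting-outcome likelihood (see [nll_loss()], [train_committor()]).
#'
#' @param n_in number of input features.
#' @param arch a [build_pyramid()] architecture.
#' @param n_out output width (1 for the two-state log-predictor, N for
#'   softmax over N states).
#' @param link `"sigmoid"` or `"softmax"`.
#' @param feature_names optional input names (default `x1...`).
#' @param seed integer seed for weight initialization.
#' @export
committor_net <- function(n_in, arch = build_pyramid(16, 2, 8), n_out = 1L,
                          link = c("sigmoid", "softmax"),
                          feature_names = NULL, seed = 1L) {
  link <- match.arg(link)
  if (link == "softmax" && n_out < 2) abort("softmax link needs n_out >= 2")
  set.seed(seed)
  sizes <- c(n_in, arch$widths, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(arch = arch, W = W, b = b, n_in = n_in, n_out = n_out,
                 link = link,
                 feature_names = feature_names %||% paste0("x", seq_len(n_in)),
                 opt = NULL, epochs_trained = 0L, last_loss = NA_real_),
            class = "committor_net")
}

act_fun <- function(z, activation) {
  if (activation == "tanh") tanh(z) else pmax(z, 0)
}
act_grad <- function(z, h, activation) {
  if (activation == "tanh") 1 - h^2 else (z > 0) * 1
}

forward_net <- function(model, X, dropout = FALSE) {
  nh <- length(model$arch$widths)
  H <- X
  cache <- list(H = vector("list", nh + 1), Z = vector("list", nh),
                mask = vector("list", nh))
  cache$H[[1]] <- H
  for (l in seq_len(nh)) {
    Z <- H %*% model$W[[l]] + rep(model$b[[l]], each = nrow(H))
    H <- act_fun(Z, model$arch$activation)
    p <- model$arch$dropout[l]
    if (dropout && p > 0) {
      mask <- matrix(runif(length(H)) >= p, nrow(H), ncol(H)) / (1 - p)
      H <- H * mask
      cache$mask[[l]] <- mask
    }
    cache$Z[[l]] <- Z
    cache$H[[l + 1]] <- H
  }
  q <- H %*% model$W[[nh + 1]] + rep(model$b[[nh + 1]], each = nrow(H))
  list(q = q, cache = cache)
}

#' Predict the log-predictor q for a feature matrix
#'
#' Generic dispatched on the model type: learned networks
#' ([committor_net()]), frozen analytic committors
#' ([analytic_committor_model()]), distilled symbolic expressions
#' ([sr_expr]) and plain functions all answer it, so any of them can guide
#' sampling or define softened states.
#'
#' @param model a committor-like model.
#' @param x feature matrix (one row per point) or vector.
#' @param ... passed to methods.
#' @return numeric vector of q values (matrix for softmax models).
#' @export
predict_q <- function(model, x, ...) UseMethod("predict_q")

#' @export
predict_q.committor_net <- function(model, x, ...) {
  if (!is.matrix(x)) x <- matrix(x, ncol = model$n_in)
  q <- forward_net(model, x)$q
  if (model$n_out == 1L) as.numeric(q) else q
}

#' @export
predict_q.function <- function(model, x, ...) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  as.numeric(model(x))
}

#' @export
predict.committor_net <- function(object, newdata,
                                  type = c("q", "prob"), ...) {
  type <- match.arg(type)
  X <- feature_matrix(newdata, object$feature_names)
  q <- predict_q(object, X)
  if (type == "q") return(q)
  if (object$link == "sigmoid") sigmoid_link(q) else softmax_link(q)
}

meta_columns <- c("chain_id", "step_index", "s", "n_A", "n_B", "outcome",
                  "weight", "p_pred")

feature_matrix <- function(data, feature_names = NULL) {
  if (is.matrix(data)) return(data)
  data <- as_tibble(data)
  cols <- feature_names %||% setdiff(names(data), meta_columns)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(paste0("missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  as.matrix(data[cols])
}

#' Assemble a shooting training set
#'
#' One row per trial trajectory: the shooting-point features plus the
#' binary outcome `s` (+1 if the trajectory entered state A first, -1 if
#' B), with chain/step provenance. The aggregate form stores per-point
#' counts `n_A`, `n_B` instead of `s`; both forms give identical
#' likelihoods.
#'
#' @param features data frame / matrix of feature vectors.
#' @param s outcome vector in \{+1, -1\} (omit when using counts).
#' @param n_A,n_B aggregate outcome counts (omit when using `s`).
#' @param chain_id,step_index provenance metadata.
#' @export
training_set <- function(features, s = NULL, n_A = NULL, n_B = NULL,
                         chain_id = 1L, step_index = NA_integer_) {
  if (is.matrix(features)) features <- as_tibble(as.data.frame(features))
  features <- as_tibble(features)
  if (is.null(s) == is.null(n_A)) {
    abort("supply exactly one of s or (n_A, n_B)")
  }
  out <- tibble(chain_id = rep_len(chain_id, nrow(features)),
                step_index = rep_len(step_index, nrow(features)))
  if (!is.null(s)) {
    if (!all(s %in% c(-1, 1))) abort("s must be +1 or -1")
    out$s <- s
  } else {
    if (any(n_A < 0) || any(n_B < 0)) abort("counts must be >= 0")
    out$n_A <- n_A; out$n_B <- n_B
  }
  dplyr::bind_cols(out, features)
}

#' Negative log-likelihood of shooting outcomes
#'
#' The maximum-likelihood loss for committor estimation from Bernoulli
#' shooting outcomes,
#' \deqn{l(w|\theta) = \sum_i \log(1 + e^{s_i q(x_i|w)}),}
#' equal (up to the fixed binomial coefficient) to
#' \eqn{-\sum_i [n_A \log(1 - p_B) + n_B \log p_B]} in the aggregate-count
#' form. `model` may be any [predict_q()]-capable object or a precomputed
#' numeric q vector.
#'
#' @param model committor model or numeric q values.
#' @param data a [training_set()] tibble (nonempty).
#' @return total loss (a scalar).
#' @export
nll_loss <- function(model, data) {
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("empty training data")
  q <- if (is.numeric(model)) {
    model
  } else {
    fn <- if (inherits(model, "committor_net")) model$feature_names else NULL
    predict_q(model, feature_matrix(data, fn))
  }
  if ("s" %in% names(data)) {
    sum(log1pexp(data$s * q))
  } else if (all(c("n_A", "n_B") %in% names(data))) {
    sum(data$n_A * log1pexp(q) + data$n_B * log1pexp(-q))
  } else {
    abort("data must contain s or (n_A, n_B)")
  }
}

# multinomial NLL for softmax models: data$outcome in 1..N
nll_loss_multi <- function(q, outcome) {
  p <- softmax_link(q)
  -sum(log(pmax(p[cbind(seq_along(outcome), outcome)], 1e-300)))
}

# gradient of the loss w.r.t. q (n x n_out)
loss_grad_q <- function(q, data) {
  if ("s" %in% names(data)) {
    matrix(data$s * plogis(data$s * as.numeric(q)), ncol = 1)
  } else if (all(c("n_A", "n_B") %in% names(data))) {
    matrix(data$n_A * plogis(as.numeric(q)) -
             data$n_B * plogis(-as.numeric(q)), ncol = 1)
  } else {
    p <- softmax_link(q)
    onehot <- matrix(0, nrow(q), ncol(q))
    onehot[cbind(seq_len(nrow(q)), data$outcome)] <- 1
    p - onehot
  }
}

adam_init <- function(model) {
  list(mW = lapply(model$W, function(w) w * 0),
       vW = lapply(model$W, function(w) w * 0),
       mb = lapply(model$b, function(b) b * 0),
       vb = lapply(model$b, function(b) b * 0),
       t = 0L)
}

#' Train the committor model by maximum likelihood
#'
#' Full-batch Adam gradient descent on [nll_loss()]. `train_epoch()` is
#' the single-pass form used inside the guided sampling loop (the live
#' validation gate scales its learning rate). Optimizer state persists in
#' the model so training can resume. Deterministic under a fixed seed.
#'
#' @param model a [committor_net()].
#' @param data a [training_set()] tibble.
#' @param epochs number of full-batch passes.
#' @param learning_rate Adam step size (the base rate is
#'   \eqn{10^{-3}}); 0 leaves the weights unchanged.
#' @param seed optional seed (dropout and any stochastic parts).
#' @param beta1,beta2,eps_adam Adam moment parameters.
#' @param trainable_layers indices of layers to update (default all);
#'   used by [transfer_retrain_last_layer()].
#' @return the updated model, with attribute `"loss_trace"`.
#' @export
train_committor <- function(model, data, epochs = 1, learning_rate = 1e-3,
                            seed = NULL, beta1 = 0.9, beta2 = 0.999,
                            eps_adam = 1e-8, trainable_layers = NULL) {
  if (learning_rate < 0) abort("learning_rate must be >= 0")
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("empty training data")
  if (!is.null(seed)) set.seed(seed)
  X <- feature_matrix(data, model$feature_names)
  if (is.null(model$opt)) model$opt <- adam_init(model)
  nL <- length(model$W)
  layers <- trainable_layers %||% seq_len(nL)
  trace <- numeric(epochs)
  use_dropout <- any(model$arch$dropout > 0)
  for (ep in seq_len(epochs)) {
    fw <- forward_net(model, X, dropout = use_dropout)
    loss <- if (model$n_out == 1L) {
      nll_loss(as.numeric(fw$q), data)
    } else {
      nll_loss_multi(fw$q, data$outcome)
    }
    if (!is.finite(loss)) abort("non-finite loss; aborting training")
    trace[ep] <- loss
    delta <- loss_grad_q(fw$q, data)           # n x n_out
    nh <- length(model$arch$widths)
    gW <- vector("list", nL); gb <- vector("list", nL)
    for (l in seq(nL, 1)) {
      H_in <- fw$cache$H[[l]]
      gW[[l]] <- unname(crossprod(H_in, delta))
      gb[[l]] <- colSums(delta)
      if (l > 1) {
        delta <- delta %*% t(model$W[[l]])
        if (!is.null(fw$cache$mask[[l - 1]])) {
          delta <- delta * fw$cache$mask[[l - 1]]
        }
        delta <- delta * act_grad(fw$cache$Z[[l - 1]], NULL_safe_H(fw, l),
                                  model$arch$activation)
      }
    }
    model$opt$t <- model$opt$t + 1L
    t <- model$opt$t
    for (l in layers) {
      model$opt$mW[[l]] <- beta1 * model$opt$mW[[l]] + (1 - beta1) * gW[[l]]
      model$opt$vW[[l]] <- beta2 * model$opt$vW[[l]] + (1 - beta2) * gW[[l]]^2
      model$opt$mb[[l]] <- beta1 * model$opt$mb[[l]] + (1 - beta1) * gb[[l]]
      model$opt$vb[[l]] <- beta2 * model$opt$vb[[l]] + (1 - beta2) * gb[[l]]^2
      mW <- model$opt$mW[[l]] / (1 - beta1^t)
      vW <- model$opt$vW[[l]] / (1 - beta2^t)
      mb <- model$opt$mb[[l]] / (1 - beta1^t)
      vb <- model$opt$vb[[l]] / (1 - beta2^t)
      model$W[[l]] <- model$W[[l]] - learning_rate * mW / (sqrt(vW) + eps_adam)
      model$b[[l]] <- model$b[[l]] - learning_rate * mb / (sqrt(vb) + eps_adam)
    }
    model$epochs_trained <- model$epochs_trained + 1L
  }
  model$last_loss <- trace[length(trace)]
  attr(model, "loss_trace") <- trace
  model
}

NULL_safe_H <- function(fw, l) {
  # post-activation H of layer l-1 before dropout is not cached separately;
  # tanh' computed from Z directly when a mask was applied
  H <- fw$cache$H[[l]]
  if (is.null(fw$cache$mask[[l - 1]])) H else tanh(fw$cache$Z[[l - 1]])
}

#' @rdname train_committor
#' @export
train_epoch <- function(model, data, learning_rate = 1e-3, seed = NULL) {
  train_committor(model, data, epochs = 1, learning_rate = learning_rate,
                  seed = seed)
}

#' Transfer-retrain the final layer on new shooting data
#'
#' The last layer (a single linear neuron, the log-predictor) is
#' re-randomized and retrained while all other weights stay frozen --
#' the mechanism by which a committor learned on one system is adapted to
#' a chemically related one from a small amount of new shooting data.
#' A fraction of `new_data` is held out; training stops when the held-out
#' loss has not improved for `patience` epochs, and the parameters with
#' the best held-out loss are returned.
#'
#' @param model a trained [committor_net()].
#' @param new_data a [training_set()] tibble.
#' @param learning_rate Adam step size (default 2.5e-5).
#' @param test_frac held-out fraction.
#' @param patience epochs without held-out improvement before stopping.
#' @param max_epochs hard cap on epochs.
#' @param seed seed for the split and re-randomization.
#' @return the adapted model, with attribute `"transfer_history"`.
#' @export
transfer_retrain_last_layer <- function(model, new_data,
                                        learning_rate = 2.5e-5,
                                        test_frac = 0.2, patience = 200,
                                        max_epochs = 5000, seed = 1L) {
  new_data <- as_tibble(new_data)
  if (nrow(new_data) == 0) abort("empty training data")
  X <- feature_matrix(new_data, model$feature_names)
  if (ncol(X) != model$n_in) abort("feature width mismatch")
  set.seed(seed)
  nL <- length(model$W)
  lim <- sqrt(6 / (nrow(model$W[[nL]]) + ncol(model$W[[nL]])))
  model$W[[nL]] <- matrix(runif(length(model$W[[nL]]), -lim, lim),
                          nrow(model$W[[nL]]), ncol(model$W[[nL]]))
  model$b[[nL]] <- model$b[[nL]] * 0
  model$opt <- adam_init(model)
  n <- nrow(new_data)
  test_idx <- sample.int(n, max(1L, round(test_frac * n)))
  train <- new_data[-test_idx, , drop = FALSE]
  test <- new_data[test_idx, , drop = FALSE]
  best <- list(loss = Inf, W = model$W[[nL]], b = model$b[[nL]])
  stale <- 0L
  hist <- numeric(0)
  for (ep in seq_len(max_epochs)) {
    model <- train_committor(model, train, epochs = 1,
                             learning_rate = learning_rate,
                             trainable_layers = nL)
    test_loss <- nll_loss(model, test)
    hist <- c(hist, test_loss)
    if (test_loss < best$loss - 1e-12) {
      best <- list(loss = test_loss, W = model$W[[nL]], b = model$b[[nL]])
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale > patience) break
    }
  }
  model$W[[nL]] <- best$W
  model$b[[nL]] <- best$b
  model$last_loss <- best$loss
  attr(model, "transfer_history") <- hist
  model
}

#' Per-coordinate gradient attribution
#'
#' Magnitude of the gradient of the log-predictor with respect to each
#' position coordinate, scaled by the inverse particle mass:
#' \eqn{|\partial q / \partial x_j| / m_j}. Gradients are taken through
#' the feature map by central finite differences, so any
#' finite-differenceable featurization works.
#'
#' @param model a [predict_q()]-capable model.
#' @param point a [phase_point()] or numeric position vector.
#' @param feature_map function from a position matrix to a feature matrix
#'   (default: identity).
#' @param masses particle masses (default: the point's own, else 1).
#' @param eps finite-difference step.
#' @return nonnegative numeric vector, one entry per coordinate.
#' @export
gradient_attribution <- function(model, point, feature_map = identity_features,
                                 masses = NULL, eps = 1e-5) {
  pos <- if (inherits(point, "phase_point")) point$positions else as.numeric(point)
  masses <- masses %||%
    (if (inherits(point, "phase_point")) point$masses else rep(1, length(pos)))
  masses <- rep_len(masses, length(pos))
  qfun <- function(p) predict_q(model, feature_map(matrix(p, nrow = 1)))
  g <- vapply(seq_along(pos), function(j) {
    hi <- pos; hi[j] <- hi[j] + eps
    lo <- pos; lo[j] <- lo[j] - eps
    (qfun(hi) - qfun(lo)) / (2 * eps)
  }, numeric(1))
  if (any(!is.finite(g))) abort("non-finite gradient")
  abs(g) / masses
}

#' @export
print.committor_net <- function(x, ...) {
  cat("<committor_net>", x$n_in, "->",
      paste(x$arch$widths, collapse = "-"),
      "->", x$n_out, sprintf("(%s link, %s)\n", x$link, x$arch$activation))
  cat("  epochs trained:", x$epochs_trained,
      " last loss:", format(x$last_loss), "\n")
  invisible(x)
}

#' @export
tidy.committor_net <- function(x, ...) {
  sizes <- c(x$n_in, x$arch$widths, x$n_out)
  tibble(layer = seq_len(length(sizes) - 1),
         width_in = sizes[-length(sizes)],
         width_out = sizes[-1],
         n_parameters = sizes[-length(sizes)] * sizes[-1] + sizes[-1],
         dropout = c(x$arch$dropout, 0))
}

#' @export
glance.committor_net <- function(x, ...) {
  tibble(n_inputs = x$n_in,
         n_hidden_layers = length(x$arch$widths),
         n_parameters = sum(tidy(x)$n_parameters),
         link = x$link,
         activation = x$arch$activation,
         epochs_trained = x$epochs_trained,
         last_loss = x$last_loss)
}
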
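test_that("sigmoid link obeys its exact values and symmetry", {
  expect_equal(sigmoid_link(0), 0.5)
  expect_equal(sigmoid_link(4), 1 / (1 + exp(-4)), tolerance = 1e-9)
  expect_equal(sigmoid_link(-4), 1 - sigmoid_link(4), tolerance = 1e-12)
  # overflow-safe far into the tails
  expect_equal(sigmoid_link(1e3), 1)
  expect_equal(sigmoid_link(-1e3), 0)
  q <- seq(-5, 5, 0.5)
  expect_true(all(diff(sigmoid_link(q)) > 0))
})

test_that("softmax link normalizes, shifts invariantly and reduces to the sigmoid", {
  expect_equal(softmax_link(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_link(c(3, 3, 3)), rep(1 / 3, 3))
  expect_lt(abs(sum(softmax_link(c(2, -1, 0.5))) - 1), 1e-12)
  expect_equal(softmax_link(c(2, -1, 0.5)), softmax_link(c(2, -1, 0.5) + 7),
               tolerance = 1e-12)
  # two-state consistency: softmax((q, 0))[2] = sigmoid(-q) = 1 - p_B(q)
  for (q in c(-3, 0, 1, 4)) {
    expect_equal(softmax_link(c(q, 0))[2], sigmoid_link(-q),
                 tolerance = 1e-12)
  }
})

test_that("the shooting-outcome loss matches its closed forms", {
  X <- matrix(runif(10), 10, 1, dimnames = list(NULL, "x1"))
  d <- training_set(X, s = rep(c(1, -1), 5))
  # maximal-ignorance value k log 2 at q = 0
  expect_equal(nll_loss(rep(0, 10), d), 10 * log(2))
  # one record entering B with q = log 9: log(1 + e^{-log 9}) = log(10/9)
  d1 <- training_set(X[1, , drop = FALSE], s = -1)
  expect_equal(nll_loss(log(9), d1), log(10 / 9), tolerance = 1e-12)
  # perfect separation limit drives the loss to zero
  expect_lt(nll_loss(d$s * -50, d), 1e-12)
  expect_error(nll_loss(numeric(0), d[0, ]), "empty")
})

test_that("per-record and aggregate-count losses agree", {
  set.seed(31)
  x <- rep(c(0.2, 0.6, 0.9), times = c(4, 3, 5))
  s <- c(1, 1, -1, -1,  1, -1, -1,  rep(-1, 4), 1)
  per <- training_set(matrix(x, ncol = 1, dimnames = list(NULL, "x1")), s = s)
  q <- 2 * x - 1
  agg <- tibble::tibble(
    n_A = c(2, 1, 1), n_B = c(2, 2, 4),
    x1 = c(0.2, 0.6, 0.9))
  expect_equal(nll_loss(q, per), nll_loss(2 * agg$x1 - 1, agg),
               tolerance = 1e-12)
})

test_that("pyramid architectures follow the printed geometric schedule", {
  # the published width-decay example: 221 -> 10 over 5 blocks
  a <- build_pyramid(221, 5, 10, dropout0 = 0.1)
  expect_equal(a$decay_factor, (10 / 221)^(1 / 4), tolerance = 1e-12)
  expect_equal(round(a$decay_factor, 4), 0.4612)
  expect_equal(length(a$widths), 5)
  expect_equal(a$widths[1], 221)
  expect_equal(a$widths[5], 10)
  expect_true(all(diff(a$widths) < 0))
  expect_equal(a$dropout, 0.1 * a$decay_factor^(0:4), tolerance = 1e-12)
  # degenerate constant-width pyramid
  b <- build_pyramid(8, 3, 8)
  expect_equal(b$widths, rep(8L, 3))
  expect_equal(build_pyramid(8, 3, 8, dropout0 = 0)$dropout, rep(0, 3))
  expect_error(build_pyramid(4, 2, 8), "final_width")
})

test_that("training reduces the loss on separable data and is seed-deterministic", {
  set.seed(32)
  X <- matrix(c(runif(40, -1, -0.2), runif(40, 0.2, 1)), ncol = 1,
              dimnames = list(NULL, "x1"))
  d <- training_set(X, s = rep(c(1, -1), each = 40))
  net <- committor_net(1, build_pyramid(8, 1), seed = 7)
  net200 <- train_committor(net, d, epochs = 200, learning_rate = 0.05)
  expect_lt(nll_loss(net200, d), 0.1 * nrow(d) * log(2))
  trace <- attr(net200, "loss_trace")
  expect_lt(trace[200], trace[1])
  # zero learning rate leaves all weights unchanged
  frozen <- train_committor(net, d, epochs = 5, learning_rate = 0)
  expect_identical(frozen$W, net$W)
  # identical seeds give identical weights
  n1 <- train_committor(committor_net(1, build_pyramid(8, 1), seed = 3),
                        d, epochs = 50, learning_rate = 0.01, seed = 5)
  n2 <- train_committor(committor_net(1, build_pyramid(8, 1), seed = 3),
                        d, epochs = 50, learning_rate = 0.01, seed = 5)
  expect_identical(n1$W, n2$W)
})

test_that("maximum likelihood recovers a planted logistic committor", {
  d <- generate_logistic_records(5000, function(X) 4 * X[, 1] - 2, seed = 33)
  net <- fit_linear_net(d, epochs = 2500, lr = 0.05)
  a_hat <- net$W[[1]][1, 1]; b_hat <- net$b[[1]]
  expect_lt(abs(a_hat - 4) / 4, 0.1)
  expect_lt(abs(b_hat - (-2)) / 2, 0.1)
  # the fitted loss matches the logistic-regression cross-check
  g <- stats::glm(I(s == -1) ~ x1, binomial, data = d)
  expect_equal(nll_loss(net, d), -as.numeric(stats::logLik(g)),
               tolerance = 1e-4)
})

test_that("flipping all outcomes negates the fitted log-predictor", {
  d <- generate_logistic_records(2000, function(X) 3 * X[, 1] - 1.5,
                                 seed = 34)
  flip <- d; flip$s <- -flip$s
  n1 <- fit_linear_net(d, epochs = 2500, lr = 0.05)
  n2 <- fit_linear_net(flip, epochs = 2500, lr = 0.05)
  grid <- matrix(seq(0, 1, 0.1), ncol = 1)
  p1 <- sigmoid_link(predict_q(n1, grid))
  p2 <- sigmoid_link(predict_q(n2, grid))
  expect_lt(max(abs(p1 - (1 - p2))), 1e-3)
})

test_that("transfer retraining touches only the last layer", {
  d <- generate_logistic_records(800, function(X) 3 * X[, 1] - 1.5 + 0 * X[, 2],
                                 d = 2, seed = 35)
  net <- committor_net(2, build_pyramid(8, 2, 4), seed = 2)
  net <- train_committor(net, d, epochs = 300, learning_rate = 5e-3)
  frozen_sum <- lapply(net$W[-length(net$W)], sum)
  # self-transfer control: adapting to the same data keeps calibration
  tr <- transfer_retrain_last_layer(net, d, learning_rate = 1e-3,
                                    patience = 100, max_epochs = 600,
                                    seed = 5)
  expect_identical(lapply(tr$W[-length(tr$W)], sum), frozen_sum)
  # self-transfer control: the adapted model explains the data about as
  # well as the original fit (per-record loss within a small margin)
  expect_lt(nll_loss(tr, d) / nrow(d), nll_loss(net, d) / nrow(d) + 0.05)
  # flipped labels reverse the monotone trend of q
  grid <- cbind(seq(0, 1, 0.25), 0.5)
  flip <- d; flip$s <- -flip$s
  trf <- transfer_retrain_last_layer(net, flip, learning_rate = 1e-3,
                                     patience = 100, max_epochs = 600,
                                     seed = 5)
  q_orig <- predict_q(net, grid); q_flip <- predict_q(trf, grid)
  expect_lt(cor(q_orig, q_flip), -0.9)
  narrow <- generate_logistic_records(50, function(X) X[, 1], d = 1,
                                      seed = 1)
  expect_error(transfer_retrain_last_layer(net, narrow), "missing feature")
})

test_that("gradient attribution scales with the inverse mass and matches analytic gradients", {
  lin <- function(X) 2 * X[, 1] + 0 * X[, 2]
  ga <- gradient_attribution(lin, phase_point(c(0.3, 0.7)))
  expect_equal(ga[1], 2, tolerance = 1e-6)   # central FD vs analytic
  expect_equal(ga[2], 0, tolerance = 1e-8)   # unused coordinate
  heavy <- gradient_attribution(lin, phase_point(c(0.3, 0.7),
                                                 masses = c(2, 1)))
  expect_equal(heavy[1], ga[1] / 2, tolerance = 1e-6)
  expect_error(gradient_attribution(function(X) rep(NaN, nrow(X)),
                                    phase_point(0)), "gradient")
})

test_that("tidy and glance summarize a committor net", {
  net <- committor_net(3, build_pyramid(6, 2, 4), seed = 1)
  td <- tidy(net)
  expect_equal(nrow(td), 3)              # two hidden layers + output
  expect_equal(td$width_in[1], 3)
  expect_equal(td$width_out[3], 1)
  gl <- glance(net)
  expect_equal(gl$n_parameters, sum(td$n_parameters))
  expect_identical(gl$link, "sigmoid")
})
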
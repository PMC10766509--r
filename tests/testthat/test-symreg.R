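test_that("the worked polymer-folding expression evaluates to its fixed point", {
  expr <- example_polymer_expression()
  # U = U0 kills the energy term, Q6 - Q6,0 = 1 kills the log: value gamma
  v <- evaluate_expression(expr, list(U = -2.351, Q6 = 1.035))
  expect_equal(as.numeric(v), 11.942, tolerance = 1e-12)
  expect_equal(complexity(expr), 7)
  # a second point cross-checked by direct arithmetic
  v2 <- evaluate_expression(expr, list(U = -3, Q6 = 0.5))
  expect_equal(as.numeric(v2),
               -7.144 * (-3 + 2.351) + 3.269 * log(0.5 - 0.035) + 11.942,
               tolerance = 1e-12)
  # out of domain (Q6 below the offset) is flagged, not an error
  v3 <- evaluate_expression(expr, list(U = -2.351, Q6 = 0.01))
  expect_true(attr(v3, "invalid"))
})

test_that("the worked dimer-contact expression matches independent arithmetic", {
  expr <- example_dimer_contact_expression()
  v <- evaluate_expression(expr, list(x9 = 0.5, x22 = 0.5))
  oracle <- -exp(0.5^2) * log(0.5 - 0.5 / log(0.5))
  expect_equal(as.numeric(v), oracle, tolerance = 1e-12)
  # constant expressions evaluate identically everywhere
  cexp <- sr_const(2.5)
  expect_equal(as.numeric(evaluate_expression(cexp,
                                              list(x9 = c(0, 1, 7)))),
               rep(2.5, 3))
})

test_that("complexity counts operator nodes with leaves free", {
  expect_equal(complexity(sr_const(3)), 0)
  # a*x + b: one multiply, one add
  lin <- sr_call("+", sr_call("*", sr_const(2), sr_var("x1")), sr_const(1))
  expect_equal(complexity(lin), 2)
  expect_equal(complexity(example_polymer_expression()), 7)
})

test_that("the regularized loss is linear in lambda and handles sentinels", {
  X <- matrix(runif(50), 50, 1, dimnames = list(NULL, "x1"))
  d <- training_set(X, s = rep(c(1, -1), 25))
  zero <- sr_const(0)
  expect_equal(regularized_loss(zero, d, lambda = 0), 50 * log(2))
  expr7 <- example_polymer_expression()
  dp <- training_set(tibble::tibble(U = runif(50, -3, -2),
                                    Q6 = runif(50, 0.5, 1)),
                     s = rep(c(1, -1), 25))
  expect_equal(regularized_loss(expr7, dp, lambda = 0.1) -
                 regularized_loss(expr7, dp, lambda = 0), 0.7,
               tolerance = 1e-12)
  # sentinel rows add the finite documented penalty
  bad <- sr_call("log", sr_call("-", sr_var("x1"), sr_const(10)))
  loss <- regularized_loss(bad, d, lambda = 0, invalid_penalty = 1e3)
  expect_equal(loss, 50 * 1e3)
  expect_true(is.finite(loss))
})

test_that("constant optimization recovers planted parameters and is stationary", {
  d <- generate_logistic_records(5000, function(X) 4 * X[, 1] - 2, seed = 71)
  lin <- sr_call("+", sr_call("*", sr_const(1), sr_var("x1")), sr_const(0))
  fit <- optimize_constants(lin, d, seed = 1)
  w <- guidedtps:::sr_constants(fit)
  expect_lt(abs(w[1] - 4) / 4, 0.1)
  expect_lt(abs(w[2] + 2) / 2, 0.1)
  # and it sits on the maximum-likelihood optimum: the glm cross-check
  g <- stats::glm(I(s == -1) ~ x1, binomial, data = d)
  expect_equal(w[1], unname(coef(g)[2]), tolerance = 1e-3)
  expect_equal(w[2], unname(coef(g)[1]), tolerance = 1e-3)
  # restarting at the optimum never worsens and changes nothing measurable
  fit2 <- optimize_constants(fit, d, seed = 1)
  expect_lte(regularized_loss(fit2, d), regularized_loss(fit, d) + 1e-12)
  expect_lt(abs(regularized_loss(fit2, d) - regularized_loss(fit, d)), 1e-6)
  # no constants: identity
  noc <- sr_var("x1")
  expect_identical(optimize_constants(noc, d), noc)
})

test_that("the (N+1) evolution strategy is elitist, seeded and guarded", {
  d <- generate_logistic_records(600, function(X) 2 * X[, 1] - 1, seed = 72)
  cfg <- sr_config(lambda = 1e-3, n_offspring = 3, generations = 25,
                   operators = c("+", "-", "*"), opt_maxit = 30, seed = 5)
  f1 <- evolve(d, "x1", cfg)
  f2 <- evolve(d, "x1", cfg)
  expect_identical(f1$history, f2$history)
  expect_true(all(diff(f1$history$fitness) <= 1e-9))
  # guard: never worse than the best constant model
  nB <- sum(d$s == -1); nA <- sum(d$s == 1)
  const_loss <- nll_loss(rep(log(nB / nA), nrow(d)), d)
  expect_lte(f1$fitness, const_loss + 1e-9)
})

test_that("heavy regularization collapses the search to minimal complexity", {
  d <- generate_logistic_records(400, function(X) 2 * X[, 1] - 1, seed = 73)
  cfg <- sr_config(lambda = 50, n_offspring = 3, generations = 25,
                   operators = c("+", "-", "*"), opt_maxit = 30, seed = 6)
  fit <- evolve(d, "x1", cfg)
  # with lambda = 50 per operation no structure can pay for itself
  expect_lte(complexity(fit$best), 1)
})

test_that("the Pareto front equals the brute-force domination oracle", {
  set.seed(74)
  cand <- tibble::tibble(val_loss = round(runif(40, 0, 10), 2),
                         complexity = sample(0:12, 40, replace = TRUE))
  front <- pareto_front(cand)
  # oracle: pairwise domination check
  dominated <- vapply(seq_len(nrow(cand)), function(i) {
    any(cand$val_loss <= cand$val_loss[i] &
          cand$complexity <= cand$complexity[i] &
          (cand$val_loss < cand$val_loss[i] |
             cand$complexity < cand$complexity[i]))
  }, logical(1))
  oracle <- cand[!dominated, ]
  oracle <- oracle[order(oracle$complexity, oracle$val_loss), ]
  expect_equal(front$val_loss, oracle$val_loss)
  expect_equal(front$complexity, oracle$complexity)
  expect_equal(sum(front$knee), 1)
  # trivial cases
  single <- pareto_front(tibble::tibble(val_loss = 1, complexity = 3))
  expect_equal(nrow(single), 1)
  two <- pareto_front(tibble::tibble(val_loss = c(1, 2),
                                     complexity = c(1, 2)))
  expect_equal(nrow(two), 1)   # the second is dominated
  expect_s3_class(plot_pareto(cand), "ggplot")
})

test_that("expressions serialize to prefix strings and back exactly", {
  exprs <- list(example_polymer_expression(),
                example_dimer_contact_expression(),
                sr_const(-1.25), sr_var("x7"))
  for (e in exprs) {
    text <- sr_serialize(e)
    back <- sr_deserialize(text)
    expect_identical(back$tree, e$tree)
  }
  f <- withr::local_tempfile(fileext = ".txt")
  write_expression(example_polymer_expression(), f)
  expect_equal(as.numeric(evaluate_expression(read_expression(f),
                                              list(U = -2.351, Q6 = 1.035))),
               11.942, tolerance = 1e-12)
  expect_error(sr_deserialize("x1 x2"), "trailing")
})
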
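test_that("the Lorentzian selection density matches hand-computed weights", {
  # q = (-2, 0, 2), gamma = 1: weights (1/5, 1, 1/5) -> (1/7, 5/7, 1/7)
  expect_equal(selection_distribution(c(-2, 0, 2)),
               c(1 / 7, 5 / 7, 1 / 7), tolerance = 1e-12)
  # constant q: uniform
  expect_equal(selection_distribution(rep(1.3, 5)), rep(0.2, 5))
  # gamma -> infinity: uniform
  expect_lt(max(abs(selection_distribution(c(-3, 0, 5, 1),
                                           policy = selection_policy(1e6)) -
                      0.25)), 1e-9)
  # sums to one for random q
  set.seed(41)
  for (i in 1:5) {
    p <- selection_distribution(rnorm(50, sd = 4),
                                policy = selection_policy(runif(1, 0.1, 5)))
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p > 0))
  }
  expect_error(selection_policy(0), "gamma")
})

test_that("acceptance probability reduces to the length ratio for uniform q", {
  model <- function(X) rep(0, nrow(X))   # q identically zero
  old <- tps_path(matrix(seq(0, 1, length.out = 100)), labels = c("A", "B"))
  new <- tps_path(matrix(seq(0, 1, length.out = 200)), labels = c("A", "B"))
  sp <- old$frames[50, ]                 # also a frame of `new`
  sp <- new$frames[99, ]
  old$frames[50, ] <- sp                 # make the SP shared exactly
  expect_equal(acceptance_probability(old, new, sp, model), 100 / 200)
  # reversed proposal is capped at 1
  expect_equal(acceptance_probability(new, old, sp, model), 1)
  # identical paths: unity
  expect_equal(acceptance_probability(old, old, sp, model), 1)
  expect_error(acceptance_probability(old, new, 99, model), "not a frame")
})

test_that("two-way shooting records both outcomes and assembles valid TPs", {
  pot <- dw_pot(); eng <- dw_eng(); states <- dw_states()
  set.seed(42)
  p0 <- make_initial_path(eng, pot, states, seed = 42)
  ch <- chain_state(p0)
  model <- analytic_committor_model(pot, 1, -0.9, 0.9)
  got_tp <- FALSE; got_fail <- FALSE
  for (i in 1:40) {
    shot <- two_way_shoot(ch, model, selection_policy(), eng, pot, states)
    expect_equal(nrow(shot$records), 2)
    expect_true(all(shot$records$s %in% c(-1, 1)))
    if (!is.null(shot$candidate)) {
      got_tp <- TRUE
      expect_true(is_valid_tp(shot$candidate, states))
      # a TP has one outcome of each sign
      expect_setequal(shot$records$s, c(-1, 1))
    } else {
      got_fail <- TRUE
      # failed shots have matching outcomes
      expect_equal(shot$records$s[1], shot$records$s[2])
    }
    if (got_tp && got_fail) break
  }
  expect_true(got_tp)
  expect_true(got_fail)
})

test_that("rejected moves repeat the path and increment its weight", {
  pot <- dw_pot(); states <- dw_states()
  # an engine that cannot commit voids every shot -> forced rejection
  tiny <- dw_eng(max_steps = 5)
  p0 <- make_initial_path(dw_eng(), pot, states, seed = 43)
  ch <- chain_state(p0)
  model <- function(X) rep(0, nrow(X))
  set.seed(44)
  st <- tps_step(ch, model, selection_policy(), tiny, pot, states)
  expect_false(st$generated)
  expect_false(st$accepted)
  expect_null(st$records)
  expect_identical(st$chain$current_path$frames, p0$frames)
  expect_equal(st$chain$current_path$weight, p0$weight + 1L)
  expect_equal(st$chain$mc_step, 1L)
})

test_that("the chain invariant holds over a short guided run", {
  pot <- dw_pot(); eng <- dw_eng(); states <- dw_states()
  model <- analytic_committor_model(pot, 1, -0.9, 0.9)
  run <- run_guided_sampling(pot, eng, states, model, n_steps = 120,
                             freeze_model = TRUE, collect_paths = TRUE,
                             seed = 45)
  for (p in run$paths) expect_true(is_valid_tp(p, states))
  for (ch in run$chains) expect_true(is_valid_tp(ch$current_path, states))
  expect_equal(nrow(run$ledger), 120)
  # records from guided sampling carry both outcomes per non-void shot
  expect_equal(nrow(run$records), 2 * sum(!run$ledger$void))
})

test_that("multiple chains share the model and the training set", {
  pot <- dw_pot(); eng <- dw_eng(); states <- dw_states()
  model <- analytic_committor_model(pot, 1, -0.9, 0.9)
  run <- run_guided_sampling(pot, eng, states, model, n_steps = 40,
                             n_chains = 2, freeze_model = TRUE, seed = 46)
  expect_setequal(unique(run$records$chain_id), c(1, 2))
  expect_setequal(unique(run$ledger$chain_id), c(1, 2))
})

test_that("guided runs are reproducible from their seed", {
  pot <- dw_pot(); eng <- dw_eng(); states <- dw_states()
  net <- committor_net(1, build_pyramid(8, 1), seed = 1)
  r1 <- run_guided_sampling(pot, eng, states, net, n_steps = 60, seed = 47)
  r2 <- run_guided_sampling(pot, eng, states, net, n_steps = 60, seed = 47)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$model$W, r2$model$W)
})

test_that("state softening shortens transition paths", {
  pot <- dw_pot(); eng <- dw_eng(); states <- dw_states()
  model <- analytic_committor_model(pot, 1, -0.9, 0.9)
  expect_error(soften_states(states, model, lo = 0.5, hi = 0.4), "lo < hi")
  # an uninformative (untrained, q = 0) model is refused
  expect_error(soften_states(states, function(X) rep(0, nrow(X))),
               "uninformative")
  soft <- soften_states(states, model, lo = 0.1, hi = 0.9)
  expect_identical(soft[[1]]$kind, "committor")
  # paired comparison: same seeds, tight vs softened states
  tight_run <- run_guided_sampling(pot, eng, states, model, n_steps = 60,
                                   freeze_model = TRUE, seed = 48)
  p0 <- make_initial_path(eng, pot, soft, seed = 48)
  soft_run <- run_guided_sampling(pot, eng, soft, model, n_steps = 60,
                                  freeze_model = TRUE, seed = 48,
                                  init_paths = list(p0))
  expect_lt(mean(soft_run$path_length), mean(tight_run$path_length))
})

test_that("both channels of the 2D system are visited under exploratory selection", {
  pot <- potential_spec("two_channel_2d")
  eng <- engine_params(kT = 0.7)
  states <- default_states_2d()
  model <- function(X) 4 * X[, 1]
  run <- run_guided_sampling(pot, eng, states, model, n_steps = 2000,
                             freeze_model = TRUE, collect_paths = TRUE,
                             policy = selection_policy(gamma = 4),
                             seed = 49)
  y_at_crossing <- vapply(run$paths, function(p) {
    p$frames[which.min(abs(p$frames[, 1])), 2]
  }, numeric(1))
  expect_true(any(y_at_crossing > 0.2) && any(y_at_crossing < -0.2))
})
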
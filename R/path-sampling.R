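#' Transition path container
#'
#' A time-ordered sequence of phase points whose endpoints lie in two
#' distinct metastable states and whose interior frames lie in none.
#' `weight` counts repeats from rejected Monte Carlo moves.
#'
#' @param frames position matrix, one row per frame.
#' @param velocities optional velocity matrix.
#' @param labels character pair: endpoint state labels (start, end).
#' @param weight integer >= 1.
#' @param sp_index optional index of the shooting point that generated the
#'   path.
#' @export
tps_path <- function(frames, velocities = NULL, labels, weight = 1L,
                     sp_index = NULL) {
  if (!is.matrix(frames)) frames <- matrix(frames, ncol = 1)
  colnames(frames) <- paste0("x", seq_len(ncol(frames)))
  structure(list(frames = frames, velocities = velocities,
                 labels = labels, weight = as.integer(weight),
                 sp_index = sp_index),
            class = "tps_path")
}

#' @export
print.tps_path <- function(x, ...) {
  cat("<tps_path>", nrow(x$frames), "frames,",
      paste(x$labels, collapse = " -> "), " weight", x$weight, "\n")
  invisible(x)
}

#' @export
as_tibble.tps_path <- function(x, ...) {
  out <- tibble(frame = seq_len(nrow(x$frames)))
  for (j in seq_len(ncol(x$frames))) out[[paste0("x", j)]] <- x$frames[, j]
  out
}

#' Validate the transition-path invariant
#'
#' Endpoints must lie in two distinct states, interior frames in none.
#'
#' @param path a [tps_path()].
#' @param states list of state definitions.
#' @return `TRUE`/`FALSE`.
#' @export
is_valid_tp <- function(path, states) {
  labs <- which_state_r(states, path$frames)
  n <- length(labs)
  if (n < 2) return(FALSE)
  !is.na(labs[1]) && !is.na(labs[n]) && labs[1] != labs[n] &&
    all(is.na(labs[-c(1, n)]))
}

#' Shooting-point selection policy
#'
#' @param gamma exploration scale of the Lorentzian selection density;
#'   larger values flatten the density towards uniform frame selection.
#' @export
selection_policy <- function(gamma = 1) {
  if (!is.finite(gamma) || gamma <= 0) abort("gamma must be finite and > 0")
  structure(list(gamma = gamma), class = "selection_policy")
}

#' Lorentzian shooting-point selection distribution
#'
#' Probability of selecting each frame of a transition path as the next
#' shooting point, centred on the learned transition-state ensemble
#' (`q = 0`):
#' \deqn{p_{sel}(x|\chi) \propto \frac{1}{q(x)^2 + \gamma^2},}
#' normalized over the frames of the path (algebraically identical to the
#' ratio-sum form of the selection rule).
#'
#' @param path a [tps_path()], or a numeric vector of precomputed q
#'   values.
#' @param model a [predict_q()]-capable committor model (ignored when
#'   `path` is numeric).
#' @param policy a [selection_policy()].
#' @param feature_map function from positions to model features.
#' @return probability vector over frames (sums to 1).
#' @export
selection_distribution <- function(path, model = NULL,
                                   policy = selection_policy(),
                                   feature_map = identity_features) {
  q <- if (is.numeric(path)) path else {
    predict_q(model, feature_map(path$frames))
  }
  if (length(q) == 0) abort("empty path")
  w <- 1 / (q^2 + policy$gamma^2)
  w / sum(w)
}

#' Metropolis acceptance probability for a two-way shooting move
#'
#' \deqn{p_{acc}(\chi'|\chi) = \min(1,
#'   p_{sel}(X_{SP}|\chi') / p_{sel}(X_{SP}|\chi))}
#' with both selection densities evaluated under the same frozen model
#' snapshot. The shooting point must be a frame of both paths.
#'
#' @param old,new [tps_path()]s sharing the shooting point.
#' @param sp_point numeric position of the shooting point, or a
#'   [phase_point()].
#' @param model frozen committor model.
#' @param policy a [selection_policy()].
#' @param feature_map function from positions to model features.
#' @export
acceptance_probability <- function(old, new, sp_point, model,
                                   policy = selection_policy(),
                                   feature_map = identity_features) {
  pos <- if (inherits(sp_point, "phase_point")) sp_point$positions else
    as.numeric(sp_point)
  find_sp <- function(path) {
    d <- abs(sweep(path$frames, 2, pos))
    i <- which(apply(d, 1, max) < 1e-10)
    if (length(i) == 0) abort("shooting point is not a frame of the path")
    i[1]
  }
  io <- find_sp(old); im <- find_sp(new)
  p_old <- selection_distribution(old, model, policy, feature_map)[io]
  p_new <- selection_distribution(new, model, policy, feature_map)[im]
  min(1, p_new / p_old)
}

#' TPS chain state
#'
#' @param path the chain's current transition path.
#' @param chain_id identifier.
#' @export
chain_state <- function(path, chain_id = 1L) {
  structure(list(current_path = path, mc_step = 0L,
                 chain_id = chain_id),
            class = "chain_state")
}

#' One two-way shooting attempt
#'
#' Selects a shooting point on the chain's current path from the
#' Lorentzian selection density, redraws Maxwell--Boltzmann velocities,
#' and propagates two trial trajectories until commitment (the backward
#' trial from the momentum-inverted point for underdamped dynamics; an
#' independent forward realization for overdamped dynamics, valid by time
#' reversibility). If the trials commit to different states a candidate
#' TP is assembled; the two Bernoulli outcomes are recorded either way,
#' so the model learns from successes and failures alike. An uncommitted
#' trial voids the shot (no records).
#'
#' @param chain a [chain_state()].
#' @param model committor model guiding selection.
#' @param policy a [selection_policy()].
#' @param engine,potential,states simulation setup (first state in
#'   `states` is the "A" of the `s = +1` outcome convention).
#' @param feature_map positions -> features.
#' @param masses particle masses.
#' @param q_cache optional precomputed q values for the current path.
#' @return list with `candidate` ([tps_path()] or `NULL`), `records`
#'   (two-row [training_set()] tibble or `NULL` if the shot was void),
#'   `sp_index`, `sp_point`, `p_pred` (model committor at the shooting
#'   point, recorded before the outcome).
#' @export
two_way_shoot <- function(chain, model, policy, engine, potential, states,
                          feature_map = identity_features, masses = 1,
                          q_cache = NULL) {
  path <- chain$current_path
  q <- q_cache %||% predict_q(model, feature_map(path$frames))
  probs <- selection_distribution(q, policy = policy)
  sp_index <- sample.int(length(probs), 1L, prob = probs)
  sp <- phase_point(path$frames[sp_index, ], masses = masses)
  p_pred <- sigmoid_link(q[sp_index])
  shot <- try_two_way(engine, potential, states, sp)
  if (is.null(shot$trials)) {
    return(list(candidate = NULL, records = NULL, sp_index = sp_index,
                sp_point = sp, p_pred = p_pred, void = TRUE))
  }
  lab_A <- states[[1]]$label
  s <- vapply(shot$trials, function(tr) if (tr$label == lab_A) 1 else -1,
              numeric(1))
  feats <- feature_map(matrix(sp$positions, nrow = 1))
  records <- training_set(feats[c(1, 1), , drop = FALSE], s = as.numeric(s),
                          chain_id = chain$chain_id,
                          step_index = chain$mc_step + 1L)
  list(candidate = shot$path, records = records, sp_index = sp_index,
       sp_point = sp, p_pred = p_pred, void = FALSE)
}

#' One step of guided transition path sampling
#'
#' Runs a two-way shooting attempt from the chain's current path and
#' applies the Metropolis acceptance rule. On acceptance the candidate
#' replaces the current path; on rejection (including failed shots) the
#' current path is repeated and its weight incremented.
#'
#' @inheritParams two_way_shoot
#' @return list with the updated `chain`, the shot `records`, and flags
#'   `generated` (a TP was formed) and `accepted`.
#' @export
tps_step <- function(chain, model, policy, engine, potential, states,
                     feature_map = identity_features, masses = 1,
                     q_cache = NULL) {
  shot <- two_way_shoot(chain, model, policy, engine, potential, states,
                        feature_map, masses, q_cache)
  accepted <- FALSE
  new_q <- NULL
  if (!is.null(shot$candidate)) {
    p_acc <- acceptance_probability(chain$current_path, shot$candidate,
                                    shot$sp_point, model, policy, feature_map)
    if (runif(1) < p_acc) {
      accepted <- TRUE
      chain$current_path <- shot$candidate
      chain$current_path$weight <- 1L
    }
  }
  if (!accepted) {
    chain$current_path$weight <- chain$current_path$weight + 1L
  }
  chain$mc_step <- chain$mc_step + 1L
  list(chain = chain, records = shot$records,
       generated = !is.null(shot$candidate), accepted = accepted,
       p_pred = shot$p_pred, void = isTRUE(shot$void))
}

#' Run the machine-guided sampling loop
#'
#' The full learn/sample iteration: one or more TPS chains advance
#' round-robin with committor-guided shooting-point selection; every
#' shooting outcome is appended to the cumulative training set; after
#' every `train_every` global steps the live-validation gate compares the
#' generated and expected TP counts over a sliding window and -- only if
#' the prediction is poor -- retrains the shared model for one epoch on
#' all accumulated records with learning rate `alpha_eff * base_lr`
#' (no training below `lr_floor`).
#'
#' @param potential,engine,states simulation setup (first state = "A").
#' @param model initial committor model (any [predict_q()]-capable
#'   object; only [committor_net()]s are trainable).
#' @param n_steps total Monte Carlo steps across all chains.
#' @param n_chains number of independent chains sharing the model.
#' @param policy a [selection_policy()].
#' @param feature_map positions -> model features.
#' @param train_every training gate cadence in MC steps.
#' @param train_epochs full-batch epochs per gated training event.
#'   Long production chains can afford one epoch per event; short
#'   desk-scale runs need several to reach the maximum-likelihood
#'   optimum within the shot budget (see the methods vignette).
#' @param base_lr,lr_floor learning-rate scaling of the gate.
#' @param window validation window length k (in MC steps).
#' @param freeze_model if `TRUE` the model is never retrained (used for
#'   validation runs with a fixed, e.g. analytic, committor).
#' @param init_paths optional list of initial TPs (length `n_chains`).
#' @param init_guess optional [phase_point()] saddle guess for
#'   [make_initial_path()].
#' @param collect_paths keep all accepted paths (memory permitting)?
#' @param masses particle masses.
#' @param seed master seed.
#' @return an object of class `guided_tps_run` with elements `model`,
#'   `records` (cumulative training set), `ledger` (per-step validation
#'   tibble), `paths` (accepted TPs if collected), `path_length`
#'   (per-step current path length), `chains`.
#' @export
run_guided_sampling <- function(potential, engine, states, model,
                                n_steps, n_chains = 1L,
                                policy = selection_policy(),
                                feature_map = identity_features,
                                train_every = 3L, train_epochs = 5L,
                                base_lr = 1e-3,
                                lr_floor = 1e-4, window = 100L,
                                freeze_model = FALSE, init_paths = NULL,
                                init_guess = NULL, collect_paths = FALSE,
                                masses = 1, seed = 1L) {
  if (n_chains < 1) abort("n_chains must be >= 1")
  seeds <- derive_seeds(seed, n_chains + 1L)
  set.seed(seeds[n_chains + 1L])
  chains <- vector("list", n_chains)
  for (c in seq_len(n_chains)) {
    p0 <- if (!is.null(init_paths)) init_paths[[c]] else {
      make_initial_path(engine, potential, states, guess = init_guess,
                        seed = seeds[c])
    }
    if (!is_valid_tp(p0, states)) abort("initial path is not a valid TP")
    chains[[c]] <- chain_state(p0, chain_id = c)
  }
  set.seed(seeds[n_chains + 1L])
  trainable <- inherits(model, "committor_net") && !freeze_model
  d_feat <- ncol(feature_map(matrix(chains[[1]]$current_path$frames[1, ],
                                    nrow = 1)))
  feat_names <- colnames(feature_map(matrix(chains[[1]]$current_path$frames[1, ],
                                            nrow = 1)))
  rec_X <- matrix(NA_real_, 2L * n_steps, d_feat)
  rec_s <- numeric(2L * n_steps)
  rec_chain <- integer(2L * n_steps); rec_step <- integer(2L * n_steps)
  n_rec <- 0L
  records_tibble <- function() {
    if (n_rec == 0L) return(tibble())
    X <- rec_X[seq_len(n_rec), , drop = FALSE]
    colnames(X) <- feat_names
    training_set(X, s = rec_s[seq_len(n_rec)],
                 chain_id = rec_chain[seq_len(n_rec)],
                 step_index = rec_step[seq_len(n_rec)])
  }
  q_caches <- lapply(chains, function(ch) {
    predict_q(model, feature_map(ch$current_path$frames))
  })
  led_step <- integer(n_steps); led_chain <- integer(n_steps)
  led_p <- rep(NA_real_, n_steps); led_gen <- integer(n_steps)
  led_acc <- logical(n_steps); led_void <- logical(n_steps)
  led_exp <- rep(NA_real_, n_steps); led_alpha <- rep(NA_real_, n_steps)
  led_trained <- logical(n_steps); led_lr <- rep(NA_real_, n_steps)
  path_len <- integer(n_steps)
  paths <- list()
  for (g in seq_len(n_steps)) {
    c <- (g - 1L) %% n_chains + 1L
    st <- tps_step(chains[[c]], model, policy, engine, potential, states,
                   feature_map, masses, q_cache = q_caches[[c]])
    chains[[c]] <- st$chain
    if (st$accepted) {
      q_caches[[c]] <- predict_q(model,
                                 feature_map(st$chain$current_path$frames))
      if (collect_paths) paths[[length(paths) + 1]] <- st$chain$current_path
    }
    if (!is.null(st$records)) {
      Xr <- feature_matrix(st$records)
      idx <- n_rec + seq_len(nrow(Xr))
      rec_X[idx, ] <- Xr
      rec_s[idx] <- st$records$s
      rec_chain[idx] <- c; rec_step[idx] <- g
      n_rec <- n_rec + nrow(Xr)
    }
    led_step[g] <- g; led_chain[g] <- c
    led_p[g] <- if (st$void) NA_real_ else st$p_pred
    led_gen[g] <- as.integer(st$generated)
    led_acc[g] <- st$accepted; led_void[g] <- st$void
    path_len[g] <- nrow(st$chain$current_path$frames)
    win <- seq(max(1L, g - window + 1L), g)
    n_exp <- sum(2 * led_p[win] * (1 - led_p[win]), na.rm = TRUE)
    n_gen <- sum(led_gen[win])
    alpha <- efficiency_factor(n_gen, n_exp)
    led_exp[g] <- n_exp; led_alpha[g] <- alpha
    if (trainable && g %% train_every == 0 && n_rec > 0L) {
      gate <- training_gate(alpha, base_lr, lr_floor)
      led_lr[g] <- gate$lr
      if (gate$should_train) {
        model <- train_committor(model, records_tibble(),
                                 epochs = train_epochs,
                                 learning_rate = gate$lr)
        led_trained[g] <- TRUE
        q_caches <- lapply(chains, function(ch) {
          predict_q(model, feature_map(ch$current_path$frames))
        })
      }
    }
  }
  ledger <- tibble(step = led_step, chain_id = led_chain, p_pred = led_p,
                   generated = led_gen, accepted = led_acc, void = led_void,
                   expected_window = led_exp, alpha_eff = led_alpha,
                   trained = led_trained, lr = led_lr)
  structure(list(model = model, records = records_tibble(),
                 ledger = ledger, paths = paths, path_length = path_len,
                 chains = chains,
                 settings = list(n_steps = n_steps, n_chains = n_chains,
                                 gamma = policy$gamma, window = window,
                                 train_every = train_every,
                                 base_lr = base_lr, lr_floor = lr_floor,
                                 seed = seed)),
            class = "guided_tps_run")
}

#' @export
print.guided_tps_run <- function(x, ...) {
  cat("<guided_tps_run>", x$settings$n_steps, "MC steps,",
      x$settings$n_chains, "chain(s)\n")
  cat("  TPs generated:", sum(x$ledger$generated),
      " accepted:", sum(x$ledger$accepted),
      " training events:", sum(x$ledger$trained), "\n")
  invisible(x)
}

#' @export
tidy.guided_tps_run <- function(x, ...) x$ledger

#' @export
glance.guided_tps_run <- function(x, ...) {
  tibble(n_steps = x$settings$n_steps,
         n_chains = x$settings$n_chains,
         n_records = nrow(x$records),
         n_tp_generated = sum(x$ledger$generated),
         n_tp_expected = sum(2 * x$ledger$p_pred * (1 - x$ledger$p_pred),
                             na.rm = TRUE),
         acceptance_rate = mean(x$ledger$accepted),
         n_training_events = sum(x$ledger$trained),
         final_alpha_eff = x$ledger$alpha_eff[nrow(x$ledger)])
}

#' Soften state definitions to committor iso-levels
#'
#' Replaces tight geometric state definitions by committor-level states:
#' A becomes \eqn{p_B(x) \le lo}, B becomes \eqn{p_B(x) \ge hi}. Widening
#' the states this way shortens transition paths and speeds up sampling.
#' Softening is refused when the model is uninformative (its committor is
#' essentially 0.5 at all probe points, as for an untrained network).
#'
#' @param states list of two state definitions (A first).
#' @param model trained committor model.
#' @param lo,hi committor levels, `0 < lo < hi < 1`.
#' @param probe_points matrix of configurations used to check that the
#'   model is informative (default: the current paths of the run, or the
#'   segment between the box states for 1D boxes).
#' @param feature_map positions -> features.
#' @export
soften_states <- function(states, model, lo = 0.1, hi = 0.9,
                          probe_points = NULL,
                          feature_map = identity_features) {
  if (lo <= 0 || hi >= 1 || lo >= hi) abort("need 0 < lo < hi < 1")
  if (is.null(probe_points)) {
    if (all_box_states(states) && length(states[[1]]$lower) == 1) {
      a <- states[[1]]$upper[1]; b <- states[[2]]$lower[1]
      probe_points <- matrix(seq(a, b, length.out = 21), ncol = 1)
    } else {
      abort("supply probe_points for non-box or multidimensional states")
    }
  }
  p <- sigmoid_link(predict_q(model, feature_map(probe_points)))
  if (max(p) - min(p) < 0.2) {
    abort("model is uninformative at the probe points; softening refused")
  }
  list(state_committor(states[[1]]$label, model, "below", lo, feature_map),
       state_committor(states[[2]]$label, model, "above", hi, feature_map))
}
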
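#' Built-in toy potentials
#'
#' Analytic potential-energy surfaces used as black-box replaceable
#' simulation engines for exercising the guided path-sampling loop.
#' Two surfaces are built in:
#'
#' * `"double_well_1d"`: \eqn{U(x) = h (1 - (x/x_0)^2)^2}, a symmetric
#'   quartic double well with minima at \eqn{\pm x_0} and barrier height `h`.
#' * `"two_channel_2d"`: the same quartic profile in `x` plus a harmonic
#'   confinement `c y^2` and a Gaussian bump of height `A` at the origin,
#'   which splits the transition region into two symmetric channels at
#'   finite \eqn{\pm y}.
#'
#' @param name one of `"double_well_1d"`, `"two_channel_2d"`.
#' @param ... named scalar parameters overriding the defaults
#'   (`h = 4, x0 = 1` for the 1D well; `h = 2, x0 = 1, c = 1, A = 3,
#'   wx = 0.5, wy = 0.5` for the 2D well).
#' @return an object of class `potential_spec` with fields `name`,
#'   `parameters`, and `dimension`.
#' @export
potential_spec <- function(name = c("double_well_1d", "two_channel_2d"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    double_well_1d = list(h = 4, x0 = 1),
    two_channel_2d = list(h = 2, x0 = 1, c = 1, A = 3, wx = 0.5, wy = 0.5)
  )
  pars <- utils::modifyList(defaults, list(...))
  if (!all(names(pars) %in% names(defaults))) {
    abort(paste0("unknown parameter(s): ",
                 paste(setdiff(names(pars), names(defaults)), collapse = ", ")))
  }
  pars <- pars[names(defaults)]
  if (!all(vapply(pars, is.finite, logical(1)))) abort("parameters must be finite")
  structure(
    list(name = name,
         id = switch(name, double_well_1d = 1L, two_channel_2d = 2L),
         parameters = pars,
         dimension = switch(name, double_well_1d = 1L, two_channel_2d = 2L)),
    class = "potential_spec"
  )
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("<potential_spec>", x$name, sprintf("(%dD)\n", x$dimension))
  cat("  ", paste(names(x$parameters), unlist(x$parameters),
                  sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a toy potential or its gradient
#'
#' @param potential a [potential_spec()].
#' @param x numeric position vector (length = dimension) or a matrix with
#'   one row per point.
#' @return energy value(s); `potential_gradient()` returns the gradient
#'   vector (or matrix, one row per point).
#' @export
potential_energy <- function(potential, x) {
  par <- unlist(potential$parameters)
  if (is.matrix(x)) {
    apply(x, 1L, function(r) cpp_potential(potential$id, par, r))
  } else {
    cpp_potential(potential$id, par, x)
  }
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(potential, x) {
  par <- unlist(potential$parameters)
  if (is.matrix(x)) {
    t(apply(x, 1L, function(r) cpp_potential_grad(potential$id, par, r)))
  } else {
    cpp_potential_grad(potential$id, par, x)
  }
}

#' Langevin engine parameters
#'
#' @param kind `"overdamped"` (Euler--Maruyama) or `"underdamped"`
#'   (velocity Verlet with per-step velocity randomization).
#' @param timestep integration timestep (reduced time units), > 0.
#' @param friction friction coefficient, > 0. For overdamped dynamics the
#'   mobility is `1/(mass * friction)`.
#' @param kT thermal energy (houses the inverse temperature `beta = 1/kT`).
#' @param max_steps maximum number of integration steps before a
#'   propagation is declared uncommitted.
#' @param stride record every `stride`-th frame (the terminal frame is
#'   always recorded).
#' @return an object of class `engine_params`.
#' @export
engine_params <- function(kind = c("overdamped", "underdamped"),
                          timestep = 1e-3, friction = 1, kT = 1,
                          max_steps = 1e6, stride = 1L) {
  kind <- match.arg(kind)
  if (timestep <= 0) abort("timestep must be > 0")
  if (friction <= 0) abort("friction must be > 0")
  if (kT <= 0) abort("kT must be > 0")
  if (max_steps < 1) abort("max_steps must be >= 1")
  if (stride < 1) abort("stride must be >= 1")
  structure(list(kind = kind, timestep = timestep, friction = friction,
                 kT = kT, max_steps = as.integer(max_steps),
                 stride = as.integer(stride)),
            class = "engine_params")
}

#' Phase point
#'
#' A configuration `X` from which trajectories are shot: positions, optional
#' velocities (present for underdamped dynamics) and particle masses.
#'
#' @param positions numeric vector.
#' @param velocities numeric vector of the same length, or `NULL`.
#' @param masses positive numeric vector (recycled to the dimension).
#' @export
phase_point <- function(positions, velocities = NULL, masses = 1) {
  positions <- as.numeric(positions)
  d <- length(positions)
  masses <- rep_len(as.numeric(masses), d)
  if (any(masses <= 0)) abort("masses must be > 0")
  if (!is.null(velocities) && length(velocities) != d) {
    abort("velocities must match positions in length")
  }
  structure(list(positions = positions, velocities = velocities,
                 masses = masses),
            class = "phase_point")
}

#' Metastable state definitions
#'
#' `state_def()` builds an axis-aligned box state: a point is inside iff
#' `lower[j] <= x[j] <= upper[j]` in every dimension (use `-Inf`/`Inf` for
#' unbounded sides). `state_committor()` builds a state bounded by an
#' iso-level of a committor model, used for state softening: side
#' `"below"` means \eqn{p_B(x) \le level} (an A-like state), `"above"`
#' means \eqn{p_B(x) \ge level}.
#'
#' @param label state label, e.g. `"A"` or `"B"`.
#' @param lower,upper numeric bounds per dimension.
#' @param model a committor model understood by [predict_q()].
#' @param side `"below"` or `"above"`.
#' @param level committor level in (0, 1).
#' @param feature_map function mapping a position matrix to model features
#'   (defaults to the identity).
#' @export
state_def <- function(label, lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper)) abort("lower/upper length mismatch")
  if (any(lower > upper)) abort("lower must be <= upper")
  structure(list(label = label, kind = "box", lower = lower, upper = upper),
            class = "state_def")
}

#' @rdname state_def
#' @export
state_committor <- function(label, model, side = c("below", "above"), level,
                            feature_map = NULL) {
  side <- match.arg(side)
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  structure(list(label = label, kind = "committor", model = model,
                 side = side, level = level, feature_map = feature_map),
            class = "state_def")
}

all_box_states <- function(states) {
  all(vapply(states, function(s) s$kind == "box", logical(1)))
}

# n_states x dim bound matrices for the compiled propagator
state_bounds <- function(states, dim) {
  lo <- do.call(rbind, lapply(states, function(s) rep_len(s$lower, dim)))
  hi <- do.call(rbind, lapply(states, function(s) rep_len(s$upper, dim)))
  list(lo = lo, hi = hi)
}

#' Test state membership
#'
#' @param state a [state_def()] or [state_committor()].
#' @param x position matrix (one row per point) or vector.
#' @return logical vector.
#' @export
state_contains <- function(state, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (state$kind == "box") {
    lo <- rep_len(state$lower, ncol(x)); hi <- rep_len(state$upper, ncol(x))
    apply(x, 1L, function(r) all(r >= lo & r <= hi))
  } else {
    fm <- state$feature_map %||% identity_features
    p <- plogis(predict_q(state$model, fm(x)))
    if (state$side == "below") p <= state$level else p >= state$level
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

which_state_r <- function(states, x) {
  # first matching state label per row, NA_character_ if none
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  out <- rep(NA_character_, nrow(x))
  for (s in states) {
    inside <- state_contains(s, x)
    out[is.na(out) & inside] <- s$label
  }
  out
}

# Box states are disjoint iff their boxes do not intersect.
check_states_disjoint <- function(states, dim) {
  if (!all_box_states(states)) return(invisible(TRUE))
  b <- state_bounds(states, dim)
  n <- nrow(b$lo)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    overlap <- all(pmax(b$lo[i, ], b$lo[j, ]) <= pmin(b$hi[i, ], b$hi[j, ]))
    if (overlap) abort("state definitions overlap")
  }
  invisible(TRUE)
}

#' Draw Maxwell--Boltzmann velocities
#'
#' Returns a copy of the phase point with velocities sampled i.i.d.
#' Gaussian with variance `kT / m` per component; positions are unchanged.
#'
#' @param point a [phase_point()].
#' @param kT thermal energy, > 0.
#' @param masses particle masses (defaults to the point's own).
#' @param seed optional integer seed.
#' @export
draw_maxwell_boltzmann <- function(point, kT, masses = point$masses,
                                   seed = NULL) {
  if (kT <= 0) abort("kT must be > 0")
  masses <- rep_len(masses, length(point$positions))
  if (any(masses <= 0)) abort("masses must be > 0")
  if (!is.null(seed)) set.seed(seed)
  v <- rnorm(length(point$positions), mean = 0, sd = sqrt(kT / masses))
  phase_point(point$positions, v, masses)
}

#' Propagate until commitment to a metastable state
#'
#' Integrates the Langevin dynamics from `start` until the first frame
#' inside one of `states` (or `max_steps`, in which case an error of class
#' `"guidedtps_uncommitted"` carrying the partial trajectory is raised --
#' the caller decides disposal). A start inside a state returns immediately
#' with that label. Box states are checked inside the compiled integrator;
#' committor-level (softened) states are checked in chunks on the R side.
#'
#' @param engine an [engine_params()].
#' @param potential a [potential_spec()].
#' @param start a [phase_point()]; must carry velocities for underdamped
#'   dynamics.
#' @param states list of state definitions.
#' @param record if `FALSE`, only the first and last frames are kept
#'   (used for committor estimation where only the terminal label matters).
#' @return a list of class `trajectory`: `frames` (matrix, one row per
#'   recorded frame), `velocities` (matrix or `NULL`), `label`, `n_steps`.
#' @export
propagate_committed <- function(engine, potential, start, states,
                                record = TRUE) {
  d <- potential$dimension
  if (length(start$positions) != d) abort("start dimension mismatch")
  if (engine$kind == "underdamped" && is.null(start$velocities)) {
    abort("underdamped dynamics needs velocities; use draw_maxwell_boltzmann()")
  }
  check_states_disjoint(states, d)
  par <- unlist(potential$parameters)
  kind <- if (engine$kind == "overdamped") 0L else 1L
  v0 <- start$velocities %||% numeric(d)

  if (all_box_states(states)) {
    b <- state_bounds(states, d)
    res <- cpp_propagate(potential$id, par, kind, start$positions, v0,
                         start$masses, engine$timestep, engine$friction,
                         engine$kT, engine$max_steps, engine$stride,
                         b$lo, b$hi, if (record) 1L else 0L)
    traj <- new_trajectory(res$frames, res$velocities,
                           if (res$state > 0) states[[res$state]]$label else NA,
                           res$n_steps, start$masses, engine)
    if (res$state == 0) uncommitted_error(traj)
    return(traj)
  }

  # chunked propagation with R-side state checks (model-defined states)
  lab0 <- which_state_r(states, matrix(start$positions, nrow = 1))
  if (!is.na(lab0)) {
    return(new_trajectory(matrix(start$positions, nrow = 1),
                          if (kind == 1L) matrix(v0, nrow = 1) else NULL,
                          lab0, 0, start$masses, engine))
  }
  chunk <- min(engine$max_steps, 5000L)
  x <- start$positions; v <- v0
  frames <- matrix(start$positions, nrow = 1)
  vels <- if (kind == 1L) matrix(v0, nrow = 1) else NULL
  steps_done <- 0
  none <- matrix(numeric(0), nrow = 0, ncol = d)
  while (steps_done < engine$max_steps) {
    n_do <- min(chunk, engine$max_steps - steps_done)
    res <- cpp_propagate(potential$id, par, kind, x, v, start$masses,
                         engine$timestep, engine$friction, engine$kT,
                         n_do, 1L, none, none, 1L)
    fr <- res$frames[-1, , drop = FALSE]
    vl <- if (kind == 1L) res$velocities[-1, , drop = FALSE] else NULL
    labs <- which_state_r(states, fr)
    hit <- which(!is.na(labs))
    if (length(hit) > 0) {
      i <- hit[1]
      frames <- rbind(frames, fr[seq_len(i), , drop = FALSE])
      if (kind == 1L) vels <- rbind(vels, vl[seq_len(i), , drop = FALSE])
      steps_done <- steps_done + i
      keep <- thin_index(nrow(frames), engine$stride)
      return(new_trajectory(frames[keep, , drop = FALSE],
                            if (kind == 1L) vels[keep, , drop = FALSE] else NULL,
                            labs[i], steps_done, start$masses, engine))
    }
    frames <- rbind(frames, fr)
    if (kind == 1L) vels <- rbind(vels, vl)
    steps_done <- steps_done + n_do
    x <- fr[nrow(fr), ]
    if (kind == 1L) v <- vl[nrow(vl), ]
  }
  keep <- thin_index(nrow(frames), engine$stride)
  uncommitted_error(new_trajectory(frames[keep, , drop = FALSE],
                                   if (kind == 1L) vels[keep, , drop = FALSE] else NULL,
                                   NA, steps_done, start$masses, engine))
}

thin_index <- function(n, stride) {
  if (stride <= 1L) return(seq_len(n))
  unique(c(seq(1L, n, by = stride), n))
}

new_trajectory <- function(frames, velocities, label, n_steps, masses,
                           engine) {
  colnames(frames) <- paste0("x", seq_len(ncol(frames)))
  structure(list(frames = frames, velocities = velocities,
                 label = label, n_steps = n_steps, masses = masses,
                 timestep = engine$timestep, stride = engine$stride),
            class = "trajectory")
}

uncommitted_error <- function(traj) {
  abort("trajectory did not commit within max_steps",
        class = "guidedtps_uncommitted", trajectory = traj)
}

#' @export
as_tibble.trajectory <- function(x, ...) {
  d <- ncol(x$frames)
  out <- tibble(time = (seq_len(nrow(x$frames)) - 1) * x$timestep * x$stride)
  for (j in seq_len(d)) out[[paste0("x", j)]] <- x$frames[, j]
  if (!is.null(x$velocities)) {
    for (j in seq_len(d)) out[[paste0("v", j)]] <- x$velocities[, j]
  }
  out
}

#' Analytic committor of 1D overdamped diffusion
#'
#' Closed-form committor for one-dimensional overdamped diffusion between
#' absorbing boundaries `a` and `b`:
#' \deqn{p_B(x) = \frac{\int_a^x e^{U(y)/kT} dy}{\int_a^b e^{U(y)/kT} dy}.}
#' Used as an independent validation oracle for the learned committor.
#' Quadrature uses [stats::integrate()] with relative tolerance `rel_tol`
#' (the integrand is rescaled by its maximum to avoid overflow).
#'
#' @param potential a 1D [potential_spec()].
#' @param kT thermal energy.
#' @param a,b absorbing boundaries, `a < b`.
#' @param x evaluation point(s); values outside `(a, b)` are clipped to
#'   0 / 1.
#' @param rel_tol quadrature relative tolerance.
#' @return committor value(s) in `[0, 1]`, monotone nondecreasing in `x`.
#' @export
analytic_committor_1d <- function(potential, kT, a, b, x, rel_tol = 1e-8) {
  if (potential$dimension != 1L) abort("analytic committor is 1D only")
  if (a >= b) abort("need a < b")
  umax <- max(vapply(seq(a, b, length.out = 257),
                     function(z) potential_energy(potential, z), numeric(1)))
  f <- function(y) {
    vapply(y, function(z) exp((potential_energy(potential, z) - umax) / kT),
           numeric(1))
  }
  denom <- integrate(f, a, b, rel.tol = rel_tol)$value
  vapply(x, function(xi) {
    if (xi <= a) return(0)
    if (xi >= b) return(1)
    integrate(f, a, xi, rel.tol = rel_tol)$value / denom
  }, numeric(1))
}

#' Frozen analytic committor model
#'
#' Wraps [analytic_committor_1d()] into an object usable wherever a learned
#' committor model is expected ([predict_q()], guided sampling, state
#' softening). The committor is precomputed on an `n_grid`-point quadrature
#' grid and interpolated monotonically; `q = logit(p)` is clamped to
#' `|q| <= q_cap` near the boundaries.
#'
#' @inheritParams analytic_committor_1d
#' @param n_grid grid size for the precomputed committor.
#' @param q_cap cap on `|q|`.
#' @export
analytic_committor_model <- function(potential, kT, a, b, n_grid = 513,
                                     q_cap = 20) {
  xs <- seq(a, b, length.out = n_grid)
  ps <- analytic_committor_1d(potential, kT, a, b, xs)
  eps <- 1e-12
  fun <- splinefun(xs, pmin(pmax(ps, eps), 1 - eps), method = "hyman")
  structure(list(p_fun = fun, a = a, b = b, q_cap = q_cap,
                 kT = kT, potential = potential$name),
            class = "analytic_committor")
}

#' @export
predict_q.analytic_committor <- function(model, x, ...) {
  if (is.matrix(x)) x <- x[, 1]
  p <- numeric(length(x))
  p[x <= model$a] <- 0
  p[x >= model$b] <- 1
  mid <- x > model$a & x < model$b
  p[mid] <- pmin(pmax(model$p_fun(x[mid]), 0), 1)
  q <- qlogis(pmin(pmax(p, plogis(-model$q_cap)), plogis(model$q_cap)))
  pmin(pmax(q, -model$q_cap), model$q_cap)
}

#' Construct an initial transition path
#'
#' TPS chains need one valid transition path (TP) to start from. Strategy
#' `"saddle"` repeatedly runs two-way shots from a guess point (default:
#' the midpoint between the two state boxes) until the two trials commit to
#' different states; `"high_temperature"` runs equilibrium dynamics at
#' `hot_factor * kT` and excises the first spontaneous transition.
#'
#' @inheritParams propagate_committed
#' @param strategy `"saddle"` or `"high_temperature"`.
#' @param guess optional [phase_point()] used as the shooting/launch point.
#' @param seed optional integer seed.
#' @param max_attempts attempts before giving up with an error.
#' @param hot_factor temperature multiplier for the high-temperature
#'   strategy.
#' @return a [tps_path()] whose endpoints lie in the two distinct states.
#' @export
make_initial_path <- function(engine, potential, states,
                              strategy = c("saddle", "high_temperature"),
                              guess = NULL, seed = NULL, max_attempts = 100,
                              hot_factor = 3) {
  strategy <- match.arg(strategy)
  check_states_disjoint(states, potential$dimension)
  if (length(states) < 2) abort("need two states")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(guess)) {
    # the built-in toys are symmetric about the origin
    guess <- phase_point(numeric(potential$dimension), masses = 1)
  }
  if (strategy == "saddle") {
    for (att in seq_len(max_attempts)) {
      shot <- try_two_way(engine, potential, states, guess)
      if (!is.null(shot$path)) return(shot$path)
    }
    abort("no transition path found within max_attempts")
  }
  hot <- engine
  hot$kT <- engine$kT * hot_factor
  for (att in seq_len(max_attempts)) {
    tps <- excise_transitions(hot, potential, states, start = guess,
                              n_tp = 1, max_chunks = 200)
    if (length(tps) >= 1) {
      p <- tps[[1]]
      # re-label under the cold engine's states (identical here), keep path
      return(p)
    }
  }
  abort("no transition path found within max_attempts")
}

# one two-way shot from a fixed point; returns list(path or NULL, labels)
try_two_way <- function(engine, potential, states, point) {
  pt <- if (engine$kind == "underdamped") {
    draw_maxwell_boltzmann(point, engine$kT)
  } else point
  fwd <- tryCatch(propagate_committed(engine, potential, pt, states),
                  guidedtps_uncommitted = function(e) NULL)
  back_pt <- if (engine$kind == "underdamped") {
    phase_point(pt$positions, -pt$velocities, pt$masses)
  } else pt
  bwd <- tryCatch(propagate_committed(engine, potential, back_pt, states),
                  guidedtps_uncommitted = function(e) NULL)
  if (is.null(fwd) || is.null(bwd)) return(list(path = NULL, trials = NULL))
  path <- NULL
  if (!identical(fwd$label, bwd$label)) {
    path <- join_two_way(bwd, fwd)
  }
  list(path = path, trials = list(backward = bwd, forward = fwd))
}

# reversed(backward) + forward, shooting point kept once
join_two_way <- function(bwd, fwd) {
  nb <- nrow(bwd$frames)
  frames <- rbind(bwd$frames[rev(seq_len(nb))[-nb], , drop = FALSE],
                  fwd$frames)
  vels <- NULL
  if (!is.null(bwd$velocities)) {
    vels <- rbind(-bwd$velocities[rev(seq_len(nb))[-nb], , drop = FALSE],
                  fwd$velocities)
  }
  tps_path(frames, vels, labels = c(bwd$label, fwd$label),
           sp_index = nb)
}

# Excise transition segments (in either direction) from one long
# equilibrium run: a TP runs from the last frame inside one state to the
# first frame inside the other, with no interior frame in any state.
excise_transitions <- function(engine, potential, states, start, n_tp,
                               max_chunks = 1000, chunk = 2e5) {
  d <- potential$dimension
  par <- unlist(potential$parameters)
  kind <- if (engine$kind == "overdamped") 0L else 1L
  x <- start$positions
  v <- start$velocities %||% numeric(d)
  none <- matrix(numeric(0), nrow = 0, ncol = d)
  paths <- list()
  last_state <- NA_character_
  buffer <- NULL  # frames since (and including) the last in-state frame
  for (ch in seq_len(max_chunks)) {
    res <- cpp_propagate(potential$id, par, kind, x, v, start$masses,
                         engine$timestep, engine$friction, engine$kT,
                         as.integer(chunk), 1L, none, none, 1L)
    fr <- if (ch == 1) res$frames else res$frames[-1, , drop = FALSE]
    labs <- which_state_r(states, fr)
    for (i in seq_len(nrow(fr))) {
      li <- labs[i]
      if (!is.na(li)) {
        if (!is.na(last_state) && li != last_state && !is.null(buffer) &&
            nrow(buffer) >= 1) {
          frames <- rbind(buffer, fr[i, , drop = FALSE])
          colnames(frames) <- paste0("x", seq_len(ncol(frames)))
          paths[[length(paths) + 1]] <-
            tps_path(frames, NULL, labels = c(last_state, li))
          if (length(paths) >= n_tp) return(paths)
        }
        last_state <- li
        buffer <- fr[i, , drop = FALSE]
      } else if (!is.null(buffer)) {
        buffer <- rbind(buffer, fr[i, , drop = FALSE])
      }
    }
    x <- fr[nrow(fr), ]
    if (kind == 1L) v <- res$velocities[nrow(res$velocities), ]
  }
  paths
}
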
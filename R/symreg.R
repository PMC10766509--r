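#' Symbolic expression trees
#'
#' Expressions are trees over a configured operator set (`+`, `-`, `*`,
#' `/`, `neg`, `exp`, `log`, `pow`) with variable and constant leaves.
#' Evaluation is total on its declared domain: protected operators flag
#' domain violations (log of a nonpositive value, division by a
#' near-zero denominator, invalid powers) as invalid rather than crash.
#' Complexity is the count of operator nodes (leaves are free; unary
#' minus counts as a node -- the counting convention is documented in
#' the methods vignette).
#'
#' @param name variable name.
#' @param value constant value.
#' @param op operator name.
#' @param ... child expressions (or raw trees).
#' @export
sr_var <- function(name) {
  new_sr_expr(list(type = "var", name = name))
}

#' @rdname sr_var
#' @export
sr_const <- function(value) {
  new_sr_expr(list(type = "const", value = as.numeric(value)))
}

#' @rdname sr_var
#' @export
sr_call <- function(op, ...) {
  args <- lapply(list(...), function(a) {
    if (inherits(a, "sr_expr")) a$tree
    else if (is.numeric(a)) list(type = "const", value = as.numeric(a))
    else if (is.character(a)) list(type = "var", name = a)
    else a
  })
  if (!op %in% names(sr_ops)) abort(paste0("unknown operator: ", op))
  if (length(args) != sr_ops[[op]]$arity) {
    abort(paste0("operator ", op, " expects ", sr_ops[[op]]$arity, " args"))
  }
  new_sr_expr(list(type = "call", op = op, args = args))
}

new_sr_expr <- function(tree) structure(list(tree = tree), class = "sr_expr")

sr_ops <- list(
  "+"   = list(arity = 2L),
  "-"   = list(arity = 2L),
  "*"   = list(arity = 2L),
  "/"   = list(arity = 2L),
  "neg" = list(arity = 1L),
  "exp" = list(arity = 1L),
  "log" = list(arity = 1L),
  "pow" = list(arity = 2L)
)

eval_tree <- function(tree, env, n) {
  if (tree$type == "const") {
    return(list(v = rep(tree$value, n), bad = rep(FALSE, n)))
  }
  if (tree$type == "var") {
    v <- env[[tree$name]]
    if (is.null(v)) abort(paste0("unknown input: ", tree$name))
    return(list(v = v, bad = rep(FALSE, n)))
  }
  a <- eval_tree(tree$args[[1]], env, n)
  if (sr_ops[[tree$op]]$arity == 1L) {
    v <- switch(tree$op,
                neg = -a$v,
                exp = exp(a$v),
                log = suppressWarnings(log(a$v)))
    bad <- a$bad | !is.finite(v)
    if (tree$op == "log") bad <- bad | a$v <= 0
    return(list(v = v, bad = bad))
  }
  b <- eval_tree(tree$args[[2]], env, n)
  bad <- a$bad | b$bad
  v <- switch(tree$op,
              "+" = a$v + b$v,
              "-" = a$v - b$v,
              "*" = a$v * b$v,
              "/" = { bad <- bad | abs(b$v) <= 1e-12; a$v / b$v },
              pow = suppressWarnings(a$v^b$v))
  bad <- bad | !is.finite(v)
  list(v = v, bad = bad)
}

#' Evaluate a symbolic expression
#'
#' Returns the log-predictor values `q` of the expression on a table of
#' inputs; the committor follows as [sigmoid_link()]`(q)`. Entries whose
#' evaluation violates an operator domain are `NA` and flagged in the
#' `"invalid"` attribute.
#'
#' @param expr an [sr_expr][sr_var] expression.
#' @param inputs data frame / named list / matrix of input columns.
#' @export
evaluate_expression <- function(expr, inputs) {
  if (is.matrix(inputs)) inputs <- as.data.frame(inputs)
  if (!is.list(inputs)) abort("inputs must be a data frame or named list")
  n <- length(inputs[[1]])
  out <- eval_tree(expr$tree, inputs, n)
  v <- out$v
  v[out$bad] <- NA_real_
  attr(v, "invalid") <- out$bad
  v
}

#' @export
predict_q.sr_expr <- function(model, x, ...) {
  if (is.matrix(x)) x <- as.data.frame(x)
  v <- evaluate_expression(model, x)
  attributes(v) <- NULL
  v
}

#' Expression complexity
#'
#' Number of mathematical operations (operator nodes) in the tree;
#' variable and constant leaves are free.
#'
#' @param expr an [sr_expr][sr_var] expression.
#' @export
complexity <- function(expr) {
  count <- function(tree) {
    if (tree$type != "call") return(0L)
    1L + sum(vapply(tree$args, count, integer(1)))
  }
  count(expr$tree)
}

#' Regularized symbolic-regression loss
#'
#' \deqn{l_{sr}(w_{sr}|\theta) = -\log L[p_B(z)] + \lambda C,}
#' the same shooting-outcome likelihood as [nll_loss()] with `q` supplied
#' by the expression, plus a complexity penalty. Records whose expression
#' evaluation is invalid contribute the fixed finite penalty
#' `invalid_penalty` each (never infinity), so that ill-defined
#' expressions lose to well-defined ones without crashing the search.
#'
#' @param expr an [sr_expr][sr_var] expression.
#' @param data a [training_set()] tibble whose feature columns match the
#'   expression's variables.
#' @param lambda complexity regularization, >= 0.
#' @param invalid_penalty per-record penalty for invalid evaluations.
#' @export
regularized_loss <- function(expr, data, lambda = 0,
                             invalid_penalty = 1e3) {
  if (lambda < 0) abort("lambda must be >= 0")
  denv <- sr_data_env(data)
  sr_nll(expr$tree, denv, invalid_penalty) + lambda * complexity(expr)
}

# lean precomputed view of a training set, shared by all objective
# evaluations inside the evolutionary search
sr_data_env <- function(data) {
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("empty training data")
  env <- as.list(data[setdiff(names(data), meta_columns)])
  list(env = env, n = nrow(data),
       s = if ("s" %in% names(data)) data$s else NULL,
       n_A = if ("n_A" %in% names(data)) data$n_A else NULL,
       n_B = if ("n_B" %in% names(data)) data$n_B else NULL)
}

sr_nll <- function(tree, denv, invalid_penalty = 1e3) {
  out <- eval_tree(tree, denv$env, denv$n)
  q <- out$v; bad <- out$bad
  per <- numeric(denv$n)
  if (!is.null(denv$s)) {
    per[!bad] <- log1pexp(denv$s[!bad] * q[!bad])
  } else if (!is.null(denv$n_A)) {
    per[!bad] <- denv$n_A[!bad] * log1pexp(q[!bad]) +
      denv$n_B[!bad] * log1pexp(-q[!bad])
  } else {
    abort("data must contain s or (n_A, n_B)")
  }
  per[bad] <- invalid_penalty
  sum(per)
}

# constants in preorder
sr_constants <- function(expr) {
  out <- numeric(0)
  walk <- function(tree) {
    if (tree$type == "const") out[[length(out) + 1]] <<- tree$value
    else if (tree$type == "call") for (a in tree$args) walk(a)
  }
  walk(expr$tree)
  out
}

sr_with_constants <- function(expr, w) {
  i <- 0L
  sub <- function(tree) {
    if (tree$type == "const") {
      i <<- i + 1L
      tree$value <- w[i]
    } else if (tree$type == "call") {
      tree$args <- lapply(tree$args, sub)
    }
    tree
  }
  new_sr_expr(sub(expr$tree))
}

#' Fit the constants of an expression by gradient-based optimization
#'
#' Minimizes the (unregularized) shooting-outcome likelihood over the
#' expression's constants with BFGS (Nelder--Mead fallback), starting
#' from the current values; bounded random restarts are used when the
#' starting objective is not finite. Expressions without constants are
#' returned unchanged. The returned loss is never worse than the
#' incoming one; deterministic under a fixed seed.
#'
#' @inheritParams regularized_loss
#' @param maxit optimizer iteration cap.
#' @param restarts random restarts when the start is invalid.
#' @param seed optional seed (restarts only).
#' @export
optimize_constants <- function(expr, data, maxit = 200, restarts = 3,
                               seed = NULL, invalid_penalty = 1e3) {
  w0 <- sr_constants(expr)
  if (length(w0) == 0) return(expr)
  if (!is.null(seed)) set.seed(seed)
  denv <- if (is.data.frame(data)) sr_data_env(data) else
    if (!is.null(data[["env"]])) data else sr_data_env(data)
  obj <- function(w) {
    sr_nll(sr_with_constants(expr, w)$tree, denv, invalid_penalty)
  }
  f0 <- obj(w0)
  start <- w0
  tries <- 0L
  while (!is.finite(f0) && tries < restarts) {
    start <- rnorm(length(w0))
    f0 <- obj(start)
    tries <- tries + 1L
  }
  if (!is.finite(f0)) return(expr)
  fit <- tryCatch(
    optim(start, obj, method = "BFGS",
          control = list(maxit = maxit, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    fit <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit * 2))
  }
  if (is.finite(fit$value) && fit$value <= obj(w0)) {
    sr_with_constants(expr, fit$par)
  } else {
    expr
  }
}

# ---- mutation machinery -------------------------------------------------

node_paths <- function(tree, path = integer(0)) {
  out <- list(path)
  if (tree$type == "call") {
    for (i in seq_along(tree$args)) {
      out <- c(out, node_paths(tree$args[[i]], c(path, i)))
    }
  }
  out
}

get_node <- function(tree, path) {
  for (i in path) tree <- tree$args[[i]]
  tree
}

set_node <- function(tree, path, node) {
  if (length(path) == 0) return(node)
  tree$args[[path[1]]] <- set_node(tree$args[[path[1]]], path[-1], node)
  tree
}

random_tree <- function(depth, inputs, operators) {
  if (depth <= 0 || runif(1) < 0.35) {
    if (runif(1) < 0.6) {
      return(list(type = "var", name = sample(inputs, 1)))
    }
    return(list(type = "const", value = round(runif(1, -2, 2), 3)))
  }
  op <- sample(operators, 1)
  args <- lapply(seq_len(sr_ops[[op]]$arity), function(i) {
    random_tree(depth - 1, inputs, operators)
  })
  list(type = "call", op = op, args = args)
}

tree_depth <- function(tree) {
  if (tree$type != "call") return(0L)
  1L + max(vapply(tree$args, tree_depth, integer(1)))
}

mutate_expr <- function(expr, inputs, operators, max_depth = 6) {
  tree <- expr$tree
  kind <- sample(c("op_swap", "subtree", "const"), 1,
                 prob = c(0.35, 0.4, 0.25))
  paths <- node_paths(tree)
  if (kind == "op_swap") {
    calls <- paths[vapply(paths, function(p) {
      get_node(tree, p)$type == "call"
    }, logical(1))]
    if (length(calls) == 0) kind <- "subtree" else {
      p <- calls[[sample.int(length(calls), 1)]]
      node <- get_node(tree, p)
      same <- operators[vapply(operators, function(o) {
        sr_ops[[o]]$arity == sr_ops[[node$op]]$arity
      }, logical(1))]
      if (length(same) > 1) {
        node$op <- sample(setdiff(same, node$op), 1)
        return(new_sr_expr(set_node(tree, p, node)))
      }
      kind <- "subtree"
    }
  }
  if (kind == "subtree") {
    p <- paths[[sample.int(length(paths), 1)]]
    repl <- random_tree(2, inputs, operators)
    cand <- set_node(tree, p, repl)
    if (tree_depth(cand) > max_depth) cand <- repl
    return(new_sr_expr(cand))
  }
  # constant mutation: perturb an existing constant, or graft one on
  consts <- paths[vapply(paths, function(p) {
    get_node(tree, p)$type == "const"
  }, logical(1))]
  if (length(consts) > 0 && runif(1) < 0.5) {
    p <- consts[[sample.int(length(consts), 1)]]
    node <- get_node(tree, p)
    node$value <- node$value + rnorm(1)
    return(new_sr_expr(set_node(tree, p, node)))
  }
  p <- paths[[sample.int(length(paths), 1)]]
  node <- get_node(tree, p)
  op <- sample(intersect(c("+", "*"), operators), 1)
  graft <- list(type = "call", op = op,
                args = list(node, list(type = "const",
                                       value = round(rnorm(1), 3))))
  cand <- set_node(tree, p, graft)
  if (tree_depth(cand) > max_depth) return(expr)
  new_sr_expr(cand)
}

#' Symbolic-regression configuration
#'
#' @param lambda complexity regularization, >= 0.
#' @param n_offspring offspring per generation (the N of the (N+1)
#'   evolution strategy).
#' @param generations number of generations.
#' @param operators operator subset to search over.
#' @param max_depth depth cap on mutated trees.
#' @param invalid_penalty per-record penalty for invalid evaluations.
#' @param opt_maxit constant-optimizer iteration cap per expression.
#' @param seed master seed of the search.
#' @export
sr_config <- function(lambda = 1e-3, n_offspring = 4L, generations = 200L,
                      operators = c("+", "-", "*", "/", "exp", "log"),
                      max_depth = 6L, invalid_penalty = 1e3,
                      opt_maxit = 60L, seed = 1L) {
  if (lambda < 0) abort("lambda must be >= 0")
  if (n_offspring < 1) abort("n_offspring must be >= 1")
  bad <- setdiff(operators, names(sr_ops))
  if (length(bad)) abort(paste0("unknown operator(s): ",
                                paste(bad, collapse = ", ")))
  structure(list(lambda = lambda, n_offspring = as.integer(n_offspring),
                 generations = as.integer(generations),
                 operators = operators, max_depth = as.integer(max_depth),
                 invalid_penalty = invalid_penalty,
                 opt_maxit = as.integer(opt_maxit), seed = seed),
            class = "sr_config")
}

#' Distill a committor into a symbolic expression by (N+1) evolution
#'
#' A (N+1) evolution strategy over expression trees: each generation, N
#' offspring are generated by random changes to the mathematical
#' structure of the fittest expression, every offspring's constants are
#' fitted by gradient-based optimization, and the fittest of parent and
#' offspring becomes the next parent. Fitness is the regularized loss
#' [regularized_loss()]. The search starts from the best constant model
#' (whose maximum-likelihood value has a closed form), so the returned
#' expression can never be less fit than it; the best fitness is monotone
#' nonincreasing across generations, and the whole search is
#' reproducible under the configuration seed.
#'
#' @param data a [training_set()] tibble.
#' @param inputs variable names the expressions may use.
#' @param config an [sr_config()].
#' @return an object of class `sr_fit`: `best` expression, `history`
#'   tibble (generation, fitness, complexity, expression), `config`.
#' @export
evolve <- function(data, inputs, config = sr_config()) {
  if (length(inputs) < 1) abort("need at least one input")
  data <- as_tibble(data)
  set.seed(config$seed)
  # closed-form ML constant: q* = log(n_B / n_A) over the pooled outcomes
  if ("s" %in% names(data)) {
    nB <- sum(data$s == -1); nA <- sum(data$s == 1)
  } else {
    nB <- sum(data$n_B); nA <- sum(data$n_A)
  }
  q0 <- log(pmax(nB, 0.5) / pmax(nA, 0.5))
  parent <- sr_const(q0)
  denv <- sr_data_env(data)
  fit_of <- function(e) {
    sr_nll(e$tree, denv, config$invalid_penalty) +
      config$lambda * complexity(e)
  }
  parent_fit <- fit_of(parent)
  hist_gen <- integer(config$generations)
  hist_fit <- numeric(config$generations)
  hist_C <- integer(config$generations)
  hist_expr <- character(config$generations)
  for (gen in seq_len(config$generations)) {
    offspring <- lapply(seq_len(config$n_offspring), function(i) {
      child <- mutate_expr(parent, inputs, config$operators,
                           config$max_depth)
      optimize_constants(child, denv, maxit = config$opt_maxit,
                         invalid_penalty = config$invalid_penalty)
    })
    fits <- vapply(offspring, function(e) {
      f <- tryCatch(fit_of(e), error = function(err) Inf)
      if (is.finite(f)) f else Inf
    }, numeric(1))
    best <- which.min(fits)
    if (length(best) == 1 && fits[best] < parent_fit) {
      parent <- offspring[[best]]
      parent_fit <- fits[best]
    }
    hist_gen[gen] <- gen
    hist_fit[gen] <- parent_fit
    hist_C[gen] <- complexity(parent)
    hist_expr[gen] <- format(parent)
  }
  structure(list(best = parent, fitness = parent_fit,
                 history = tibble(generation = hist_gen,
                                  fitness = hist_fit,
                                  complexity = hist_C,
                                  expression = hist_expr),
                 config = config),
            class = "sr_fit")
}

#' @export
print.sr_fit <- function(x, ...) {
  cat("<sr_fit>", format(x$best), "\n")
  cat("  fitness", format(x$fitness), " complexity", complexity(x$best),
      " after", nrow(x$history), "generations\n")
  invisible(x)
}

#' @export
tidy.sr_fit <- function(x, ...) x$history

#' @export
glance.sr_fit <- function(x, ...) {
  tibble(fitness = x$fitness, complexity = complexity(x$best),
         n_constants = length(sr_constants(x$best)),
         generations = nrow(x$history), lambda = x$config$lambda,
         expression = format(x$best))
}

#' Run symbolic regression over input combinations and penalties
#'
#' Convenience wrapper enumerating independent [evolve()] searches over
#' subsets of the most relevant inputs (as ranked by
#' [permutation_importance()]) and a grid of regularization strengths,
#' collecting one candidate expression per search. When validation data
#' are supplied the candidate table carries a held-out loss for Pareto
#' selection; otherwise the training loss is used.
#'
#' @param data training [training_set()].
#' @param input_sets list of character vectors of input names.
#' @param lambdas regularization values to scan.
#' @param config base [sr_config()] (its lambda/seed are overridden per
#'   search).
#' @param val_data optional held-out [training_set()].
#' @return tibble of candidates: `expression`, `complexity`,
#'   `train_loss`, `val_loss`, `lambda`, `inputs`, plus the fitted
#'   objects in the `fit` list-column.
#' @export
distill_expressions <- function(data, input_sets, lambdas = c(1e-3, 1e-4),
                                config = sr_config(), val_data = NULL) {
  grid <- expand.grid(set = seq_along(input_sets),
                      lambda = lambdas, stringsAsFactors = FALSE)
  seeds <- derive_seeds(config$seed, nrow(grid))
  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$lambda <- grid$lambda[i]
    cfg$seed <- seeds[i]
    inputs <- input_sets[[grid$set[i]]]
    fit <- evolve(data, inputs, cfg)
    train_loss <- regularized_loss(fit$best, data, lambda = 0,
                                   invalid_penalty = cfg$invalid_penalty)
    val_loss <- if (!is.null(val_data)) {
      regularized_loss(fit$best, val_data, lambda = 0,
                       invalid_penalty = cfg$invalid_penalty)
    } else train_loss
    tibble(expression = format(fit$best), complexity = complexity(fit$best),
           train_loss = train_loss, val_loss = val_loss,
           lambda = grid$lambda[i],
           inputs = paste(inputs, collapse = ","), fit = list(fit))
  })
  dplyr::bind_rows(res)
}

#' Pareto front over (loss, complexity)
#'
#' Non-dominated set of candidate expressions under simultaneously
#' decreasing validation loss and complexity, with a knee suggestion:
#' the front point of maximal perpendicular distance to the chord
#' joining the front's endpoints (after scaling both axes to `[0, 1]`).
#' The full front is always returned; the knee is a suggestion only.
#'
#' @param candidates tibble with columns `loss_col` and `c_col` (e.g.
#'   from [distill_expressions()], using `val_loss`).
#' @param loss_col,c_col column names.
#' @return the front rows, sorted by complexity, with a logical `knee`
#'   column.
#' @export
pareto_front <- function(candidates, loss_col = "val_loss",
                         c_col = "complexity") {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) abort("no candidates")
  loss <- candidates[[loss_col]]; C <- candidates[[c_col]]
  dominated <- vapply(seq_along(loss), function(i) {
    any(loss <= loss[i] & C <= C[i] & (loss < loss[i] | C < C[i]))
  }, logical(1))
  front <- candidates[!dominated, , drop = FALSE]
  front <- front[order(front[[c_col]], front[[loss_col]]), , drop = FALSE]
  n <- nrow(front)
  knee <- rep(FALSE, n)
  if (n >= 3) {
    x <- front[[c_col]]; y <- front[[loss_col]]
    xs <- (x - min(x)) / max(diff(range(x)), 1e-12)
    ys <- (y - min(y)) / max(diff(range(y)), 1e-12)
    x1 <- xs[1]; y1 <- ys[1]; x2 <- xs[n]; y2 <- ys[n]
    dist <- abs((y2 - y1) * xs - (x2 - x1) * ys + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
    knee[which.max(dist)] <- TRUE
  } else {
    knee[n] <- TRUE
  }
  front$knee <- knee
  front
}

#' @rdname pareto_front
#' @param front a candidates or front tibble.
#' @export
plot_pareto <- function(front, loss_col = "val_loss",
                        c_col = "complexity") {
  ggplot2::ggplot(front, ggplot2::aes(x = .data[[c_col]],
                                      y = .data[[loss_col]])) +
    ggplot2::geom_point() +
    ggplot2::geom_step(data = pareto_front(front, loss_col, c_col),
                       direction = "hv", colour = "red") +
    ggplot2::labs(x = "complexity (operations)", y = "loss") +
    ggplot2::theme_minimal()
}

# ---- formatting and serialization --------------------------------------

format_tree <- function(tree) {
  if (tree$type == "var") return(tree$name)
  if (tree$type == "const") return(format(tree$value, digits = 6))
  a <- vapply(tree$args, format_tree, character(1))
  switch(tree$op,
         neg = paste0("-(", a[1], ")"),
         exp = paste0("exp(", a[1], ")"),
         log = paste0("log(", a[1], ")"),
         pow = paste0("(", a[1], ")^(", a[2], ")"),
         paste0("(", a[1], " ", tree$op, " ", a[2], ")"))
}

#' @export
format.sr_expr <- function(x, ...) format_tree(x$tree)

#' @export
print.sr_expr <- function(x, ...) {
  cat("<sr_expr>", format(x), " [C =", complexity(x), "]\n")
  invisible(x)
}

#' Prefix-notation serialization of expressions
#'
#' `sr_serialize()` writes an expression as a prefix string (operators and
#' leaves separated by spaces, constants in full precision);
#' `sr_deserialize()` parses it back. Round trips are exact.
#'
#' @param expr an [sr_expr][sr_var] expression.
#' @export
sr_serialize <- function(expr) {
  ser <- function(tree) {
    if (tree$type == "var") return(tree$name)
    if (tree$type == "const") {
      return(paste0("#", format(tree$value, digits = 17)))
    }
    paste(c(tree$op, vapply(tree$args, ser, character(1))), collapse = " ")
  }
  ser(expr$tree)
}

#' @rdname sr_serialize
#' @param text a prefix string from [sr_serialize()].
#' @export
sr_deserialize <- function(text) {
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  i <- 0L
  parse1 <- function() {
    i <<- i + 1L
    tok <- tokens[i]
    if (tok %in% names(sr_ops)) {
      args <- lapply(seq_len(sr_ops[[tok]]$arity), function(k) parse1())
      return(list(type = "call", op = tok, args = args))
    }
    if (startsWith(tok, "#")) {
      return(list(type = "const", value = as.numeric(substring(tok, 2))))
    }
    list(type = "var", name = tok)
  }
  out <- new_sr_expr(parse1())
  if (i != length(tokens)) abort("trailing tokens in expression text")
  out
}

#' Worked distilled expressions
#'
#' `example_polymer_expression()` is the distilled two-variable committor
#' model of homopolymer coil-to-crystal folding,
#' \deqn{q_B(U, Q_6) = \alpha (U - U_0) + \beta \log(Q_6 - Q_{6,0}) + \gamma,}
#' with constants \eqn{\alpha = -7.144}, \eqn{\beta = 3.269},
#' \eqn{\gamma = 11.942}, \eqn{U_0 = -2.351}, \eqn{Q_{6,0} = 0.035}
#' (`U` is the polymer potential energy, `Q6` its global crystallinity).
#' `example_dimer_contact_expression()` is the distilled two-contact
#' committor model of transmembrane-dimer assembly,
#' \deqn{q_B(x_9, x_{22}) = -\exp(x_9^2)\,\log(x_9 - x_9/\log(x_{22})),}
#' a function of two switched interhelical contact distances. Both serve
#' as evaluation fixtures for the generic expression machinery.
#'
#' @export
example_polymer_expression <- function() {
  sr_call("+",
          sr_call("+",
                  sr_call("*", sr_const(-7.144),
                          sr_call("-", sr_var("U"), sr_const(-2.351))),
                  sr_call("*", sr_const(3.269),
                          sr_call("log",
                                  sr_call("-", sr_var("Q6"),
                                          sr_const(0.035))))),
          sr_const(11.942))
}

#' @rdname example_polymer_expression
#' @export
example_dimer_contact_expression <- function() {
  sr_call("neg",
          sr_call("*",
                  sr_call("exp", sr_call("*", sr_var("x9"), sr_var("x9"))),
                  sr_call("log",
                          sr_call("-", sr_var("x9"),
                                  sr_call("/", sr_var("x9"),
                                          sr_call("log", sr_var("x22")))))))
}
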
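#' Configure a target-barrier search
#'
#' @param target Target activation barrier, kcal/mol.
#' @param tolerance Success tolerance, kcal/mol: a reaction satisfices when
#'   its measured barrier lies within `tolerance` of `target` (inclusive;
#'   the default 1.0 is the usual chemical-accuracy threshold).
#' @param initial_sample_size Number of successfully measured reactions in
#'   the initial random sample (default 5). A warm-start reaction counts
#'   toward this number.
#' @param use_low_level Use the low-level barrier as a model feature? The
#'   table must then have a complete `low_level` column (see
#'   [impute_low_level()]).
#' @param warm_start Optional known starting reaction: a list with `reaction`
#'   (option labels) or `index` (canonical index), and optionally `barrier`
#'   (its measured barrier; measured through the oracle when absent). Its
#'   measurement is counted like any other. Used by the model-guided
#'   searches.
#' @param seed Integer RNG seed; every algorithm is deterministic given the
#'   seed, config and table.
#' @param max_measurements Measurement budget (default: the space size, so
#'   exhaustion is well defined when no satisficing barrier exists).
#' @param alphas Ridge penalty grid for the surrogate
#'   (default [default_alpha_grid()]).
#' @param scramble_features If `TRUE`, the feature-to-reaction mapping is
#'   randomly permuted at the start of the run (a negative control: the
#'   surrogate can then learn nothing real about the landscape).
#' @param pop_size,crossover_rate,mutation_rate,tournament_k Genetic-search
#'   parameters: population size (default 20), probability of single-point
#'   crossover (0.9), per-position mutation probability (0.1), tournament
#'   size (3).
#' @return A `search_config` list.
#' @export
search_config <- function(target, tolerance = 1.0, initial_sample_size = 5L,
                          use_low_level = FALSE, warm_start = NULL,
                          seed = 1L, max_measurements = NULL,
                          alphas = default_alpha_grid(),
                          scramble_features = FALSE,
                          pop_size = 20L, crossover_rate = 0.9,
                          mutation_rate = 0.1, tournament_k = 3L) {
  stopifnot(is.numeric(target), length(target) == 1L)
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("`tolerance` must be > 0", call. = FALSE)
  }
  if (initial_sample_size < 1L) {
    stop("`initial_sample_size` must be >= 1", call. = FALSE)
  }
  if (!is.null(max_measurements) &&
      max_measurements < initial_sample_size) {
    stop("`max_measurements` must be >= `initial_sample_size`", call. = FALSE)
  }
  structure(
    list(target = target, tolerance = tolerance,
         initial_sample_size = as.integer(initial_sample_size),
         use_low_level = isTRUE(use_low_level), warm_start = warm_start,
         seed = as.integer(seed), max_measurements = max_measurements,
         alphas = alphas, scramble_features = isTRUE(scramble_features),
         pop_size = as.integer(pop_size), crossover_rate = crossover_rate,
         mutation_rate = mutation_rate, tournament_k = as.integer(tournament_k)),
    class = "search_config"
  )
}

# ---- shared run machinery ---------------------------------------------------

# mutable run state: trajectory recorder + candidate pool + oracle counting
new_run_state <- function(table, config, oracle = NULL) {
  st <- new.env(parent = emptyenv())
  st$N <- nrow(table$space)
  if (st$N == 0L) stop("the reaction space is empty", call. = FALSE)
  st$max_m <- if (is.null(config$max_measurements)) st$N
              else min(config$max_measurements, st$N)
  st$oracle <- if (is.null(oracle)) {
    high <- table$high_level
    function(i) high[i]
  } else {
    oracle
  }
  st$target <- config$target
  st$tol <- config$tolerance
  st$idx <- integer(st$max_m)
  st$out <- numeric(st$max_m)
  st$phase <- character(st$max_m)
  st$n <- 0L
  st$pool <- rep(TRUE, st$N)  # not yet measured (in any way)
  st$success <- FALSE
  st
}

# measure reaction i (once only), record phase, update pool/success.
# `value` overrides the oracle (warm starts with a known barrier).
st_measure <- function(st, i, phase, value = NULL) {
  if (!st$pool[i]) stop("internal: reaction ", i, " measured twice")
  val <- if (is.null(value)) st$oracle(i) else value
  st$n <- st$n + 1L
  st$idx[st$n] <- i
  st$out[st$n] <- if (is.null(val) || is.na(val)) NA_real_ else as.numeric(val)
  st$phase[st$n] <- phase
  st$pool[i] <- FALSE
  if (!is.na(st$out[st$n]) && abs(st$out[st$n] - st$target) <= st$tol) {
    st$success <- TRUE
  }
  st$out[st$n]
}

st_budget_left <- function(st) st$n < st$max_m

st_result <- function(st, algorithm, config) {
  n <- st$n
  traj <- data.frame(step = seq_len(n), index = st$idx[seq_len(n)],
                     barrier = st$out[seq_len(n)],
                     phase = st$phase[seq_len(n)],
                     stringsAsFactors = FALSE)
  ok <- !is.na(traj$barrier) & abs(traj$barrier - config$target) <= config$tolerance
  found <- if (any(ok)) which(ok)[1L] else NA_integer_
  structure(
    list(algorithm = algorithm, target = config$target,
         tolerance = config$tolerance, seed = config$seed,
         trajectory = traj, n_measurements = n,
         success = any(ok),
         found_index = if (is.na(found)) NA_integer_ else traj$index[found],
         found_barrier = if (is.na(found)) NA_real_ else traj$barrier[found]),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("%s search for target %.2f kcal/mol (tolerance %.2f)\n",
              x$algorithm, x$target, x$tolerance))
  if (x$success) {
    cat(sprintf("  success after %d measurements: reaction %d, barrier %.3f\n",
                x$n_measurements, x$found_index, x$found_barrier))
  } else {
    cat(sprintf("  no satisficing reaction within %d measurements (censored)\n",
                x$n_measurements))
  }
  invisible(x)
}

resolve_warm_start <- function(ws, table) {
  if (is.null(ws)) return(NULL)
  if (!is.null(ws$index)) {
    idx <- as.integer(ws$index)
    if (idx < 1L || idx > nrow(table$space)) {
      stop("warm-start index out of range", call. = FALSE)
    }
  } else if (!is.null(ws$reaction)) {
    key <- space_keys(space_codes(table$space, table$scheme))
    codes <- assignment_codes(ws$reaction, table$scheme)
    idx <- lookup_index(codes, table$scheme, key)
    if (is.na(idx)) stop("warm-start reaction not in the space", call. = FALSE)
  } else {
    stop("warm_start must have `index` or `reaction`", call. = FALSE)
  }
  list(index = idx, barrier = ws$barrier)
}

# feature accessors with optional scrambling (rows of the bit matrix and the
# low-level vector permuted once per run from the run's RNG stream)
make_feature_source <- function(table, config) {
  bits <- encode_space(table$space, table$scheme)
  N <- nrow(bits)
  low <- table$low_level
  if (config$use_low_level && anyNA(low)) {
    stop("use_low_level = TRUE but low_level has missing entries; run ",
         "impute_low_level() first", call. = FALSE)
  }
  map <- if (config$scramble_features) sample.int(N) else seq_len(N)
  list(bits = bits, low = low, map = map, use_low = config$use_low_level)
}

# design matrix for reactions `rows`, low-level column standardized with
# statistics of the training rows only
fs_matrix <- function(fs, rows, train_idx) {
  X <- fs$bits[fs$map[rows], , drop = FALSE]
  if (fs$use_low) {
    lowv <- fs$low[fs$map]
    X <- cbind(X, low_level = scale_by_train(lowv, train_idx)[rows])
  }
  X
}

# initial phase shared by the model-guided searches: warm start, then random
# draws without replacement until `initial_sample_size` successful
# measurements are on hand (failed draws are replaced by fresh draws, every
# draw counted), without early stopping inside the phase.
run_initial_phase <- function(st, config, table) {
  ws <- resolve_warm_start(config$warm_start, table)
  if (!is.null(ws)) {
    st_measure(st, ws$index, "warm_start", value = ws$barrier)
  }
  n_success <- sum(!is.na(st$out[seq_len(st$n)]))
  draws_issued <- 0L
  needed <- config$initial_sample_size - if (is.null(ws)) 0L else 1L
  while (n_success < config$initial_sample_size &&
         any(st$pool) && st_budget_left(st)) {
    i <- resample(which(st$pool), 1L)
    phase <- if (draws_issued < needed) "initial" else "replacement"
    draws_issued <- draws_issued + 1L
    val <- st_measure(st, i, phase)
    if (!is.na(val)) n_success <- n_success + 1L
  }
  invisible(st)
}

# sample() without its scalar-x surprise
resample <- function(x, size) x[sample.int(length(x), size)]

train_rows <- function(st) {
  sel <- seq_len(st$n)
  st$idx[sel][!is.na(st$out[sel])]
}

# ---- algorithms -------------------------------------------------------------

#' Active-learning ridge search for a target barrier
#'
#' The recommended algorithm. An initial random sample of reactions is
#' measured (a warm-start reaction, when given, is part of this sample;
#' failed measurements are replaced by fresh random draws, and every
#' measurement counts). Then, iteratively: a ridge regression on the one-hot
#' features (optionally concatenated with the low-level barrier feature) is
#' tuned by 5-fold cross-validated MAE and fitted to all measured barriers,
#' all unmeasured reactions are predicted, and the reaction predicted
#' closest to the target is measured. A failed measurement is discarded from
#' the candidate pool and the next-closest prediction is measured instead,
#' without refitting. The run stops as soon as a measured barrier lies
#' within the tolerance of the target, or when the measurement budget is
#' exhausted (returned as an unsuccessful, censored result, not an error).
#'
#' @param table A [barrier_table()].
#' @param config A [search_config()].
#' @param oracle Optional measurement callback `function(canonical_index)`
#'   returning a barrier in kcal/mol or `NA` for a failed measurement;
#'   defaults to the table's high-level column.
#' @return A `search_result`: the ordered measurement `trajectory` (with a
#'   `phase` column distinguishing warm-start, initial, replacement and
#'   model-selected measurements), `n_measurements` (every oracle call,
#'   including failures), `success`, and the satisficing reaction when found.
#' @examples
#' sch <- rgroup_scheme(list(R1 = letters[1:4], R2 = letters[1:4]))
#' tab <- barrier_table(sch, high_level = 1:16)
#' ml_search(tab, search_config(target = 12, seed = 1))
#' @export
ml_search <- function(table, config, oracle = NULL) {
  stopifnot(inherits(table, "barrier_table"), inherits(config, "search_config"))
  set.seed(config$seed)
  st <- new_run_state(table, config, oracle)
  fs <- make_feature_source(table, config)
  run_initial_phase(st, config, table)

  while (!st$success && st_budget_left(st) && any(st$pool)) {
    tr <- train_rows(st)
    if (length(tr) < 2L) {
      # not enough signal to fit: fall back to a random draw
      st_measure(st, resample(which(st$pool), 1L), "model")
      next
    }
    sel <- seq_len(st$n)
    y <- st$out[sel][!is.na(st$out[sel])]
    fit <- ridge_tuned(fs_matrix(fs, tr, tr), y, alphas = config$alphas)
    cand <- which(st$pool)
    pred <- ridge_predict(fit, fs_matrix(fs, cand, tr))
    ord <- cand[order(abs(pred - config$target), cand)]
    for (i in ord) {
      if (!st_budget_left(st)) break
      val <- st_measure(st, i, "model")
      if (!is.na(val)) break  # refit on the augmented training set
    }
  }
  st_result(st, "ml", config)
}

#' Random search baseline
#'
#' Measures uniformly random reactions without replacement until one
#' satisfices; failed measurements count. The simplest possible baseline.
#'
#' @inheritParams ml_search
#' @return A `search_result`.
#' @export
random_search <- function(table, config, oracle = NULL) {
  stopifnot(inherits(table, "barrier_table"), inherits(config, "search_config"))
  set.seed(config$seed)
  st <- new_run_state(table, config, oracle)
  perm <- sample.int(st$N)
  for (i in perm) {
    if (st$success || !st_budget_left(st)) break
    st_measure(st, i, "random")
  }
  st_result(st, "random", config)
}

#' Local search baselines
#'
#' Both walk the one-substitution neighborhood graph: the neighbors of a
#' reaction are the canonical forms of all assignments differing at exactly
#' one position. `local_search()` starts at a random reaction and moves to a
#' uniformly random unmeasured neighbor. `guided_local_search()` instead
#' moves to the unmeasured neighbor whose barrier, predicted by the same
#' CV-tuned ridge surrogate as [ml_search()] trained on all measurements so
#' far, is closest to the target. When every neighbor has been measured (or
#' failed), the walk restarts from a fresh random unmeasured reaction.
#' Failed measurements count; the walk continues from the failed reaction's
#' position.
#'
#' @inheritParams ml_search
#' @return A `search_result`.
#' @export
local_search <- function(table, config, oracle = NULL) {
  local_search_impl(table, config, oracle, guided = FALSE)
}

#' @rdname local_search
#' @export
guided_local_search <- function(table, config, oracle = NULL) {
  local_search_impl(table, config, oracle, guided = TRUE)
}

local_search_impl <- function(table, config, oracle, guided) {
  stopifnot(inherits(table, "barrier_table"), inherits(config, "search_config"))
  set.seed(config$seed)
  st <- new_run_state(table, config, oracle)
  fs <- make_feature_source(table, config)
  codes_mat <- space_codes(table$space, table$scheme)
  key <- space_keys(codes_mat)
  nb_cache <- vector("list", st$N)
  neighbors_of <- function(i) {
    if (is.null(nb_cache[[i]])) {
      nb_cache[[i]] <<- neighbor_indices(i, table$scheme, codes_mat, key)
    }
    nb_cache[[i]]
  }

  current <- resample(which(st$pool), 1L)
  st_measure(st, current, "restart")
  while (!st$success && st_budget_left(st) && any(st$pool)) {
    nb <- neighbors_of(current)
    nb <- nb[st$pool[nb]]
    if (!length(nb)) {
      current <- resample(which(st$pool), 1L)
      st_measure(st, current, "restart")
      next
    }
    if (guided && length(train_rows(st)) >= 2L && length(nb) > 1L) {
      tr <- train_rows(st)
      sel <- seq_len(st$n)
      y <- st$out[sel][!is.na(st$out[sel])]
      fit <- ridge_tuned(fs_matrix(fs, tr, tr), y, alphas = config$alphas)
      pred <- ridge_predict(fit, fs_matrix(fs, nb, tr))
      nxt <- nb[order(abs(pred - config$target), nb)][1L]
    } else {
      nxt <- resample(nb, 1L)
    }
    st_measure(st, nxt, "move")
    current <- nxt
  }
  st_result(st, if (guided) "guided_local" else "local", config)
}

#' Bayesian-optimization baseline
#'
#' Follows the same loop structure as [ml_search()] (including the initial
#' sample, failure handling and counting) but replaces the ridge surrogate
#' with a Gaussian process (squared-exponential kernel, median-distance
#' lengthscale heuristic, small nugget) on the same features, and ranks
#' candidates by the expected improvement of the target-matching objective
#' `-|barrier - target|` over the best measured distance so far. Candidates
#' with zero acquisition fall back to the posterior-mean distance ranking.
#'
#' @inheritParams ml_search
#' @return A `search_result`.
#' @export
bayesian_opt_search <- function(table, config, oracle = NULL) {
  stopifnot(inherits(table, "barrier_table"), inherits(config, "search_config"))
  set.seed(config$seed)
  st <- new_run_state(table, config, oracle)
  fs <- make_feature_source(table, config)
  run_initial_phase(st, config, table)

  while (!st$success && st_budget_left(st) && any(st$pool)) {
    tr <- train_rows(st)
    if (length(tr) < 2L) {
      st_measure(st, resample(which(st$pool), 1L), "model")
      next
    }
    sel <- seq_len(st$n)
    y <- st$out[sel][!is.na(st$out[sel])]
    fit <- gp_fit(fs_matrix(fs, tr, tr), y)
    cand <- which(st$pool)
    post <- gp_predict(fit, fs_matrix(fs, cand, tr))
    d_best <- min(abs(y - config$target))
    ei <- ei_target(post$mean, post$sd, config$target, d_best)
    ord <- cand[order(-ei, abs(post$mean - config$target), cand)]
    for (i in ord) {
      if (!st_budget_left(st)) break
      val <- st_measure(st, i, "model")
      if (!is.na(val)) break
    }
  }
  st_result(st, "bayesopt", config)
}

# single-point crossover over the position vector: parent 1 up to `cut`,
# parent 2 after
ga_crossover <- function(p1, p2, cut) {
  c(p1[seq_len(cut)], p2[(cut + 1L):length(p2)])
}

# per-position mutation to a uniformly random different option
ga_mutate <- function(codes, rate, n_options) {
  for (p in seq_along(codes)) {
    if (n_options[p] > 1L && stats::runif(1) < rate) {
      codes[p] <- resample(setdiff(seq_len(n_options[p]), codes[p]), 1L)
    }
  }
  codes
}

#' Genetic-algorithm baseline
#'
#' A generational GA over position assignments. The initial population is a
#' random sample of distinct reactions, all measured. Fitness is
#' `-|measured barrier - target|`, with failed measurements assigned the
#' worst fitness. Each generation builds `pop_size` offspring by tournament
#' selection, single-point crossover over the position vector, and
#' per-position mutation; every offspring is canonicalized, forced to be
#' novel against the whole trajectory (by extra mutations, falling back to a
#' random unmeasured reaction), and measured.
#'
#' @inheritParams ml_search
#' @return A `search_result`.
#' @export
genetic_search <- function(table, config, oracle = NULL) {
  stopifnot(inherits(table, "barrier_table"), inherits(config, "search_config"))
  if (config$pop_size < 2L && config$mutation_rate <= 0) {
    stop("degenerate genetic configuration: population of 1 with no ",
         "mutation cannot generate new candidates", call. = FALSE)
  }
  set.seed(config$seed)
  st <- new_run_state(table, config, oracle)
  scheme <- table$scheme
  codes_mat <- space_codes(table$space, scheme)
  key <- space_keys(codes_mat)
  P <- length(scheme$positions)
  k <- lengths(scheme$options)

  pop_n <- min(config$pop_size, st$N)
  pop <- resample(which(st$pool), pop_n)
  for (i in pop) {
    if (st$success || !st_budget_left(st)) break
    st_measure(st, i, "initial")
  }
  fitness_of <- function(idx) {
    pos <- match(idx, st$idx[seq_len(st$n)])
    val <- st$out[pos]
    ifelse(is.na(val), -Inf, -abs(val - st$target))
  }

  mutate <- function(codes, rate) ga_mutate(codes, rate, k)

  while (!st$success && st_budget_left(st) && any(st$pool)) {
    fit <- fitness_of(pop)
    children <- integer(0)
    for (m in seq_len(pop_n)) {
      if (st$success || !st_budget_left(st) || !any(st$pool)) break
      tk <- min(config$tournament_k, length(pop))
      # tournament: pick tk contestants, keep the fittest
      tourn <- function() {
        cont <- resample(seq_along(pop), tk)
        pop[cont[which.max(fit[cont])]]
      }
      p1 <- tourn()
      p2 <- tourn()
      child <- codes_mat[p1, ]
      if (P > 1L && stats::runif(1) < config$crossover_rate) {
        cut <- resample(seq_len(P - 1L), 1L)
        child <- ga_crossover(codes_mat[p1, ], codes_mat[p2, ], cut)
      }
      child <- mutate(child, config$mutation_rate)
      idx <- lookup_index(child, scheme, key)
      tries <- 0L
      while (!st$pool[idx] && tries < 20L) {
        child <- mutate(child, max(config$mutation_rate, 0.3))
        idx <- lookup_index(child, scheme, key)
        tries <- tries + 1L
      }
      if (!st$pool[idx]) idx <- resample(which(st$pool), 1L)
      st_measure(st, idx, "offspring")
      children <- c(children, idx)
    }
    if (length(children)) pop <- children
  }
  st_result(st, "genetic", config)
}
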
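#' Build the evaluation target grid for a barrier table
#'
#' Targets span the barrier distribution at roughly 2 kcal/mol spacing, and
#' every target is an actual available barrier: the first target is the
#' minimum available barrier, and each subsequent target is the available
#' barrier closest to 2 kcal/mol above the previous one (ties broken toward
#' the lower barrier), until the maximum barrier is selected.
#'
#' @param table A [barrier_table()].
#' @param spacing Grid spacing in kcal/mol (default 2).
#' @return Numeric vector of strictly increasing target barriers.
#' @export
build_target_grid <- function(table, spacing = 2.0) {
  stopifnot(inherits(table, "barrier_table"))
  b <- sort(unique(table$high_level[!is.na(table$high_level)]))
  if (!length(b)) stop("no available barriers in the table", call. = FALSE)
  targets <- b[1L]
  t <- b[1L]
  bmax <- b[length(b)]
  while (t < bmax) {
    cand <- b[b > t]
    d <- abs(cand - (t + spacing))
    t <- cand[order(d, cand)][1L]  # tie toward the lower barrier
    targets <- c(targets, t)
  }
  targets
}

#' Run the benchmark protocol
#'
#' For each algorithm and each target of the grid, runs `repeats` seeded
#' searches (per-repeat seed = `seed + repeat - 1`, so repeats share their
#' initial random sample across algorithms) and records the mean number of
#' measurements. Runs that exhaust the measurement budget without success
#' are counted at their full measurement count and flagged as censored,
#' never silently treated as successes.
#'
#' @param table A [barrier_table()].
#' @param algorithms Character vector from `ml`, `random`, `local`,
#'   `guided_local`, `bayesopt`, `genetic`.
#' @param repeats Number of repeats per target (default 25).
#' @param seed Master seed (mandatory; no silent nondeterminism in the
#'   reported means).
#' @param targets Target grid (default [build_target_grid()] of the table).
#' @param use_low_level,scramble_features,... Passed to [search_config()].
#' @return A `benchmark_summary`: data.frame `per_target` with columns
#'   `algorithm`, `target`, `mean_n` (mean measurements over repeats),
#'   `n_censored`, plus the run metadata.
#' @export
run_benchmark <- function(table, algorithms = c("ml", "random"),
                          repeats = 25L, seed, targets = NULL,
                          use_low_level = FALSE, scramble_features = FALSE,
                          ...) {
  stopifnot(inherits(table, "barrier_table"))
  if (missing(seed)) stop("`seed` is mandatory for benchmarks", call. = FALSE)
  algorithms <- match.arg(algorithms,
                          c("ml", "random", "local", "guided_local",
                            "bayesopt", "genetic"),
                          several.ok = TRUE)
  if (is.null(targets)) targets <- build_target_grid(table)
  runners <- list(ml = ml_search, random = random_search,
                  local = local_search, guided_local = guided_local_search,
                  bayesopt = bayesian_opt_search, genetic = genetic_search)

  rows <- vector("list", length(algorithms) * length(targets))
  r <- 0L
  for (alg in algorithms) {
    for (t in targets) {
      ns <- integer(repeats)
      cens <- 0L
      for (rep in seq_len(repeats)) {
        cfg <- search_config(target = t, seed = seed + rep - 1L,
                             use_low_level = use_low_level,
                             scramble_features = scramble_features, ...)
        res <- runners[[alg]](table, cfg)
        ns[rep] <- res$n_measurements
        if (!res$success) cens <- cens + 1L
      }
      r <- r + 1L
      rows[[r]] <- data.frame(algorithm = alg, target = t,
                              mean_n = mean(ns), n_censored = cens,
                              stringsAsFactors = FALSE)
    }
  }
  structure(
    list(per_target = do.call(rbind, rows), targets = targets,
         algorithms = algorithms, repeats = repeats, seed = seed),
    class = "benchmark_summary"
  )
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("Benchmark:", length(x$targets), "targets x", x$repeats,
      "repeats, algorithms:", paste(x$algorithms, collapse = ", "), "\n")
  wide <- summarize_regions(x)
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Region-averaged mean sample counts
#'
#' Aggregates per-target mean measurement counts into three regions of the
#' target grid: `all` targets; `central`, excluding the `k` highest and `k`
#' lowest targets (where most searches are easy, since barriers are dense);
#' and `tails`, only the `k` highest and `k` lowest targets (the hardest
#' searches). `k` defaults to 5; 3 suits data sets with a short barrier
#' range. The central region is reported as `NA` when the grid has no more
#' than `2k` targets.
#'
#' @param summary A `benchmark_summary` from [run_benchmark()].
#' @param k Number of extreme targets on each side (default 5).
#' @return A data.frame with one row per algorithm and columns `all`,
#'   `central`, `tails`, `n_censored`.
#' @export
summarize_regions <- function(summary, k = 5L) {
  stopifnot(inherits(summary, "benchmark_summary"))
  pt <- summary$per_target
  targets <- sort(summary$targets)
  nt <- length(targets)
  tails_t <- if (nt <= 2L * k) targets
             else c(utils::head(targets, k), utils::tail(targets, k))
  central_t <- setdiff(targets, tails_t)
  out <- lapply(summary$algorithms, function(alg) {
    sub <- pt[pt$algorithm == alg, ]
    m <- function(ts) {
      if (!length(ts)) return(NA_real_)
      mean(sub$mean_n[sub$target %in% ts])
    }
    data.frame(algorithm = alg,
               all = m(targets),
               central = if (nt > 2L * k) m(central_t) else NA_real_,
               tails = m(tails_t),
               n_censored = sum(sub$n_censored),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare regression models at search-scale training sizes
#'
#' The model-selection experiment behind the choice of ridge regression as
#' the search surrogate: each model family is trained on `n_train` randomly
#' selected reactions with available barriers (hyperparameters tuned by the
#' same 5-fold CV-MAE grid search) and evaluated on the remaining available
#' reactions; repeated `repeats` times and averaged.
#'
#' Models: `linear` (ordinary least squares), `ridge` (CV-tuned penalty),
#' `rf` (random forest), `gbr` (gradient boosting), `krr` (kernel ridge,
#' RBF kernel), `gp` (Gaussian process). `rf` and `gbr` require the
#' randomForest and xgboost packages.
#'
#' @param tables Named list of [barrier_table()]s (the data sets).
#' @param models Character vector of model names (default: all six).
#' @param n_train Training-set size (default 30).
#' @param repeats Number of random train/test splits (default 5).
#' @param seed Master seed.
#' @param use_low_level Include the low-level barrier feature.
#' @return A data.frame with one row per (dataset, model): mean training
#'   MAE and mean held-out MAE over the repeats, in kcal/mol.
#' @export
model_selection_experiment <- function(tables,
                                       models = c("linear", "ridge", "rf",
                                                  "gbr", "krr", "gp"),
                                       n_train = 30L, repeats = 5L,
                                       seed = 1L, use_low_level = FALSE) {
  if (inherits(tables, "barrier_table")) tables <- list(dataset = tables)
  models <- match.arg(models, c("linear", "ridge", "rf", "gbr", "krr", "gp"),
                      several.ok = TRUE)
  rows <- list()
  for (ds in names(tables)) {
    table <- tables[[ds]]
    avail <- which(!is.na(table$high_level))
    if (length(avail) < n_train + 1L) {
      stop("dataset '", ds, "' has ", length(avail),
           " available barriers; need more than n_train = ", n_train,
           call. = FALSE)
    }
    feats <- assemble_features(table, use_low_level = use_low_level,
                               train_idx = avail)
    X <- feats$X
    y <- table$high_level
    err <- array(0, dim = c(length(models), 2L),
                 dimnames = list(models, c("train", "test")))
    for (rep in seq_len(repeats)) {
      set.seed(seed + rep - 1L)
      tr <- sample(avail, n_train)
      te <- setdiff(avail, tr)
      for (mod in models) {
        f <- fit_model(mod, X[tr, , drop = FALSE], y[tr])
        err[mod, "train"] <- err[mod, "train"] +
          mean(abs(f(X[tr, , drop = FALSE]) - y[tr]))
        err[mod, "test"] <- err[mod, "test"] +
          mean(abs(f(X[te, , drop = FALSE]) - y[te]))
      }
    }
    err <- err / repeats
    rows[[ds]] <- data.frame(dataset = ds, model = models,
                             train_mae = unname(err[, "train"]),
                             test_mae = unname(err[, "test"]),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# uniform fit/predict contract: returns function(Xnew) -> predictions
fit_model <- function(name, X, y) {
  switch(name,
    linear = {
      # minimum-norm least squares (one-hot blocks are rank-deficient)
      fit <- ridge_fit(X, y, alpha = 1e-8)
      function(Xn) ridge_predict(fit, Xn)
    },
    ridge = {
      fit <- ridge_tuned(X, y)
      function(Xn) ridge_predict(fit, Xn)
    },
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("model 'rf' needs the randomForest package", call. = FALSE)
      }
      p <- ncol(X)
      grid <- unique(pmax(1L, c(floor(p / 3), floor(sqrt(p)))))
      mtry <- tune_by_cv(grid, X, y, function(g, Xtr, ytr) {
        fit <- randomForest::randomForest(Xtr, ytr, ntree = 200, mtry = g)
        function(Xn) unname(stats::predict(fit, Xn))
      })
      fit <- randomForest::randomForest(X, y, ntree = 500, mtry = mtry)
      function(Xn) unname(stats::predict(fit, Xn))
    },
    gbr = {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        stop("model 'gbr' needs the xgboost package", call. = FALSE)
      }
      grid <- c(2L, 3L)
      mk <- function(g, Xtr, ytr) {
        fit <- xgboost::xgboost(Xtr, ytr, nrounds = 100,
                                max_depth = g, learning_rate = 0.1,
                                verbosity = 0, nthreads = 1)
        function(Xn) stats::predict(fit, Xn)
      }
      depth <- tune_by_cv(grid, X, y, mk)
      mk(depth, X, y)
    },
    krr = {
      ell <- median_lengthscale(X)
      grid <- c(1e-3, 1e-2, 1e-1, 1)
      mk <- function(g, Xtr, ytr) {
        fit <- krr_fit(Xtr, ytr, lambda = g, lengthscale = ell)
        function(Xn) krr_predict(fit, Xn)
      }
      lam <- tune_by_cv(grid, X, y, mk)
      mk(lam, X, y)
    },
    gp = {
      fit <- gp_fit(X, y)
      function(Xn) gp_predict(fit, Xn)$mean
    }
  )
}

# generic CV-MAE grid tuner over a scalar hyperparameter grid
tune_by_cv <- function(grid, X, y, make_fit, nfolds = 5L) {
  if (length(grid) == 1L) return(grid[[1L]])
  folds <- cv_folds(nrow(X), nfolds)
  err <- numeric(length(grid))
  for (f in seq_len(max(folds))) {
    hold <- folds == f
    for (g in seq_along(grid)) {
      pr <- make_fit(grid[[g]], X[!hold, , drop = FALSE], y[!hold])
      err[g] <- err[g] + sum(abs(pr(X[hold, , drop = FALSE]) - y[hold]))
    }
  }
  grid[[which.min(err)]]
}

median_lengthscale <- function(X) {
  d <- stats::dist(X[seq_len(min(nrow(X), 200L)), , drop = FALSE])
  d <- d[d > 0]
  if (length(d)) stats::median(d) else 1
}

krr_fit <- function(X, y, lambda, lengthscale) {
  K <- exp(-as.matrix(stats::dist(X))^2 / (2 * lengthscale^2))
  ym <- mean(y)
  alpha <- solve(K + lambda * diag(nrow(K)), y - ym)
  list(X = X, alpha = alpha, ym = ym, lengthscale = lengthscale)
}

krr_predict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  d2 <- outer(rowSums(Xnew^2), rowSums(fit$X^2), "+") - 2 * Xnew %*% t(fit$X)
  d2[d2 < 0] <- 0
  Ks <- exp(-d2 / (2 * fit$lengthscale^2))
  drop(Ks %*% fit$alpha) + fit$ym
}
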
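#' Barrier tables
#'
#' A barrier table aligns two fidelities of activation barrier to the
#' enumerated reaction space of a scheme: the expensive, target-fidelity
#' ("high-level") barrier, which may be missing where the calculation or
#' experiment failed, and an optional cheap, approximate ("low-level")
#' barrier used as a model feature. All barriers are in kcal/mol; missing
#' values are `NA`.
#'
#' @param scheme An [rgroup_scheme()].
#' @param high_level Numeric vector, one entry per canonical reaction
#'   (`NA` = barrier unavailable).
#' @param low_level Optional numeric vector of the same length.
#' @param space Optional pre-enumerated space (from [enumerate_space()]);
#'   enumerated from `scheme` when omitted.
#' @return An object of class `barrier_table` with elements `scheme`,
#'   `space`, `high_level`, `low_level` and `low_imputed` (logical flag per
#'   reaction, `TRUE` where the low-level value was filled by a model).
#' @seealso [load_barrier_csv()], [impute_low_level()], [assemble_features()]
#' @export
barrier_table <- function(scheme, high_level, low_level = NULL, space = NULL) {
  stopifnot(inherits(scheme, "rgroup_scheme"))
  if (is.null(space)) space <- enumerate_space(scheme)
  n <- nrow(space)
  if (length(high_level) != n) {
    stop("`high_level` has length ", length(high_level),
         "; the enumerated space has ", n, " reactions", call. = FALSE)
  }
  if (!is.null(low_level) && length(low_level) != n) {
    stop("`low_level` has length ", length(low_level),
         "; the enumerated space has ", n, " reactions", call. = FALSE)
  }
  structure(
    list(scheme = scheme, space = space,
         high_level = as.numeric(high_level),
         low_level = if (is.null(low_level)) rep(NA_real_, n)
                     else as.numeric(low_level),
         low_imputed = rep(FALSE, n)),
    class = "barrier_table"
  )
}

#' @export
print.barrier_table <- function(x, ...) {
  n <- length(x$high_level)
  cat("Barrier table:", n, "canonical reactions\n")
  cat(sprintf("  high-level barriers: %d available (convergence rate %.1f%%)\n",
              sum(!is.na(x$high_level)), 100 * convergence_rate(x)))
  nlow <- sum(!is.na(x$low_level))
  cat(sprintf("  low-level barriers: %d available (%d imputed)\n",
              nlow, sum(x$low_imputed)))
  invisible(x)
}

#' Fraction of the space with an available high-level barrier
#'
#' The convergence rate of a data set: the proportion of the enumerated
#' reactions for which the target-fidelity barrier calculation succeeded.
#'
#' @param table A [barrier_table()].
#' @return A number in \[0, 1\].
#' @export
convergence_rate <- function(table) {
  stopifnot(inherits(table, "barrier_table"))
  mean(!is.na(table$high_level))
}

#' Load a barrier CSV against a scheme
#'
#' The file must have one column per scheme position plus `high_level` and
#' optionally `low_level` (kcal/mol). Missing barriers are empty cells or the
#' configured sentinel. Rows are canonicalized; symmetry-duplicate rows with
#' agreeing values are merged, and conflicting duplicates are an error.
#' Reactions of the space absent from the file get `NA` high-level barriers.
#'
#' @param path CSV file path.
#' @param scheme An [rgroup_scheme()].
#' @param missing Sentinel string(s) marking a missing barrier (default:
#'   empty cell; `"NA"` is always accepted).
#' @return A [barrier_table()].
#' @export
load_barrier_csv <- function(path, scheme, missing = "") {
  stopifnot(inherits(scheme, "rgroup_scheme"))
  if (!file.exists(path)) {
    stop("barrier CSV not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- c(scheme$positions, "high_level")
  absent <- setdiff(need, names(raw))
  if (length(absent)) {
    stop("barrier CSV lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  has_low <- "low_level" %in% names(raw)

  parse_barrier <- function(x, col) {
    x[x %in% c("", missing, "NA")] <- NA  # empty cells always mean missing
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop("non-numeric ", col, " value '", x[bad[1L]], "' at data row ",
           bad[1L], call. = FALSE)
    }
    out
  }
  hi <- parse_barrier(raw$high_level, "high_level")
  lo <- if (has_low) parse_barrier(raw$low_level, "low_level") else NULL

  space <- enumerate_space(scheme)
  key <- space_keys(space_codes(space, scheme))
  n <- nrow(space)
  high <- rep(NA_real_, n)
  low <- rep(NA_real_, n)
  seen_hi <- rep(FALSE, n)
  seen_lo <- rep(FALSE, n)

  for (r in seq_len(nrow(raw))) {
    codes <- assignment_codes(vapply(scheme$positions,
                                     function(p) raw[[p]][r], character(1)),
                              scheme)
    idx <- lookup_index(codes, scheme, key)
    if (is.na(idx)) stop("row ", r, " is not in the enumerated space",
                         call. = FALSE)
    conflict <- function(old, new) {
      !is.na(old) && !is.na(new) && abs(old - new) > 1e-9 ||
        is.na(old) != is.na(new)
    }
    if (seen_hi[idx] && conflict(high[idx], hi[r])) {
      stop("symmetry-duplicate rows with conflicting high_level barriers ",
           "for canonical reaction ", idx, call. = FALSE)
    }
    if (has_low && seen_lo[idx] && conflict(low[idx], lo[r])) {
      stop("symmetry-duplicate rows with conflicting low_level barriers ",
           "for canonical reaction ", idx, call. = FALSE)
    }
    high[idx] <- hi[r]
    seen_hi[idx] <- TRUE
    if (has_low) {
      low[idx] <- lo[r]
      seen_lo[idx] <- TRUE
    }
  }
  barrier_table(scheme, high, low = if (has_low) low else NULL, space = space)
}

#' Write a barrier table as CSV
#'
#' Inverse of [load_barrier_csv()]: one row per canonical reaction with a
#' column per position, `high_level` and (when any value is present)
#' `low_level`; missing barriers become empty cells.
#'
#' @param table A [barrier_table()].
#' @param path Output file path.
#' @export
write_barrier_csv <- function(table, path) {
  stopifnot(inherits(table, "barrier_table"))
  out <- as.data.frame(table$space)
  out$high_level <- table$high_level
  if (any(!is.na(table$low_level))) out$low_level <- table$low_level
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Impute missing low-level barriers with ridge regression
#'
#' Fits a ridge regression on the one-hot encoding (bits only; the low-level
#' barrier cannot feed itself) to all reactions with an observed low-level
#' barrier, with the penalty chosen by the same 5-fold cross-validated
#' mean-absolute-error grid search used by the search surrogate, then fills
#' every missing low-level entry with the model prediction. Observed values
#' are never altered; imputed entries are flagged, and re-running the
#' imputation is a no-op.
#'
#' @param table A [barrier_table()].
#' @param alphas Ridge penalty grid (default [default_alpha_grid()]).
#' @return The table with `low_level` complete and `low_imputed` updated.
#' @export
impute_low_level <- function(table, alphas = default_alpha_grid()) {
  stopifnot(inherits(table, "barrier_table"))
  obs <- which(!is.na(table$low_level) & !table$low_imputed)
  miss <- which(is.na(table$low_level))
  if (!length(miss)) return(table)
  if (length(obs) < 2L) {
    stop("need at least 2 observed low-level barriers to impute; supply ",
         "more low-level calculations", call. = FALSE)
  }
  X <- encode_space(table$space, table$scheme)
  fit <- ridge_tuned(X[obs, , drop = FALSE], table$low_level[obs],
                     alphas = alphas)
  table$low_level[miss] <- ridge_predict(fit, X[miss, , drop = FALSE])
  table$low_imputed[miss] <- TRUE
  table
}

#' Assemble the model feature matrix and response
#'
#' Builds the design matrix used by the search surrogate: the one-hot bits
#' of every canonical reaction, optionally concatenated with the low-level
#' barrier feature. The low-level column is standardized (centered/scaled)
#' using statistics of the training rows only, so that no information leaks
#' from unmeasured reactions; during a search this is recomputed at every
#' iteration as the training set grows.
#'
#' @param table A [barrier_table()].
#' @param use_low_level Append the low-level barrier column?
#' @param train_idx Canonical indices of the training rows (default: all
#'   reactions with an available high-level barrier).
#' @return List with `X` (full feature matrix, rows in canonical order), `y`
#'   (high-level barriers, `NA` where unavailable) and `train_idx`.
#' @export
assemble_features <- function(table, use_low_level = FALSE, train_idx = NULL) {
  stopifnot(inherits(table, "barrier_table"))
  if (is.null(train_idx)) train_idx <- which(!is.na(table$high_level))
  X <- encode_space(table$space, table$scheme)
  if (use_low_level) {
    if (anyNA(table$low_level)) {
      stop("low_level has missing entries; run impute_low_level() first",
           call. = FALSE)
    }
    X <- cbind(X, low_level = scale_by_train(table$low_level, train_idx))
  }
  list(X = X, y = table$high_level, train_idx = train_idx)
}

# center/scale a column by training-row statistics (sd guard for constants)
scale_by_train <- function(x, train_idx) {
  m <- mean(x[train_idx])
  s <- stats::sd(x[train_idx])
  if (!is.finite(s) || s < 1e-12) s <- 1
  (x - m) / s
}
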
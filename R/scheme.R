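#' Define a combinatorial R-group scheme
#'
#' An R-group scheme describes a reaction space built from a fixed core plus
#' interchangeable functional groups: an ordered set of substitution
#' positions, the ordered list of group labels allowed at each position, and
#' optional symmetry permutations of the positions under which a reaction is
#' chemically unchanged (e.g. two ligand sites that can be swapped).
#'
#' Symmetries are declared explicitly as position permutations rather than
#' inferred from chemistry, which keeps the scheme structure-agnostic. The
#' permutations supplied are treated as generators; the full group is their
#' closure under composition (the identity is always included).
#'
#' @param options Named list. Names are position labels in order (e.g.
#'   `R1`..`R4`, `X`, `Y`); each element is a character vector of allowed
#'   functional-group labels for that position (non-empty, no duplicates).
#' @param symmetries List of permutations. Each permutation is a named
#'   character vector mapping source positions to destination positions;
#'   positions not mentioned are fixed. Every mapped pair of positions must
#'   have identical option lists.
#' @return An object of class `rgroup_scheme` with elements `positions`,
#'   `options`, `generators` and `group` (the closed symmetry group as a list
#'   of integer permutations of the positions, identity first).
#' @examples
#' # E2/SN2-style space: 4 substituent positions, a leaving group and a
#' # nucleophile, with the simultaneous (R1,R2)<->(R3,R4) exchange
#' sub <- paste0("g", 1:5)
#' sch <- rgroup_scheme(
#'   options = list(R1 = sub, R2 = sub, R3 = sub, R4 = sub,
#'                  X = paste0("x", 1:3), Y = paste0("y", 1:4)),
#'   symmetries = list(c(R1 = "R3", R2 = "R4", R3 = "R1", R4 = "R2"))
#' )
#' space_size(sch)  # 3900
#' @export
rgroup_scheme <- function(options, symmetries = list()) {
  if (!is.list(options) || length(options) == 0L || is.null(names(options)) ||
      any(!nzchar(names(options)))) {
    stop("`options` must be a non-empty named list (one element per position)",
         call. = FALSE)
  }
  positions <- names(options)
  if (anyDuplicated(positions)) {
    stop("duplicate position labels: ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "),
         call. = FALSE)
  }
  for (p in positions) {
    opt <- options[[p]]
    if (!is.character(opt) || length(opt) == 0L) {
      stop("option list for position '", p,
           "' must be a non-empty character vector", call. = FALSE)
    }
    if (anyDuplicated(opt)) {
      stop("duplicate option label '", opt[duplicated(opt)][1L],
           "' at position '", p, "'", call. = FALSE)
    }
  }

  generators <- lapply(symmetries, function(s) as_perm(s, positions, options))
  group <- close_group(generators, length(positions))

  structure(
    list(positions = positions, options = options,
         generators = generators, group = group),
    class = "rgroup_scheme"
  )
}

# named character map -> integer permutation (perm[i] = image of position i)
as_perm <- function(sym, positions, options) {
  if (is.null(names(sym)) || !is.character(sym)) {
    stop("each symmetry must be a named character vector mapping positions ",
         "to positions", call. = FALSE)
  }
  bad <- setdiff(c(names(sym), unname(sym)), positions)
  if (length(bad)) {
    stop("unknown position label in symmetry: '", bad[1L], "'", call. = FALSE)
  }
  perm <- seq_along(positions)
  names(perm) <- positions
  perm[names(sym)] <- match(unname(sym), positions)
  if (anyDuplicated(perm)) {
    stop("symmetry is not a permutation of positions", call. = FALSE)
  }
  for (i in seq_along(positions)) {
    if (!identical(options[[i]], options[[perm[i]]])) {
      stop("symmetry maps position '", positions[i], "' to '",
           positions[perm[i]], "', which has a different option list",
           call. = FALSE)
    }
  }
  unname(perm)
}

# closure of generators under composition; identity always present
close_group <- function(generators, n) {
  id <- seq_len(n)
  elems <- list(id)
  keys <- paste(id, collapse = ",")
  queue <- generators
  while (length(queue)) {
    g <- queue[[1L]]
    queue <- queue[-1L]
    key <- paste(g, collapse = ",")
    if (key %in% keys) next
    elems <- c(elems, list(g))
    keys <- c(keys, key)
    for (h in elems) {
      queue <- c(queue, list(g[h]), list(h[g]))
    }
  }
  elems
}

#' @export
print.rgroup_scheme <- function(x, ...) {
  cat("R-group scheme:", length(x$positions), "positions, option counts (",
      paste(lengths(x$options), collapse = ", "), "), ",
      length(x$group), "symmetry element(s)\n")
  cat("Space size (canonical reactions):", space_size(x), "\n")
  invisible(x)
}

#' Number of symmetry-distinct reactions in a scheme
#'
#' Counted by Burnside's lemma: the orbit count is the mean, over the
#' symmetry group, of the number of assignments fixed by each permutation.
#'
#' @param scheme An [rgroup_scheme()].
#' @return Integer count of canonical reactions.
#' @export
space_size <- function(scheme) {
  stopifnot(inherits(scheme, "rgroup_scheme"))
  k <- lengths(scheme$options)
  fixed <- vapply(scheme$group, function(g) {
    # assignments fixed by g: one free choice per cycle of the permutation
    seen <- rep(FALSE, length(g))
    total <- 1
    for (i in seq_along(g)) {
      if (seen[i]) next
      j <- i
      while (!seen[j]) {
        seen[j] <- TRUE
        j <- g[j]
      }
      total <- total * k[i]
    }
    total
  }, numeric(1))
  count <- sum(fixed) / length(scheme$group)
  as.integer(round(count))
}

# ---- assignments ------------------------------------------------------------

# validate a label assignment, return integer codes (one per position)
assignment_codes <- function(assignment, scheme) {
  positions <- scheme$positions
  if (!is.null(names(assignment))) {
    bad <- setdiff(names(assignment), positions)
    if (length(bad)) {
      stop("unknown position label: '", bad[1L], "'", call. = FALSE)
    }
    if (!setequal(names(assignment), positions)) {
      stop("assignment must cover every position exactly once", call. = FALSE)
    }
    assignment <- assignment[positions]
  } else if (length(assignment) != length(positions)) {
    stop("assignment has ", length(assignment), " entries; scheme has ",
         length(positions), " positions", call. = FALSE)
  }
  codes <- integer(length(positions))
  for (i in seq_along(positions)) {
    codes[i] <- match(assignment[[i]], scheme$options[[i]])
    if (is.na(codes[i])) {
      stop("unknown option label '", assignment[[i]], "' at position '",
           positions[i], "'", call. = FALSE)
    }
  }
  codes
}

# apply permutation g to assignment codes a: the group acts by moving the
# group at position i to position g[i], so the new occupant of j is a[g^-1(j)]
apply_perm <- function(codes, g) {
  out <- codes
  out[g] <- codes
  out
}

canonical_codes <- function(codes, group) {
  best <- codes
  for (g in group[-1L]) {
    img <- apply_perm(codes, g)
    for (i in seq_along(img)) {
      if (img[i] < best[i]) {
        best <- img
        break
      }
      if (img[i] > best[i]) break
    }
  }
  best
}

#' Canonicalize a reaction under the scheme's symmetries
#'
#' Two assignments related by a scheme symmetry describe the same reaction.
#' The canonical representative of an orbit is, by package convention, the
#' lexicographically smallest assignment (positions compared in scheme order,
#' options in option-list order). The operation is idempotent and constant
#' on symmetry orbits.
#'
#' @param reaction Character vector of option labels, one per position (in
#'   scheme order, or named by position).
#' @param scheme An [rgroup_scheme()].
#' @return Named character vector: the canonical assignment.
#' @examples
#' sub <- letters[1:3]
#' sch <- rgroup_scheme(list(R3 = sub, R4 = sub),
#'                      symmetries = list(c(R3 = "R4", R4 = "R3")))
#' canonicalize(c("c", "a"), sch)  # -> a, c
#' @export
canonicalize <- function(reaction, scheme) {
  stopifnot(inherits(scheme, "rgroup_scheme"))
  codes <- assignment_codes(reaction, scheme)
  best <- canonical_codes(codes, scheme$group)
  out <- vapply(seq_along(best),
                function(i) scheme$options[[i]][best[i]], character(1))
  names(out) <- scheme$positions
  out
}

#' Enumerate all symmetry-distinct reactions of a scheme
#'
#' Generates every ordered assignment of options to positions, keeps exactly
#' one canonical representative per symmetry orbit, and returns them in
#' deterministic lexicographic order (first position most significant).
#' The row number of a reaction is its stable canonical index, used
#' throughout the package to identify reactions.
#'
#' @param scheme An [rgroup_scheme()].
#' @return A data.frame with one character column per position and attribute
#'   `scheme`; row `i` is the reaction with canonical index `i`.
#' @export
enumerate_space <- function(scheme) {
  stopifnot(inherits(scheme, "rgroup_scheme"))
  k <- lengths(scheme$options)
  P <- length(k)
  total <- prod(k)
  if (total > 5e6) {
    stop("scheme has ", total, " ordered assignments; too large to enumerate",
         call. = FALSE)
  }
  # code matrix in lexicographic order: first position most significant
  grid <- expand.grid(rev(lapply(k, seq_len)), KEEP.OUT.ATTRS = FALSE)
  codes <- as.matrix(grid[, rev(seq_len(P)), drop = FALSE])
  colnames(codes) <- scheme$positions

  keep <- rep(TRUE, nrow(codes))
  for (g in scheme$group[-1L]) {
    img <- codes
    img[, g] <- codes  # group at position i moves to position g[i]
    # keep rows that are <= their image lexicographically
    lt <- rep(FALSE, nrow(codes))  # image strictly smaller so far
    undec <- rep(TRUE, nrow(codes))
    for (j in seq_len(P)) {
      smaller <- undec & (img[, j] < codes[, j])
      larger <- undec & (img[, j] > codes[, j])
      lt <- lt | smaller
      undec <- undec & !smaller & !larger
    }
    keep <- keep & !lt
  }
  codes <- codes[keep, , drop = FALSE]

  out <- as.data.frame(lapply(seq_len(P), function(i) {
    scheme$options[[i]][codes[, i]]
  }), stringsAsFactors = FALSE)
  names(out) <- scheme$positions
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  out
}

# integer code matrix for an enumerated space (rows = canonical index)
space_codes <- function(space, scheme) {
  m <- vapply(seq_along(scheme$positions), function(i) {
    match(space[[i]], scheme$options[[i]])
  }, integer(nrow(space)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(space))
  colnames(m) <- scheme$positions
  m
}

# canonical index of assignment codes within an enumerated space
lookup_index <- function(codes, scheme, space_key) {
  canon <- canonical_codes(codes, scheme$group)
  match(paste(canon, collapse = "\r"), space_key)
}

space_keys <- function(codes_matrix) {
  apply(codes_matrix, 1L, paste, collapse = "\r")
}

# ---- encoding ---------------------------------------------------------------

#' One-hot encode a reaction
#'
#' Each position contributes a block of indicator bits, one per allowed
#' option (1 marks the occupying group, 0 absence); blocks are concatenated
#' in scheme position order. Optionally a low-level (cheap, approximate)
#' activation barrier is appended as one extra numeric feature.
#'
#' Only canonical reactions may be encoded, so that symmetry-equivalent
#' assignments share a single representation.
#'
#' @param reaction Character vector of option labels (one per position).
#' @param scheme An [rgroup_scheme()].
#' @param low_level Optional scalar: low-level barrier in kcal/mol.
#' @return Numeric feature vector of length `sum(lengths(scheme$options))`,
#'   plus 1 if `low_level` is given.
#' @export
one_hot_encode <- function(reaction, scheme, low_level = NULL) {
  stopifnot(inherits(scheme, "rgroup_scheme"))
  codes <- assignment_codes(reaction, scheme)
  if (!identical(codes, canonical_codes(codes, scheme$group))) {
    stop("reaction is not in canonical form; call canonicalize() first",
         call. = FALSE)
  }
  k <- lengths(scheme$options)
  bits <- numeric(sum(k))
  off <- c(0L, cumsum(k))
  bits[off[seq_along(k)] + codes] <- 1
  names(bits) <- unlist(lapply(seq_along(k), function(i) {
    paste0(scheme$positions[i], ".", scheme$options[[i]])
  }), use.names = FALSE)
  if (!is.null(low_level)) {
    stopifnot(is.numeric(low_level), length(low_level) == 1L)
    bits <- c(bits, low_level = as.numeric(low_level))
  }
  bits
}

# one-hot bit matrix for all rows of an enumerated space
encode_space <- function(space, scheme) {
  codes <- space_codes(space, scheme)
  k <- lengths(scheme$options)
  off <- c(0L, cumsum(k))
  n <- nrow(codes)
  X <- matrix(0, n, sum(k))
  for (i in seq_along(k)) {
    X[cbind(seq_len(n), off[i] + codes[, i])] <- 1
  }
  colnames(X) <- unlist(lapply(seq_along(k), function(i) {
    paste0(scheme$positions[i], ".", scheme$options[[i]])
  }), use.names = FALSE)
  X
}

# canonical indices of all single-position substitutions of reaction `idx`
# (self and duplicates removed); `codes_mat`/`key` from the enumerated space
neighbor_indices <- function(idx, scheme, codes_mat, key) {
  codes <- codes_mat[idx, ]
  out <- integer(0)
  for (p in seq_along(scheme$positions)) {
    kp <- length(scheme$options[[p]])
    for (o in seq_len(kp)) {
      if (o == codes[p]) next
      cand <- codes
      cand[p] <- o
      j <- lookup_index(cand, scheme, key)
      out <- c(out, j)
    }
  }
  setdiff(unique(out), idx)
}

# ---- config i/o -------------------------------------------------------------

#' Read or write an R-group scheme as a YAML config
#'
#' The config has keys `positions` (ordered labels), `options` (map from
#' position to label list) and optional `symmetries` (list of maps from
#' source position to destination position).
#'
#' @param path File path.
#' @return `read_scheme()` returns an [rgroup_scheme()];
#'   `write_scheme()` returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) {
    stop("scheme config not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$options)) stop("scheme config lacks `options`", call. = FALSE)
  opts <- lapply(cfg$options, function(x) as.character(unlist(x)))
  if (!is.null(cfg$positions)) {
    pos <- as.character(unlist(cfg$positions))
    bad <- setdiff(pos, names(opts))
    if (length(bad)) {
      stop("position '", bad[1L], "' listed but has no option list",
           call. = FALSE)
    }
    opts <- opts[pos]
  }
  syms <- lapply(cfg$symmetries, function(s) {
    v <- vapply(s, function(x) as.character(x)[1L], character(1))
    v
  })
  rgroup_scheme(opts, symmetries = syms)
}

#' @rdname read_scheme
#' @param scheme An [rgroup_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "rgroup_scheme"))
  syms <- lapply(scheme$generators, function(g) {
    moved <- which(g != seq_along(g))
    as.list(stats::setNames(scheme$positions[g[moved]],
                            scheme$positions[moved]))
  })
  cfg <- list(positions = as.list(scheme$positions),
              options = lapply(scheme$options, as.list))
  if (length(syms)) cfg$symmetries <- syms
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export an enumerated space as CSV
#'
#' Writes one row per canonical reaction: a `canonical_index` column followed
#' by one column per position.
#'
#' @param space Result of [enumerate_space()].
#' @param path Output file path.
#' @export
write_space_csv <- function(space, path) {
  out <- cbind(canonical_index = seq_len(nrow(space)),
               as.data.frame(space))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
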
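#' Specify a synthetic barrier landscape
#'
#' A landscape assigns every canonical reaction of a scheme a high-level
#' barrier built from an additive model over the occupying functional
#' groups, optionally a few sparse pairwise interactions, and Gaussian
#' noise:
#'
#'   barrier = base + sum(position effects) + sum(interactions) + N(0, sd)
#'
#' A correlated low-level barrier is generated as the high-level barrier
#' plus independent Gaussian noise scaled so that the population Pearson
#' correlation between the two fidelities equals `low_level_correlation`
#' (mimicking a cheap level of theory that tracks the expensive one).
#' High-level entries are then masked missing to emulate calculation
#' failures. Effects are computed on canonical assignments, so
#' symmetry-equivalent reactions receive identical barriers by construction.
#'
#' @param scheme An [rgroup_scheme()].
#' @param base_barrier Baseline barrier, kcal/mol (default 15).
#' @param position_effects Per-position numeric vectors of per-option
#'   additive contributions (kcal/mol), or `NULL` to draw them i.i.d.
#'   N(0, `effect_sd`) from the spec seed.
#' @param effect_sd Spread of drawn position effects, kcal/mol (default 1.5).
#' @param interactions Either a list of
#'   `list(positions = c(i, j), options = c(oi, oj), delta)` entries (a
#'   contribution added when position `i` holds its option `oi` and `j`
#'   holds `oj`), or an integer count of random interactions to draw with
#'   spread `interaction_sd`.
#' @param interaction_sd Spread of drawn interaction contributions
#'   (default 0.5).
#' @param noise_sd Barrier noise, kcal/mol (default 0.3).
#' @param low_level_correlation Target Pearson correlation between low- and
#'   high-level barriers, in (0, 1].
#' @param missing_rate Probability that a high-level barrier is missing, in
#'   \[0, 1).
#' @param missing_model `"uniform"` (missingness independent of the barrier)
#'   or `"barrier"` (logistic in the standardized barrier, so failures
#'   concentrate at high barriers).
#' @param low_missing_rate Probability that a low-level barrier is missing
#'   (default 0; use with [impute_low_level()]).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   tables.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(scheme, base_barrier = 15,
                           position_effects = NULL, effect_sd = 1.5,
                           interactions = 0L, interaction_sd = 0.5,
                           noise_sd = 0.3, low_level_correlation = 0.9,
                           missing_rate = 0, missing_model = "uniform",
                           low_missing_rate = 0, seed = 1L) {
  stopifnot(inherits(scheme, "rgroup_scheme"))
  if (low_level_correlation <= 0 || low_level_correlation > 1) {
    stop("`low_level_correlation` must be in (0, 1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  if (low_missing_rate < 0 || low_missing_rate >= 1) {
    stop("`low_missing_rate` must be in [0, 1)", call. = FALSE)
  }
  missing_model <- match.arg(missing_model, c("uniform", "barrier"))
  if (!is.null(position_effects)) {
    stopifnot(identical(names(position_effects), scheme$positions),
              all(lengths(position_effects) == lengths(scheme$options)))
  }
  structure(
    list(scheme = scheme, base_barrier = base_barrier,
         position_effects = position_effects, effect_sd = effect_sd,
         interactions = interactions, interaction_sd = interaction_sd,
         noise_sd = noise_sd, low_level_correlation = low_level_correlation,
         missing_rate = missing_rate, missing_model = missing_model,
         low_missing_rate = low_missing_rate, seed = as.integer(seed)),
    class = "landscape_spec"
  )
}

#' Generate a synthetic barrier landscape
#'
#' Realizes a [landscape_spec()]: enumerates the space, draws or applies the
#' additive effects and interactions, adds noise, derives the correlated
#' low-level barriers, and masks high-level entries missing. The unmasked
#' ground truth is returned alongside the table for assertions and oracles.
#'
#' @param spec A [landscape_spec()].
#' @return A list of class `landscape` with elements `table` (a
#'   [barrier_table()] with masked high-level entries), `spec`, and `truth`:
#'   the pre-masking `high` and `low` barriers, the realized
#'   `position_effects` and `interactions`, and the low-level noise sd used.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  scheme <- spec$scheme
  set.seed(spec$seed)
  space <- enumerate_space(scheme)
  codes <- space_codes(space, scheme)
  N <- nrow(space)
  k <- lengths(scheme$options)
  P <- length(k)

  effects <- spec$position_effects
  if (is.null(effects)) {
    effects <- lapply(seq_len(P), function(i) stats::rnorm(k[i], 0, spec$effect_sd))
    names(effects) <- scheme$positions
  }
  high <- rep(spec$base_barrier, N)
  for (i in seq_len(P)) {
    high <- high + effects[[i]][codes[, i]]
  }

  inter <- spec$interactions
  if (is.numeric(inter) && length(inter) == 1L) {
    n_int <- as.integer(inter)
    inter <- list()
    if (n_int > 0L && P > 1L) {
      for (q in seq_len(n_int)) {
        pq <- sort(resample(seq_len(P), 2L))
        inter[[q]] <- list(
          positions = pq,
          options = c(resample(seq_len(k[pq[1L]]), 1L),
                      resample(seq_len(k[pq[2L]]), 1L)),
          delta = stats::rnorm(1, 0, spec$interaction_sd))
      }
    }
  }
  for (it in inter) {
    hit <- codes[, it$positions[1L]] == it$options[1L] &
      codes[, it$positions[2L]] == it$options[2L]
    high[hit] <- high[hit] + it$delta
  }
  if (spec$noise_sd > 0) high <- high + stats::rnorm(N, 0, spec$noise_sd)

  r <- spec$low_level_correlation
  low_noise_sd <- if (r < 1) stats::sd(high) * sqrt(1 / r^2 - 1) else 0
  low <- high + if (low_noise_sd > 0) stats::rnorm(N, 0, low_noise_sd) else 0

  miss_hi <- if (spec$missing_rate > 0) {
    if (spec$missing_model == "uniform") {
      stats::runif(N) < spec$missing_rate
    } else {
      z <- as.numeric(scale(high))
      stats::runif(N) < stats::plogis(stats::qlogis(spec$missing_rate) + z)
    }
  } else {
    rep(FALSE, N)
  }
  miss_lo <- if (spec$low_missing_rate > 0) {
    stats::runif(N) < spec$low_missing_rate
  } else {
    rep(FALSE, N)
  }

  table <- barrier_table(scheme, replace(high, miss_hi, NA_real_),
                         low = replace(low, miss_lo, NA_real_), space = space)
  structure(
    list(table = table, spec = spec,
         truth = list(high = high, low = low, position_effects = effects,
                      interactions = inter, low_noise_sd = low_noise_sd)),
    class = "landscape"
  )
}

#' Preset synthetic landscapes mirroring the study data sets
#'
#' Four named [landscape_spec()]s whose space sizes, symmetry types,
#' missingness rates and low/high-level correlation strengths mirror the
#' four activation-barrier data sets the search was evaluated on:
#'
#' * `MA` — aza-Michael-addition-like: 1000 reactions (three positions with
#'   ten options each, no symmetry), fully converged, moderate correlation.
#' * `H2` — dihydrogen-activation-like (Vaska-type catalyst): 2574 reactions
#'   (positions with 3 and 13 options plus an interchangeable ligand pair
#'   with 11 options each), 24.4% missing, very strong correlation, short
#'   barrier range.
#' * `SN2` — 3900 reactions (four substituent positions with five options
#'   under the simultaneous pair-swap symmetry, three leaving groups, four
#'   nucleophiles), 55.9% missing, moderate correlation.
#' * `E2` — same scheme shape as `SN2`, 74.4% missing, moderate correlation.
#'
#' Option labels, effect values and the correlation coefficients are
#' synthetic placeholders (the real per-dataset correlations are not
#' published as numbers); sizes, symmetries and missingness rates are the
#' documented dataset properties.
#'
#' @return Named list of four `landscape_spec` objects.
#' @export
preset_landscapes <- function() {
  sub10 <- sprintf("g%02d", 1:10)
  ma_scheme <- rgroup_scheme(list(R1 = sub10, R2 = sub10, R3 = sub10))

  lig11 <- sprintf("L%02d", 1:11)
  h2_scheme <- rgroup_scheme(
    list(R1 = sprintf("a%d", 1:3), R2 = sprintf("b%02d", 1:13),
         R3 = lig11, R4 = lig11),
    symmetries = list(c(R3 = "R4", R4 = "R3"))
  )

  sub5 <- paste0("g", 1:5)
  e2_scheme <- rgroup_scheme(
    list(R1 = sub5, R2 = sub5, R3 = sub5, R4 = sub5,
         X = paste0("x", 1:3), Y = paste0("y", 1:4)),
    symmetries = list(c(R1 = "R3", R2 = "R4", R3 = "R1", R4 = "R2"))
  )

  list(
    MA = landscape_spec(ma_scheme, base_barrier = 15, effect_sd = 2.0,
                        interactions = 5L, noise_sd = 0.3,
                        low_level_correlation = 0.85, missing_rate = 0,
                        seed = 2301L),
    H2 = landscape_spec(h2_scheme, base_barrier = 10, effect_sd = 1.0,
                        interactions = 5L, noise_sd = 0.3,
                        low_level_correlation = 0.97, missing_rate = 0.244,
                        seed = 2302L),
    SN2 = landscape_spec(e2_scheme, base_barrier = 20, effect_sd = 1.5,
                         interactions = 5L, noise_sd = 0.3,
                         low_level_correlation = 0.85, missing_rate = 0.559,
                         seed = 2303L),
    E2 = landscape_spec(e2_scheme, base_barrier = 25, effect_sd = 1.5,
                        interactions = 5L, noise_sd = 0.3,
                        low_level_correlation = 0.85, missing_rate = 0.744,
                        seed = 2304L)
  )
}
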
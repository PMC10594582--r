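# search algorithms: counting semantics, termination, determinism, behavior

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

test_that("a satisficing initial sample stops before any model is trained", {
  sch <- tiny_scheme()
  tab <- barrier_table(sch, rep(10, 8))  # every reaction satisfices
  res <- ml_search(tab, search_config(target = 10, seed = 3))
  expect_true(res$success)
  expect_identical(res$n_measurements, 5L)
  expect_identical(unique(res$trajectory$phase), "initial")
})

test_that("search_config validates its invariants", {
  expect_error(search_config(target = 5, tolerance = 0), "tolerance")
  expect_error(search_config(target = 5, initial_sample_size = 0),
               "initial_sample_size")
  expect_error(search_config(target = 5, max_measurements = 3,
                             initial_sample_size = 5), "max_measurements")
})

test_that("random search mean matches the sampling-without-replacement law", {
  # N = 4: two failed, two available, one satisficing; the measurement count
  # is the position of the satisficing reaction in the sampling order, so
  # the exact mean is the brute-force average over all 4! orderings
  sch <- rgroup_scheme(list(P = paste0("o", 1:4)))
  tab <- barrier_table(sch, c(NA, 5, NA, 50))
  sat <- 2L
  brute <- mean(vapply(all_permutations(4L),
                       function(p) which(p == sat), numeric(1)))
  expect_equal(brute, 2.5)
  ns <- vapply(1:4000, function(s) {
    random_search(tab, search_config(target = 5, seed = s))$n_measurements
  }, integer(1))
  se <- sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - brute), 3 * se + 1e-9)
})

test_that("every algorithm terminates, never remeasures, and is seed-deterministic", {
  land <- tiny_landscape(missing_rate = 0.25, r = 0.9, seed = 13)
  tab <- land$table
  runners <- list(ml = ml_search, random = random_search,
                  local = local_search, guided_local = guided_local_search,
                  bayesopt = bayesian_opt_search, genetic = genetic_search)
  # unattainable target: all runs must exhaust the space and report censoring
  cfg_far <- search_config(target = 1e3, seed = 5, use_low_level = TRUE,
                           initial_sample_size = 3)
  for (nm in names(runners)) {
    res <- runners[[nm]](tab, cfg_far)
    expect_false(res$success)
    expect_identical(res$n_measurements, nrow(tab$space))
    expect_false(anyDuplicated(res$trajectory$index) > 0)
    expect_identical(res$n_measurements, nrow(res$trajectory))

    # identical seed + config + table -> identical trajectory
    cfg <- search_config(target = median(land$truth$high), seed = 11,
                         use_low_level = TRUE, initial_sample_size = 3)
    r1 <- runners[[nm]](tab, cfg)
    r2 <- runners[[nm]](tab, cfg)
    expect_identical(r1$trajectory, r2$trajectory)
  }
})

test_that("failed measurements are counted and permanently discarded", {
  land <- tiny_landscape(scheme = rgroup_scheme(
    list(A = paste0("a", 1:4), B = paste0("b", 1:4))),
    missing_rate = 0.4, seed = 17, r = 0.9)
  tab <- land$table
  t <- land$truth$high[which(is.na(tab$high_level))[1]]  # only missing nearby
  cfg <- search_config(target = 1e3, seed = 2, use_low_level = TRUE)
  res <- ml_search(tab, cfg)
  n_failed <- sum(is.na(res$trajectory$barrier))
  expect_identical(n_failed, sum(is.na(tab$high_level)))
  expect_identical(res$n_measurements, nrow(tab$space))
})

test_that("ml_search finds a unique extreme barrier on a complete tiny space", {
  land <- tiny_landscape(seed = 23)
  tab <- land$table
  target <- max(tab$high_level)
  # verify the satisficing set is reachable, then search
  expect_gte(sum(abs(tab$high_level - target) <= 1), 1)
  for (s in 1:10) {
    res <- ml_search(tab, search_config(target = target, seed = s,
                                        initial_sample_size = 2))
    expect_true(res$success)
    expect_lte(res$n_measurements, 8L)
    expect_lte(abs(res$found_barrier - target), 1)
  }
})

test_that("a provided warm start is the first, counted measurement", {
  land <- tiny_landscape(seed = 29)
  tab <- land$table
  cfg <- search_config(target = min(tab$high_level), seed = 4,
                       warm_start = list(index = 3L, barrier = 99))
  res <- ml_search(tab, cfg)
  expect_identical(res$trajectory$index[1], 3L)
  expect_identical(res$trajectory$barrier[1], 99)
  expect_identical(res$trajectory$phase[1], "warm_start")
  # warm start counts toward the initial sample of 5
  expect_identical(sum(res$trajectory$phase %in% c("warm_start", "initial")),
                   5L)
})

test_that("one-substitution neighborhoods have sum(k - 1) members", {
  sub <- paste0("g", 1:5)
  nosym <- rgroup_scheme(list(R1 = sub, R2 = sub, R3 = sub, R4 = sub,
                              X = paste0("x", 1:3), Y = paste0("y", 1:4)))
  sp <- enumerate_space(nosym)
  cm <- barriersearch:::space_codes(sp, nosym)
  key <- barriersearch:::space_keys(cm)
  nb <- barriersearch:::neighbor_indices(1L, nosym, cm, key)
  expect_length(nb, 21L)  # 4*4 + 2 + 3

  # with the pair-swap symmetry, merging can only shrink the neighborhood
  e2 <- e2_scheme()
  sp2 <- enumerate_space(e2)
  cm2 <- barriersearch:::space_codes(sp2, e2)
  key2 <- barriersearch:::space_keys(cm2)
  nb2 <- barriersearch:::neighbor_indices(1L, e2, cm2, key2)
  expect_lte(length(nb2), 21L)
})

test_that("on a single-position space local search behaves like random search", {
  sch <- rgroup_scheme(list(P = paste0("o", 1:12)))
  barriers <- seq(0, 44, by = 4)[1:12]
  tab <- barrier_table(sch, barriers)
  target <- barriers[6]  # exactly one barrier within 1 kcal/mol
  n_loc <- vapply(1:600, function(s) {
    local_search(tab, search_config(target = target, seed = s))$n_measurements
  }, integer(1))
  n_rnd <- vapply(1:600, function(s) {
    random_search(tab, search_config(target = target, seed = s))$n_measurements
  }, integer(1))
  expected <- (12 + 1) / (1 + 1)
  expect_lt(abs(mean(n_loc) - expected), 0.5)
  expect_lt(abs(mean(n_rnd) - expected), 0.5)
})

test_that("Bayesian optimization stays within 3x of ml_search on central targets", {
  sch <- rgroup_scheme(list(A = paste0("a", 1:6), B = paste0("b", 1:6),
                            C = paste0("c", 1:6)))
  land <- generate_landscape(landscape_spec(sch, noise_sd = 0,
                                            interactions = 0L,
                                            low_level_correlation = 1,
                                            effect_sd = 2, seed = 31))
  tab <- land$table
  target <- median(tab$high_level)
  n_ml <- n_bo <- numeric(25)
  for (s in 1:25) {
    cfg <- search_config(target = target, seed = s, use_low_level = TRUE)
    n_ml[s] <- ml_search(tab, cfg)$n_measurements
    n_bo[s] <- bayesian_opt_search(tab, cfg)$n_measurements
  }
  expect_lt(mean(n_bo), 3 * mean(n_ml))
  expect_lt(mean(n_ml), 3 * mean(n_bo))
})

test_that("genetic operators behave as documented", {
  expect_identical(barriersearch:::ga_crossover(c(1L, 2L, 3L, 4L),
                                                c(5L, 6L, 7L, 8L), 2L),
                   c(1L, 2L, 7L, 8L))
  # crossover of identical parents is the identity
  p <- c(2L, 3L, 1L)
  expect_identical(barriersearch:::ga_crossover(p, p, 1L), p)
  # degenerate configuration refused
  land <- tiny_landscape()
  expect_error(
    genetic_search(land$table,
                   search_config(target = 10, pop_size = 1,
                                 mutation_rate = 0)),
    "degenerate")
})

test_that("a live oracle callback is measured, counted and never re-asked", {
  land <- tiny_landscape(seed = 37)
  tab <- land$table
  calls <- integer(0)
  oracle <- function(i) {
    calls <<- c(calls, i)
    if (i %% 3 == 0) NA_real_ else land$truth$high[i]
  }
  res <- ml_search(tab, search_config(target = min(land$truth$high), seed = 8),
                   oracle = oracle)
  expect_identical(length(calls), res$n_measurements)
  expect_false(anyDuplicated(calls) > 0)
  expect_identical(calls, res$trajectory$index)
})
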
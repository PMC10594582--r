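# shared fixtures: small schemes and an independent brute-force orbit oracle

# the E2/SN2-style scheme: 5 substituent options at R1-R4, 3 leaving groups,
# 4 nucleophiles, simultaneous (R1,R2)<->(R3,R4) exchange
e2_scheme <- function() {
  sub <- paste0("g", 1:5)
  rgroup_scheme(
    list(R1 = sub, R2 = sub, R3 = sub, R4 = sub,
         X = paste0("x", 1:3), Y = paste0("y", 1:4)),
    symmetries = list(c(R1 = "R3", R2 = "R4", R3 = "R1", R4 = "R2"))
  )
}

# Vaska-style interchangeable pair
pair_scheme <- function(opts = letters[1:3]) {
  rgroup_scheme(list(R3 = opts, R4 = opts),
                symmetries = list(c(R3 = "R4", R4 = "R3")))
}

# tiny asymmetric scheme (2 x 2 x 2 = 8 reactions, no symmetry)
tiny_scheme <- function() {
  rgroup_scheme(list(A = c("p", "q"), B = c("p", "q"), C = c("p", "q")))
}

# brute-force symmetry orbit of a label assignment, independent of the
# package's group-closure and canonicalization code: BFS over the generator
# maps applied directly to label vectors
orbit_bruteforce <- function(labels, positions, generators) {
  apply_gen <- function(x, gen) {
    out <- x
    out[match(unname(gen), positions)] <- x[match(names(gen), positions)]
    out
  }
  seen <- list(labels)
  keys <- paste(labels, collapse = "|")
  queue <- list(labels)
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (gen in generators) {
      img <- apply_gen(cur, gen)
      key <- paste(img, collapse = "|")
      if (!key %in% keys) {
        seen <- c(seen, list(img))
        keys <- c(keys, key)
        queue <- c(queue, list(img))
      }
    }
  }
  seen
}

# lexicographic minimum of a list of label vectors, compared by the
# per-position option order of the scheme
orbit_min <- function(orbit, scheme) {
  codes <- t(vapply(orbit, function(x) {
    vapply(seq_along(x), function(i) match(x[i], scheme$options[[i]]),
           integer(1))
  }, integer(length(orbit[[1]]))))
  best <- do.call(order, as.data.frame(codes))[1]
  orbit[[best]]
}

# brute-force orbit count: enumerate all ordered assignments, dedup by
# orbit membership
count_orbits_bruteforce <- function(scheme) {
  grid <- expand.grid(scheme$options, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  gens <- lapply(scheme$generators, function(g) {
    moved <- which(g != seq_along(g))
    stats::setNames(scheme$positions[g[moved]], scheme$positions[moved])
  })
  keys <- character(0)
  n <- 0L
  for (r in seq_len(nrow(grid))) {
    x <- as.character(unlist(grid[r, ]))
    key <- paste(x, collapse = "|")
    if (key %in% keys) next
    orb <- orbit_bruteforce(x, scheme$positions, gens)
    keys <- c(keys, vapply(orb, paste, character(1), collapse = "|"))
    n <- n + 1L
  }
  n
}

# a small complete noiseless additive landscape for search tests
tiny_landscape <- function(scheme = tiny_scheme(), seed = 7L, noise = 0,
                           missing_rate = 0, r = 1) {
  generate_landscape(landscape_spec(
    scheme, base_barrier = 10, effect_sd = 2, interactions = 0L,
    noise_sd = noise, low_level_correlation = r,
    missing_rate = missing_rate, seed = seed))
}
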
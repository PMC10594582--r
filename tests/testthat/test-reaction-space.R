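# scheme definition, canonicalization, enumeration, one-hot encoding

test_that("scheme validation rejects malformed definitions", {
  expect_error(rgroup_scheme(list(R1 = character(0))), "non-empty")
  expect_error(rgroup_scheme(list(R1 = c("a", "a"))), "duplicate option")
  expect_error(
    rgroup_scheme(list(R1 = c("a"), R2 = c("a", "b")),
                  symmetries = list(c(R1 = "R2", R2 = "R1"))),
    "different option list")
  expect_error(
    rgroup_scheme(list(R1 = "a"), symmetries = list(c(R1 = "Rx"))),
    "Rx")
  expect_error(
    rgroup_scheme(list(R1 = c("a", "b"), R2 = c("a", "b")),
                  symmetries = list(c(R1 = "R2"))),
    "not a permutation")
})

test_that("canonicalize maps symmetry partners to one representative", {
  sch <- e2_scheme()
  a <- canonicalize(c("g2", "g1", "g1", "g3", "x1", "y2"), sch)
  b <- canonicalize(c("g1", "g3", "g2", "g1", "x1", "y2"), sch)
  expect_identical(a, b)

  # fully symmetric assignment is a fixed point
  fx <- c("g1", "g1", "g1", "g1", "x2", "y3")
  expect_identical(unname(canonicalize(fx, sch)), fx)

  # interchangeable pair orders its two slots
  ps <- pair_scheme()
  expect_identical(unname(canonicalize(c("c", "a"), ps)), c("a", "c"))

  expect_error(canonicalize(c("zz", "a"), ps), "zz")
})

test_that("canonicalize is idempotent and equals the brute-force orbit minimum", {
  schemes <- list(
    pair_scheme(),
    e2_scheme(),
    rgroup_scheme(
      list(R1 = c("a", "b", "c"), R2 = c("a", "b", "c"),
           R3 = c("a", "b", "c")),
      symmetries = list(c(R1 = "R2", R2 = "R1"), c(R2 = "R3", R3 = "R2")))
  )
  for (sch in schemes) {
    gens <- lapply(sch$generators, function(g) {
      moved <- which(g != seq_along(g))
      stats::setNames(sch$positions[g[moved]], sch$positions[moved])
    })
    set.seed(11)
    for (rep in 1:25) {
      labels <- vapply(sch$options, function(o) sample(o, 1), character(1))
      canon <- canonicalize(labels, sch)
      expect_identical(canonicalize(canon, sch), canon)  # idempotent
      orbit <- orbit_bruteforce(unname(labels), sch$positions, gens)
      expect_identical(unname(canon),
                       orbit_min(orbit, sch))           # orbit minimum
      # constant on the orbit
      for (img in orbit) {
        expect_identical(unname(canonicalize(img, sch)), unname(canon))
      }
    }
  }
})

test_that("enumerate_space matches brute-force dedup and Burnside counting", {
  # no symmetry: n options at a single position
  one <- rgroup_scheme(list(P = letters[1:7]))
  expect_identical(nrow(enumerate_space(one)), 7L)

  # 2 interchangeable positions, 3 options: n(n+1)/2 = 6
  ps <- pair_scheme()
  sp <- enumerate_space(ps)
  expect_identical(nrow(sp), 6L)
  expect_identical(nrow(sp), count_orbits_bruteforce(ps))

  # assorted small schemes (< 1000 ordered assignments)
  small <- list(
    rgroup_scheme(list(R1 = letters[1:4], R2 = letters[1:4], X = c("u", "v")),
                  symmetries = list(c(R1 = "R2", R2 = "R1"))),
    rgroup_scheme(
      list(R1 = letters[1:3], R2 = letters[1:3], R3 = letters[1:3],
           R4 = letters[1:3]),
      symmetries = list(c(R1 = "R3", R2 = "R4", R3 = "R1", R4 = "R2"))),
    rgroup_scheme(list(A = letters[1:5], B = letters[1:6]))
  )
  for (sch in small) {
    sp <- enumerate_space(sch)
    expect_identical(nrow(sp), count_orbits_bruteforce(sch))
    expect_identical(nrow(sp), space_size(sch))
    # every row is canonical and unique
    canon <- apply(sp, 1, function(x) {
      paste(canonicalize(as.character(x), sch), collapse = "|")
    })
    expect_identical(canon, apply(sp, 1, paste, collapse = "|"))
    expect_false(anyDuplicated(canon) > 0)
  }
})

test_that("pair-swap Burnside formula holds: (n^4 + n^2)/2 times |X||Y|", {
  for (n in 2:4) {
    sub <- paste0("s", seq_len(n))
    sch <- rgroup_scheme(
      list(R1 = sub, R2 = sub, R3 = sub, R4 = sub,
           X = c("x1", "x2"), Y = c("y1", "y2", "y3")),
      symmetries = list(c(R1 = "R3", R2 = "R4", R3 = "R1", R4 = "R2")))
    expect_identical(space_size(sch), as.integer((n^4 + n^2) / 2 * 6))
  }
})

test_that("one-hot encoding has indicator blocks and is injective", {
  sch <- rgroup_scheme(list(P = c("A", "B", "C")))
  expect_equal(unname(one_hot_encode(c("B"), sch)), c(0, 1, 0))

  e2 <- e2_scheme()
  v <- one_hot_encode(canonicalize(c("g2", "g1", "g1", "g3", "x1", "y2"), e2),
                      e2)
  expect_length(v, 27L)  # 5+5+5+5+3+4
  v2 <- one_hot_encode(canonicalize(c("g2", "g1", "g1", "g3", "x1", "y2"), e2),
                       e2, low_level = 12.5)
  expect_length(v2, 28L)
  expect_equal(unname(v2[28]), 12.5)

  # non-canonical input refused (encoding must be orbit-unique)
  expect_error(one_hot_encode(c("g2", "g1", "g1", "g3", "x1", "y2"), e2),
               "canonical")

  # symmetry partners encode identically after canonicalization
  a <- one_hot_encode(canonicalize(c("g1", "g3", "g2", "g1", "x1", "y2"), e2), e2)
  expect_identical(a, v)

  # block structure and injectivity over a whole small space
  ps <- pair_scheme()
  sp <- enumerate_space(ps)
  X <- apply(sp, 1, function(x) one_hot_encode(as.character(x), ps))
  expect_false(anyDuplicated(t(X)) > 0)
  blocks <- rbind(colSums(X[1:3, , drop = FALSE]),
                  colSums(X[4:6, , drop = FALSE]))
  expect_true(all(blocks == 1))  # each block sums to exactly 1
})

test_that("scheme YAML round-trips and spaces export to CSV", {
  sch <- e2_scheme()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scheme(sch, path)
  sch2 <- read_scheme(path)
  expect_identical(sch2$positions, sch$positions)
  expect_identical(sch2$options, sch$options)
  expect_identical(length(sch2$group), length(sch$group))

  ps <- pair_scheme()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_space_csv(enumerate_space(ps), csv)
  out <- read.csv(csv)
  expect_identical(nrow(out), 6L)
  expect_identical(out$canonical_index, 1:6)
})
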
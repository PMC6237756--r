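test_that("simple state space matches exhaustive interval-set counts", {
  s2 <- enumerate_simple_states(2)
  expect_equal(s2$n, 5L)
  expect_setequal(s2$key, c("root", "(1,1)", "(2,2)", "(1,2)",
                            "(1,1)(2,2)"))
  expect_equal(s2$key[1L], "root")
  expect_equal(sum(s2$absorbing), 2L)

  s3 <- enumerate_simple_states(3)
  expect_equal(s3$n, 13L)
  expect_equal(sum(s3$absorbing), 4L)

  # absorbing states are the compositions of N: 2^(N-1)
  for (N in c(1, 4, 9))
    expect_equal(sum(enumerate_simple_states(N)$absorbing), 2L^(N - 1L))

  expect_error(enumerate_simple_states(10), "9 introns")
})

test_that("full state space encodes availability flags with frozen-site microstates", {
  s1 <- enumerate_full_states(1)
  expect_equal(s1$n, 5L)                  # 4 flag combinations + 1 absorbed
  expect_equal(sum(s1$absorbing), 1L)

  s2 <- enumerate_full_states(2)
  expect_equal(s2$n, 29L)
  expect_equal(sum(s2$absorbing), 5L)
  # the skip isoform (1,2) keeps the 4 flag combinations of its two unused
  # interior sites as distinct absorbing microstates (4^n for n skipped)
  skip_states <- vapply(s2$states, function(st)
    nrow(st$P) == 1L && all(st$P[1L, ] == c(1L, 2L)), logical(1L))
  expect_equal(sum(skip_states), 4L)
  include_states <- vapply(s2$states, function(st)
    nrow(st$P) == 2L, logical(1L))
  expect_equal(sum(include_states), 1L)

  expect_error(enumerate_full_states(4), "simple")
})

test_that("the chains are rooted DAGs: no edges into the root, none out of absorbing states", {
  for (space in list(enumerate_simple_states(3), enumerate_full_states(2))) {
    expect_false(1L %in% space$edges$to)               # root has no parents
    expect_false(any(space$edges$from %in% which(space$absorbing)))
    expect_true(all(space$edges$from != space$edges$to))
    # acyclic: every edge strictly increases (pairings, flags) progress
    prog <- function(s) if (space$model == "simple")
      nrow(s) else nrow(s$P) * 100L + sum(s$a5, s$a3)
    p <- vapply(space$states, prog, integer(1L))
    expect_true(all(p[space$edges$to] > p[space$edges$from]))
  }
})

test_that("generators conserve probability and honor phase gating", {
  g <- two_intron_gene()
  r <- splice_rates(2)
  space <- enumerate_full_states(2)
  G <- build_generator(space, g, r)
  expect_true(all(abs(rowSums(G)) < 1e-12))
  expect_true(all(G[upper.tri(G) | lower.tri(G)] >= 0))

  # phase with only 5'ss(1) synthesized: a single reaction from the root at
  # rate k5'(1)
  G1 <- build_generator(space, g, r, n5 = 1L, n3 = 0L)
  root_out <- G1[1L, -1L]
  expect_equal(sum(root_out > 0), 1L)
  expect_equal(sum(root_out), r$k5[1L])
  to <- which(root_out > 0) + 1L
  expect_equal(space$states[[to]]$a5, c(TRUE, FALSE))

  # with all sites synthesized, a state with a5[1], a3[2] available and no
  # pairings can do the skipping pairing at kp(1,2)
  idx <- which(vapply(space$states, function(st)
    nrow(st$P) == 0L && identical(st$a5, c(TRUE, FALSE)) &&
      identical(st$a3, c(FALSE, TRUE)), logical(1L)))
  expect_length(idx, 1L)
  skip_to <- which(vapply(space$states, function(st)
    nrow(st$P) == 1L && all(st$P[1L, ] == c(1L, 2L)) &&
      identical(st$a5, c(TRUE, FALSE)) && identical(st$a3, c(FALSE, TRUE)),
    logical(1L)))
  Gfull <- build_generator(space, g, r)
  expect_equal(Gfull[idx, skip_to], r$kp[1L, 2L])

  # simple engine: pairing (i, j) is gated on the synthesis of intron j
  ss <- enumerate_simple_states(2)
  Gp1 <- build_generator(ss, g, r, n3 = 1L, block = ss$n)
  enabled_from_root <- which(Gp1[1L, ] > 0)
  expect_equal(ss$key[enabled_from_root], "(1,1)")
})

test_that("interval-disjointness forbids pairings across an excised region", {
  ss <- enumerate_simple_states(3)
  e <- ss$edges
  # from state (2,2), the skipping pairing (1,3) would straddle the excised
  # intron 2 and must be absent
  from22 <- which(ss$key == "(2,2)")
  pairs_from <- e[e$from == from22, c("i", "j")]
  expect_false(any(pairs_from$i == 1 & pairs_from$j == 3))
  expect_setequal(paste(pairs_from$i, pairs_from$j),
                  c("1 1", "3 3"))
})
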
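test_that("apply_reversal reverses, negates, and is an involution", {
  expect_equal(apply_reversal(c(1, 2, 3, 4, 5), 3, 3), c(1, 2, -3, 4, 5))
  expect_equal(apply_reversal(c(1, 2, -3, 4, 5), 2, 4), c(1, -4, 3, -2, 5))
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    p <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
    i <- sample(n, 1); j <- i + sample.int(n - i + 1L, 1L) - 1L
    expect_equal(apply_reversal(apply_reversal(p, i, j), i, j), p)
  }
  expect_error(apply_reversal(1:3, 0, 2), "out of range")
  expect_error(apply_reversal(1:3, 2, 4), "out of range")
  expect_error(apply_reversal(c(1, 2, 2), 1, 1), "signed permutation")
  expect_error(apply_reversal(c(0, 1), 1, 1), "non-zero|unsigned")
})

test_that("breakpoint counting uses the framed signed extension", {
  expect_equal(breakpoint_count(c(1, -4, 3, -2, 5)), 4L)
  for (n in c(1, 3, 9)) expect_equal(breakpoint_count(seq_len(n)), 0L)
  expect_equal(breakpoint_count(c(-1)), 2L)
})

test_that("reversal distance matches the printed two-inversion instance and edge cases", {
  expect_equal(reversal_distance(1:5, c(1, -4, 3, -2, 5)), 2L)
  expect_equal(reversal_distance(c(1, -4, 3, -2, 5), 1:5), 2L)  # symmetric
  p <- c(3, -1, 2)
  expect_equal(reversal_distance(p, p), 0L)
  expect_equal(reversal_distance(1:3, c(-3, -2, -1)), 1L)
  expect_error(reversal_distance(1:3, 1:4), "same length|element")
})

test_that("distance obeys the breakpoint lower bound and trivial upper bounds", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(2:7, 1)
    p <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
    d <- reversal_distance(p)
    b <- breakpoint_count(p)
    expect_gte(d, ceiling(b / 2))
    expect_lte(d, n + 1L)
    expect_equal(reversal_distance(seq_len(n), p), d)
  }
})

test_that("hurdle corrections raise distance above the breakpoint and cycle bounds", {
  # (2, 1) is the classic unoriented component: 3 breakpoints would allow
  # d = 2 but the hurdle forces a third reversal
  expect_equal(reversal_distance(c(2, 1)), 3L)
  expect_equal(bfs_distance_oracle(c(2, 1)), 3L)
  expect_equal(reversal_distance(c(3, 2, 1)), bfs_distance_oracle(c(3, 2, 1)))
  # two separated hurdles
  p <- c(2, 1, 4, 3, 6, 5)
  expect_equal(reversal_distance(p), bfs_distance_oracle(p))
})

test_that("minimal scenario enumeration returns both orders of the nested inversions", {
  sc <- enumerate_minimal_scenarios(1:5, c(1, -4, 3, -2, 5))
  expect_length(sc, 2L)
  expect_scenario_setequal(sc, list(
    matrix(c(3L, 3L, 2L, 4L), ncol = 2, byrow = TRUE),
    matrix(c(2L, 4L, 3L, 3L), ncol = 2, byrow = TRUE)
  ))
  expect_false(attr(sc, "truncated"))
  expect_equal(attr(sc, "distance"), 2L)

  id <- enumerate_minimal_scenarios(c(2, -1, 3), c(2, -1, 3))
  expect_length(id, 1L)
  expect_equal(nrow(id[[1]]), 0L)

  one <- enumerate_minimal_scenarios(c(1, 2), c(-2, -1))
  expect_length(one, 1L)
  expect_equal(one[[1]], matrix(c(1L, 2L), ncol = 2,
                                dimnames = list(NULL, c("i", "j"))))
})

test_that("every enumerated scenario transforms source into target", {
  set.seed(5)
  for (rep in 1:15) {
    n <- sample(3:5, 1)
    src <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
    tgt <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
    d <- reversal_distance(src, tgt)
    sc <- enumerate_minimal_scenarios(src, tgt, max_count = 500L)
    if (attr(sc, "truncated")) next
    expect_gte(length(sc), 1L)
    for (steps in sc) {
      expect_equal(nrow(steps), d)
      cur <- src
      for (r in seq_len(nrow(steps)))
        cur <- apply_reversal(cur, steps[r, 1], steps[r, 2])
      expect_equal(cur, tgt)
    }
  }
})

test_that("scenario count is invariant under block relabeling", {
  set.seed(9)
  for (rep in 1:10) {
    n <- 5
    src <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
    tgt <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
    n1 <- length(enumerate_minimal_scenarios(src, tgt, max_count = 2000L))
    # relabel: apply a random signed renaming to both
    ren <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
    relab <- function(p) as.integer(sign(p) * sign(ren[abs(p)]) * abs(ren[abs(p)]))
    n2 <- length(enumerate_minimal_scenarios(relab(src), relab(tgt),
                                             max_count = 2000L))
    expect_equal(n1, n2)
  }
})

test_that("max_count truncates with a flag instead of an error", {
  sc <- enumerate_minimal_scenarios(c(-3, -2, -1, -4), 1:4, max_count = 1L)
  expect_length(sc, 1L)
  expect_true(attr(sc, "truncated"))
})

test_that("the BFS oracle agrees with the breakpoint-graph distance at small n", {
  # exhaustive n <= 4 here; the full n <= 5 sweep and random n in {6,7}
  # run in the acceptance suite
  for (n in 1:4) {
    for (p0 in combinat_perms(n)) for (s in sign_patterns(n)) {
      p <- as.integer(p0 * s)
      expect_equal(reversal_distance(p), bfs_distance_oracle(p))
    }
  }
  expect_equal(bfs_distance_oracle(c(1, -4, 3, -2, 5)), 2L)
  expect_error(bfs_distance_oracle(sample(9) * 1L), "n <= 8")
})

test_that("signed permutation files round-trip and reject unsigned input", {
  path <- withr::local_tempfile(fileext = ".txt")
  perms <- list(`species A X` = c(1L, 2L, 3L, 4L, 5L),
                `species B X1` = c(1L, -4L, 3L, -2L, 5L))
  write_signed_permutations(perms, path)
  got <- read_signed_permutations(path)
  expect_equal(got, perms)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">broken", "1 0 2"), bad)
  expect_error(read_signed_permutations(bad), "non-zero|unsigned")
})
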
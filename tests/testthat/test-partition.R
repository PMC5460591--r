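zsp_is_valid <- function(zsp, values) {
  idx <- sort(unlist(zsp$parts))
  identical(idx, seq_along(values)) &&
    all(vapply(zsp$parts, function(ix) sum(values[ix]) == 0, TRUE)) &&
    all(lengths(zsp$parts) >= 2L)
}

test_that("the dynamic program solves small frozen instances", {
  expect_equal(mzsp_dp(c(2, -2))$p, 1L)
  expect_equal(mzsp_dp(c(1, 1, -2, 3, -3))$p, 2L)
  expect_equal(mzsp_dp(c(1, 1, 1, -3))$p, 1L)
  expect_equal(mzsp_dp(numeric(0))$p, 0L)
  z <- mzsp_dp(c(1, 1, -2, 3, -3))
  expect_true(zsp_is_valid(z, c(1, 1, -2, 3, -3)))
  expect_error(mzsp_dp(c(1, 2)), "sum to zero")
  expect_error(mzsp_dp(c(1, 0, -1)), "nonzero")
  err <- tryCatch(mzsp_dp(rep(c(1, -1), 11L)), condition = identity)
  expect_s3_class(err, "wdcj_capacity_error")
  expect_match(conditionMessage(err), "mzsp_ilp")
})

test_that("brute force and ILP agree with the DP on frozen instances", {
  expect_equal(mzsp_bruteforce(c(2, -2))$p, 1L)
  expect_equal(mzsp_bruteforce(c(1, -1, 2, -2))$p, 2L)
  expect_equal(mzsp_bruteforce(c(1, 2, -3, 3, -2, -1))$p, 3L)
  expect_equal(mzsp_ilp(c(2, -2, 3, -3))$p, 2L)
  expect_equal(mzsp_ilp(c(1, 1, -2))$p, 1L)
  expect_equal(mzsp_ilp(numeric(0))$p, 0L)
  expect_s3_class(tryCatch(mzsp_bruteforce(rep(c(1, -1), 6L)),
                           condition = identity),
                  "wdcj_capacity_error")
})

test_that("the three solvers agree on random zero-sum multisets", {
  for (seed in 1:40) {
    vals <- random_zero_sum_multiset(size = sample(2:8, 1L), magnitude = 6,
                                     seed = seed)
    a <- mzsp_dp(vals)
    b <- mzsp_ilp(vals)
    cc <- mzsp_bruteforce(vals)
    expect_equal(a$p, cc$p)
    expect_equal(b$p, cc$p)
    expect_true(zsp_is_valid(a, vals))
    expect_true(zsp_is_valid(b, vals))
    expect_true(zsp_is_valid(cc, vals))
    expect_lte(a$p, length(vals) %/% 2L)   # two cycles per balanced part
    # symmetry breaking does not change the optimum
    expect_equal(mzsp_ilp(vals, symmetry_break = FALSE)$p, b$p)
  }
})

test_that("greedy pairing is optimal for opposite pairs", {
  gp <- greedy_pairs(c(2, -2, 2, -2, 3, -3))
  expect_length(gp$pairs, 3L)
  expect_length(gp$remainder, 0L)
  gp <- greedy_pairs(c(1, 1, -2))
  expect_length(gp$pairs, 0L)
  expect_equal(sort(gp$remainder), c(-2, 1, 1))
  gp <- greedy_pairs(c(5, -5, 5))
  expect_length(gp$pairs, 1L)
  expect_equal(gp$remainder, 5)
  for (seed in 41:60) {
    vals <- random_zero_sum_multiset(size = sample(3:9, 1L), magnitude = 4,
                                     seed = seed)
    gp <- greedy_pairs(vals)
    counted <- sum(vapply(sort(unique(vals[vals > 0])), function(v)
      min(sum(vals == v), sum(vals == -v)), 0))
    expect_length(gp$pairs, counted)
    expect_true(all(vapply(gp$pairs, function(ix) sum(vals[ix]) == 0, TRUE)))
    # remainder holds no value together with its opposite
    expect_false(any(gp$remainder %in% -gp$remainder))
  }
})

test_that("greedy triplets match the frozen traces and the 1/3 guarantee", {
  expect_length(greedy_triplets(c(1, 1, -2))$triplets, 1L)
  expect_length(greedy_triplets(c(1, 1, 1, -3))$triplets, 0L)
  expect_length(greedy_triplets(c(1, 5, -6, 2, 4, -6, 3, 3, -6))$triplets, 3L)
  # guarantee on exhaustive small multisets without opposite pairs
  pool <- c(-5, -4, -2, 1, 3)          # no value with its opposite
  for (size in 3:5) {
    for (vals in multisets_from(pool, size)) {
      gt <- greedy_triplets(vals)
      expect_true(all(vapply(gt$triplets, function(ix) sum(vals[ix]) == 0,
                             TRUE)))
      expect_gte(3L * length(gt$triplets), opt_triplet_count(vals))
    }
  }
})
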
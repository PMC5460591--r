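test_that("the chain step conserves W and is reproducible under a seed", {
  g <- genome(data.frame(u = c("1", "3", "5"), v = c("2", "4", "6"),
                         w = c(10, 5, 5)))
  a <- random_wdcj_step(g, seed = 11)
  b <- random_wdcj_step(g, seed = 11)
  expect_true(genomes_equal(a, b))
  expect_equal(total_weight(a), 20)
  g1 <- genome(data.frame(u = "1", v = "2", w = 5))
  expect_error(random_wdcj_step(g1), "n >= 2")
})

test_that("trajectories record n_u against the fixed start genome", {
  set.seed(3)
  start <- sample_equilibrium_genome(20, 2000)
  t0 <- simulate_trajectory(start, 0)
  expect_equal(nrow(t0), 1L)
  expect_equal(t0$n_u, 0L)
  expect_equal(t0$c, 20L)

  tr <- simulate_trajectory(start, 200, seed = 5)
  tr2 <- simulate_trajectory(start, 200, seed = 5)
  expect_identical(tr, tr2)
  expect_equal(nrow(tr), 201L)
  expect_true(all(tr$n_u <= 20L))
  expect_true(all(tr$c == tr$n_u + tr$n_b))
  expect_equal(tr$bound, tr$k / sqrt(20))
  # the first step always merges two trivial balanced cycles: n_u stays 0
  expect_equal(tr$n_u[2L], 0L)
})

test_that("equilibrium samples honour the exact total weight", {
  set.seed(9)
  for (i in 1:20) {
    g <- sample_equilibrium_genome(10, 99999)
    expect_equal(total_weight(g), 99999)
    expect_length(g$vertices, 20L)
  }
  g1 <- sample_equilibrium_genome(1, 77)
  expect_equal(g1$edges$w, 77)
})

test_that("the Dirichlet MLE recovers known concentrations", {
  rdirichlet <- function(n, alpha, d) {
    x <- matrix(rgamma(n * d, shape = alpha, scale = 1), nrow = n)
    x / rowSums(x)
  }
  set.seed(101)
  a2 <- fit_dirichlet_alpha(rdirichlet(2000, 2, 10))
  expect_gt(a2, 1.85)
  expect_lt(a2, 2.15)
  a5 <- fit_dirichlet_alpha(rdirichlet(2000, 5, 10))
  expect_gt(a5, 4.6)
  expect_lt(a5, 5.4)
  expect_warning(out <- fit_dirichlet_alpha(matrix(0.25, nrow = 5, ncol = 4)),
                 "diverges")
  expect_identical(out, Inf)
  expect_warning(fit_dirichlet_alpha(rbind(c(1, 0, 0), c(.4, .3, .3))),
                 "zero coordinates")
  expect_error(fit_dirichlet_alpha(rbind(c(0.5, 0.2))), "sum to 1")
})

test_that("detailed balance holds up under exact transition counting", {
  ga <- genome(data.frame(u = c("a", "c"), v = c("b", "d"), w = c(50, 50)))
  gb <- genome(data.frame(u = c("a", "b"), v = c("c", "d"), w = c(40, 60)))
  r1 <- stationarity_ratio_check(ga, gb)
  expect_gt(r1, 0.9)
  expect_lt(r1, 1.1)
  ga10 <- genome(data.frame(u = c("a", "c"), v = c("b", "d"), w = c(500, 500)))
  gb10 <- genome(data.frame(u = c("a", "b"), v = c("c", "d"), w = c(400, 600)))
  r10 <- stationarity_ratio_check(ga10, gb10)
  expect_lt(abs(r10 - 1), abs(r1 - 1))   # boundary effects vanish with scale
  expect_error(stationarity_ratio_check(ga, ga), "exactly one wDCJ")
  gz <- genome(data.frame(u = c("a", "b"), v = c("c", "d"), w = c(0, 100)))
  expect_error(stationarity_ratio_check(ga, gz), "positive")
})

test_that("a long chain visits positive-weight states as Pi ~ prod(w)", {
  # n = 2, W = 6: 3 matchings x 5 positive splits; compare empirical visit
  # frequencies (restricted to states with both weights positive) with the
  # product-of-weights law; total variation must shrink with chain length
  set.seed(42)
  labs <- c("1", "2", "3", "4")
  start <- genome(data.frame(u = c("1", "3"), v = c("2", "4"), w = c(3, 3)))
  idx <- wdcj:::.gen_index(start, labs)
  mate <- idx$mate; wv <- idx$w
  key <- function(mate, wv) {
    reps <- which(seq_along(mate) < mate)
    paste(sprintf("%d-%d:%d", reps, mate[reps], wv[reps]), collapse = ";")
  }
  run <- function(steps) {
    counts <- new.env(parent = emptyenv())
    m <- mate; w <- wv
    for (i in seq_len(steps)) {
      st <- wdcj:::.step_index(m, w)
      m <- st$mate; w <- st$w
      if (all(w > 0)) {
        k <- key(m, w)
        counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
      }
    }
    counts
  }
  # theoretical Pi over positive states: weight product w * (6 - w)
  mats <- list(c(2L, 1L, 4L, 3L), c(3L, 4L, 1L, 2L), c(4L, 3L, 2L, 1L))
  pi_keys <- character(0); pi_val <- numeric(0)
  for (m in mats) for (w in 1:5) {
    reps <- which(seq_along(m) < m)
    wvv <- numeric(4L); wvv[reps[1L]] <- w; wvv[m[reps[1L]]] <- w
    wvv[reps[2L]] <- 6 - w; wvv[m[reps[2L]]] <- 6 - w
    pi_keys <- c(pi_keys, key(m, wvv))
    pi_val <- c(pi_val, w * (6 - w))
  }
  pi_val <- pi_val / sum(pi_val)
  tv <- function(counts) {
    emp <- vapply(pi_keys, function(k)
      if (is.null(counts[[k]])) 0 else counts[[k]], 0)
    emp <- emp / sum(emp)
    sum(abs(emp - pi_val)) / 2
  }
  tv_short <- tv(run(4000))
  tv_long <- tv(run(60000))
  expect_lt(tv_long, 0.08)
  expect_lt(tv_long, tv_short + 0.02)
})
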
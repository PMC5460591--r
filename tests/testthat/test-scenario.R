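test_that("apply_wdcj rewrites exactly two adjacencies and conserves weight", {
  g <- genome(data.frame(u = c("1", "3"), v = c("2", "4"), w = c(3, 1)))
  op <- wdcj_op(c("1", "2"), c("3", "4"), c("1", "3"), c("2", "4"), 2, 2)
  g2 <- apply_wdcj(g, op)
  expect_equal(total_weight(g2), 4)
  expect_true(genomes_equal(g2, genome(data.frame(
    u = c("1", "2"), v = c("3", "4"), w = c(2, 2)))))
  op_bad <- wdcj_op(c("1", "2"), c("3", "4"), c("1", "3"), c("2", "4"), 4, 1)
  expect_error(apply_wdcj(g, op_bad), "conservation")
  op_missing <- wdcj_op(c("1", "3"), c("2", "4"), c("1", "2"), c("3", "4"), 2, 2)
  expect_error(apply_wdcj(g, op_missing), "not present")
  expect_error(wdcj_op(c("1", "2"), c("3", "4"), c("1", "2"), c("3", "4"),
                       -1, 5), "non-negative")
})

test_that("splitting a balanced cycle emits a balanced trivial cycle", {
  g1 <- genome(data.frame(u = c("a", "c"), v = c("b", "d"), w = c(3, 1)))
  g2 <- genome(data.frame(u = c("b", "d"), v = c("c", "a"), w = c(2, 2)))
  bg <- breakpoint_graph(genome_pair(g1, g2))
  expect_equal(bg$c, 1L)
  sp <- split_balanced_cycle(bg$cycles[[1L]])
  expect_equal(sp$trivial$length, 2L)
  expect_equal(sp$trivial$imbalance, 0)
  expect_equal(sp$rest$imbalance, 0)
  expect_equal(sp$op$w_join1 + sp$op$w_join2, 4)   # 3 + 1 - 2 = 2 on ad
  expect_setequal(c(sp$op$w_join1, sp$op$w_join2), c(2, 2))

  # all-zero weights: any triple qualifies, both products weigh zero
  z1 <- genome(data.frame(u = c("a", "c"), v = c("b", "d"), w = c(0, 0)))
  z2 <- genome(data.frame(u = c("b", "d"), v = c("c", "a"), w = c(0, 0)))
  bgz <- breakpoint_graph(genome_pair(z1, z2))
  spz <- split_balanced_cycle(bgz$cycles[[1L]])
  expect_equal(spz$op$w_join1, 0)
  expect_equal(spz$op$w_join2, 0)

  triv <- breakpoint_graph(genome_pair(g1, g1))$cycles[[1L]]
  expect_error(split_balanced_cycle(triv), "cannot be split")
  # unbalanced cycles are refused
  u2 <- genome(data.frame(u = c("b", "d"), v = c("c", "a"), w = c(1, 3)))
  bgu <- breakpoint_graph(genome_pair(g1, u2))
  if (bgu$cycles[[1L]]$imbalance != 0)
    expect_error(split_balanced_cycle(bgu$cycles[[1L]]), "balanced")
})

test_that("merging cycles adds imbalances; self-merge (freeze) is refused", {
  g1 <- genome(data.frame(u = c("1", "3"), v = c("2", "4"), w = c(3, 1)))
  h2 <- genome(data.frame(u = c("1", "3"), v = c("2", "4"), w = c(1, 3)))
  bg <- breakpoint_graph(genome_pair(g1, h2))
  expect_equal(bg$summary$imbalance, c(2, -2))
  op <- merge_cycles(bg$cycles[[1L]], bg$cycles[[2L]])
  merged <- apply_wdcj(g1, op)
  bg2 <- breakpoint_graph(genome_pair(merged, h2))
  expect_equal(bg2$c, 1L)
  expect_equal(bg2$summary$imbalance, 0)     # +2 and -2 cancel
  expect_error(merge_cycles(bg$cycles[[1L]], bg$cycles[[1L]]), "freeze")

  # same-sign imbalances simply add up: {+1, +1, -2}, merge the two +1s
  gg1 <- genome(data.frame(u = c("1", "3", "5"), v = c("2", "4", "6"),
                           w = c(3, 3, 0)))
  gg2 <- genome(data.frame(u = c("1", "3", "5"), v = c("2", "4", "6"),
                           w = c(2, 2, 2)))
  bgg <- breakpoint_graph(genome_pair(gg1, gg2))
  opg <- merge_cycles(bgg$cycles[[1L]], bgg$cycles[[2L]])
  mg <- apply_wdcj(gg1, opg)
  expect_setequal(breakpoint_graph(genome_pair(mg, gg2))$summary$imbalance,
                  c(2, -2))
})

test_that("scenarios replay to the target with the reported length", {
  g1 <- genome(data.frame(u = c("1", "3"), v = c("2", "4"), w = c(3, 1)))
  s0 <- sorting_scenario(genome_pair(g1, g1))
  expect_length(s0$steps, 0L)
  expect_true(validate_scenario(s0))

  for (seed in 1:20) {
    pair <- random_genome_pair(n = sample(2:7, 1L), max_weight = 8,
                               seed = seed)
    for (method in c("dp", "approx")) {
      plan <- wdcj_distance(pair, method)
      scn <- sorting_scenario(pair, plan = plan)
      expect_length(scn$steps, plan$distance)
      expect_true(validate_scenario(scn))
      kinds <- step_kinds(scn)
      expect_false(any(kinds == "freeze"))
      # merges strictly precede splits
      if (any(kinds == "merge") && any(kinds == "split"))
        expect_lt(max(which(kinds == "merge")), min(which(kinds == "split")))
      expect_equal(sum(kinds == "merge"), plan$m)
    }
  }
})

test_that("after the merge phase every prefix keeps all cycles balanced", {
  for (seed in c(3, 9, 14)) {
    pair <- random_genome_pair(n = 6, max_weight = 8, seed = seed)
    plan <- wdcj_distance(pair, "dp")
    scn <- sorting_scenario(pair, plan = plan)
    cur <- pair$g1
    for (i in seq_along(scn$steps)) {
      cur <- apply_wdcj(cur, scn$steps[[i]])
      if (i >= plan$m)   # split phase
        expect_equal(breakpoint_graph(genome_pair(cur, pair$g2))$n_u, 0L)
    }
  }
})

test_that("tampered scenarios are rejected by validation", {
  g1 <- genome(data.frame(u = c("1", "3"), v = c("2", "4"), w = c(3, 1)))
  h2 <- genome(data.frame(u = c("1", "3"), v = c("2", "4"), w = c(1, 3)))
  pair <- genome_pair(g1, h2)
  scn <- sorting_scenario(pair)
  expect_true(validate_scenario(scn))

  bad <- scn
  bad$steps[[1L]]$w_join1 <- bad$steps[[1L]]$w_join1 + 1
  v <- validate_scenario(bad)
  expect_false(isTRUE(v))
  expect_match(attr(v, "failure")$reason, "conservation")

  short <- scn
  short$steps <- short$steps[-length(short$steps)]
  v2 <- validate_scenario(short)
  expect_false(isTRUE(v2))
  expect_match(attr(v2, "failure")$reason, "mismatch")
})

test_that("operations round-trip through their text form", {
  op <- wdcj_op(c("1", "2"), c("3", "4"), c("1", "3"), c("2", "4"), 2, 2)
  line <- format_op(op, 3, 1)
  expect_match(line, "^CUT 1-2\\[3\\] 3-4\\[1\\] JOIN 1-3\\[2\\] 2-4\\[2\\]$")
  op2 <- parse_op(line)
  expect_equal(op2$join1, op$join1)
  expect_equal(op2$w_join2, op$w_join2)
  expect_error(parse_op("CUT nonsense"), "malformed")
})
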
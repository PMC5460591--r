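#' A single wDCJ operation
#'
#' Cuts edges `cut1` and `cut2` of the current genome and joins their four
#' extremities as `join1` and `join2`, reassigning the freed intergene
#' nucleotides: `w_join1 + w_join2` must equal the summed weights of the
#' cut edges.
#'
#' @param cut1,cut2,join1,join2 character vectors of length 2 (the edge
#'   endpoints).
#' @param w_join1,w_join2 non-negative integer weights of the new edges.
#' @return an object of class `wdcj_op`.
#' @export
wdcj_op <- function(cut1, cut2, join1, join2, w_join1, w_join2) {
  stopifnot(length(cut1) == 2L, length(cut2) == 2L,
            length(join1) == 2L, length(join2) == 2L)
  if (!setequal(c(cut1, cut2), c(join1, join2)) ||
      length(unique(c(cut1, cut2))) != 4L)
    stop_input("joins must re-pair exactly the four cut extremities")
  if (w_join1 < 0 || w_join2 < 0 ||
      w_join1 != floor(w_join1) || w_join2 != floor(w_join2))
    stop_input("join weights must be non-negative integers")
  structure(list(cut1 = cut1, cut2 = cut2, join1 = join1, join2 = join2,
                 w_join1 = w_join1, w_join2 = w_join2),
            class = "wdcj_op")
}

#' @export
print.wdcj_op <- function(x, ...) {
  cat(format_op(x), "\n")
  invisible(x)
}

#' Format / parse the one-line text form of a wDCJ operation
#'
#' `CUT u1-v1[w] u2-v2[w] JOIN a1-b1[w] a2-b2[w]`; weights of the cut
#' edges are filled in at application time when formatting a scenario.
#'
#' @param op a `wdcj_op`.
#' @param w_cut1,w_cut2 weights of the cut edges (for display).
#' @return a character scalar.
#' @export
format_op <- function(op, w_cut1 = NA, w_cut2 = NA) {
  fmt <- function(e, w) sprintf("%s-%s[%s]", e[1L], e[2L],
                                if (is.na(w)) "?" else format(w, scientific = FALSE))
  sprintf("CUT %s %s JOIN %s %s",
          fmt(op$cut1, w_cut1), fmt(op$cut2, w_cut2),
          fmt(op$join1, op$w_join1), fmt(op$join2, op$w_join2))
}

#' @rdname format_op
#' @param line a line produced by `format_op()`.
#' @export
parse_op <- function(line) {
  tok <- strsplit(trimws(line), "[ \t]+")[[1L]]
  if (length(tok) != 6L || tok[1L] != "CUT" || tok[4L] != "JOIN")
    stop_input(sprintf("malformed scenario line: '%s'", line))
  bits <- lapply(tok[c(2L, 3L, 5L, 6L)], function(s) {
    p <- regmatches(s, regexec("^([^-]+)-([^-]+)\\[([0-9?]+)\\]$", s))[[1L]]
    if (length(p) != 4L) stop_input(sprintf("malformed edge token: '%s'", s))
    list(e = c(p[2L], p[3L]), w = suppressWarnings(as.numeric(p[4L])))
  })
  wdcj_op(bits[[1L]]$e, bits[[2L]]$e, bits[[3L]]$e, bits[[4L]]$e,
          bits[[3L]]$w, bits[[4L]]$w)
}

#' Apply a wDCJ operation to a genome
#'
#' Checks that both cut edges exist, that the joins conserve the total
#' weight, and returns the rewritten genome (still a perfect matching with
#' the same `W`).
#'
#' @param g a [genome()].
#' @param op a [wdcj_op()].
#' @return the transformed genome.
#' @export
apply_wdcj <- function(g, op) {
  stopifnot(inherits(g, "wdcj_genome"), inherits(op, "wdcj_op"))
  ed <- g$edges
  find_edge <- function(e) {
    i <- which((ed$u == e[1L] & ed$v == e[2L]) | (ed$u == e[2L] & ed$v == e[1L]))
    if (length(i) != 1L)
      stop_input(sprintf("cut edge %s-%s not present in genome", e[1L], e[2L]))
    i
  }
  i1 <- find_edge(op$cut1)
  i2 <- find_edge(op$cut2)
  if (i1 == i2) stop_input("the two cut edges must be distinct")
  if (op$w_join1 + op$w_join2 != ed$w[i1] + ed$w[i2])
    stop_input(sprintf(
      "weight conservation violated: %s + %s != %s + %s",
      format(op$w_join1), format(op$w_join2),
      format(ed$w[i1]), format(ed$w[i2])))
  keep <- ed[-c(i1, i2), , drop = FALSE]
  new <- data.frame(u = c(op$join1[1L], op$join2[1L]),
                    v = c(op$join1[2L], op$join2[2L]),
                    w = c(op$w_join1, op$w_join2), stringsAsFactors = FALSE)
  genome(rbind(keep, new), name = g$name)
}

#' Split one balanced trivial cycle off a balanced cycle
#'
#' In any balanced cycle there are three consecutive edges `e = ab`,
#' `f = bc`, `g = cd` with `e`, `g` genome-1 edges and
#' `w(e) + w(g) >= w(f)` (summing the negation around the cycle would
#' force a negative total).  Cutting `ab` and `cd` and joining `bc` (with
#' weight `w(f)`) and `ad` (with the non-negative remainder) detaches a
#' balanced 2-cycle on `{b, c}` and leaves a balanced cycle of length
#' `len - 2`.  The first qualifying triple from the cycle's canonical
#' start is used.
#'
#' @param cycle a balanced `wdcj_cycle` of length at least 4.
#' @return a list with the `op`, the `trivial` balanced 2-cycle, and the
#'   `rest` of the cycle.
#' @export
split_balanced_cycle <- function(cycle) {
  stopifnot(inherits(cycle, "wdcj_cycle"))
  if (cycle$imbalance != 0)
    stop_input("only balanced cycles can be split without leaving debt")
  if (cycle$length < 4L)
    stop_input("a trivial cycle (length 2) cannot be split")
  verts <- cycle$vertices
  L <- cycle$length
  half <- L %/% 2L
  wg1 <- cycle$g1_edges$w
  wg2 <- cycle$g2_edges$w
  for (t in seq_len(half)) {
    tn <- if (t == half) 1L else t + 1L
    w_e <- wg1[t]; w_f <- wg2[t]; w_g <- wg1[tn]
    if (w_e + w_g >= w_f) {
      a <- verts[2L * t - 1L]; b <- verts[2L * t]
      cc <- verts[2L * tn - 1L]; d <- verts[2L * tn]
      op <- wdcj_op(cut1 = c(a, b), cut2 = c(cc, d),
                    join1 = c(b, cc), join2 = c(a, d),
                    w_join1 = w_f, w_join2 = w_e + w_g - w_f)
      trivial <- .make_cycle(
        data.frame(u = b, v = cc, w = w_f, stringsAsFactors = FALSE),
        cycle$g2_edges[t, , drop = FALSE])
      rest_g1 <- rbind(cycle$g1_edges[-c(t, tn), , drop = FALSE],
                       data.frame(u = a, v = d, w = w_e + w_g - w_f,
                                  stringsAsFactors = FALSE))
      rest_g2 <- cycle$g2_edges[-t, , drop = FALSE]
      rest <- .make_cycle(rest_g1, rest_g2)
      return(list(op = op, trivial = trivial, rest = rest))
    }
  }
  stop("internal error: no qualifying triple in a balanced cycle")
}

#' Merge two distinct breakpoint-graph cycles
#'
#' Cuts the genome-1 edge incident to each cycle's canonical start vertex
#' and joins across, producing a single cycle whose imbalance is the sum
#' of the two.  Each join inherits the weight of the cut edge on its
#' genome-1 side (identity transfer; any conserving rule is valid).
#' Merging a cycle with itself is a freeze and is rejected: freezes never
#' occur in optimal scenarios.
#'
#' @param c1,c2 distinct `wdcj_cycle` objects.
#' @return a [wdcj_op()].
#' @export
merge_cycles <- function(c1, c2) {
  stopifnot(inherits(c1, "wdcj_cycle"), inherits(c2, "wdcj_cycle"))
  if (length(intersect(c1$vertices, c2$vertices)) > 0L)
    stop_input("cannot merge a cycle with itself (freeze)")
  e1 <- c1$g1_edges[1L, ]
  e2 <- c2$g1_edges[1L, ]
  wdcj_op(cut1 = c(e1$u, e1$v), cut2 = c(e2$u, e2$v),
          join1 = c(e1$u, e2$u), join2 = c(e1$v, e2$v),
          w_join1 = e1$w, w_join2 = e2$w)
}

#' Build an optimal (or certified approximate) sorting scenario
#'
#' Realises the distance reported by [wdcj_distance()] as an explicit
#' sequence of wDCJ: first the merges (chaining, in ascending cycle
#' index, the cycles of each zero-sum part of the plan), then splits that
#' peel one balanced trivial cycle at a time until the two genomes are
#' equal.  Merges strictly precede splits, and no freeze occurs.
#'
#' @param pair a [genome_pair()].
#' @param method forwarded to [wdcj_distance()] when `plan` is missing.
#' @param plan optionally, a `wdcj_dist` report for `pair`.
#' @return an object of class `wdcj_scenario`: list with `steps`
#'   (list of [wdcj_op()]), `start`, `end`, `n_merges` and the planned
#'   `distance`.
#' @export
sorting_scenario <- function(pair, method = c("dp", "ilp", "approx"),
                             plan = NULL) {
  stopifnot(inherits(pair, "wdcj_pair"))
  if (is.null(plan)) plan <- wdcj_distance(pair, method = match.arg(method))
  stopifnot(inherits(plan, "wdcj_dist"))
  if (plan$n != pair$n)
    stop_input("plan does not match the genome pair")
  bg <- plan$bg
  cur <- pair$g1
  steps <- list()
  # merge phase: within each zero-sum part, chain cycles in ascending index
  for (part in plan$parts_idx) {
    part <- sort(part)
    reps <- vapply(part, function(i) bg$cycles[[i]]$vertices[1L], "")
    acc <- reps[1L]
    for (j in seq_along(part)[-1L]) {
      m1 <- .mate_of(cur, acc)
      m2 <- .mate_of(cur, reps[j])
      op <- wdcj_op(cut1 = c(acc, m1$mate), cut2 = c(reps[j], m2$mate),
                    join1 = c(acc, reps[j]), join2 = c(m1$mate, m2$mate),
                    w_join1 = m1$w, w_join2 = m2$w)
      cur <- apply_wdcj(cur, op)
      steps[[length(steps) + 1L]] <- op
    }
  }
  # split phase: all cycles are now balanced; peel trivial cycles off
  repeat {
    bgc <- breakpoint_graph(genome_pair(cur, pair$g2))
    big <- which(bgc$summary$length >= 4L)
    if (length(big) == 0L) break
    sp <- split_balanced_cycle(bgc$cycles[[big[1L]]])
    cur <- apply_wdcj(cur, sp$op)
    steps[[length(steps) + 1L]] <- sp$op
  }
  if (!genomes_equal(cur, pair$g2))
    stop("internal error: scenario replay does not reach the target genome")
  if (length(steps) != plan$distance)
    stop("internal error: scenario length differs from the planned distance")
  structure(list(steps = steps, start = pair$g1, end = pair$g2,
                 n_merges = plan$m, distance = plan$distance,
                 method = plan$method),
            class = "wdcj_scenario")
}

#' @export
print.wdcj_scenario <- function(x, ...) {
  cat(sprintf("wDCJ sorting scenario (%s): %d step(s), %d merge(s) then %d split(s)\n",
              x$method, length(x$steps), x$n_merges,
              length(x$steps) - x$n_merges))
  invisible(x)
}

#' Replay and verify a sorting scenario
#'
#' Replays every step with [apply_wdcj()] (which enforces matching and
#' weight-conservation invariants) and checks that the final genome
#' equals the scenario's declared end genome.  Failures are reported, not
#' raised.
#'
#' @param scenario a `wdcj_scenario` (or a list with `steps`, `start`,
#'   `end`).
#' @return `TRUE`, or `FALSE` with attribute `failure` describing the
#'   first failing step.
#' @export
validate_scenario <- function(scenario) {
  cur <- scenario$start
  for (i in seq_along(scenario$steps)) {
    res <- tryCatch(apply_wdcj(cur, scenario$steps[[i]]), error = identity)
    if (inherits(res, "error"))
      return(structure(FALSE, failure = list(step = i,
                                             reason = conditionMessage(res))))
    cur <- res
  }
  if (!genomes_equal(cur, scenario$end))
    return(structure(FALSE, failure = list(step = length(scenario$steps),
                                           reason = "end genome mismatch")))
  TRUE
}
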
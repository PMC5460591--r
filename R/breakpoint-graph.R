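#' Breakpoint graph of a genome pair
#'
#' The union of the two matchings is a disjoint set of even alternating
#' cycles.  Each cycle carries `w1` and `w2`, the summed intergene sizes of
#' its genome-1 and genome-2 edges, and its imbalance `I = w1 - w2`; a
#' cycle is balanced iff `I = 0`.  Cycle enumeration is deterministic:
#' each cycle starts at its smallest unvisited vertex (byte order) and is
#' traversed along its genome-1 edge first.
#'
#' @param pair a [genome_pair()].
#' @return an object of class `wdcj_bg` with counts `n`, `c`, `n_b`,
#'   `n_u`, the multiset `unbalanced_imbalances`, a per-cycle `summary`
#'   data frame and the list `cycles` of `wdcj_cycle` objects.
#' @export
breakpoint_graph <- function(pair) {
  stopifnot(inherits(pair, "wdcj_pair"))
  labs <- pair$vertices
  i1 <- .gen_index(pair$g1, labs)
  i2 <- .gen_index(pair$g2, labs)
  d <- bg_decompose_cpp(i1$mate, i2$mate, i1$w, i2$w)
  c_n <- d$n_cycles
  ends <- cumsum(d$sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  cycles <- vector("list", c_n)
  for (k in seq_len(c_n)) {
    verts <- labs[d$verts[starts[k]:ends[k]]]
    cycles[[k]] <- .make_cycle_from_traversal(verts, i1, i2, labs)
  }
  imb <- d$w1 - d$w2
  summ <- data.frame(cycle = seq_len(c_n), length = d$sizes,
                     w1 = d$w1, w2 = d$w2, imbalance = imb)
  structure(list(n = pair$n, c = c_n,
                 n_b = sum(imb == 0), n_u = sum(imb != 0),
                 unbalanced_imbalances = imb[imb != 0],
                 summary = summ, cycles = cycles, vertices = labs),
            class = "wdcj_bg")
}

# cycle object from a traversal v0, v1, ..., v_{L-1}: genome-1 edges at
# positions (1,2), (3,4), ...; genome-2 edges at (2,3), ..., (L,1)
.make_cycle_from_traversal <- function(verts, i1, i2, labs) {
  L <- length(verts)
  idx <- match(verts, labs)
  o1 <- seq(1L, L, by = 2L)
  o2 <- seq(2L, L, by = 2L)
  g1 <- data.frame(u = verts[o1], v = verts[o2], w = i1$w[idx[o1]],
                   stringsAsFactors = FALSE)
  g2 <- data.frame(u = verts[o2], v = verts[c(o1[-1L], 1L)],
                   w = i2$w[idx[o2]], stringsAsFactors = FALSE)
  w1 <- sum(g1$w); w2 <- sum(g2$w)
  structure(list(vertices = verts, g1_edges = g1, g2_edges = g2,
                 length = L, w1 = w1, w2 = w2, imbalance = w1 - w2),
            class = "wdcj_cycle")
}

# rebuild a canonical cycle object from explicit edge lists forming one
# alternating cycle (used when splitting rewrites a cycle locally)
.make_cycle <- function(g1_edges, g2_edges) {
  verts_all <- sort(unique(c(g1_edges$u, g1_edges$v)), method = "radix")
  part1 <- character(0); part2 <- character(0); w1m <- numeric(0); w2m <- numeric(0)
  env1 <- new.env(parent = emptyenv()); env2 <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(g1_edges))) {
    assign(g1_edges$u[i], list(m = g1_edges$v[i], w = g1_edges$w[i]), envir = env1)
    assign(g1_edges$v[i], list(m = g1_edges$u[i], w = g1_edges$w[i]), envir = env1)
  }
  for (i in seq_len(nrow(g2_edges))) {
    assign(g2_edges$u[i], list(m = g2_edges$v[i], w = g2_edges$w[i]), envir = env2)
    assign(g2_edges$v[i], list(m = g2_edges$u[i], w = g2_edges$w[i]), envir = env2)
  }
  start <- verts_all[1L]
  verts <- character(0)
  v <- start
  i1w <- numeric(0); i2w <- numeric(0)
  repeat {
    e1 <- get(v, envir = env1)
    verts <- c(verts, v, e1$m)
    e2 <- get(e1$m, envir = env2)
    v <- e2$m
    if (v == start) break
  }
  L <- length(verts)
  o1 <- seq(1L, L, by = 2L); o2 <- seq(2L, L, by = 2L)
  g1 <- data.frame(u = verts[o1], v = verts[o2],
                   w = vapply(verts[o1], function(x) get(x, envir = env1)$w, 0),
                   stringsAsFactors = FALSE)
  g2 <- data.frame(u = verts[o2], v = verts[c(o1[-1L], 1L)],
                   w = vapply(verts[o2], function(x) get(x, envir = env2)$w, 0),
                   stringsAsFactors = FALSE)
  rownames(g1) <- rownames(g2) <- NULL
  w1 <- sum(g1$w); w2 <- sum(g2$w)
  structure(list(vertices = verts, g1_edges = g1, g2_edges = g2,
                 length = L, w1 = w1, w2 = w2, imbalance = w1 - w2),
            class = "wdcj_cycle")
}

#' @export
print.wdcj_bg <- function(x, ...) {
  cat(sprintf("breakpoint graph: n = %d, c = %d (balanced %d, unbalanced %d)\n",
              x$n, x$c, x$n_b, x$n_u))
  print(x$summary)
  invisible(x)
}

#' @export
print.wdcj_cycle <- function(x, ...) {
  cat(sprintf("alternating cycle: length %d, w1 = %s, w2 = %s, imbalance %s\n",
              x$length, format(x$w1), format(x$w2), format(x$imbalance)))
  invisible(x)
}

#' Classical (unweighted) DCJ distance
#'
#' Ignoring intergene sizes, the DCJ distance is `n - c` where `c` is the
#' number of breakpoint-graph cycles.
#'
#' @param x a `wdcj_bg` or a [genome_pair()].
#' @return a non-negative integer.
#' @export
classical_dcj_distance <- function(x) {
  if (inherits(x, "wdcj_pair")) x <- breakpoint_graph(x)
  stopifnot(inherits(x, "wdcj_bg"))
  x$n - x$c
}
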
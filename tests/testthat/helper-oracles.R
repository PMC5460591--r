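# Independent oracles and exhaustive-enumeration machinery.
#
# The move-graph oracle materialises the whole wDCJ state space for tiny
# (n, W): states are (perfect matching, integer weight composition) on 2n
# labelled vertices, moves are every wDCJ (every unordered edge pair, both
# recombinations, every integer weight split), and distances are unweighted
# shortest paths (breadth-first search) on that graph, computed with igraph.
# It is entirely independent of the breakpoint-graph / zero-sum-partition
# route used by the package.

pad_labels <- function(n2) sprintf("%02d", seq_len(n2))

# all perfect matchings on vertices 1..n2 as mate vectors
all_matchings <- function(n2) {
  if (n2 == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(mate, free) {
    if (length(free) == 0L) {
      out[[length(out) + 1L]] <<- mate
      return(invisible())
    }
    a <- free[1L]
    for (b in free[-1L]) {
      mate[a] <- b; mate[b] <- a
      rec(mate, setdiff(free, c(a, b)))
    }
  }
  rec(integer(n2), seq_len(n2))
  out
}

# all vectors of k non-negative integers summing to W
compositions <- function(W, k) {
  if (k == 1L) return(list(W))
  out <- list()
  for (first in 0:W)
    for (rest in compositions(W - first, k - 1L))
      out[[length(out) + 1L]] <- c(first, rest)
  out
}

# per-vertex weight vector from a mate vector and per-edge weights (edges
# ordered by their smaller endpoint)
edge_weights_to_vertex <- function(mate, ew) {
  reps <- which(seq_along(mate) < mate)
  wv <- numeric(length(mate))
  wv[reps] <- ew
  wv[mate[reps]] <- ew
  wv
}

state_key <- function(mate, wv) {
  reps <- which(seq_along(mate) < mate)
  paste(sprintf("%d-%d:%d", reps, mate[reps], wv[reps]), collapse = ";")
}

# all wDCJ successors of a state, as keys
state_neighbours <- function(mate, wv) {
  reps <- which(seq_along(mate) < mate)
  keys <- character(0)
  if (length(reps) < 2L) return(keys)
  for (i in seq_len(length(reps) - 1L)) {
    for (j in (i + 1L):length(reps)) {
      a <- reps[i]; b <- mate[a]; cc <- reps[j]; d <- mate[cc]
      tot <- wv[a] + wv[cc]
      for (t in 0:tot) {
        for (type in 1:2) {
          m2 <- mate; w2 <- wv
          if (type == 1L) {           # ac | bd
            m2[a] <- cc; m2[cc] <- a; m2[b] <- d; m2[d] <- b
            w2[a] <- w2[cc] <- t; w2[b] <- w2[d] <- tot - t
          } else {                    # ad | bc
            m2[a] <- d; m2[d] <- a; m2[b] <- cc; m2[cc] <- b
            w2[a] <- w2[d] <- t; w2[b] <- w2[cc] <- tot - t
          }
          keys <- c(keys, state_key(m2, w2))
        }
      }
    }
  }
  unique(keys)
}

state_to_genome <- function(mate, wv) {
  labs <- pad_labels(length(mate))
  reps <- which(seq_along(mate) < mate)
  genome(data.frame(u = labs[reps], v = labs[mate[reps]], w = wv[reps],
                    stringsAsFactors = FALSE))
}

# Exhaustive comparison over all genome pairs on <= 6 vertices with total
# weight <= max_W: BFS distances vs the exact formula, and the 4/3 ratio.
# Pairs are grouped by breakpoint-graph signature (n, n_b, sorted imbalance
# multiset), which determines both the exact and the approximate distance;
# every ordered pair is still checked against the oracle individually.
# The result is cached so several test blocks can share one computation.
.oracle_cache <- new.env(parent = emptyenv())

exhaustive_small_summary <- function(max_W = 6L) {
  if (!is.null(.oracle_cache$summary)) return(.oracle_cache$summary)
  skip_if_not_installed("igraph")
  n_pairs <- 0L
  mismatches <- 0L
  max_ratio <- 1
  n_sig <- 0L
  for (n in 1:3) {
    mats <- all_matchings(2L * n)
    for (W in 0:max_W) {
      ew <- compositions(W, n)
      states <- list()
      for (m in mats)
        for (e in ew)
          states[[length(states) + 1L]] <-
            list(mate = m, wv = edge_weights_to_vertex(m, unlist(e)))
      keys <- vapply(states, function(s) state_key(s$mate, s$wv), "")
      ns <- length(states)
      if (n >= 2L) {
        from <- character(0); to <- character(0)
        for (s in states) {
          k <- state_key(s$mate, s$wv)
          nb <- state_neighbours(s$mate, s$wv)
          from <- c(from, rep(k, length(nb)))
          to <- c(to, nb)
        }
        gr <- igraph::graph_from_data_frame(
          data.frame(from = from, to = to), directed = FALSE,
          vertices = data.frame(name = keys))
        D <- igraph::distances(gr)
        D <- D[keys, keys]
      } else {
        D <- matrix(0, 1L, 1L)
      }
      sig_env <- new.env(parent = emptyenv())
      for (i in seq_len(ns)) {
        si <- states[[i]]
        for (j in seq_len(ns)) {
          sj <- states[[j]]
          d <- bg_decompose_cpp(si$mate, sj$mate, si$wv, sj$wv)
          imb <- sort(d$w1 - d$w2)
          key <- paste(n, d$n_cycles, paste(imb, collapse = ","), sep = "|")
          rec <- sig_env[[key]]
          if (is.null(rec)) {
            pair <- genome_pair(state_to_genome(si$mate, si$wv),
                                state_to_genome(sj$mate, sj$wv))
            exact <- wdcj_distance(pair, method = "dp")$distance
            approx <- wdcj_distance(pair, method = "approx")$distance
            rec <- c(exact = exact, approx = approx)
            sig_env[[key]] <- rec
            n_sig <- n_sig + 1L
            if (exact > 0)
              max_ratio <- max(max_ratio, approx / exact)
          }
          n_pairs <- n_pairs + 1L
          if (D[i, j] != rec[["exact"]]) mismatches <- mismatches + 1L
        }
      }
    }
  }
  .oracle_cache$summary <- list(n_pairs = n_pairs, mismatches = mismatches,
                                max_ratio = max_ratio,
                                n_signatures = n_sig)
  .oracle_cache$summary
}

# direct single-pair BFS distance (for spot checks)
bfs_distance <- function(pair) {
  skip_if_not_installed("igraph")
  labs <- pair$vertices
  st <- function(g) {
    idx <- wdcj:::.gen_index(g, labs)
    list(mate = idx$mate, wv = idx$w)
  }
  s1 <- st(pair$g1); s2 <- st(pair$g2)
  k1 <- state_key(s1$mate, s1$wv); k2 <- state_key(s2$mate, s2$wv)
  if (k1 == k2) return(0L)
  # BFS expanding keys on demand
  dist <- new.env(parent = emptyenv())
  assign(k1, 0L, envir = dist)
  frontier <- list(s1)
  fkeys <- k1
  repeat {
    if (length(frontier) == 0L) stop("target unreachable")
    nxt <- list(); nkeys <- character(0)
    for (s in frontier) {
      d0 <- get(state_key(s$mate, s$wv), envir = dist)
      reps <- which(seq_along(s$mate) < s$mate)
      for (i in seq_len(length(reps) - 1L)) for (j in (i + 1L):length(reps)) {
        a <- reps[i]; b <- s$mate[a]; cc <- reps[j]; d <- s$mate[cc]
        tot <- s$wv[a] + s$wv[cc]
        for (t in 0:tot) for (type in 1:2) {
          m2 <- s$mate; w2 <- s$wv
          if (type == 1L) {
            m2[a] <- cc; m2[cc] <- a; m2[b] <- d; m2[d] <- b
            w2[a] <- w2[cc] <- t; w2[b] <- w2[d] <- tot - t
          } else {
            m2[a] <- d; m2[d] <- a; m2[b] <- cc; m2[cc] <- b
            w2[a] <- w2[d] <- t; w2[b] <- w2[cc] <- tot - t
          }
          k <- state_key(m2, w2)
          if (k == k2) return(d0 + 1L)
          if (is.null(dist[[k]])) {
            assign(k, d0 + 1L, envir = dist)
            nxt[[length(nxt) + 1L]] <- list(mate = m2, wv = w2)
          }
        }
      }
    }
    frontier <- nxt
  }
}

# maximum number of disjoint zero-sum triplets (exhaustive recursion)
opt_triplet_count <- function(values) {
  n <- length(values)
  rec <- function(avail) {
    if (length(avail) < 3L) return(0L)
    i <- avail[1L]
    best <- rec(avail[-1L])            # i unused
    rest <- avail[-1L]
    if (length(rest) >= 2L) {
      for (a in seq_len(length(rest) - 1L)) for (b in (a + 1L):length(rest)) {
        if (values[i] + values[rest[a]] + values[rest[b]] == 0)
          best <- max(best, 1L + rec(rest[-c(a, b)]))
      }
    }
    best
  }
  rec(seq_len(n))
}

# all multisets (nondecreasing vectors) of given size from a value pool
multisets_from <- function(pool, size) {
  out <- list()
  rec <- function(start, cur) {
    if (length(cur) == size) {
      out[[length(out) + 1L]] <<- cur
      return(invisible())
    }
    for (i in start:length(pool)) rec(i, c(cur, pool[i]))
  }
  rec(1L, numeric(0))
  out
}
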
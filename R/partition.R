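#' @name mzsp
#' @title Maximum zero-sum partition of cycle imbalances
#'
#' @description
#' Given the multiset of imbalances of the unbalanced breakpoint-graph
#' cycles (nonzero integers summing to zero), a maximum zero-sum partition
#' splits it into the largest possible number `p` of parts each summing to
#' zero.  Each part of size `k` costs `k - 1` cycle merges, so the minimum
#' total number of merges is `m = n_u - p` and the wDCJ distance is
#' `n - c + 2 m`.  Three solvers are provided: a fixed-parameter dynamic
#' program in `O*(3^n)`, an integer-programming formulation solved exactly
#' by branch and bound, and a brute-force enumeration of set partitions
#' used as an independent oracle in tests.
#'
#' @param values numeric vector of nonzero integers summing to zero.
#' @param cap capacity limit on `length(values)` for the chosen solver.
#' @return an object of class `wdcj_zsp`: a list with `values`, `parts`
#'   (list of index vectors into `values`), `p = length(parts)` and
#'   `method`.
NULL

.check_multiset <- function(values, zero_sum = TRUE) {
  if (length(values) == 0L) return(invisible(numeric(0)))
  if (!is.numeric(values) || anyNA(values) || any(values != floor(values)))
    stop_input("imbalances must be integers")
  if (any(values == 0))
    stop_input("imbalances must be nonzero (balanced cycles are excluded)")
  if (zero_sum && sum(values) != 0)
    stop_input("imbalance multiset must sum to zero")
  invisible(values)
}

.zsp <- function(values, assignment, method) {
  if (length(values) == 0L)
    return(structure(list(values = values, parts = list(), p = 0L,
                          method = method), class = "wdcj_zsp"))
  parts <- unname(split(seq_along(values), assignment))
  parts <- lapply(parts, sort)
  parts <- parts[order(vapply(parts, min, 0L))]
  structure(list(values = values, parts = parts, p = length(parts),
                 method = method), class = "wdcj_zsp")
}

#' @export
print.wdcj_zsp <- function(x, ...) {
  cat(sprintf("zero-sum partition (%s): p = %d part(s)\n", x$method, x$p))
  for (pt in x$parts)
    cat("  {", paste(x$values[pt], collapse = ", "), "}\n")
  invisible(x)
}

#' @rdname mzsp
#' @details `mzsp_dp()` fills the Held-Karp style table over the `3^n`
#'   disjoint subset pairs (part under construction, elements still free)
#'   and recovers a witness partition by backtracking.  Instances beyond
#'   `cap` elements raise a capacity error suggesting [mzsp_ilp()].
#' @export
mzsp_dp <- function(values, cap = 20L) {
  .check_multiset(values)
  if (length(values) > cap)
    stop_capacity(sprintf(
      "dynamic program capacity exceeded (%d > %d elements); use mzsp_ilp()",
      length(values), cap))
  res <- mzsp_dp_cpp(as.numeric(values))
  .zsp(values, res$assignment, "dp")
}

#' @rdname mzsp
#' @details `mzsp_bruteforce()` enumerates every set partition (with a
#'   feasibility prune only) and keeps a maximum-cardinality one whose
#'   parts all sum to zero; it is exponential in `length(values)` and
#'   intended as a testing oracle.
#' @export
mzsp_bruteforce <- function(values, cap = 10L) {
  .check_multiset(values)
  n <- length(values)
  if (n > cap)
    stop_capacity(sprintf("brute force capacity exceeded (%d > %d elements)",
                          n, cap))
  if (n == 0L) return(.zsp(values, integer(0), "brute"))
  best <- new.env(parent = emptyenv())
  best$p <- -1L
  best$assign <- NULL
  rec <- function(i, nblocks, assign, sums) {
    if (i > n) {
      if (all(sums[seq_len(nblocks)] == 0) && nblocks > best$p) {
        best$p <- nblocks
        best$assign <- assign
      }
      return(invisible())
    }
    # blocks already forced nonzero need at least one of the remaining
    # elements each; prune when that is impossible
    if (nblocks > 0L && sum(sums[seq_len(nblocks)] != 0) > n - i + 1L)
      return(invisible())
    for (b in seq_len(nblocks)) {
      assign[i] <- b
      sums[b] <- sums[b] + values[i]
      rec(i + 1L, nblocks, assign, sums)
      sums[b] <- sums[b] - values[i]
    }
    assign[i] <- nblocks + 1L
    sums[nblocks + 1L] <- values[i]
    rec(i + 1L, nblocks + 1L, assign, sums)
  }
  rec(1L, 0L, integer(n), numeric(n))
  .zsp(values, best$assign, "brute")
}

#' @rdname mzsp
#' @details `mzsp_ilp()` builds the 0/1 program with assignment variables
#'   `x[i,j]` (unbalanced cycle `i` in part `j`, `j <= floor(n/2)`) and
#'   part-use indicators `p[j]`, under (2) every cycle in exactly one
#'   part, (3) every part's imbalances summing to zero, and (4)
#'   `p[j] <= sum_i x[i,j]`, maximising `sum_j p[j]`.  The program is
#'   solved exactly by depth-first branch and bound with the admissible
#'   bound `p <= used + floor((remaining - open)/2)`; `symmetry_break`
#'   (default `TRUE`) restricts each cycle to at most one previously
#'   unused part, the standard cure for the formulation's permuted-part
#'   symmetry, without affecting the optimum.
#' @param symmetry_break logical; see Details.
#' @export
mzsp_ilp <- function(values, symmetry_break = TRUE) {
  .check_multiset(values)
  n <- length(values)
  if (n == 0L) {
    out <- .zsp(values, integer(0), "ilp")
    out$model <- list(n_vars = 0L, n_constraints = 0L)
    return(out)
  }
  J <- max(1L, n %/% 2L)            # p <= n/2: a part needs >= 2 cycles
  best <- new.env(parent = emptyenv())
  best$p <- -1L
  best$assign <- NULL
  rec <- function(i, used, sums, counts, assign) {
    if (i > n) {
      nonempty <- counts > 0L
      if (all(sums[nonempty] == 0) && sum(nonempty) > best$p) {
        best$p <- sum(nonempty)
        best$assign <- assign
      }
      return(invisible())
    }
    r <- n - i + 1L
    open <- sum(counts > 0L & sums != 0)
    if (open > r) return(invisible())
    if (sum(counts > 0L) + (r - open) %/% 2L <= best$p) return(invisible())
    # a fresh part is tried first, so deep values of p are found (and the
    # bound tightened) early; with symmetry breaking, only one unused part
    # index is ever considered
    bs <- if (symmetry_break) {
      c(if (used < J) used + 1L, seq_len(used))
    } else {
      c(if (used < J) used + 1L, seq_len(used), if (used + 1L < J) (used + 2L):J)
    }
    for (b in bs) {
      assign[i] <- b
      sums[b] <- sums[b] + values[i]
      counts[b] <- counts[b] + 1L
      rec(i + 1L, max(used, b), sums, counts, assign)
      sums[b] <- sums[b] - values[i]
      counts[b] <- counts[b] - 1L
    }
  }
  rec(1L, 0L, numeric(J), integer(J), integer(n))
  stopifnot(best$p >= 1L)            # the whole multiset is one feasible part
  out <- .zsp(values, best$assign, "ilp")
  out$model <- list(n_vars = n * J + J, n_constraints = n + 2L * J)
  out
}

#' Greedy opposite-pair extraction
#'
#' Finds a maximum set of two-element zero-sum parts, i.e. pairs of
#' unbalanced cycles whose imbalances are opposite; pairing by value and
#' its opposite is optimal for pairs.  Step (a) of the 4/3 approximation.
#'
#' @param values numeric vector of nonzero integers (any sum).
#' @return a list with `pairs` (list of index pairs), `remainder_idx`
#'   (indices not paired) and `remainder` (their values; it contains no
#'   value together with its opposite).
#' @export
greedy_pairs <- function(values) {
  .check_multiset(values, zero_sum = FALSE)
  pairs <- list()
  used <- rep(FALSE, length(values))
  for (v in sort(unique(values[values > 0]))) {
    iv <- which(values == v)
    im <- which(values == -v)
    k <- min(length(iv), length(im))
    if (k > 0L)
      for (t in seq_len(k)) {
        pairs[[length(pairs) + 1L]] <- c(iv[t], im[t])
        used[c(iv[t], im[t])] <- TRUE
      }
  }
  list(pairs = pairs, remainder_idx = which(!used),
       remainder = values[!used])
}

#' Greedy zero-sum triplet extraction
#'
#' The 1/3-approximation for extracting disjoint zero-sum triplets from a
#' multiset with no opposite pair (the remainder of [greedy_pairs()]):
#' scanning candidates `x` in ascending value order, find the first
#' ascending pair `(y, z)` with `y + z = -x`, emit the triplet and remove
#' all three; a candidate with no completing pair is discarded from the
#' scan but stays in the remainder.  The number of triplets found is at
#' least one third of the optimum.  Step (b) of the 4/3 approximation.
#'
#' @param values numeric vector of nonzero integers.
#' @return a list with `triplets` (list of index triples) and
#'   `remainder_idx` (indices in no triplet).
#' @export
greedy_triplets <- function(values) {
  .check_multiset(values, zero_sum = FALSE)
  n <- length(values)
  alive <- rep(TRUE, n)
  triplets <- list()
  ord <- order(values, seq_len(n))
  for (x in ord) {
    if (!alive[x]) next
    cand <- setdiff(ord[alive[ord]], x)
    hit <- NULL
    m <- length(cand)
    if (m >= 2L) {
      for (a in seq_len(m - 1L)) {
        for (b in (a + 1L):m) {
          if (values[cand[a]] + values[cand[b]] == -values[x]) {
            hit <- c(cand[a], cand[b])
            break
          }
        }
        if (!is.null(hit)) break
      }
    }
    if (!is.null(hit)) {
      triplets[[length(triplets) + 1L]] <- sort(c(x, hit))
      alive[c(x, hit)] <- FALSE
    }
    # otherwise x is dropped from the scan but remains unpartitioned
  }
  in_triplet <- rep(FALSE, n)
  for (tr in triplets) in_triplet[tr] <- TRUE
  list(triplets = triplets, remainder_idx = which(!in_triplet))
}
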
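#' A 3-Partition instance
#'
#' A multiset `A` of `3n` positive integers with `sum(A) = B * n` and
#' `B/4 < a_i < B/2` for every element, so that any zero-sum grouping
#' against `-B` targets uses exactly three elements.
#'
#' @param A integer vector of length `3n`.
#' @param B the target sum.
#' @return an object of class `wdcj_3part` with `A`, `B` and `n`.
#' @export
three_partition <- function(A, B) {
  if (length(A) %% 3L != 0L || length(A) == 0L)
    stop_input("A must contain 3n positive integers")
  n <- length(A) %/% 3L
  if (any(A != floor(A)) || any(A <= 0))
    stop_input("A must contain positive integers")
  if (sum(A) != B * n)
    stop_input(sprintf("sum(A) = %s must equal B * n = %s",
                       format(sum(A)), format(B * n)))
  if (!all(A > B / 4 & A < B / 2))
    stop_input("every element must satisfy B/4 < a_i < B/2")
  structure(list(A = A, B = B, n = n), class = "wdcj_3part")
}

#' Hard genome pairs by reduction from 3-Partition
#'
#' Builds two genomes on `8n` vertices sharing one matching of `4n`
#' adjacencies, so the breakpoint graph consists of `4n` trivial cycles.
#' For `i <= 3n` the genome-1 edge of cycle `i` weighs `a_i` and the
#' genome-2 edge 0 (imbalance `a_i`); for the remaining `n` cycles the
#' weights are 0 and `B` (imbalance `-B`).  The instance is satisfiable
#' iff the wDCJ distance is exactly `6n`: each balanced group must spend
#' three merges (three `a_i` plus one `-B`), and `3n` splits then finish
#' the sorting.
#'
#' @param inst a [three_partition()] instance.
#' @return a [genome_pair()].
#' @export
reduction_from_3partition <- function(inst) {
  stopifnot(inherits(inst, "wdcj_3part"))
  n <- inst$n
  m <- 4L * n
  wdt <- nchar(as.character(m))
  ua <- sprintf("c%0*d_a", wdt, seq_len(m))
  ub <- sprintf("c%0*d_b", wdt, seq_len(m))
  w1 <- c(inst$A, rep(0, n))
  w2 <- c(rep(0, 3L * n), rep(inst$B, n))
  g1 <- genome(data.frame(u = ua, v = ub, w = w1, stringsAsFactors = FALSE),
               name = "g1")
  g2 <- genome(data.frame(u = ua, v = ub, w = w2, stringsAsFactors = FALSE),
               name = "g2")
  genome_pair(g1, g2)
}

#' Random evenly weighted genome pair
#'
#' Two independent uniform perfect matchings on `2n` labelled vertices
#' with integer weights uniform on `0..max_weight`; the weight totals are
#' then evened up by adding the deficit to the canonically last edge of
#' the lighter genome.
#'
#' @param n adjacencies per genome (`>= 1`).
#' @param max_weight maximum edge weight drawn.
#' @param seed optional integer seed.
#' @return a [genome_pair()].
#' @export
random_genome_pair <- function(n, max_weight, seed = NULL) {
  stopifnot(n >= 1, max_weight >= 0)
  if (!is.null(seed)) set.seed(seed)
  labs <- sprintf("v%0*d", nchar(2L * n), seq_len(2L * n))
  rnd <- function() {
    perm <- sample(2L * n)
    genome(data.frame(u = labs[perm[seq(1L, 2L * n, by = 2L)]],
                      v = labs[perm[seq(2L, 2L * n, by = 2L)]],
                      w = sample.int(max_weight + 1L, n, replace = TRUE) - 1L,
                      stringsAsFactors = FALSE))
  }
  g1 <- rnd()
  g2 <- rnd()
  d <- total_weight(g1) - total_weight(g2)
  fix <- function(g, add) {
    ed <- g$edges
    ed$w[nrow(ed)] <- ed$w[nrow(ed)] + add
    genome(ed, name = g$name)
  }
  if (d > 0) g2 <- fix(g2, d) else if (d < 0) g1 <- fix(g1, -d)
  genome_pair(g1, g2)
}

#' Random zero-sum multiset of nonzero integers
#'
#' Draws `size - 1` nonzero integers uniformly from
#' `[-magnitude, magnitude]` and closes the multiset with the negated
#' sum, retrying until the closing element is nonzero and within range.
#' Used to fuzz the zero-sum partition solvers.
#'
#' @param size number of elements (`>= 2`).
#' @param magnitude bound on absolute values (`>= 1`).
#' @param seed optional integer seed.
#' @return an integer vector summing to zero with no zero element.
#' @export
random_zero_sum_multiset <- function(size, magnitude, seed = NULL) {
  stopifnot(size >= 2, magnitude >= 1)
  if (!is.null(seed)) set.seed(seed)
  pool <- setdiff(seq.int(-magnitude, magnitude), 0L)
  for (try in seq_len(10000L)) {
    v <- sample(pool, size - 1L, replace = TRUE)
    last <- -sum(v)
    if (last != 0 && abs(last) <= magnitude)
      return(c(v, last))
  }
  stop_input("could not draw a zero-sum multiset under these constraints")
}
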
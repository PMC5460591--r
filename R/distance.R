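#' wDCJ distance between two evenly weighted genomes
#'
#' The wDCJ distance is `n - c + 2m`, where `c` is the number of
#' breakpoint-graph cycles and `m` the minimum number of cycle merges
#' needed to turn the unbalanced cycles into balanced ones.  The minimum
#' is `m = n_u - p`, with `p` the maximum zero-sum partition of the
#' unbalanced imbalances; computing `p` is the NP-hard core of the
#' problem.
#'
#' * `method = "dp"` / `"ilp"`: exact, via [mzsp_dp()] / [mzsp_ilp()].
#' * `method = "approx"`: the 4/3-approximation, which merges a maximum
#'   number of opposite-imbalance pairs ([greedy_pairs()]), then greedy
#'   zero-sum triplets ([greedy_triplets()]), then chains every remaining
#'   unbalanced cycle into a single balanced one.  Its result is always
#'   between the exact distance and 4/3 times it.
#'
#' @param pair a [genome_pair()].
#' @param method `"dp"`, `"ilp"` or `"approx"`.
#' @param cap capacity limit forwarded to [mzsp_dp()].
#' @return an object of class `wdcj_dist`: a list with counts `n`, `c`,
#'   `n_b`, `n_u`, the partition size `p` (`NA` for `"approx"`), the merge
#'   count `m`, the `distance`, the `method`, the breakpoint graph `bg`
#'   and `parts_idx`, the grouping of unbalanced-cycle indices realising
#'   the `m` merges (the approximation's certificate: pairs, triplets,
#'   leftover chain).
#' @examples
#' g1 <- genome(data.frame(u = c("1", "3"), v = c("2", "4"), w = c(3, 1)))
#' g2 <- genome(data.frame(u = c("1", "3"), v = c("2", "4"), w = c(1, 3)))
#' wdcj_distance(genome_pair(g1, g2))   # two trivial cycles, one merge: 2
#' @export
wdcj_distance <- function(pair, method = c("dp", "ilp", "approx"), cap = 20L) {
  method <- match.arg(method)
  stopifnot(inherits(pair, "wdcj_pair"))
  bg <- breakpoint_graph(pair)
  uidx <- which(bg$summary$imbalance != 0)      # cycle indices, unbalanced
  imb <- bg$summary$imbalance[uidx]
  if (method %in% c("dp", "ilp")) {
    zsp <- if (method == "dp") mzsp_dp(imb, cap = cap) else mzsp_ilp(imb)
    p <- zsp$p
    m <- bg$n_u - p
    parts_idx <- lapply(zsp$parts, function(ix) uidx[ix])
  } else {
    gp <- greedy_pairs(imb)
    rem1 <- gp$remainder_idx
    gt <- greedy_triplets(imb[rem1])
    parts_idx <- c(lapply(gp$pairs, function(ix) uidx[ix]),
                   lapply(gt$triplets, function(ix) uidx[rem1[ix]]))
    leftover <- uidx[rem1[gt$remainder_idx]]
    if (length(leftover) == 1L)
      stop("internal error: a single leftover unbalanced cycle cannot sum to zero")
    if (length(leftover) > 0L)
      parts_idx <- c(parts_idx, list(leftover))
    p <- NA_integer_
    m <- bg$n_u - length(parts_idx)
  }
  distance <- bg$n - bg$c + 2L * m
  structure(list(n = bg$n, c = bg$c, n_b = bg$n_b, n_u = bg$n_u,
                 p = p, m = m, distance = distance, method = method,
                 parts_idx = parts_idx, bg = bg),
            class = "wdcj_dist")
}

#' @export
print.wdcj_dist <- function(x, ...) {
  cat(sprintf(
    "wDCJ distance (%s): %d  [n = %d, c = %d, n_b = %d, n_u = %d, m = %d%s]\n",
    x$method, x$distance, x$n, x$c, x$n_b, x$n_u, x$m,
    if (!is.na(x$p)) sprintf(", p = %d", x$p) else ""))
  invisible(x)
}

# plain-list view for JSON output
.dist_report_list <- function(x) {
  list(method = x$method, n = x$n, c = x$c, n_b = x$n_b, n_u = x$n_u,
       p = if (is.na(x$p)) NULL else x$p, m = x$m, distance = x$distance)
}
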
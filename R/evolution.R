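# --- Markov chain of evolution by random wDCJ ------------------------------
#
# From the current genome, an unordered pair of distinct adjacencies
# {ab, cd} is chosen uniformly; they are replaced by ac|bd or ad|bc with
# probability 1/2 each; integer nucleotide counts x ~ U{0..w(ab)} and
# y ~ U{0..w(cd)} are drawn and x + y is assigned to one new adjacency
# (probability 1/2 per side), the remainder to the other.  The total
# intergene size W is conserved at every step.

# one step on the integer-index view (mate / per-vertex weight vectors)
.step_index <- function(mate, wv) {
  N <- length(mate)
  a <- sample.int(N, 1L)
  b <- mate[a]
  repeat {
    cc <- sample.int(N, 1L)
    if (cc != a && cc != b) break
  }
  d <- mate[cc]
  w1 <- wv[a]; w2 <- wv[cc]
  s <- (sample.int(w1 + 1L, 1L) - 1L) + (sample.int(w2 + 1L, 1L) - 1L)
  if (runif(1L) >= 0.5) s <- w1 + w2 - s     # which new edge gets x + y
  if (runif(1L) < 0.5) {                     # ac | bd
    mate[a] <- cc; mate[cc] <- a; mate[b] <- d; mate[d] <- b
    wv[a] <- wv[cc] <- s
    wv[b] <- wv[d] <- w1 + w2 - s
  } else {                                   # ad | bc
    mate[a] <- d; mate[d] <- a; mate[b] <- cc; mate[cc] <- b
    wv[a] <- wv[d] <- s
    wv[b] <- wv[cc] <- w1 + w2 - s
  }
  list(mate = mate, w = wv)
}

#' One random wDCJ step of the evolution Markov chain
#'
#' @param g a [genome()] with at least two adjacencies.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return the successor genome; `W` is conserved.
#' @export
random_wdcj_step <- function(g, seed = NULL) {
  stopifnot(inherits(g, "wdcj_genome"))
  if (nrow(g$edges) < 2L)
    stop_input("the chain needs at least two adjacencies (n >= 2)")
  if (!is.null(seed)) set.seed(seed)
  idx <- .gen_index(g, g$vertices)
  st <- .step_index(idx$mate, idx$w)
  .gen_from_index(st$mate, st$w, g$vertices, name = g$name)
}

#' Simulate a trajectory of evolution by wDCJ
#'
#' Applies `k` random wDCJ to `start` and records, after every step, the
#' cycle statistics of the breakpoint graph between the fixed start genome
#' and the current one: `n_u` (unbalanced cycles, the parameter governing
#' the exact algorithms), `n_b`, `c`, and the theoretical expectation
#' bound `k/sqrt(n)`.
#'
#' @param start a [genome()].
#' @param k number of steps (`>= 0`).
#' @param seed optional integer seed.
#' @return a data frame of class `wdcj_trajectory` with one row per step
#'   `0..k` and columns `k`, `n_u`, `n_b`, `c`, `bound`.
#' @export
simulate_trajectory <- function(start, k, seed = NULL) {
  stopifnot(inherits(start, "wdcj_genome"), k >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(start$edges)
  if (k > 0 && n < 2L)
    stop_input("the chain needs at least two adjacencies (n >= 2)")
  labs <- start$vertices
  i1 <- .gen_index(start, labs)
  mate <- i1$mate
  wv <- i1$w
  n_u <- integer(k + 1L); n_b <- integer(k + 1L); cc <- integer(k + 1L)
  n_u[1L] <- 0L; n_b[1L] <- n; cc[1L] <- n
  for (step in seq_len(k)) {
    st <- .step_index(mate, wv)
    mate <- st$mate; wv <- st$w
    d <- bg_decompose_cpp(i1$mate, mate, i1$w, wv)
    imb <- d$w1 - d$w2
    n_u[step + 1L] <- sum(imb != 0)
    n_b[step + 1L] <- sum(imb == 0)
    cc[step + 1L] <- d$n_cycles
  }
  out <- data.frame(k = 0:k, n_u = n_u, n_b = n_b, c = cc,
                    bound = (0:k) / sqrt(n))
  attr(out, "n") <- n
  class(out) <- c("wdcj_trajectory", "data.frame")
  out
}

#' Sample a genome from the chain's equilibrium distribution
#'
#' At equilibrium a genome has probability proportional to the product of
#' its intergene sizes; equivalently, the matching is uniform and the
#' normalised weight vector follows a symmetric Dirichlet law with
#' concentration 2.  The sampler draws a uniform perfect matching of `2n`
#' labelled extremities, draws `n` independent Gamma(shape 2, scale 1)
#' variates, scales them to total `total_weight` and rounds by largest
#' remainder so the total is met exactly.
#'
#' @param n number of adjacencies.
#' @param total_weight total intergene size `W` (non-negative integer).
#' @param seed optional integer seed.
#' @return a [genome()] on vertices `v1..v<2n>` (zero-padded labels).
#' @export
sample_equilibrium_genome <- function(n, total_weight, seed = NULL) {
  stopifnot(n >= 1, total_weight >= 0, total_weight == floor(total_weight))
  if (!is.null(seed)) set.seed(seed)
  labs <- sprintf("v%0*d", nchar(2L * n), seq_len(2L * n))
  perm <- sample(2L * n)
  u <- labs[perm[seq(1L, 2L * n, by = 2L)]]
  v <- labs[perm[seq(2L, 2L * n, by = 2L)]]
  if (n == 1L) {
    w <- total_weight
  } else {
    gam <- rgamma(n, shape = 2, scale = 1)
    tgt <- gam / sum(gam) * total_weight
    w <- floor(tgt)
    need <- total_weight - sum(w)
    if (need > 0) {
      add <- order(tgt - w, decreasing = TRUE)[seq_len(need)]
      w[add] <- w[add] + 1
    }
  }
  genome(data.frame(u = u, v = v, w = w, stringsAsFactors = FALSE))
}

#' Maximum-likelihood concentration of a symmetric Dirichlet law
#'
#' Fits the one-parameter symmetric Dirichlet(alpha) to vectors of
#' normalised intergene sizes by Newton iteration on the concave
#' log-likelihood (gradient `N d [digamma(d a) - digamma(a)] + S` with
#' `S` the total log of all coordinates).
#'
#' @param x a matrix (rows = samples, columns = the `d >= 2` normalised
#'   weights, each row summing to 1) or a list of such vectors.
#' @param tol Newton convergence tolerance on the gradient step.
#' @param max_iter iteration cap.
#' @return the MLE of alpha.  Vectors containing zero coordinates are
#'   dropped with a warning (the likelihood is degenerate there);
#'   variance-free input (all rows uniform) yields `Inf` with a warning.
#' @export
fit_dirichlet_alpha <- function(x, tol = 1e-8, max_iter = 200L) {
  if (is.list(x)) x <- do.call(rbind, x)
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  if (any(x < 0)) stop_input("normalised weights must be non-negative")
  if (any(abs(rowSums(x) - 1) > 1e-6))
    stop_input("each weight vector must sum to 1")
  bad <- apply(x, 1L, function(r) any(r == 0))
  if (any(bad)) {
    warning(sprintf("dropping %d weight vector(s) with zero coordinates (degenerate likelihood)",
                    sum(bad)))
    x <- x[!bad, , drop = FALSE]
    if (nrow(x) == 0L) stop_input("no usable weight vectors left")
  }
  d <- ncol(x)
  N <- nrow(x)
  S <- sum(log(x))
  if (var(as.vector(x)) < .Machine$double.eps) {
    warning("uniform weight vectors: the Dirichlet MLE diverges upward")
    return(Inf)
  }
  # moment start: Var(x_j) = (d-1) / (d^2 (d a + 1))
  vbar <- mean(apply(x, 2L, var))
  alpha <- if (is.finite(vbar) && vbar > 0)
    max(((d - 1) / (d^2 * vbar) - 1) / d, 1e-3) else 1
  for (it in seq_len(max_iter)) {
    grad <- N * d * (digamma(d * alpha) - digamma(alpha)) + S
    hess <- N * d * (d * trigamma(d * alpha) - trigamma(alpha))
    step <- grad / hess
    new <- alpha - step
    while (new <= 0) {
      step <- step / 2
      new <- alpha - step
    }
    if (abs(new - alpha) < tol * max(1, alpha)) {
      alpha <- new
      break
    }
    alpha <- new
  }
  alpha
}

#' Detailed-balance ratio of the equilibrium law on one transition
#'
#' For two genomes one wDCJ apart, returns
#' `Pi(g_a) P(g_a -> g_b) / (Pi(g_b) P(g_b -> g_a))` with
#' `Pi(g)` proportional to the product of edge weights and the transition
#' probability computed by exact enumeration of the `(x, y)` draws.  The
#' equilibrium argument makes the ratio approach 1 as the four involved
#' weights grow (the discrete boundary terms vanish).
#'
#' @param g_a,g_b genomes differing by exactly one wDCJ, with strictly
#'   positive weights on the four involved edges.
#' @return the ratio (a positive number).
#' @export
stationarity_ratio_check <- function(g_a, g_b) {
  stopifnot(inherits(g_a, "wdcj_genome"), inherits(g_b, "wdcj_genome"))
  if (!identical(g_a$vertices, g_b$vertices))
    stop_input("genomes must share a vertex set")
  key <- function(g) paste(g$edges$u, g$edges$v, g$edges$w, sep = "\r")
  ka <- key(g_a); kb <- key(g_b)
  only_a <- g_a$edges[!(ka %in% kb), , drop = FALSE]
  only_b <- g_b$edges[!(kb %in% ka), , drop = FALSE]
  if (nrow(only_a) != 2L || nrow(only_b) != 2L ||
      !setequal(c(only_a$u, only_a$v), c(only_b$u, only_b$v)))
    stop_input("genomes must differ by exactly one wDCJ (two rewired adjacencies)")
  W1 <- only_a$w[1L]; W2 <- only_a$w[2L]
  T1 <- only_b$w[1L]; T2 <- only_b$w[2L]
  if (min(W1, W2, T1, T2) <= 0)
    stop_input("the four involved adjacencies must have positive weights")
  # number of (x, y) draws with x in 0..wa, y in 0..wb and x + y = t
  ncomb <- function(t, wa, wb) max(0, min(wa, t) - max(0, t - wb) + 1)
  p_w <- function(wa, wb, t1, t2)
    (ncomb(t1, wa, wb) + ncomb(t2, wa, wb)) / (2 * (wa + 1) * (wb + 1))
  # shared edges and the uniform pair/type choices cancel in the ratio
  (W1 * W2 * p_w(W1, W2, T1, T2)) / (T1 * T2 * p_w(T1, T2, W1, W2))
}
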
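#' Construct a weighted genome
#'
#' A genome on `2n` gene extremities is a perfect matching with `n` edges
#' (gene adjacencies); the weight of an edge is the intergene size in
#' nucleotides, a non-negative integer.  Edges are stored canonically: each
#' unordered pair with its byte-order (C locale) smaller label first, rows
#' sorted by first label, so that two genomes are equal iff their edge
#' tables are identical.
#'
#' @param edges a data frame (or list) with columns `u`, `v` (vertex
#'   labels, character) and `w` (non-negative integer weights).
#' @param name optional genome name, used when writing `.wadj` files.
#' @return an object of class `wdcj_genome` with elements `edges`
#'   (canonical data frame), `vertices` (sorted labels) and `name`.
#' @examples
#' g <- genome(data.frame(u = c("1", "3"), v = c("2", "4"), w = c(3, 1)))
#' total_weight(g)
#' @export
genome <- function(edges, name = NULL) {
  u <- as.character(edges$u)
  v <- as.character(edges$v)
  w <- edges$w
  if (length(u) == 0L) stop_input("a genome needs at least one adjacency")
  if (length(u) != length(v) || length(u) != length(w))
    stop_input("u, v and w must have equal length")
  if (anyNA(u) || anyNA(v) || anyNA(w))
    stop_input("missing values in genome edges")
  if (!is.numeric(w) || any(!is.finite(w)) || any(w < 0) || any(w != floor(w)))
    stop_input("edge weights must be non-negative integers")
  if (any(u == v))
    stop_input("matching violation: self-loop adjacency (u == v)")
  labs <- sort(c(u, v), method = "radix")
  if (anyDuplicated(labs))
    stop_input("matching violation: a vertex is covered by more than one adjacency")
  iu <- match(u, labs)
  iv <- match(v, labs)
  swap <- iu > iv
  uu <- ifelse(swap, v, u)
  vv <- ifelse(swap, u, v)
  ord <- order(pmin(iu, iv))
  ed <- data.frame(u = uu[ord], v = vv[ord], w = as.numeric(w)[ord],
                   stringsAsFactors = FALSE)
  rownames(ed) <- NULL
  structure(list(edges = ed, vertices = labs, name = name),
            class = "wdcj_genome")
}

#' @export
print.wdcj_genome <- function(x, ...) {
  cat(sprintf("wdcj genome%s: %d adjacencies on %d extremities, total intergene size %s\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$edges), length(x$vertices),
              format(total_weight(x), scientific = FALSE)))
  print(utils::head(x$edges, 10L))
  if (nrow(x$edges) > 10L) cat("...\n")
  invisible(x)
}

#' Total intergene size of a genome
#'
#' @param g a [genome()].
#' @return the sum of all edge weights, `W(g)`.
#' @export
total_weight <- function(g) {
  stopifnot(inherits(g, "wdcj_genome"))
  sum(g$edges$w)
}

#' Test two genomes for equality (same matching, same weights)
#'
#' @param g1,g2 genomes.
#' @return `TRUE` iff the canonical edge tables agree.
#' @export
genomes_equal <- function(g1, g2) {
  identical(g1$edges$u, g2$edges$u) &&
    identical(g1$edges$v, g2$edges$v) &&
    isTRUE(all.equal(g1$edges$w, g2$edges$w))
}

# integer-index view of a genome on a fixed sorted label vector:
# mate[i] = partner vertex, w[i] = weight of the incident edge
.gen_index <- function(g, labs) {
  iu <- match(g$edges$u, labs)
  iv <- match(g$edges$v, labs)
  if (anyNA(iu) || anyNA(iv))
    stop_input("genome vertices do not match the reference vertex set")
  mate <- integer(length(labs))
  wv <- numeric(length(labs))
  mate[iu] <- iv
  mate[iv] <- iu
  wv[iu] <- g$edges$w
  wv[iv] <- g$edges$w
  list(mate = mate, w = wv)
}

# rebuild a genome from an integer-index view
.gen_from_index <- function(mate, wv, labs, name = NULL) {
  i <- which(seq_along(mate) < mate)
  genome(data.frame(u = labs[i], v = labs[mate[i]], w = wv[i],
                    stringsAsFactors = FALSE), name = name)
}

.mate_of <- function(g, vertex) {
  ed <- g$edges
  i <- which(ed$u == vertex)
  if (length(i)) return(list(mate = ed$v[i[1L]], w = ed$w[i[1L]]))
  i <- which(ed$v == vertex)
  if (!length(i)) stop_input(sprintf("vertex '%s' not in genome", vertex))
  list(mate = ed$u[i[1L]], w = ed$w[i[1L]])
}

#' Validate two genomes as a comparable pair
#'
#' Two genomes are comparable when they live on the same vertex set and are
#' evenly weighted, `W(g1) = W(g2)`; the wDCJ distance is only defined in
#' that case (the total intergene size is conserved by every wDCJ).
#'
#' @param g1,g2 genomes.
#' @return an object of class `wdcj_pair` with elements `g1`, `g2`,
#'   `vertices` and `n` (adjacencies per genome).
#' @export
genome_pair <- function(g1, g2) {
  stopifnot(inherits(g1, "wdcj_genome"), inherits(g2, "wdcj_genome"))
  if (!identical(g1$vertices, g2$vertices))
    stop_input("vertex-set mismatch: the genomes are not defined on the same extremities")
  if (total_weight(g1) != total_weight(g2))
    stop_input(sprintf("weight-sum mismatch: W(g1) = %s but W(g2) = %s",
                       format(total_weight(g1)), format(total_weight(g2))))
  structure(list(g1 = g1, g2 = g2, vertices = g1$vertices,
                 n = nrow(g1$edges)),
            class = "wdcj_pair")
}

#' @export
print.wdcj_pair <- function(x, ...) {
  cat(sprintf("wdcj genome pair: n = %d adjacencies, W = %s\n", x$n,
              format(total_weight(x$g1), scientific = FALSE)))
  invisible(x)
}

.parse_wadj_lines <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  genomes <- list()
  cur <- NULL
  name <- NULL
  flush <- function() {
    if (is.null(name)) return()
    if (is.null(cur))
      stop_input(sprintf("genome block '%s' has no adjacencies", name))
    genomes[[length(genomes) + 1L]] <<- genome(cur, name = name)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      name <- trimws(sub("^>", "", ln))
      cur <- NULL
    } else {
      if (is.null(name))
        stop_input("adjacency line before any '>name' block header")
      tok <- strsplit(ln, "[ \t]+")[[1L]]
      if (length(tok) != 3L)
        stop_input(sprintf("malformed adjacency line: '%s'", ln))
      w <- suppressWarnings(as.numeric(tok[3L]))
      if (is.na(w) || w < 0 || w != floor(w) || grepl("[^0-9]", tok[3L]))
        stop_input(sprintf("weight must be a non-negative integer: '%s'", tok[3L]))
      cur <- rbind(cur, data.frame(u = tok[1L], v = tok[2L], w = w,
                                   stringsAsFactors = FALSE))
    }
  }
  flush()
  genomes
}

#' Read genomes from a weighted-adjacency (.wadj) file
#'
#' The `.wadj` format is tab- or space-separated text: `#` starts a
#' comment, `>name` starts a genome block, and each following line is
#' `u v w` with `w` a non-negative base-10 integer intergene size.
#'
#' @param file path or connection.
#' @return a list of [genome()] objects, one per block.
#' @export
read_wadj <- function(file) {
  .parse_wadj_lines(readLines(file))
}

#' Write genomes to a weighted-adjacency (.wadj) file
#'
#' Edges are emitted in canonical order, so `read_wadj(write_wadj(g))`
#' round-trips bit-exactly.
#'
#' @param genomes a genome or list of genomes.
#' @param file path or connection; omit to get the lines invisibly.
#' @return the character vector of lines, invisibly.
#' @export
write_wadj <- function(genomes, file = NULL) {
  if (inherits(genomes, "wdcj_genome")) genomes <- list(genomes)
  lines <- character(0)
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    stopifnot(inherits(g, "wdcj_genome"))
    nm <- if (!is.null(g$name)) g$name else sprintf("g%d", i)
    lines <- c(lines, paste0(">", nm),
               sprintf("%s\t%s\t%s", g$edges$u, g$edges$v,
                       format(g$edges$w, scientific = FALSE, trim = TRUE)))
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Construct a circular gene order with intergene sizes
#'
#' @param chromosomes a list; each element describes one circular
#'   chromosome either as a string of alternating signed genes and
#'   intergene sizes (`"+a 5 -b 7"`, the size following each gene in
#'   circular order) or as a data frame with columns `gene`, `sign`
#'   (+1/-1) and `intergene`.
#' @return an object of class `wdcj_gene_order`.
#' @export
gene_order <- function(chromosomes) {
  if (!is.list(chromosomes)) chromosomes <- as.list(chromosomes)
  chrs <- lapply(chromosomes, function(ch) {
    if (is.character(ch) && length(ch) == 1L) {
      tok <- strsplit(trimws(ch), "[ \t]+")[[1L]]
      if (length(tok) == 0L || length(tok) %% 2L != 0L)
        stop_input("gene-order tokens must alternate signed gene and intergene size")
      genes <- tok[seq(1L, length(tok), by = 2L)]
      sizes <- tok[seq(2L, length(tok), by = 2L)]
      sgn <- ifelse(startsWith(genes, "-"), -1L,
                    ifelse(startsWith(genes, "+"), 1L, NA_integer_))
      if (anyNA(sgn)) stop_input("genes must be signed, e.g. '+a' or '-b'")
      w <- suppressWarnings(as.numeric(sizes))
      if (anyNA(w) || any(w < 0) || any(w != floor(w)))
        stop_input("intergene sizes must be non-negative integers")
      ch <- data.frame(gene = substring(genes, 2L), sign = sgn,
                       intergene = w, stringsAsFactors = FALSE)
    }
    stopifnot(is.data.frame(ch),
              all(c("gene", "sign", "intergene") %in% names(ch)))
    if (nrow(ch) < 1L) stop_input("each chromosome needs at least one gene")
    ch
  })
  genes <- unlist(lapply(chrs, `[[`, "gene"))
  if (anyDuplicated(genes))
    stop_input("each gene must appear exactly once across all chromosomes")
  structure(list(chromosomes = chrs), class = "wdcj_gene_order")
}

#' Read a circular gene order (.wgo) file as one genome description
#'
#' Each chromosome is a `>chrName circular` header followed by one line of
#' alternating signed genes and intergene sizes.  Only circular
#' chromosomes are supported; co-tailed linear genomes must be given
#' directly in the matching (`.wadj`) representation.
#'
#' @param file path or connection.
#' @return a [gene_order()] object.
#' @export
read_wgo <- function(file) {
  lines <- sub("#.*$", "", readLines(file))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  chroms <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">"))
      stop_input("expected '>chrName circular' header")
    hdr <- strsplit(sub("^>", "", lines[i]), "[ \t]+")[[1L]]
    if (length(hdr) < 2L || hdr[2L] != "circular")
      stop_input("only circular chromosomes are supported in .wgo input")
    if (i + 1L > length(lines))
      stop_input("chromosome header without gene line")
    chroms[[length(chroms) + 1L]] <- lines[i + 1L]
    i <- i + 2L
  }
  gene_order(chroms)
}

#' Convert a circular gene order to its matching representation
#'
#' Each gene `g` contributes a tail extremity `g_t` and a head extremity
#' `g_h`.  Read left to right, `+g` traverses `(g_t, g_h)` and `-g`
#' traverses `(g_h, g_t)`; an adjacency joins the trailing extremity of
#' each gene to the leading extremity of its circular successor, weighted
#' by the intergene size between them.
#'
#' @param go a [gene_order()].
#' @return a [genome()] with one edge per gene.
#' @export
gene_order_to_genome <- function(go) {
  stopifnot(inherits(go, "wdcj_gene_order"))
  u <- character(0); v <- character(0); w <- numeric(0)
  for (ch in go$chromosomes) {
    k <- nrow(ch)
    lead <- ifelse(ch$sign > 0, paste0(ch$gene, "_t"), paste0(ch$gene, "_h"))
    trail <- ifelse(ch$sign > 0, paste0(ch$gene, "_h"), paste0(ch$gene, "_t"))
    nxt <- c(seq_len(k)[-1L], 1L)
    u <- c(u, trail)
    v <- c(v, lead[nxt])
    w <- c(w, ch$intergene)
  }
  genome(data.frame(u = u, v = v, w = w, stringsAsFactors = FALSE))
}
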
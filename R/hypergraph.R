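#' Hypergraphs
#'
#' A hypergraph is a node count `n` plus hyperedge lists grouped by size:
#' `edges[["2"]]` is a 2-by-E integer matrix of links, `edges[["3"]]` a
#' 3-by-E matrix of triangles, and so on. Node ids are 1-based integers.
#' Triangles are *not* required to have their pairwise links present — this
#' is a hypergraph model, not a simplicial complex. Duplicate hyperedges are
#' permitted and retained; each one is an independent contagion channel.
#'
#' @param edges a list of integer vectors (one hyperedge each, any sizes),
#'   or a list of m-by-E integer matrices named by size.
#' @param n node count; defaults to the largest id seen.
#' @return a `hypergraph` object.
#' @export
hypergraph <- function(edges = list(), n = NULL) {
  by_size <- list()
  if (length(edges)) {
    if (all(vapply(edges, is.matrix, logical(1)))) {
      for (em in edges) {
        storage.mode(em) <- "integer"
        if (ncol(em) > 0 && nrow(em) > 1) {
          em <- apply(em, 2, sort)          # canonical member order
        }
        by_size[[as.character(nrow(em))]] <- em
      }
    } else {
      sizes <- lengths(edges)
      if (any(sizes < 2L)) stop("hyperedges must have size >= 2", call. = FALSE)
      for (m in sort(unique(sizes))) {
        by_size[[as.character(m)]] <-
          vapply(edges[sizes == m], function(e) sort(as.integer(e)),
                 integer(m))
      }
    }
  }
  max_id <- 0L
  for (em in by_size) if (length(em)) max_id <- max(max_id, max(em))
  n <- as.integer(n %||% max_id)
  validate_hypergraph(structure(list(n = n, edges = by_size),
                                class = "hypergraph"))
}

validate_hypergraph <- function(h) {
  stopifnot(h$n >= 0)
  for (m_chr in names(h$edges)) {
    em <- h$edges[[m_chr]]
    m <- as.integer(m_chr)
    if (nrow(em) != m) stop("edge matrix row count must equal its size")
    if (ncol(em) > 0) {
      if (min(em) < 1L || max(em) > h$n) {
        stop("hyperedge node ids must lie in 1..n", call. = FALSE)
      }
      dup <- apply(em, 2, anyDuplicated) > 0
      if (any(dup)) {
        stop("hyperedge members must be distinct (edge ",
             which(dup)[1], " of size ", m, ")", call. = FALSE)
      }
    }
  }
  h
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("<hypergraph> %d nodes\n", x$n))
  for (m in names(x$edges)) {
    cat(sprintf("  size-%s hyperedges: %d\n", m, ncol(x$edges[[m]])))
  }
  invisible(x)
}

#' @export
as_tibble.hypergraph <- function(x, ...) {
  purrr::map_dfr(names(x$edges), function(m_chr) {
    em <- x$edges[[m_chr]]
    tibble::tibble(
      size = as.integer(m_chr),
      edge = seq_len(ncol(em)),
      nodes = lapply(seq_len(ncol(em)), function(j) em[, j])
    )
  })
}

#' Hyperdegrees and the counting identity
#'
#' `hyperdegree()` returns per-node counts \eqn{k^{(m)}} of size-m hyperedges;
#' `mean_hyperdegree()` returns their mean, which by the edge-counting
#' identity equals \eqn{m |E_m| / n} exactly.
#'
#' @param h a `hypergraph`.
#' @param m hyperedge size.
#' @return `hyperdegree()`: integer vector of length `n`;
#'   `mean_hyperdegree()`: a single number.
#' @export
hyperdegree <- function(h, m) {
  stopifnot(inherits(h, "hypergraph"))
  em <- h$edges[[as.character(m)]]
  if (is.null(em)) return(integer(h$n) * 0L)
  tabulate(as.vector(em), nbins = h$n)
}

#' @rdname hyperdegree
#' @export
mean_hyperdegree <- function(h, m) {
  if (h$n == 0L) return(0)
  sum(hyperdegree(h, m)) / h$n
}

#' Sample random hypergraphs with prescribed wiring statistics
#'
#' `sample_links()` draws size-2 edges so that the probability that nodes of
#' degree k and k' are linked is k k'/(n<k>), as in the configuration model.
#' The default `"weighted"` method fixes the edge count at round(n<k>/2) and
#' draws endpoint pairs proportional to degree (matching the connection
#' probability in expectation with no multi-edge cleanup); `"stub"` performs
#' classical stub matching, reproducing the degree sequence exactly (an odd
#' stub total is padded by one stub, with a message).
#'
#' `sample_triangles()` draws round(n*mean_q/3) size-3 hyperedges. Under
#' `"correlated"` wiring the three members are drawn proportional to their
#' link degree (probability of a given triple proportional to k k1 k2);
#' under `"uncorrelated"` wiring members are drawn uniformly. Members within
#' a hyperedge are distinct; duplicate hyperedges may occur and are kept.
#'
#' `sample_hyperedges()` generalises the correlated rule to any sizes:
#' for each size m it draws round(n*mean_km/m) hyperedges with members
#' proportional to degree, so a node's expected size-m hyperdegree is
#' proportional to its degree with mean `mean_km`.
#'
#' @param degrees integer degree sequence (one entry per node).
#' @param mean_q target mean number of triangles per node.
#' @param wiring `"correlated"` or `"uncorrelated"`.
#' @param sizes integer vector of hyperedge sizes (each >= 2).
#' @param mean_km numeric vector, target mean hyperdegree per size.
#' @param seed optional integer seed.
#' @param method link generation method.
#' @return a `hypergraph` with the sampled edges.
#' @export
sample_links <- function(degrees, seed = NULL,
                         method = c("weighted", "stub")) {
  method <- match.arg(method)
  n <- length(degrees)
  if (n == 0L) stop("empty degree sequence", call. = FALSE)
  if (sum(degrees) == 0) {
    return(hypergraph(list(`2` = matrix(integer(), 2, 0)), n = n))
  }
  with_seed(seed, {
    if (method == "stub") {
      stubs <- rep.int(seq_len(n), degrees)
      if (length(stubs) %% 2L == 1L) {
        message("odd stub total; padding with one extra stub")
        stubs <- c(stubs, sample.int(n, 1L))
      }
      stubs <- sample(stubs)
      em <- matrix(stubs, nrow = 2L)
      # repair self-loops by swapping one stub with a random other edge
      # (degree-preserving); drop stragglers if the repair cannot converge
      for (iter in 1:50) {
        loops <- which(em[1, ] == em[2, ])
        if (!length(loops)) break
        for (j in loops) {
          r <- sample.int(ncol(em), 1L)
          tmp <- em[2L, j]; em[2L, j] <- em[2L, r]; em[2L, r] <- tmp
        }
      }
      em <- em[, em[1, ] != em[2, ], drop = FALSE]
    } else {
      n_edges <- round(sum(degrees) / 2)
      em <- draw_tuples(n, 2L, n_edges, w = degrees)
    }
    hypergraph(list(`2` = em), n = n)
  })
}

#' @rdname sample_links
#' @export
sample_triangles <- function(degrees, wiring = c("correlated", "uncorrelated"),
                             mean_q, seed = NULL) {
  wiring <- match.arg(wiring)
  n <- length(degrees)
  if (n < 3L) stop("need at least 3 nodes to form triangles", call. = FALSE)
  if (mean_q < 0) stop("`mean_q` must be non-negative", call. = FALSE)
  n_tri <- round(n * mean_q / 3)
  with_seed(seed, {
    w <- if (wiring == "correlated") degrees else rep(1, n)
    em <- draw_tuples(n, 3L, n_tri, w = w)
    hypergraph(list(`3` = em), n = n)
  })
}

#' @rdname sample_links
#' @export
sample_hyperedges <- function(degrees, sizes, mean_km, seed = NULL) {
  n <- length(degrees)
  stopifnot(length(sizes) == length(mean_km))
  if (any(sizes < 2L)) stop("hyperedge sizes must be >= 2", call. = FALSE)
  if (any(sizes > n)) {
    stop("hyperedge size exceeds the number of nodes", call. = FALSE)
  }
  with_seed(seed, {
    mats <- purrr::map2(sizes, mean_km, function(m, km) {
      draw_tuples(n, as.integer(m), round(n * km / m), w = degrees)
    })
    names(mats) <- as.character(sizes)
    hypergraph(mats, n = n)
  })
}

# draw `count` m-tuples of distinct nodes with per-node weight w;
# vectorised draw-with-replacement, redrawing tuples with repeated members
draw_tuples <- function(n, m, count, w) {
  if (count == 0L) return(matrix(integer(), m, 0))
  if (all(w == 0)) w <- rep(1, n)
  em <- matrix(sample_weighted(n, m * count, w), nrow = m)
  for (iter in 1:100) {
    bad <- which(apply_dup(em))
    if (!length(bad)) break
    em[, bad] <- matrix(sample_weighted(n, m * length(bad), w), nrow = m)
  }
  if (length(which(apply_dup(em)))) {
    stop("could not draw distinct-member hyperedges; weights too concentrated",
         call. = FALSE)
  }
  matrix(as.integer(em), nrow = m)
}

apply_dup <- function(em) {
  if (nrow(em) == 2L) em[1, ] == em[2, ]
  else apply(em, 2, anyDuplicated) > 0
}

#' Combine hypergraphs on the same node set
#'
#' Merges the edge lists of several hypergraphs (e.g. a link layer and a
#' triangle layer) into one.
#'
#' @param ... `hypergraph` objects with identical `n`.
#' @return a `hypergraph`.
#' @export
merge_hypergraphs <- function(...) {
  hs <- list(...)
  stopifnot(length(hs) > 0, all(vapply(hs, inherits, logical(1), "hypergraph")))
  n <- unique(vapply(hs, function(h) h$n, integer(1)))
  if (length(n) != 1L) stop("hypergraphs must share the node count", call. = FALSE)
  edges <- list()
  for (h in hs) {
    for (m in names(h$edges)) {
      edges[[m]] <- if (is.null(edges[[m]])) h$edges[[m]] else
        cbind(edges[[m]], h$edges[[m]])
    }
  }
  hypergraph(edges[order(as.integer(names(edges)))], n = n)
}
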
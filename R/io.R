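#' Read and write hyperedge lists
#'
#' The hyperedge-list text format: one hyperedge per line, whitespace-
#' separated 0-based integer node ids; lines starting with `#` are comments;
#' an optional first non-comment line `N <count>` declares the node count
#' (needed when isolated nodes exist). Reader and writer round-trip exactly.
#' Node ids are converted to the package's internal 1-based convention on
#' read.
#'
#' @param path file path.
#' @param h a `hypergraph`.
#' @return `read_hyperedge_list()`: a `hypergraph`;
#'   `write_hyperedge_list()`: `path`, invisibly.
#' @export
read_hyperedge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  n_declared <- NULL
  edges <- list()
  seen_edge <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (!seen_edge && is.null(n_declared) && identical(toks[1], "N")) {
      n_declared <- as.integer(toks[2])
      if (is.na(n_declared)) {
        stop("line ", i, ": malformed N declaration", call. = FALSE)
      }
      next
    }
    ids <- suppressWarnings(as.integer(toks))
    if (any(is.na(ids)) || any(as.numeric(toks) != ids)) {
      stop("line ", i, ": non-integer node id", call. = FALSE)
    }
    if (length(ids) < 2L) {
      stop("line ", i, ": hyperedge of size ", length(ids), call. = FALSE)
    }
    if (anyDuplicated(ids)) {
      stop("line ", i, ": duplicate node within a hyperedge", call. = FALSE)
    }
    if (any(ids < 0L)) stop("line ", i, ": negative node id", call. = FALSE)
    edges[[length(edges) + 1L]] <- ids + 1L
    seen_edge <- TRUE
  }
  max_id <- if (length(edges)) max(unlist(edges)) else 0L
  hypergraph(edges, n = max(n_declared %||% 0L, max_id))
}

#' @rdname read_hyperedge_list
#' @export
write_hyperedge_list <- function(h, path) {
  stopifnot(inherits(h, "hypergraph"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("N %d", h$n), con)
  for (m in names(h$edges)) {
    em <- h$edges[[m]]
    if (ncol(em) > 0) {
      writeLines(apply(em - 1L, 2, paste, collapse = " "), con)
    }
  }
  invisible(path)
}

#' Write a result object as CSV
#'
#' Deterministic column order, header row, full double precision; identical
#' inputs produce byte-identical files.
#'
#' @param obj a result tibble (`fixed_points`, `sweep_result`,
#'   `phase_diagram`, `bistability_curve`, `sis_trajectory`, or any data
#'   frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  stopifnot(is.data.frame(obj))
  readr::write_csv(tibble::as_tibble(obj), path, progress = FALSE)
  invisible(path)
}

#' Seeded fixture hypergraphs
#'
#' Writes a preset hypergraph to `dir` as a hyperedge-list file and returns
#' its path. Presets:
#' \describe{
#'   \item{`"fig3"`}{N = 10000, truncated power-law degrees (exponent 4 on
#'     67..1000), configuration-model links plus uncorrelated triangles with
#'     mean triangle degree equal to the mean link degree.}
#'   \item{`"fig3-small"`}{the same recipe at N = 1000.}
#'   \item{`"regular-links"`}{k-regular link-only graph, k = 100, N = 2000
#'     (stub matching).}
#'   \item{`"toy-triangle"`}{3 nodes, one triangle, no links.}
#' }
#'
#' @param name preset id.
#' @param dir output directory.
#' @param seed integer seed.
#' @return path of the written file, invisibly; the `hypergraph` itself in
#'   attribute `"hypergraph"`.
#' @export
make_fixture <- function(name = c("fig3", "fig3-small", "regular-links",
                                  "toy-triangle"),
                         dir = tempdir(), seed = 1L) {
  name <- match.arg(name)
  h <- with_seed(seed, switch(name,
    "fig3" = fixture_powerlaw(10000L),
    "fig3-small" = fixture_powerlaw(1000L),
    "regular-links" = sample_links(rep(100L, 2000L), method = "stub"),
    "toy-triangle" = hypergraph(list(c(1L, 2L, 3L)), n = 3L)
  ))
  path <- file.path(dir, paste0(name, ".hyperedges"))
  write_hyperedge_list(h, path)
  out <- invisible(path)
  attr(out, "hypergraph") <- h
  out
}

fixture_powerlaw <- function(n) {
  d <- dist_preset("powerlaw-r4")
  degs <- sample_degrees(d, n)
  merge_hypergraphs(
    sample_links(degs),
    sample_triangles(degs, wiring = "uncorrelated", mean_q = mean(degs))
  )
}
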
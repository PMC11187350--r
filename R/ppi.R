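#' Protein-protein interactome container
#'
#' A `ppi_graph` wraps an undirected, unweighted [igraph::igraph] whose
#' vertices are uppercase gene symbols and whose edges are physical
#' (binding) interactions. Self-loops and duplicate edges are never stored;
#' counts of what was dropped at load time travel with the object in its
#' load report. All distances downstream are shortest-path hop counts.
#'
#' @param graph an igraph object (undirected, named vertices).
#' @param report list of load diagnostics (`n_lines`, `n_edges`,
#'   `n_self_loops`, `n_duplicates`).
#' @return an object of class `ppi_graph`.
#' @keywords internal
new_ppi_graph <- function(graph, report = list()) {
  stopifnot(igraph::is_igraph(graph))
  structure(list(graph = graph, report = report), class = "ppi_graph")
}

#' Build an interactome from a two-column edge table
#'
#' Symbols are uppercased and trimmed; self-loops and duplicate (unordered)
#' edges are removed and counted. Endpoints of removed self-loops remain as
#' isolated nodes.
#'
#' @param from,to character vectors of equal length giving edge endpoints.
#' @param drop_self_loops drop `A--A` edges (always counted; if `FALSE`
#'   they are still excluded from the edge set, as the invariants forbid
#'   loops, but the caller is warned).
#' @return a [new_ppi_graph()] object.
#' @export
ppi_from_edges <- function(from, to, drop_self_loops = TRUE) {
  stopifnot(length(from) == length(to))
  from <- toupper(trimws(as.character(from)))
  to <- toupper(trimws(as.character(to)))
  n_raw <- length(from)

  loop <- from == to
  n_loops <- sum(loop)
  if (n_loops > 0L && !drop_self_loops) {
    warning("self-loops are not representable in a ppi_graph; ",
            n_loops, " dropped regardless of drop_self_loops = FALSE")
  }
  nodes <- sort(unique(c(from, to)))
  from2 <- from[!loop]
  to2 <- to[!loop]
  # canonical unordered orientation, then dedup
  a <- pmin(from2, to2)
  b <- pmax(from2, to2)
  key <- paste(a, b, sep = "\t")
  dup <- duplicated(key)
  n_dup <- sum(dup)

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (any(!dup)) {
    g <- igraph::add_edges(g, rbind(a[!dup], b[!dup]))
  }
  new_ppi_graph(g, report = list(
    n_lines = n_raw,
    n_edges = igraph::ecount(g),
    n_self_loops = n_loops,
    n_duplicates = n_dup
  ))
}

#' Read an interactome edge list
#'
#' Parses a whitespace- or tab-separated two-column edge list. Lines
#' starting with `#` and blank lines are skipped; columns beyond the second
#' are ignored with a warning (the network is unweighted and undirected).
#'
#' @param path path to the edge-list file.
#' @param drop_self_loops see [ppi_from_edges()].
#' @return a `ppi_graph`; its `$report` records line, self-loop and
#'   duplicate counts.
#' @examples
#' tf <- tempfile()
#' writeLines(c("# toy", "A\tB", "B\tC", "C\tA"), tf)
#' g <- read_ppi_edgelist(tf)
#' ppi_nodes(g)
#' @export
read_ppi_edgelist <- function(path, drop_self_loops = TRUE) {
  if (!file.exists(path)) {
    stop_input("interactome file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(ppi_from_edges(character(), character()))
  }
  fields <- strsplit(trimws(lines[idx]), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- idx[which(nf < 2L)[1L]]
    stop_input("edge-list parse error: line ", bad, " has fewer than 2 fields")
  }
  if (any(nf > 2L)) {
    warning("edge list has extra columns on ", sum(nf > 2L),
            " line(s); treated as unweighted and undirected")
  }
  ppi_from_edges(vapply(fields, `[[`, "", 1L),
                 vapply(fields, `[[`, "", 2L),
                 drop_self_loops = drop_self_loops)
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("ppi_graph: ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges\n", sep = "")
  r <- x$report
  if (length(r)) {
    cat("  load report: ", r$n_self_loops %||% 0, " self-loop(s), ",
        r$n_duplicates %||% 0, " duplicate edge(s) dropped\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Node symbols of an interactome
#' @param g a `ppi_graph`.
#' @return character vector of gene symbols.
#' @export
ppi_nodes <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  igraph::V(g$graph)$name
}

#' Edge table of an interactome
#' @param g a `ppi_graph`.
#' @return two-column data.frame (`from`, `to`), canonically ordered.
#' @export
ppi_edges <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  el <- igraph::as_edgelist(g$graph)
  df <- data.frame(from = pmin(el[, 1], el[, 2]),
                   to = pmax(el[, 1], el[, 2]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}
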
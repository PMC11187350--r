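#' Map a gene set onto the interactome
#'
#' Splits a set's members into those present as network nodes and those
#' absent. No identifier translation is attempted: matching is exact on
#' the normalized (uppercase, trimmed) symbol.
#'
#' @param graph a `ppi_graph`.
#' @param genes a `gene_set` or character vector of symbols.
#' @return list with `mapped` and `dropped` character vectors
#'   (`mapped` and `dropped` partition the members).
#' @export
map_gene_set <- function(graph, genes) {
  members <- if (inherits(genes, "gene_set")) genes$members else
    unique(normalize_symbols(genes))
  nodes <- ppi_nodes(graph)
  inside <- members %in% nodes
  list(mapped = members[inside], dropped = members[!inside])
}

#' Hop distances from a set of source nodes
#'
#' Minimum shortest-path hop count from any source to every reachable
#' node (a multi-source breadth-first search). Sources map to 0;
#' unreachable nodes are absent from the result.
#'
#' @param graph a `ppi_graph`.
#' @param sources character vector of node symbols, non-empty, all present
#'   in the graph.
#' @return named integer vector of distances over reachable nodes.
#' @export
single_source_distances <- function(graph, sources) {
  if (length(sources) == 0L) stop_input("sources must be non-empty")
  nodes <- ppi_nodes(graph)
  if (!all(sources %in% nodes)) {
    stop_input("source(s) not in graph: ",
               paste(setdiff(sources, nodes), collapse = ", "))
  }
  d <- igraph::distances(graph$graph, v = sources, to = igraph::V(graph$graph))
  dmin <- apply(d, 2L, min)
  dmin <- dmin[is.finite(dmin)]
  stats::setNames(as.integer(dmin), names(dmin))
}

# Distance matrix restricted to two mapped node sets; rows = from, cols = to.
set_distances <- function(graph, from, to) {
  igraph::distances(graph$graph, v = from, to = to)
}

#' Directed closest distance between two mapped sets
#'
#' The average, over members of `Y` reachable from `X`, of the hop
#' distance to the nearest member of `X`. Members of `Y` unreachable from
#' every member of `X` are excluded from the average and counted.
#'
#' @param graph a `ppi_graph`.
#' @param X,Y non-empty character vectors of mapped node symbols (see
#'   [map_gene_set()]).
#' @return list with `value` (numeric, or `NA` when no member of `Y` is
#'   reachable) and `n_excluded`.
#' @export
closest_distance_directed <- function(graph, X, Y) {
  if (length(X) == 0L || length(Y) == 0L) {
    stop_input("X and Y must be non-empty mapped sets")
  }
  d <- set_distances(graph, X, Y)
  mins <- apply(d, 2L, min)
  reach <- is.finite(mins)
  value <- if (any(reach)) mean(mins[reach]) else NA_real_
  list(value = value, n_excluded = sum(!reach))
}

#' Internal closest distance of a mapped set
#'
#' Average, over members of `A`, of the hop distance to the nearest
#' *other* member of `A` (self excluded). Members with no reachable other
#' member are left out of the average; a singleton set has internal
#' distance 0 by convention (flagged via the `singleton` attribute);
#' a set whose members are mutually unreachable is undefined (`NA`).
#'
#' @param graph a `ppi_graph`.
#' @param A non-empty character vector of mapped node symbols.
#' @return numeric scalar (or `NA`); attribute `singleton` is `TRUE` for
#'   one-member sets.
#' @export
internal_distance <- function(graph, A) {
  if (length(A) == 0L) stop_input("A must be a non-empty mapped set")
  if (length(A) == 1L) {
    return(structure(0, singleton = TRUE))
  }
  d <- set_distances(graph, A, A)
  diag(d) <- Inf
  mins <- apply(d, 1L, min)
  reach <- is.finite(mins)
  if (!any(reach)) return(NA_real_)
  mean(mins[reach])
}

#' Network separation between a herb target set and a symptom gene set
#'
#' Computes the separation score `s_ab = d_ab - (d_aa + d_bb)/2`, where
#' `d_aa` and `d_bb` are the internal closest distances of the two sets
#' and `d_ab` their cross closest distance. Negative scores mean the two
#' sets occupy the same network neighborhood; positive scores mean they
#' are topologically separated.
#'
#' By default `d_ab` is symmetrized (average of nearest-cross-member
#' distances over members of both sets), which makes the score independent
#' of argument order. `directed = TRUE` instead averages only over members
#' of `B` of their distance to the nearest member of `A` (herb as source
#' set), the literal one-directional form.
#'
#' Degenerate inputs (unmapped sets, mutually unreachable sets) never
#' raise: the result carries `status = "undefined"` and `NA` fields so
#' batch runs always complete.
#'
#' @param graph a `ppi_graph`.
#' @param A herb target [gene_set()] (or character vector).
#' @param B symptom [gene_set()] (or character vector).
#' @param directed use the one-directional closest distance (A -> B).
#' @return object of class `separation_result`: fields `herb`, `symptom`,
#'   `d_ab`, `d_aa`, `d_bb`, `s_ab`, `n_mapped_a`, `n_mapped_b`,
#'   `n_unreachable`, `status`.
#' @examples
#' g <- ppi_from_edges(c("A", "B", "C", "D"), c("B", "C", "D", "E"))
#' separation(g, gene_set("herb", c("A", "B"), "herb_target"),
#'            gene_set("sym", c("D", "E")))
#' @export
separation <- function(graph, A, B, directed = FALSE) {
  name_a <- if (inherits(A, "gene_set")) A$name else "A"
  name_b <- if (inherits(B, "gene_set")) B$name else "B"
  ma <- map_gene_set(graph, A)
  mb <- map_gene_set(graph, B)
  res <- list(herb = name_a, symptom = name_b,
              d_ab = NA_real_, d_aa = NA_real_, d_bb = NA_real_,
              s_ab = NA_real_,
              n_mapped_a = length(ma$mapped),
              n_mapped_b = length(mb$mapped),
              n_unreachable = NA_integer_, status = "undefined")
  class(res) <- "separation_result"
  if (length(ma$mapped) == 0L || length(mb$mapped) == 0L) {
    res$n_unreachable <- 0L
    return(res)
  }
  d <- set_distances(graph, ma$mapped, mb$mapped)
  b_min <- apply(d, 2L, min)   # nearest herb member, per symptom gene
  a_min <- apply(d, 1L, min)   # nearest symptom gene, per herb member
  if (directed) {
    reach <- is.finite(b_min)
    res$n_unreachable <- sum(!reach)
    res$d_ab <- if (any(reach)) mean(b_min[reach]) else NA_real_
  } else {
    reach_b <- is.finite(b_min)
    reach_a <- is.finite(a_min)
    res$n_unreachable <- sum(!reach_a) + sum(!reach_b)
    n_terms <- sum(reach_a) + sum(reach_b)
    res$d_ab <- if (n_terms > 0L) {
      (sum(b_min[reach_b]) + sum(a_min[reach_a])) / n_terms
    } else NA_real_
  }
  res$d_aa <- as.numeric(internal_distance(graph, ma$mapped))
  res$d_bb <- as.numeric(internal_distance(graph, mb$mapped))
  if (!anyNA(c(res$d_ab, res$d_aa, res$d_bb))) {
    res$s_ab <- res$d_ab - (res$d_aa + res$d_bb) / 2
    res$status <- "ok"
  }
  res
}

#' @export
print.separation_result <- function(x, ...) {
  cat("separation ", x$herb, " ~ ", x$symptom, ": ", sep = "")
  if (x$status == "ok") {
    cat(sprintf("s_ab = %.5f (d_ab %.4f, d_aa %.4f, d_bb %.4f)\n",
                x$s_ab, x$d_ab, x$d_aa, x$d_bb))
  } else {
    cat("undefined\n")
  }
  invisible(x)
}

#' Genes shared by a herb target set and a symptom gene-set union
#'
#' Intersects a herb target set with the union of several symptom gene
#' sets; the result is alphabetically sorted.
#'
#' @param A a `gene_set` (herb targets) or character vector.
#' @param sets non-empty list of `gene_set` objects (or character vectors).
#' @return sorted character vector (possibly empty).
#' @export
overlap_genes <- function(A, sets) {
  if (length(sets) == 0L) stop_input("sets must be non-empty")
  members_a <- if (inherits(A, "gene_set")) A$members else
    unique(normalize_symbols(A))
  pool <- unique(unlist(lapply(sets, function(s) {
    if (inherits(s, "gene_set")) s$members else normalize_symbols(s)
  })))
  sort(intersect(members_a, pool))
}

#' Separation of one herb against many symptom gene sets
#'
#' Runs [separation()] for each symptom set, preserving input order.
#' Undefined pairs are reported, never fatal.
#'
#' @inheritParams separation
#' @param herb herb target `gene_set`.
#' @param symptom_sets list of symptom `gene_set` objects.
#' @return list of `separation_result`, one per symptom set.
#' @seealso [separation_table()] for the flat report.
#' @export
batch_separation <- function(graph, herb, symptom_sets, directed = FALSE) {
  lapply(symptom_sets, function(s) separation(graph, herb, s, directed))
}

#' Flatten separation results into a report table
#'
#' One row per herb-symptom pair; undefined metric fields are `NA` (written
#' as `-` by [write_results()]).
#'
#' @param results list of `separation_result` objects.
#' @return data.frame with columns `herb`, `symptom`, `d_ab`, `d_aa`,
#'   `d_bb`, `s_ab`, `n_mapped_a`, `n_mapped_b`, `status`.
#' @export
separation_table <- function(results) {
  if (inherits(results, "separation_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(herb = r$herb, symptom = r$symptom,
               d_ab = r$d_ab, d_aa = r$d_aa, d_bb = r$d_bb,
               s_ab = r$s_ab, n_mapped_a = r$n_mapped_a,
               n_mapped_b = r$n_mapped_b, status = r$status,
               stringsAsFactors = FALSE)
  }))
}
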
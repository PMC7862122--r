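## PPI topology: degree / betweenness / closeness centralities and the
## iterative greater-than-median hub screen.
##
## Conventions (matching Cytoscape NetworkAnalyzer, whose normalised values
## the printed thresholds of published screens fall in):
##   betweenness: Brandes accumulation, normalised by 2 / ((n-1)(n-2)) on
##     the current (sub)graph; graphs with n < 3 get all zeros.
##   closeness: reciprocal of the mean shortest-path distance to the nodes
##     reachable within the connected component; isolated nodes get 0.

as_ppi_graph <- function(g) {
  if (!igraph::is_igraph(g)) {
    validation_error("expected an igraph object")
  }
  if (igraph::is_directed(g)) {
    validation_error("PPI graph must be undirected")
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

#' Node degrees of a PPI graph
#'
#' @param g Undirected igraph object (loops and multi-edges are collapsed).
#' @return Named integer vector of incident-edge counts.
#' @export
compute_degree <- function(g) {
  g <- as_ppi_graph(g)
  d <- igraph::degree(g, loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' Normalised betweenness centrality
#'
#' Shortest-path betweenness (endpoints excluded, path multiplicities
#' weighted fractionally), normalised to `[0, 1]` by `2 / ((n-1)(n-2))`
#' where `n` is the node count of `g`.
#'
#' @param g Undirected igraph object.
#' @param normalized Divide by the number of node pairs (default).
#' @return Named numeric vector.
#' @export
compute_betweenness <- function(g, normalized = TRUE) {
  g <- as_ppi_graph(g)
  n <- igraph::vcount(g)
  if (n == 0L) return(setNames(numeric(0), character(0)))
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  if (normalized) {
    b <- if (n < 3L) b * 0 else 2 * b / ((n - 1) * (n - 2))
  }
  b
}

#' Component-wise closeness centrality
#'
#' Closeness of a node is the reciprocal of its mean shortest-path distance
#' to the nodes it can reach (its connected component); isolated nodes get
#' 0 by convention.  Values lie in `(0, 1]` for connected nodes.
#'
#' @param g Undirected igraph object.
#' @return Named numeric vector.
#' @export
compute_closeness <- function(g) {
  g <- as_ppi_graph(g)
  n <- igraph::vcount(g)
  if (n == 0L) return(setNames(numeric(0), character(0)))
  d <- igraph::distances(g, weights = NA)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0L) 0 else 1 / mean(di)
  }, numeric(1)) |> setNames(igraph::V(g)$name)
}

#' Per-node centrality table
#'
#' @param g Undirected igraph object.
#' @return data.frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`, one row per node.
#' @export
centrality_table <- function(g) {
  g <- as_ppi_graph(g)
  nodes <- igraph::V(g)$name
  data.frame(
    node = nodes,
    degree = unname(compute_degree(g)[nodes]),
    betweenness = unname(compute_betweenness(g)[nodes]),
    closeness = unname(compute_closeness(g)[nodes]),
    stringsAsFactors = FALSE
  )
}

#' Median thresholds of a centrality table
#'
#' The screening thresholds: the median of each of the three centralities
#' over the current node set (even node counts use the mean of the two
#' central order statistics).
#'
#' @param ct A [centrality_table()] data.frame.
#' @return Named numeric vector `c(degree, betweenness, closeness)`.
#' @export
median_thresholds <- function(ct) {
  if (!is.data.frame(ct) || nrow(ct) == 0L) {
    input_error("centrality table is empty")
  }
  c(degree = median(ct$degree),
    betweenness = median(ct$betweenness),
    closeness = median(ct$closeness))
}

#' One round of median-threshold hub screening
#'
#' Computes the three centralities on `g`, takes their medians as
#' thresholds, and keeps the nodes meeting all three (`>=` by default,
#' strict `>` with `inclusive = FALSE`).  Returns the survivors, the
#' thresholds used, the subgraph induced on the survivors and its edge
#' count.  If no node survives, an empty round is returned (flagged, not an
#' error).
#'
#' @param g Undirected igraph object with at least 2 nodes.
#' @param inclusive Threshold comparison: `>=` (default) or strict `>`.
#' @param round_index Label stored in the result.
#' @return A `screening_round` list: `round_index`, `thresholds`,
#'   `survivors`, `n_nodes`, `induced_edge_count`, `subgraph`, `empty`.
#' @export
screen_round <- function(g, inclusive = TRUE, round_index = 1L) {
  g <- as_ppi_graph(g)
  if (igraph::vcount(g) < 2L) {
    input_error("screening needs a graph with at least 2 nodes")
  }
  ct <- centrality_table(g)
  thr <- median_thresholds(ct)
  keep <- if (inclusive) {
    ct$degree >= thr[["degree"]] &
      ct$betweenness >= thr[["betweenness"]] &
      ct$closeness >= thr[["closeness"]]
  } else {
    ct$degree > thr[["degree"]] &
      ct$betweenness > thr[["betweenness"]] &
      ct$closeness > thr[["closeness"]]
  }
  survivors <- ct$node[keep]
  sub <- igraph::induced_subgraph(g, survivors)
  structure(
    list(
      round_index = as.integer(round_index),
      thresholds = thr,
      survivors = sort(survivors),
      n_nodes = length(survivors),
      induced_edge_count = as.integer(igraph::ecount(sub)),
      subgraph = sub,
      empty = length(survivors) == 0L
    ),
    class = "screening_round"
  )
}

#' @export
print.screening_round <- function(x, ...) {
  cat(sprintf(
    "Screening round %d: thresholds degree >= %g, betweenness >= %.8g, closeness >= %.8g\n",
    x$round_index, x$thresholds[["degree"]], x$thresholds[["betweenness"]],
    x$thresholds[["closeness"]]))
  cat(sprintf("  %d survivors, %d induced edges\n",
              x$n_nodes, x$induced_edge_count))
  invisible(x)
}

#' Iterative two-round (or until-stable) hub screening
#'
#' Applies [screen_round()] repeatedly, recomputing the centralities and
#' their medians on each induced subgraph (the thresholds therefore change
#' between rounds, as they do in published two-round screens).  Stops after
#' `rounds` rounds, or earlier when a round keeps every current node
#' (converged) and `until_stable` is set.  An all-eliminating round stops
#' the procedure with `converged = FALSE`.
#'
#' @param g Undirected igraph object.
#' @param rounds Maximum number of screening rounds.
#' @param inclusive Threshold comparison, see [screen_round()].
#' @param until_stable Stop early once a round eliminates nothing.
#' @return A `screening_result` list: `rounds` (list of `screening_round`),
#'   `final_hubs` (sorted node names), `final_graph`, `converged`.
#' @examples
#' g <- igraph::make_graph(~ a - b - c - d - e)
#' res <- iterative_screen(g, rounds = 2)
#' res$final_hubs
#' @export
iterative_screen <- function(g, rounds = 2L, inclusive = TRUE,
                             until_stable = FALSE) {
  if (!is_count(rounds)) input_error("rounds must be a positive integer")
  g <- as_ppi_graph(g)
  history <- list()
  current <- g
  converged <- FALSE
  for (i in seq_len(rounds)) {
    if (igraph::vcount(current) < 2L) break
    r <- screen_round(current, inclusive = inclusive, round_index = i)
    history[[i]] <- r
    if (r$empty) {
      converged <- FALSE
      current <- r$subgraph
      break
    }
    kept_all <- r$n_nodes == igraph::vcount(current)
    current <- r$subgraph
    if (kept_all) {
      converged <- TRUE
      if (until_stable) break
    } else {
      converged <- FALSE
    }
  }
  structure(
    list(
      rounds = history,
      final_hubs = sort(igraph::V(current)$name),
      final_graph = current,
      converged = converged
    ),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Iterative hub screening: %d round(s), %d final hubs%s\n",
              length(x$rounds), length(x$final_hubs),
              if (x$converged) " (converged)" else ""))
  for (r in x$rounds) print(r)
  invisible(x)
}

#' Write a centrality table and screening report to disk
#'
#' @param result A `screening_result` from [iterative_screen()].
#' @param g The graph the screen was run on (for the full first-round
#'   centrality table).
#' @param dir Output directory.
#' @return Invisibly, the paths written (`centrality_table.tsv`,
#'   `screening_report.json`, `hubs.txt`).
#' @export
write_screening_outputs <- function(result, g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ct <- centrality_table(as_ppi_graph(g))
  ct$betweenness <- sprintf("%.8f", ct$betweenness)
  ct$closeness <- sprintf("%.8f", ct$closeness)
  p1 <- write_tsv(ct, file.path(dir, "centrality_table.tsv"))
  report <- lapply(result$rounds, function(r) {
    list(round = r$round_index,
         degree_threshold = unname(r$thresholds[["degree"]]),
         betweenness_threshold = unname(r$thresholds[["betweenness"]]),
         closeness_threshold = unname(r$thresholds[["closeness"]]),
         n_survivors = r$n_nodes,
         induced_edge_count = r$induced_edge_count)
  })
  p2 <- file.path(dir, "screening_report.json")
  jsonlite::write_json(
    list(rounds = report, final_hubs = result$final_hubs,
         converged = result$converged),
    p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p3 <- write_lines(result$final_hubs, file.path(dir, "hubs.txt"))
  invisible(c(p1, p2, p3))
}
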
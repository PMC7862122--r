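## Compound-target (C-T) and compound-target-pathway (C-T-P) layered
## networks, plus export/import in Cytoscape-friendly formats.

#' Construct a layered network
#'
#' Validated container for the tripartite compound/target/pathway networks:
#' edges may only connect adjacent layers (compound-target, labelled
#' `targets`; target-pathway, labelled `member_of`), endpoints must exist,
#' and duplicate edges are forbidden.  Nodes and edges are kept sorted so
#' exports are deterministic.
#'
#' @param nodes data.frame with columns `id`, `layer` (one of `compound`,
#'   `target`, `pathway`).
#' @param edges data.frame with columns `from`, `to`, `relation` (may have
#'   zero rows).
#' @return Object of class `layered_network`.
#' @export
layered_network <- function(nodes, edges) {
  nodes <- data.frame(id = as.character(nodes$id),
                      layer = as.character(nodes$layer),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) validation_error("duplicate node ids")
  if (!all(nodes$layer %in% c("compound", "target", "pathway"))) {
    validation_error("layers must be compound, target or pathway")
  }
  if (nrow(edges) > 0L) {
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        relation = as.character(edges$relation),
                        stringsAsFactors = FALSE)
    miss <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(miss) > 0L) {
      validation_error(paste0("edge endpoint(s) not in node table: ",
                              paste(head(miss, 5L), collapse = ", ")))
    }
    layer_of <- setNames(nodes$layer, nodes$id)
    pair <- paste(layer_of[edges$from], layer_of[edges$to])
    ok <- pair %in% c("compound target", "target compound",
                      "target pathway", "pathway target")
    if (!all(ok)) {
      validation_error("edges must connect adjacent layers (compound-target or target-pathway)")
    }
    ## orient compound->target and target->pathway, then sort + dedupe
    flip <- pair %in% c("target compound", "pathway target")
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
    if (anyDuplicated(edges[, c("from", "to")])) {
      validation_error("duplicate edges are not allowed")
    }
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        relation = character(0), stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$layer, nodes$id), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "layered_network")
}

#' @export
print.layered_network <- function(x, ...) {
  tab <- table(factor(x$nodes$layer, c("compound", "target", "pathway")))
  cat(sprintf(
    "Layered network: %d compounds, %d targets, %d pathways; %d edges\n",
    tab[["compound"]], tab[["target"]], tab[["pathway"]], nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a layered network
#' @param net A [layered_network()].
#' @return Named integer vector over all nodes.
#' @export
network_degree <- function(net) {
  counts <- table(factor(c(net$edges$from, net$edges$to),
                         levels = net$nodes$id))
  setNames(as.integer(counts), net$nodes$id)
}

#' Build the compound-target network
#'
#' One node per compound and per target, one `targets` edge per
#' deduplicated association.  With `restrict_to`, only targets in that set
#' (e.g. the key-target hubs) are kept, so each compound's degree equals
#' its key-target count.
#'
#' @param associations data.frame with columns `compound_id`, `target_id`.
#' @param restrict_to Optional gene set to restrict targets to (`NULL`
#'   keeps all; an empty vector keeps none).
#' @param synonym_table Passed to [normalize_ids()].
#' @return A [layered_network()].
#' @export
build_ct_network <- function(associations, restrict_to = NULL,
                             synonym_table = NULL) {
  sets <- union_compound_targets(associations, synonym_table)$per_compound
  if (!is.null(restrict_to)) {
    allowed <- unique(normalize_ids(restrict_to, synonym_table))
    sets <- lapply(sets, intersect, allowed)
  }
  compounds <- names(sets)
  targets <- sort(unique(unlist(sets, use.names = FALSE)))
  edges <- do.call(rbind, lapply(compounds, function(cid) {
    if (length(sets[[cid]]) == 0L) return(NULL)
    data.frame(from = cid, to = sets[[cid]], relation = "targets",
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        relation = character(0))
  }
  layered_network(
    nodes = data.frame(
      id = c(compounds, targets),
      layer = c(rep("compound", length(compounds)),
                rep("target", length(targets))),
      stringsAsFactors = FALSE),
    edges = edges
  )
}

#' Extend a compound-target network with top enriched pathways
#'
#' Adds the `top_n` best-ranked enrichment terms as pathway nodes and a
#' `member_of` edge from every target node of `ct` belonging to the term.
#' Compound-target edges are unchanged.
#'
#' @param ct A compound-target [layered_network()].
#' @param enrichment Ranked [ora()] output (its `members` list-column
#'   supplies the term gene sets).
#' @param top_n Number of top-ranked terms to add; if it exceeds the
#'   available rows, all are used with a warning.
#' @return A [layered_network()] with the pathway layer added.
#' @export
build_ctp_network <- function(ct, enrichment, top_n = 10L) {
  if (!inherits(ct, "layered_network")) {
    validation_error("ct must be a layered_network")
  }
  if (top_n > nrow(enrichment)) {
    warning(sprintf("top_n = %d exceeds the %d available terms; using all",
                    top_n, nrow(enrichment)))
    top_n <- nrow(enrichment)
  }
  sel <- head(enrichment, top_n)
  targets <- ct$nodes$id[ct$nodes$layer == "target"]
  new_edges <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i) {
    hit <- intersect(sel$members[[i]], targets)
    if (length(hit) == 0L) return(NULL)
    data.frame(from = hit, to = sel$term_id[i], relation = "member_of",
               stringsAsFactors = FALSE)
  }))
  nodes <- rbind(ct$nodes,
                 data.frame(id = sel$term_id,
                            layer = rep("pathway", nrow(sel)),
                            stringsAsFactors = FALSE))
  edges <- ct$edges
  if (!is.null(new_edges)) edges <- rbind(edges, new_edges)
  layered_network(nodes, edges)
}

#' Write / read a PPI edge list as two-column TSV
#'
#' @param g Undirected igraph object.
#' @param path File path (`from`/`to` header; edges sorted).
#' @return `write_edge_tsv` invisibly returns `path`; `read_edge_tsv`
#'   returns an undirected igraph object.
#' @export
write_edge_tsv <- function(g, path) {
  g <- as_ppi_graph(g)
  el <- igraph::as_data_frame(g, what = "edges")
  el <- el[order(el$from, el$to), c("from", "to"), drop = FALSE]
  write_tsv(el, path)
}

#' @rdname write_edge_tsv
#' @export
read_edge_tsv <- function(path) {
  el <- read_tsv(path)
  if (!all(c("from", "to") %in% names(el))) {
    validation_error("edge TSV must have columns from and to")
  }
  ids <- sort(unique(c(el$from, el$to)))
  igraph::graph_from_data_frame(el[, c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = ids))
}

## ---- export / import ------------------------------------------------------

layered_to_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$id, layer = net$nodes$layer,
                          stringsAsFactors = FALSE))
}

igraph_to_layered <- function(g) {
  nodes <- data.frame(id = igraph::V(g)$name,
                      layer = igraph::V(g)$layer,
                      stringsAsFactors = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(from = el$from, to = el$to,
                      relation = if ("relation" %in% names(el)) el$relation
                                 else rep("targets", nrow(el)),
                      stringsAsFactors = FALSE)
  layered_network(nodes, edges)
}

#' Export a network for visualization tools
#'
#' Writes a [layered_network()] (or a plain undirected igraph) in one of
#' three interchange formats:
#'
#' * `"sif"` — Cytoscape simple interaction format
#'   (`source<TAB>relation<TAB>target`), plus a sidecar attribute table
#'   `<path>.attrs.tsv` (`id`, `layer`, `degree`) since SIF carries no
#'   attributes; isolated nodes are written as single-column lines.
#' * `"graphml"` — GraphML with the `layer` node attribute (via igraph).
#' * `"tsv"` — two-column edge list.
#'
#' Output is deterministic: nodes and edges are written sorted.
#'
#' @param net A [layered_network()] or undirected igraph object.
#' @param path Output file.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) validation_error(
                       "unknown format; use sif, graphml or tsv"))
  if (igraph::is_igraph(net)) {
    g <- as_ppi_graph(net)
    el <- igraph::as_data_frame(g, what = "edges")
    el <- el[order(el$from, el$to), , drop = FALSE]
    if (format == "sif") {
      lines <- character(0)
      if (nrow(el) > 0L) lines <- paste(el$from, "pp", el$to, sep = "\t")
      isolated <- setdiff(igraph::V(g)$name, c(el$from, el$to))
      write_lines(c(lines, sort(isolated)), path)
      nm <- sort(igraph::V(g)$name)
      write_tsv(data.frame(id = nm, layer = "protein",
                           degree = unname(igraph::degree(g)[nm]),
                           stringsAsFactors = FALSE),
                paste0(path, ".attrs.tsv"))
    } else if (format == "graphml") {
      igraph::write_graph(g, path, format = "graphml")
    } else {
      write_tsv(el[, c("from", "to")], path)
    }
    return(invisible(path))
  }
  if (!inherits(net, "layered_network")) {
    validation_error("net must be a layered_network or igraph object")
  }
  if (format == "sif") {
    lines <- character(0)
    if (nrow(net$edges) > 0L) {
      lines <- paste(net$edges$from, net$edges$relation, net$edges$to,
                     sep = "\t")
    }
    isolated <- setdiff(net$nodes$id, c(net$edges$from, net$edges$to))
    lines <- c(lines, sort(isolated))
    write_lines(lines, path)
    attrs <- data.frame(id = net$nodes$id, layer = net$nodes$layer,
                        degree = unname(network_degree(net)[net$nodes$id]),
                        stringsAsFactors = FALSE)
    write_tsv(attrs, paste0(path, ".attrs.tsv"))
  } else if (format == "graphml") {
    g <- layered_to_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_tsv(net$edges[, c("from", "to")], path)
  }
  invisible(path)
}

#' Import a network written by [export_graph()]
#'
#' SIF layers are reconstructed from the relation labels (`targets`:
#' compound-target; `member_of`: target-pathway) and the sidecar attribute
#' table when present; GraphML restores the stored `layer` attribute.
#'
#' @param path File to read.
#' @param format `"sif"` or `"graphml"`.
#' @return A [layered_network()] when the file carries layer information
#'   (`targets` / `member_of` relations or a `layer` attribute); otherwise
#'   a plain undirected igraph object.
#' @export
import_graph <- function(path, format = c("sif", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) validation_error(
                       "unknown format; use sif or graphml"))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if ("layer" %in% igraph::vertex_attr_names(g)) {
      return(igraph_to_layered(g))
    }
    return(as_ppi_graph(g))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_f <- vapply(fields, length, integer(1))
  if (any(!n_f %in% c(1L, 3L))) {
    validation_error("malformed SIF: lines must have 1 or 3 fields")
  }
  edges <- do.call(rbind, lapply(fields[n_f == 3L], function(f) {
    data.frame(from = f[1], to = f[3], relation = f[2],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        relation = character(0))
  }
  iso <- unlist(fields[n_f == 1L], use.names = FALSE)
  if (nrow(edges) > 0L && !all(edges$relation %in% c("targets", "member_of"))) {
    ## plain protein-protein SIF -> undirected igraph
    ids <- sort(unique(c(edges$from, edges$to, iso)))
    return(igraph::graph_from_data_frame(
      edges[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = ids)))
  }
  attr_path <- paste0(path, ".attrs.tsv")
  if (file.exists(attr_path)) {
    attrs <- read_tsv(attr_path)
    if (all(attrs$layer %in% c("compound", "target", "pathway"))) {
      nodes <- data.frame(id = attrs$id, layer = attrs$layer,
                          stringsAsFactors = FALSE)
      return(layered_network(nodes, edges))
    }
  }
  ids <- unique(c(edges$from, edges$to, iso))
  layer <- setNames(rep("target", length(ids)), ids)
  layer[unique(edges$from[edges$relation == "targets"])] <- "compound"
  layer[unique(edges$to[edges$relation == "member_of"])] <- "pathway"
  nodes <- data.frame(id = ids, layer = unname(layer[ids]),
                      stringsAsFactors = FALSE)
  layered_network(nodes, edges)
}
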
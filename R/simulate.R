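## Synthetic-data module: generates every pipeline input with known planted
## structure so each downstream stage has a ground truth to recover.  All
## generators are deterministic given the config: each draws from a stream
## derived from (seed, stage name).

target_universe <- function(config) {
  sprintf("G%04d", seq_len(config$n_target_universe))
}

draw_in_range <- function(range, n = 1L) {
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

#' Generate a candidate compound table with a planted ADME-passing subset
#'
#' Exactly `round(n_compounds * ob_pass_fraction)` compounds are constructed
#' to satisfy the default ADME cutoffs (OB >= 30 on a percent scale,
#' DL >= 0.18 on a 0-1 scale); every other compound fails at least one
#' cutoff.  The passing ids are recorded as ground truth.
#'
#' @param config A [simulation_config()].
#' @return A data.frame with columns `id`, `name`, `ob`, `dl`, carrying the
#'   planted `passing_compound_ids` in its [ground_truth()] attribute.
#' @examples
#' tab <- generate_compound_table(simulation_config(seed = 1))
#' nrow(filter_adme(tab))
#' @export
generate_compound_table <- function(config) {
  validate_simulation_config(config)
  n <- config$n_compounds
  n_pass <- round(n * config$ob_pass_fraction)
  with_stage_seed(config$seed, "compounds", {
    pass <- sample(c(rep(TRUE, n_pass), rep(FALSE, n - n_pass)))
    ob <- numeric(n)
    dl <- numeric(n)
    ob[pass] <- runif(n_pass, 32, 95)
    dl[pass] <- runif(n_pass, 0.20, 1.20)
    n_fail <- n - n_pass
    if (n_fail > 0L) {
      ## each failing compound misses at least one cutoff, with a margin so
      ## that rounding for display cannot flip it across the boundary
      mode <- sample(c("ob", "dl", "both"), n_fail, replace = TRUE)
      ob[!pass] <- ifelse(mode %in% c("ob", "both"),
                          runif(n_fail, 2, 28), runif(n_fail, 32, 95))
      dl[!pass] <- ifelse(mode %in% c("dl", "both"),
                          runif(n_fail, 0.01, 0.16), runif(n_fail, 0.20, 1.20))
    }
    out <- data.frame(
      id = sprintf("CMP%03d", seq_len(n)),
      name = sprintf("compound_%03d", seq_len(n)),
      ob = round(ob, 2),
      dl = round(dl, 3),
      stringsAsFactors = FALSE
    )
    attr(out, "ground_truth") <- list(passing_compound_ids = out$id[pass])
    out
  })
}

#' Generate per-compound target predictions across mock sources
#'
#' Each compound receives a target set whose size is drawn uniformly from
#' `config$targets_per_compound`; a fraction of associations is duplicated
#' under a second source label (sometimes with lower-case gene symbols) so
#' downstream deduplication and identifier normalisation are exercised, as
#' they would be when merging several prediction databases.
#'
#' @param config A [simulation_config()].
#' @param compounds A non-empty compound table (typically the ADME-passing
#'   subset, since targets are only predicted for active compounds).
#' @return A data.frame with columns `compound_id`, `target_id`, `source`.
#' @export
generate_target_associations <- function(config, compounds) {
  validate_simulation_config(config)
  if (!is.data.frame(compounds) || nrow(compounds) == 0L) {
    input_error("compound table is empty; target prediction needs at least one compound")
  }
  universe <- target_universe(config)
  sources <- c("tcm_catalog", "chem_similarity", "interaction_db",
               "target_panel", "pharmacophore")
  with_stage_seed(config$seed, "targets", {
    parts <- lapply(compounds$id, function(cid) {
      s <- draw_in_range(config$targets_per_compound)
      tg <- sample(universe, s)
      df <- data.frame(
        compound_id = cid, target_id = tg,
        source = sample(sources, s, replace = TRUE),
        stringsAsFactors = FALSE
      )
      dup <- which(runif(s) < 0.3)
      if (length(dup) > 0L) {
        extra <- df[dup, , drop = FALSE]
        extra$source <- vapply(extra$source, function(x)
          sample(setdiff(sources, x), 1L), character(1))
        lower <- runif(nrow(extra)) < 0.5
        extra$target_id[lower] <- tolower(extra$target_id[lower])
        df <- rbind(df, extra)
      }
      df
    })
    do.call(rbind, parts)
  })
}

#' Generate a disease gene list with a planted overlap
#'
#' The intersection between the disease list and the union of all compound
#' targets is fixed to `round(disease_overlap_fraction * |union|)` genes,
#' drawn from the union; the remaining disease genes are drawn outside it.
#' The planted intersection is recorded as ground truth.
#'
#' @param config A [simulation_config()].
#' @param associations Association table from
#'   [generate_target_associations()].
#' @return Character vector of disease genes with a [ground_truth()]
#'   attribute holding `true_overlap_genes`.
#' @export
generate_disease_genes <- function(config, associations) {
  validate_simulation_config(config)
  if (!is.data.frame(associations) || nrow(associations) == 0L) {
    input_error("association table is empty")
  }
  union_set <- sort(unique(normalize_ids(associations$target_id)))
  n_overlap <- round(config$disease_overlap_fraction * length(union_set))
  if (n_overlap > config$n_disease_genes) {
    config_error(sprintf(
      "requested overlap (%d genes) exceeds the disease list size (%d)",
      n_overlap, config$n_disease_genes))
  }
  with_stage_seed(config$seed, "disease", {
    overlap <- if (n_overlap > 0L) sample(union_set, n_overlap) else character(0)
    n_rest <- config$n_disease_genes - n_overlap
    pool <- setdiff(target_universe(config), union_set)
    rest <- if (n_rest <= length(pool)) {
      sample(pool, n_rest)
    } else {
      c(pool, sprintf("DGENE%04d", seq_len(n_rest - length(pool))))
    }
    genes <- sample(c(overlap, rest))
    attr(genes, "ground_truth") <- list(true_overlap_genes = sort(overlap))
    genes
  })
}

#' Generate a PPI graph with planted high-centrality hubs
#'
#' Builds a simple undirected graph on `ppi_n_nodes` genes: every pair with
#' at least one planted hub endpoint (including hub-hub pairs) is connected
#' independently with `ppi_hub_attach_prob`, every background pair with
#' `ppi_background_edge_prob`.  No self-loops or duplicate edges.
#'
#' @param config A [simulation_config()].
#' @param nodes Gene identifiers to build the graph on; must contain at
#'   least `ppi_n_nodes` distinct ids.
#' @return An [igraph][igraph::graph_from_data_frame] object whose
#'   [ground_truth()] attribute holds `planted_hub_ids`.
#' @export
generate_ppi <- function(config, nodes) {
  validate_simulation_config(config)
  nodes <- unique(as.character(nodes))
  if (config$ppi_n_nodes > length(nodes)) {
    config_error(sprintf(
      "ppi_n_nodes (%d) exceeds the available gene list (%d ids)",
      config$ppi_n_nodes, length(nodes)))
  }
  with_stage_seed(config$seed, "ppi", {
    sel <- sort(sample(nodes, config$ppi_n_nodes))
    hubs <- sort(sample(sel, config$ppi_n_planted_hubs))
    is_hub <- sel %in% hubs
    g <- if (length(sel) >= 2L) {
      pairs <- combn(length(sel), 2L)
      p <- ifelse(is_hub[pairs[1L, ]] | is_hub[pairs[2L, ]],
                  config$ppi_hub_attach_prob,
                  config$ppi_background_edge_prob)
      keep <- runif(ncol(pairs)) < p
      edges <- data.frame(from = sel[pairs[1L, keep]],
                          to = sel[pairs[2L, keep]],
                          stringsAsFactors = FALSE)
      igraph::graph_from_data_frame(edges, directed = FALSE,
                                    vertices = data.frame(name = sel))
    } else {
      igraph::make_empty_graph(directed = FALSE) +
        igraph::vertices(sel)
    }
    attr(g, "ground_truth") <- list(planted_hub_ids = hubs)
    g
  })
}

#' Generate an annotation collection with one planted enriched term
#'
#' Produces `n_terms` gene sets with sizes drawn from `term_size_range` and
#' categories assigned among BP, CC, MF and pathway.  One term is planted:
#' its overlap with `query` is inflated to `planted_term_enrichment` times
#' the hypergeometric expectation `K * |query| / |universe|` (capped at
#' `min(K, |query|)`).  With `planted_term_enrichment = 1` all terms are
#' random draws and nothing is planted (a signal-free collection).
#'
#' @param config A [simulation_config()].
#' @param universe Gene universe the terms are drawn from.
#' @param query Gene set the planted term is enriched against; must be a
#'   subset of `universe`.
#' @return A [gene_set_collection()] whose [ground_truth()] attribute holds
#'   `planted_term_id` (`NA` if no term was planted).
#' @export
generate_annotation <- function(config, universe, query) {
  validate_simulation_config(config)
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!all(query %in% universe)) {
    input_error("query genes must be a subset of the annotation universe")
  }
  if (config$term_size_range[2] > length(universe)) {
    config_error("term sizes exceed the provided universe")
  }
  n <- config$n_terms
  with_stage_seed(config$seed, "annotation", {
    sizes <- draw_in_range(config$term_size_range, n)
    categories <- sample(c("BP", "CC", "MF", "pathway"), n, replace = TRUE)
    plant <- config$planted_term_enrichment > 1 && length(query) > 0L
    planted_idx <- if (plant) sample.int(n, 1L) else NA_integer_
    members <- lapply(seq_len(n), function(i) {
      k_size <- sizes[i]
      if (plant && i == planted_idx) {
        expected <- k_size * length(query) / length(universe)
        o <- min(k_size, length(query),
                 max(1L, round(config$planted_term_enrichment * expected)))
        sort(c(sample(query, o),
               sample(setdiff(universe, query), k_size - o)))
      } else {
        sort(sample(universe, k_size))
      }
    })
    coll <- gene_set_collection(
      term_id = sprintf("T%03d", seq_len(n)),
      name = sprintf("term_%03d", seq_len(n)),
      category = categories,
      members = members
    )
    attr(coll, "ground_truth") <- list(
      planted_term_id = if (plant) coll$term_id[planted_idx] else NA_character_
    )
    coll
  })
}

#' Generate a qPCR Ct table with a known true fold change
#'
#' Control and treated groups are measured for a target and a reference
#' gene.  The treated target Ct is shifted by `-log2(ct_true_fold)` relative
#' to control; Gaussian noise of `ct_noise_sd` cycles is added to every
#' measurement.  With zero noise, [delta_delta_ct()] recovers the true fold
#' exactly.
#'
#' @param config A [simulation_config()].
#' @return A data.frame with columns `sample_id`, `group`, `gene`, `ct`,
#'   carrying `true_fold` in its [ground_truth()] attribute.
#' @export
generate_ct_table <- function(config) {
  validate_simulation_config(config)
  n <- config$n_ct_replicates
  with_stage_seed(config$seed, "ct", {
    group <- rep(c("control", "treated"), each = n)
    sample_id <- paste(group, rep(seq_len(n), times = 2L), sep = "_")
    shift <- -log2(config$ct_true_fold)
    target_ct <- 25 + ifelse(group == "treated", shift, 0) +
      rnorm(2L * n, 0, config$ct_noise_sd)
    ref_ct <- 20 + rnorm(2L * n, 0, config$ct_noise_sd)
    out <- rbind(
      data.frame(sample_id = sample_id, group = group,
                 gene = config$ct_target_gene, ct = target_ct,
                 stringsAsFactors = FALSE),
      data.frame(sample_id = sample_id, group = group,
                 gene = config$ct_reference_gene, ct = ref_ct,
                 stringsAsFactors = FALSE)
    )
    out <- out[order(out$sample_id, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "ground_truth") <- list(true_fold = config$ct_true_fold)
    out
  })
}

#' Generate the full set of synthetic pipeline inputs
#'
#' Runs every generator in funnel order: compound table, ADME screen, target
#' associations for the active compounds, disease gene list, PPI graph on
#' the true overlap set, annotation collection planted against the overlap
#' set, and the Ct table.  When the realised overlap set is smaller than
#' `ppi_n_nodes` (e.g. a zero-overlap configuration) the PPI stage shrinks
#' to the available genes so degenerate settings still produce valid, empty
#' downstream outputs.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, all inputs are written there
#'   as plain-text files (`compounds.tsv`, `associations.tsv`,
#'   `disease_genes.txt`, `ppi_edges.tsv`, `annotation.gmt`,
#'   `annotation_categories.tsv`, `ct_table.tsv`, `ground_truth.json`).
#' @return A list with elements `compounds`, `associations`,
#'   `disease_genes`, `ppi`, `annotation`, `ct_table`, `ground_truth`; the
#'   combined ground truth is also attached as an attribute.
#' @examples
#' inp <- simulate_inputs(simulation_config(seed = 7))
#' inp$ground_truth$passing_compound_ids
#' @export
simulate_inputs <- function(config, dir = NULL) {
  validate_simulation_config(config)
  compounds <- generate_compound_table(config)
  active <- filter_adme(compounds)
  associations <- generate_target_associations(config, active)
  disease_genes <- generate_disease_genes(config, associations)
  overlap <- ground_truth(disease_genes)$true_overlap_genes

  ppi_cfg <- config
  ppi_cfg$ppi_n_nodes <- min(config$ppi_n_nodes, max(length(overlap), 1L))
  ppi_cfg$ppi_n_planted_hubs <- min(config$ppi_n_planted_hubs,
                                    max(ppi_cfg$ppi_n_nodes - 1L, 1L))
  ppi <- if (length(overlap) > 1L) {
    generate_ppi(ppi_cfg, overlap)
  } else {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(overlap)
    attr(g, "ground_truth") <- list(planted_hub_ids = character(0))
    g
  }

  annotation <- generate_annotation(config, target_universe(config), overlap)
  ct_table <- generate_ct_table(config)

  truth <- list(
    passing_compound_ids = ground_truth(compounds)$passing_compound_ids,
    true_overlap_genes = overlap,
    planted_hub_ids = ground_truth(ppi)$planted_hub_ids,
    planted_term_id = ground_truth(annotation)$planted_term_id,
    true_fold = config$ct_true_fold
  )

  out <- list(compounds = compounds, associations = associations,
              disease_genes = disease_genes, ppi = ppi,
              annotation = annotation, ct_table = ct_table,
              ground_truth = truth)
  attr(out, "ground_truth") <- truth

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(compounds, file.path(dir, "compounds.tsv"))
    write_tsv(associations, file.path(dir, "associations.tsv"))
    write_lines(disease_genes, file.path(dir, "disease_genes.txt"))
    write_edge_tsv(ppi, file.path(dir, "ppi_edges.tsv"))
    write_gmt(annotation, file.path(dir, "annotation.gmt"),
              category_path = file.path(dir, "annotation_categories.tsv"))
    write_tsv(transform(ct_table, ct = sprintf("%.6f", ct)),
              file.path(dir, "ct_table.tsv"))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
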
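## Pipeline orchestration: screen -> map -> PPI screen -> enrich -> report,
## with deterministic artifacts and a funnel report mirroring the stage
## counts.

#' Stage parameters for the analysis funnel
#'
#' @param ob_min,dl_min,adme_inclusive ADME screen thresholds and
#'   comparison mode, see [filter_adme()].
#' @param rounds,screen_inclusive,until_stable Hub-screen settings, see
#'   [iterative_screen()].
#' @param fdr_cutoff,top_n Enrichment reporting, see [top_terms()].
#' @param top_pathways Number of top pathway-category terms added to the
#'   compound-target-pathway network.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(ob_min = 30, dl_min = 0.18,
                            adme_inclusive = TRUE,
                            rounds = 2L, screen_inclusive = TRUE,
                            until_stable = FALSE,
                            fdr_cutoff = 0.05, top_n = 20L,
                            top_pathways = 10L) {
  p <- list(ob_min = ob_min, dl_min = dl_min,
            adme_inclusive = isTRUE(adme_inclusive),
            rounds = rounds, screen_inclusive = isTRUE(screen_inclusive),
            until_stable = isTRUE(until_stable),
            fdr_cutoff = fdr_cutoff, top_n = top_n,
            top_pathways = top_pathways)
  if (!is_count(p$rounds) || !is_count(p$top_n + 1) ||
      !is_proportion(p$fdr_cutoff)) {
    config_error("invalid pipeline parameters")
  }
  structure(p, class = "pipeline_params")
}

#' Run the full network-pharmacology funnel
#'
#' Executes every stage in order on synthetic inputs generated from
#' `config` (or on pre-generated inputs in `input_dir`): ADME screen of
#' the compound table, per-compound target union of the active compounds,
#' intersection with the disease gene list, two-round median hub screen of
#' the PPI graph, per-compound key-target counts, compound-target and
#' compound-target-pathway network construction, overrepresentation
#' analysis of the hubs, and the 2^-ddCt computation on the Ct table.  All
#' stage artifacts are written under `out_dir` and a funnel report of the
#' stage counts is returned.  Reruns with the same config and inputs are
#' byte-identical.
#'
#' @param config A [simulation_config()]; defines the synthetic inputs and
#'   the Ct gene labels.
#' @param out_dir Directory for artifacts (created if needed).
#' @param params A [pipeline_params()].
#' @param input_dir Optional directory of pre-generated inputs as written
#'   by [simulate_inputs()]; default generates them under
#'   `out_dir/inputs`.
#' @return A list of class `funnel_report` (also written as
#'   `funnel_report.json` and `funnel_report.md` under `out_dir`).
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         params = pipeline_params(), input_dir = NULL) {
  validate_simulation_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(input_dir)) {
    input_dir <- file.path(out_dir, "inputs")
    simulate_inputs(config, input_dir)
  }
  compounds <- read_tsv(file.path(input_dir, "compounds.tsv"))
  associations <- read_tsv(file.path(input_dir, "associations.tsv"))
  disease_genes <- readLines(file.path(input_dir, "disease_genes.txt"))
  annotation <- read_gmt(file.path(input_dir, "annotation.gmt"),
                         file.path(input_dir, "annotation_categories.tsv"))
  ct_table <- read_tsv(file.path(input_dir, "ct_table.tsv"))
  ppi_path <- file.path(input_dir, "ppi_edges.tsv")
  ppi <- if (file.exists(ppi_path)) read_edge_tsv(ppi_path) else NULL

  ## 1. ADME screen
  screened <- filter_adme(compounds, params$ob_min, params$dl_min,
                          inclusive = params$adme_inclusive)
  write_tsv(screened, file.path(out_dir, "active_compounds.tsv"))

  ## 2. target mapping
  assoc_active <- associations[
    associations$compound_id %in% screened$id, , drop = FALSE]
  uni <- union_compound_targets(assoc_active)
  venn <- intersect_with_disease(uni$union, normalize_ids(disease_genes))
  write_lines(venn$overlap, file.path(out_dir, "overlap_genes.txt"))
  jsonlite::write_json(unclass(venn), file.path(out_dir, "venn_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## 3. PPI hub screen (restricted to the overlap set)
  hubs <- character(0)
  screen <- NULL
  if (!is.null(ppi)) {
    keep <- intersect(igraph::V(ppi)$name, venn$overlap)
    g <- igraph::induced_subgraph(ppi, keep)
    if (igraph::vcount(g) >= 2L) {
      screen <- iterative_screen(g, rounds = params$rounds,
                                 inclusive = params$screen_inclusive,
                                 until_stable = params$until_stable)
      hubs <- screen$final_hubs
      write_screening_outputs(screen, g, out_dir)
    }
  }
  if (is.null(screen)) {
    write_lines(character(0), file.path(out_dir, "hubs.txt"))
  }

  ## 4. networks
  key_counts <- per_compound_key_counts(assoc_active, hubs)
  ct_full <- build_ct_network(assoc_active)
  export_graph(ct_full, file.path(out_dir, "ct_network_full.sif"), "sif")
  ct_key <- build_ct_network(assoc_active, restrict_to = hubs)
  export_graph(ct_key, file.path(out_dir, "ct_network_key.sif"), "sif")

  ## 5. enrichment of the hubs
  enrich <- NULL
  passing_terms <- NULL
  if (length(hubs) > 0L) {
    enrich <- suppressMessages(ora(hubs, annotation))
    write_enrichment_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
    passing_terms <- top_terms(enrich, params$top_n, params$fdr_cutoff)
    path_rows <- enrich[enrich$category == "pathway" &
                          enrich$fdr < params$fdr_cutoff, , drop = FALSE]
    if (nrow(path_rows) > 0L) {
      ctp <- build_ctp_network(ct_key, path_rows,
                               min(params$top_pathways, nrow(path_rows)))
      export_graph(ctp, file.path(out_dir, "ctp_network.graphml"), "graphml")
    }
  } else {
    empty <- data.frame(term_id = character(0), name = character(0),
                        category = character(0), k = integer(0),
                        K = integer(0), n = integer(0), N = integer(0),
                        p_value = numeric(0), fdr = numeric(0),
                        rank = integer(0))
    empty$genes <- I(list())
    write_enrichment_tsv(empty, file.path(out_dir, "enrichment.tsv"))
  }

  ## 6. validation arithmetic
  ddct <- delta_delta_ct(ct_table, config$ct_target_gene,
                         config$ct_reference_gene)
  ps <- ddct$per_sample
  ps$delta_ct <- sprintf("%.6f", ps$delta_ct)
  ps$delta_delta_ct <- sprintf("%.6f", ps$delta_delta_ct)
  ps$fold <- sprintf("%.6f", ps$fold)
  write_tsv(ps, file.path(out_dir, "fold_changes.tsv"))

  treated_fold <- ddct$summary$mean_fold[ddct$summary$group == "treated"]
  report <- structure(list(
    n_compounds_in = nrow(compounds),
    n_compounds_passing = nrow(screened),
    per_compound_targets = as.list(uni$counts),
    n_targets_union = length(uni$union),
    n_disease_genes = venn$n_disease_genes,
    n_overlap = venn$n_overlap,
    screening_rounds = if (is.null(screen)) list() else
      lapply(screen$rounds, function(r) list(
        round = r$round_index,
        degree_threshold = unname(r$thresholds[["degree"]]),
        betweenness_threshold = unname(r$thresholds[["betweenness"]]),
        closeness_threshold = unname(r$thresholds[["closeness"]]),
        n_nodes = r$n_nodes,
        n_edges = r$induced_edge_count)),
    n_final_hubs = length(hubs),
    per_compound_key_counts = as.list(key_counts),
    n_terms_tested = if (is.null(enrich)) 0L else nrow(enrich),
    n_terms_passing = if (is.null(passing_terms)) 0L else nrow(passing_terms),
    treated_mean_fold = if (length(treated_fold) == 1L) treated_fold else NA_real_
  ), class = "funnel_report")

  write_report(report, file.path(out_dir, "funnel_report.json"), "json")
  write_report(report, file.path(out_dir, "funnel_report.md"), "markdown")
  report
}

#' Write a funnel report as JSON or markdown
#'
#' @param report A `funnel_report` from [run_pipeline()].
#' @param path Output file.
#' @param format `"json"` (machine-readable, round-trips) or `"markdown"`
#'   (one table row per funnel stage).
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    lines <- c(
      "# Funnel report", "",
      "| stage | value |",
      "| --- | --- |",
      sprintf("| compounds in | %d |", report$n_compounds_in),
      sprintf("| compounds passing ADME | %d |", report$n_compounds_passing),
      sprintf("| compound-target union | %d |", report$n_targets_union),
      sprintf("| disease genes | %d |", report$n_disease_genes),
      sprintf("| overlap (potential targets) | %d |", report$n_overlap),
      vapply(report$screening_rounds, function(r) sprintf(
        "| screen round %d (degree >= %g) | %d nodes, %d edges |",
        r$round, r$degree_threshold, r$n_nodes, r$n_edges), character(1)),
      sprintf("| final hubs | %d |", report$n_final_hubs),
      sprintf("| enriched terms (tested) | %d |", report$n_terms_tested),
      sprintf("| enriched terms (passing) | %d |", report$n_terms_passing)
    )
    write_lines(lines, path)
  }
  invisible(path)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Network-pharmacology funnel\n")
  cat(sprintf("  compounds: %d -> %d pass ADME\n",
              x$n_compounds_in, x$n_compounds_passing))
  cat(sprintf("  targets: union %d; disease genes %d; overlap %d\n",
              x$n_targets_union, x$n_disease_genes, x$n_overlap))
  for (r in x$screening_rounds) {
    cat(sprintf("  screen round %d: %d nodes, %d edges (degree >= %g)\n",
                r$round, r$n_nodes, r$n_edges, r$degree_threshold))
  }
  cat(sprintf("  final hubs: %d; enriched terms passing FDR: %d\n",
              x$n_final_hubs, x$n_terms_passing))
  invisible(x)
}

#' Recount funnel quantities from written artifacts
#'
#' Independent audit of a pipeline output directory: re-derives the main
#' funnel counts directly from the artifact files, for comparison against
#' the returned report.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @return Named list of recounted values.
#' @export
recount_funnel <- function(out_dir) {
  overlap <- readLines(file.path(out_dir, "overlap_genes.txt"))
  hubs <- readLines(file.path(out_dir, "hubs.txt"))
  screened <- read_tsv(file.path(out_dir, "active_compounds.tsv"))
  enrich <- read_tsv(file.path(out_dir, "enrichment.tsv"))
  list(
    n_compounds_passing = nrow(screened),
    n_overlap = length(overlap[nzchar(overlap)]),
    n_final_hubs = length(hubs[nzchar(hubs)]),
    n_terms_tested = nrow(enrich)
  )
}
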
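#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic input generators into a validated
#' object.  The defaults define the package's reference "easy" study
#' conditions: planted structure well separated from background, so each
#' downstream stage can recover it (the methods vignette motivates each
#' value).
#'
#' @param seed Integer master seed.  Each generator derives its own stream
#'   from `(seed, stage name)`, so stages can be regenerated independently.
#' @param n_compounds Number of candidate compounds in the table.
#' @param ob_pass_fraction Fraction of compounds constructed to pass the
#'   default ADME cutoffs (OB >= 30, DL >= 0.18); the rest fail at least one.
#' @param n_target_universe Size of the gene universe targets are drawn from.
#' @param targets_per_compound Integer range `c(lo, hi)`: per-compound
#'   target-set size (after deduplication) is drawn uniformly from it.
#' @param n_disease_genes Length of the disease gene list.
#' @param disease_overlap_fraction Fraction of the compound-target union that
#'   is planted into the disease list (the true overlap set).
#' @param ppi_n_nodes Number of nodes of the synthetic PPI graph (must not
#'   exceed the gene list it is built on).
#' @param ppi_n_planted_hubs Number of planted high-centrality hubs.
#' @param ppi_background_edge_prob Edge probability between non-hub pairs.
#' @param ppi_hub_attach_prob Edge probability for hub-incident pairs
#'   (hub-hub pairs use the same rule); must exceed the background.
#' @param n_terms Number of annotation gene sets.
#' @param term_size_range Integer range `c(lo, hi)` of term sizes.
#' @param planted_term_enrichment Multiplier (>= 1) applied to the
#'   hypergeometric expected query/term overlap for the one planted term.
#'   `1` means no term is planted (a signal-free collection, used for null
#'   calibration).
#' @param ct_true_fold True expression fold change planted in the Ct table.
#' @param ct_noise_sd Gaussian noise on each Ct measurement, in cycles.
#' @param n_ct_replicates Biological replicates per group in the Ct table.
#' @param ct_target_gene,ct_reference_gene Gene labels used in the Ct table.
#' @return A validated object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(seed = 1, n_compounds = 20, ob_pass_fraction = 0.25)
#' cfg$n_compounds
#' @export
simulation_config <- function(seed = 1L,
                              n_compounds = 20L,
                              ob_pass_fraction = 0.25,
                              n_target_universe = 400L,
                              targets_per_compound = c(20L, 60L),
                              n_disease_genes = 200L,
                              disease_overlap_fraction = 0.6,
                              ppi_n_nodes = 80L,
                              ppi_n_planted_hubs = 16L,
                              ppi_background_edge_prob = 0.05,
                              ppi_hub_attach_prob = 0.6,
                              n_terms = 50L,
                              term_size_range = c(10L, 40L),
                              planted_term_enrichment = 5,
                              ct_true_fold = 2,
                              ct_noise_sd = 0.2,
                              n_ct_replicates = 4L,
                              ct_target_gene = "ACTA2",
                              ct_reference_gene = "GAPDH") {
  cfg <- list(
    seed = seed, n_compounds = n_compounds,
    ob_pass_fraction = ob_pass_fraction,
    n_target_universe = n_target_universe,
    targets_per_compound = targets_per_compound,
    n_disease_genes = n_disease_genes,
    disease_overlap_fraction = disease_overlap_fraction,
    ppi_n_nodes = ppi_n_nodes,
    ppi_n_planted_hubs = ppi_n_planted_hubs,
    ppi_background_edge_prob = ppi_background_edge_prob,
    ppi_hub_attach_prob = ppi_hub_attach_prob,
    n_terms = n_terms, term_size_range = term_size_range,
    planted_term_enrichment = planted_term_enrichment,
    ct_true_fold = ct_true_fold, ct_noise_sd = ct_noise_sd,
    n_ct_replicates = n_ct_replicates,
    ct_target_gene = ct_target_gene,
    ct_reference_gene = ct_reference_gene
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) config_error(msg)
  chk(is_count(abs(cfg$seed) + 1), "seed must be a single integer")
  for (f in c("n_compounds", "n_target_universe", "n_disease_genes",
              "ppi_n_nodes", "ppi_n_planted_hubs", "n_terms",
              "n_ct_replicates")) {
    chk(is_count(cfg[[f]]), paste0(f, " must be a positive integer"))
  }
  for (f in c("ob_pass_fraction", "disease_overlap_fraction",
              "ppi_background_edge_prob", "ppi_hub_attach_prob")) {
    chk(is_proportion(cfg[[f]]), paste0(f, " must lie in [0, 1]"))
  }
  for (f in c("targets_per_compound", "term_size_range")) {
    r <- cfg[[f]]
    chk(length(r) == 2L && all(r == round(r)) && r[1] >= 1 && r[1] <= r[2],
        paste0(f, " must be an increasing positive integer range c(lo, hi)"))
  }
  chk(cfg$ppi_n_planted_hubs < cfg$ppi_n_nodes,
      "ppi_n_planted_hubs must be smaller than ppi_n_nodes")
  chk(cfg$ppi_hub_attach_prob > cfg$ppi_background_edge_prob,
      "ppi_hub_attach_prob must exceed ppi_background_edge_prob")
  chk(is_scalar_number(cfg$planted_term_enrichment) &&
        cfg$planted_term_enrichment >= 1,
      "planted_term_enrichment must be >= 1 (1 = no planted term)")
  chk(cfg$term_size_range[2] <= cfg$n_target_universe,
      "term sizes cannot exceed the target universe")
  chk(cfg$targets_per_compound[2] <= cfg$n_target_universe,
      "targets_per_compound cannot exceed the target universe")
  chk(is_scalar_number(cfg$ct_true_fold) && cfg$ct_true_fold > 0,
      "ct_true_fold must be a positive number")
  chk(is_scalar_number(cfg$ct_noise_sd) && cfg$ct_noise_sd >= 0,
      "ct_noise_sd must be non-negative")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic study conditions (simulation_config)\n")
  cat(sprintf("  seed %d | %d compounds (%.0f%% pass ADME) | universe %d genes\n",
              x$seed, x$n_compounds, 100 * x$ob_pass_fraction,
              x$n_target_universe))
  cat(sprintf("  %d disease genes, overlap fraction %.2f\n",
              x$n_disease_genes, x$disease_overlap_fraction))
  cat(sprintf("  PPI: %d nodes, %d planted hubs (attach %.2f vs background %.2f)\n",
              x$ppi_n_nodes, x$ppi_n_planted_hubs,
              x$ppi_hub_attach_prob, x$ppi_background_edge_prob))
  cat(sprintf("  annotation: %d terms of %d-%d genes, planted enrichment x%g\n",
              x$n_terms, x$term_size_range[1], x$term_size_range[2],
              x$planted_term_enrichment))
  cat(sprintf("  qPCR: fold %g, noise sd %g cycles, %d replicates/group\n",
              x$ct_true_fold, x$ct_noise_sd, x$n_ct_replicates))
  invisible(x)
}
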
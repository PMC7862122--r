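test_that("compound generator plants the exact number of ADME passers", {
  cfg <- simulation_config(seed = 1, n_compounds = 20, ob_pass_fraction = 0.25)
  tab <- generate_compound_table(cfg)
  expect_equal(nrow(tab), 20)
  expect_false(anyDuplicated(tab$id) > 0)
  pass <- tab$ob >= 30 & tab$dl >= 0.18
  expect_equal(sum(pass), 5)
  expect_setequal(tab$id[pass], ground_truth(tab)$passing_compound_ids)
  ## every non-passer fails at least one cutoff
  expect_true(all(tab$ob[!pass] < 30 | tab$dl[!pass] < 0.18))
})

test_that("generators are deterministic under a fixed config", {
  cfg <- simulation_config(seed = 11)
  expect_identical(generate_compound_table(cfg), generate_compound_table(cfg))
  tab <- filter_adme(generate_compound_table(cfg))
  expect_identical(generate_target_associations(cfg, tab),
                   generate_target_associations(cfg, tab))
  assoc <- generate_target_associations(cfg, tab)
  expect_identical(generate_disease_genes(cfg, assoc),
                   generate_disease_genes(cfg, assoc))
  overlap <- ground_truth(generate_disease_genes(cfg, assoc))$true_overlap_genes
  g1 <- generate_ppi(simulation_config(seed = 11, ppi_n_nodes = 40,
                                       ppi_n_planted_hubs = 8), overlap)
  g2 <- generate_ppi(simulation_config(seed = 11, ppi_n_nodes = 40,
                                       ppi_n_planted_hubs = 8), overlap)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_identical(generate_ct_table(cfg), generate_ct_table(cfg))
  u <- sprintf("G%04d", 1:400)
  expect_identical(generate_annotation(cfg, u, overlap),
                   generate_annotation(cfg, u, overlap))
})

test_that("ADME filter recovers the planted passer set (round trip)", {
  cfg <- simulation_config(seed = 2, n_compounds = 200, ob_pass_fraction = 0.5)
  tab <- generate_compound_table(cfg)
  expect_setequal(filter_adme(tab)$id, ground_truth(tab)$passing_compound_ids)
})

test_that("association generator respects set sizes, universe and dedup", {
  cfg <- simulation_config(seed = 3, targets_per_compound = c(3, 3))
  tab <- generate_compound_table(cfg)
  assoc <- generate_target_associations(cfg, tab)
  sets <- union_compound_targets(assoc)$per_compound
  expect_true(all(vapply(sets, length, integer(1)) == 3))
  expect_true(all(unlist(sets) %in% sprintf("G%04d", 1:400)))
  ## duplicate (compound, target) rows exist across sources by design
  cfg2 <- simulation_config(seed = 3)
  assoc2 <- generate_target_associations(cfg2, tab)
  key <- paste(assoc2$compound_id, toupper(assoc2$target_id))
  expect_gt(sum(duplicated(key)), 0)
  expect_error(generate_target_associations(cfg, tab[0, ]),
               class = "herbnet_input_error")
})

test_that("disease generator plants the exact overlap", {
  tab <- filter_adme(generate_compound_table(simulation_config(seed = 4)))
  assoc <- generate_target_associations(simulation_config(seed = 4), tab)
  union_set <- union_compound_targets(assoc)$union

  for (frac in c(0, 0.5, 1)) {
    cfg <- simulation_config(seed = 4, disease_overlap_fraction = frac)
    dg <- generate_disease_genes(cfg, assoc)
    truth <- ground_truth(dg)$true_overlap_genes
    venn <- intersect_with_disease(union_set, normalize_ids(dg))
    expect_identical(venn$overlap, truth)
    expect_equal(venn$n_overlap, round(frac * length(union_set)))
  }
  dg1 <- generate_disease_genes(
    simulation_config(seed = 4, disease_overlap_fraction = 1), assoc)
  expect_true(all(union_set %in% normalize_ids(dg1)))
  expect_error(
    generate_disease_genes(
      simulation_config(seed = 4, n_disease_genes = 5), assoc),
    class = "herbnet_config_error")
})

test_that("planted-hub graph is simple and hubs attach as specified", {
  ## degenerate probabilities force two overlapping stars
  cfg <- simulation_config(seed = 5, ppi_n_nodes = 10, ppi_n_planted_hubs = 2,
                           ppi_background_edge_prob = 0,
                           ppi_hub_attach_prob = 1)
  g <- generate_ppi(cfg, sprintf("G%04d", 1:50))
  hubs <- ground_truth(g)$planted_hub_ids
  deg <- compute_degree(g)
  expect_equal(unname(deg[hubs]), c(9, 9))  # hub-hub pairs also linked
  expect_equal(unname(sort(unique(deg[setdiff(names(deg), hubs)]))), 2)
  expect_equal(igraph::ecount(g), 17)
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
})

test_that("planted hubs have higher mean degree than background nodes", {
  diffs <- vapply(1:20, function(s) {
    cfg <- simulation_config(seed = 100 + s, ppi_n_nodes = 40,
                             ppi_n_planted_hubs = 8)
    g <- generate_ppi(cfg, sprintf("G%04d", 1:100))
    hubs <- ground_truth(g)$planted_hub_ids
    deg <- compute_degree(g)
    mean(deg[hubs]) - mean(deg[setdiff(names(deg), hubs)])
  }, numeric(1))
  expect_true(all(diffs > 0))
  expect_error(generate_ppi(simulation_config(ppi_n_nodes = 80),
                            sprintf("G%04d", 1:10)),
               class = "herbnet_config_error")
})

test_that("annotation terms stay inside the universe and carry the plant", {
  u <- sprintf("G%04d", 1:400)
  q <- sample(u, 60)
  cfg <- simulation_config(seed = 6)
  coll <- generate_annotation(cfg, u, q)
  expect_s3_class(coll, "gene_set_collection")
  expect_length(coll, cfg$n_terms)
  sizes <- vapply(coll$members, length, integer(1))
  expect_true(all(sizes >= cfg$term_size_range[1] &
                    sizes <= cfg$term_size_range[2]))
  expect_true(all(unlist(coll$members) %in% u))
  planted <- ground_truth(coll)$planted_term_id
  expect_true(planted %in% coll$term_id)
  ## the planted term's query overlap is inflated over expectation
  i <- match(planted, coll$term_id)
  k <- length(intersect(coll$members[[i]], q))
  expect_gt(k, length(coll$members[[i]]) * length(q) / length(u))
  ## enrichment multiplier 1 plants nothing
  coll0 <- generate_annotation(
    simulation_config(seed = 6, planted_term_enrichment = 1), u, q)
  expect_true(is.na(ground_truth(coll0)$planted_term_id))
  expect_error(generate_annotation(cfg, u, c(q, "NOT_IN_UNIVERSE")),
               class = "herbnet_input_error")
})

test_that("Ct generator inverts exactly without noise and nearly with noise", {
  for (fold in c(1, 2)) {
    cfg <- simulation_config(seed = 7, ct_true_fold = fold, ct_noise_sd = 0)
    ct <- generate_ct_table(cfg)
    res <- delta_delta_ct(ct, cfg$ct_target_gene, cfg$ct_reference_gene)
    expect_equal(res$per_sample$fold[res$per_sample$group == "treated"],
                 rep(fold, 4), tolerance = 1e-12)
  }
  est <- vapply(1:100, function(s) {
    cfg <- simulation_config(seed = 200 + s, ct_true_fold = 2,
                             ct_noise_sd = 0.2, n_ct_replicates = 4)
    res <- delta_delta_ct(generate_ct_table(cfg), cfg$ct_target_gene,
                          cfg$ct_reference_gene)
    res$summary$mean_fold[res$summary$group == "treated"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 2) / 2, 0.1)
})

test_that("simulate_inputs writes consistent files and ground truth", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 8)
  inp <- simulate_inputs(cfg, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "compounds.tsv", "associations.tsv", "disease_genes.txt",
    "ppi_edges.tsv", "annotation.gmt", "annotation_categories.tsv",
    "ct_table.tsv", "ground_truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$passing_compound_ids,
                  inp$ground_truth$passing_compound_ids)
  ## ground truth refers only to identifiers present in the tables
  expect_true(all(truth$passing_compound_ids %in% inp$compounds$id))
  expect_true(all(truth$true_overlap_genes %in%
                    normalize_ids(inp$disease_genes)))
  expect_true(all(truth$planted_hub_ids %in% igraph::V(inp$ppi)$name))
  expect_true(truth$planted_term_id %in% inp$annotation$term_id)
})
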
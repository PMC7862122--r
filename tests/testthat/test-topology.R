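test_that("degree, betweenness and closeness match analytic values", {
  star4 <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star4)$name <- c("hub", "l1", "l2", "l3")
  d <- compute_degree(star4)
  expect_equal(unname(d[c("hub", "l1")]), c(3L, 1L))

  empty <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c("a", "b"))
  expect_equal(unname(compute_degree(empty)), c(0L, 0L))
  expect_equal(unname(compute_betweenness(empty)), c(0, 0))
  expect_equal(unname(compute_closeness(empty)), c(0, 0))

  p3 <- igraph::make_graph(~ a - b - c)
  b <- compute_betweenness(p3)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))
  cl <- compute_closeness(p3)
  expect_equal(unname(cl[c("a", "b")]), c(2 / 3, 1))

  k4 <- igraph::make_full_graph(4)
  expect_equal(unname(compute_betweenness(k4)), rep(0, 4))

  star5 <- igraph::make_star(5, mode = "undirected", center = 1)
  cl5 <- compute_closeness(star5)
  expect_equal(unname(cl5), c(1, rep(4 / 7, 4)))
})

test_that("centralities match the BFS path-counting oracle on random graphs", {
  for (i in 1:20) {
    n <- 5 + (i %% 20)
    A <- random_test_graph(n, p = 0.25, seed = 300 + i)
    g <- adjacency_to_igraph(A)
    ref <- oracle_centralities(A)
    ct <- centrality_table(g)
    idx <- match(ct$node, ref$node)
    expect_equal(ct$degree, unname(ref$degree[idx]), tolerance = 0)
    expect_equal(ct$betweenness, ref$betweenness[idx], tolerance = 1e-9)
    expect_equal(ct$closeness, ref$closeness[idx], tolerance = 1e-9)
  }
})

test_that("medians use the even-count mean rule", {
  ct <- data.frame(node = letters[1:5], degree = c(1, 2, 2, 2, 1),
                   betweenness = 0, closeness = 0)
  expect_equal(unname(median_thresholds(ct)[["degree"]]), 2)
  ct2 <- data.frame(node = c("a", "b"), degree = c(1, 2),
                    betweenness = c(0.1, 0.3), closeness = c(0.5, 1))
  thr <- median_thresholds(ct2)
  expect_equal(unname(thr), c(1.5, 0.2, 0.75))
  withr::with_seed(13, {
    vals <- runif(11)
    ct3 <- data.frame(node = sprintf("n%d", 1:11), degree = vals,
                      betweenness = vals, closeness = vals)
    expect_equal(unname(median_thresholds(ct3)[["degree"]]),
                 sort(vals)[6])
  })
  expect_error(median_thresholds(ct[0, ]), class = "herbnet_input_error")
})

test_that("worked example: one round on the 5-node path", {
  r <- screen_round(path5())
  expect_equal(unname(r$thresholds),
               c(2, 0.5, 4 / 7), tolerance = 1e-12)
  expect_equal(r$survivors, c("b", "c", "d"))
  expect_equal(r$induced_edge_count, 2)
})

test_that("symmetric graphs survive whole; strict mode empties them", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  r <- screen_round(k5)
  expect_equal(r$n_nodes, 5)
  r_strict <- screen_round(k5, inclusive = FALSE)
  expect_true(r_strict$empty)
  expect_equal(r_strict$n_nodes, 0)
})

test_that("iterative screen recomputes thresholds and converges on the path", {
  res <- iterative_screen(path5(), rounds = 2)
  expect_length(res$rounds, 2)
  expect_equal(res$rounds[[1]]$survivors, c("b", "c", "d"))
  expect_equal(unname(res$rounds[[2]]$thresholds),
               c(1, 0, 2 / 3), tolerance = 1e-12)
  expect_equal(res$final_hubs, c("b", "c", "d"))
  expect_true(res$converged)

  ## edgeless graph: all metrics 0, everything survives immediately
  e <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c("x", "y", "z"))
  res_e <- iterative_screen(e, rounds = 2)
  expect_equal(res_e$final_hubs, c("x", "y", "z"))
  expect_true(res_e$converged)
})

test_that("screening shrinks monotonically and survivors satisfy thresholds", {
  for (i in 1:10) {
    A <- random_test_graph(30, p = 0.15, seed = 400 + i)
    g <- adjacency_to_igraph(A)
    res <- iterative_screen(g, rounds = 3)
    sizes <- c(igraph::vcount(g),
               vapply(res$rounds, function(r) r$n_nodes, integer(1)))
    expect_true(all(diff(sizes) <= 0))
    edge_counts <- c(igraph::ecount(g),
                     vapply(res$rounds, function(r) r$induced_edge_count,
                            integer(1)))
    expect_true(all(diff(edge_counts) <= 0))
    ## threshold soundness, checked round by round against a recomputation
    current <- g
    for (r in res$rounds) {
      ct <- centrality_table(current)
      thr <- r$thresholds
      ok <- ct$degree >= thr[["degree"]] &
        ct$betweenness >= thr[["betweenness"]] &
        ct$closeness >= thr[["closeness"]]
      expect_setequal(ct$node[ok], r$survivors)
      current <- r$subgraph
    }
  }
})

test_that("screening is invariant under node relabelling", {
  A <- random_test_graph(20, p = 0.2, seed = 77)
  g <- adjacency_to_igraph(A)
  res1 <- iterative_screen(g, rounds = 2)
  perm <- withr::with_seed(78, sample(igraph::vcount(g)))
  relabel <- setNames(sprintf("w%02d", perm), igraph::V(g)$name)
  g2 <- g
  igraph::V(g2)$name <- unname(relabel[igraph::V(g)$name])
  res2 <- iterative_screen(g2, rounds = 2)
  expect_setequal(unname(relabel[res1$final_hubs]), res2$final_hubs)
  expect_equal(res1$rounds[[1]]$thresholds, res2$rounds[[1]]$thresholds)
})

test_that("screening outputs are written and self-consistent", {
  dir <- withr::local_tempdir()
  A <- random_test_graph(25, p = 0.2, seed = 55)
  g <- adjacency_to_igraph(A)
  res <- iterative_screen(g, rounds = 2)
  write_screening_outputs(res, g, dir)
  hubs <- readLines(file.path(dir, "hubs.txt"))
  expect_equal(hubs, res$final_hubs)
  rep <- jsonlite::read_json(file.path(dir, "screening_report.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$rounds$n_survivors,
               vapply(res$rounds, function(r) r$n_nodes, integer(1)))
  ct <- read.delim(file.path(dir, "centrality_table.tsv"))
  expect_equal(nrow(ct), igraph::vcount(g))
})
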
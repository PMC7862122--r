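test_that("hypergeometric upper tail is exact", {
  expect_identical(hypergeom_upper_tail(0, 5, 4, 10), 1)
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10), 5 / 210, tolerance = 1e-14)
  expect_error(hypergeom_upper_tail(5, 4, 5, 10),
               class = "herbnet_validation_error")
  expect_error(hypergeom_upper_tail(1, 11, 4, 10),
               class = "herbnet_validation_error")
  expect_error(hypergeom_upper_tail(-1, 5, 4, 10),
               class = "herbnet_validation_error")
})

test_that("upper tail matches direct PMF summation and the PMF sums to 1", {
  withr::with_seed(31, {
    for (i in 1:50) {
      N <- sample(5:60, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(hypergeom_upper_tail(k, K, n, N),
                   oracle_upper_tail(k, K, n, N), tolerance = 1e-12)
      ks <- max(0, n - (N - K)):min(K, n)
      expect_equal(sum(hyper_pmf(ks, K, n, N)), 1, tolerance = 1e-12)
    }
  })
})

test_that("p-value decreases as the overlap grows", {
  p <- vapply(0:8, hypergeom_upper_tail, numeric(1), K = 10, n = 8, N = 50)
  expect_true(all(diff(p) < 0))
})

test_that("BH step-up matches the hand-applied rule and a reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "herbnet_validation_error")
  withr::with_seed(32, {
    for (i in 1:30) {
      p <- runif(sample(1:50, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(adj >= p))
      ord <- order(p)
      expect_true(all(diff(adj[ord]) >= -1e-12))
    }
  })
})

make_collection <- function() {
  gene_set_collection(
    term_id = c("t1", "t2", "t3", "t4"),
    name = c("alpha", "beta", "gamma", "delta"),
    category = c("BP", "BP", "pathway", "MF"),
    members = list(c("A", "B", "C"), c("C", "D"), c("E", "F", "G"),
                   c("A", "H"))
  )
}

test_that("ORA counts match brute-force set intersections", {
  coll <- make_collection()
  universe <- LETTERS[1:10]
  query <- c("A", "B", "C", "E")
  rows <- ora(query, coll, universe = universe, include_zero = TRUE)
  expect_setequal(rows$term_id, coll$term_id)
  for (i in seq_len(nrow(rows))) {
    members <- coll$members[[match(rows$term_id[i], coll$term_id)]]
    expect_equal(rows$k[i], length(intersect(members, query)))
    expect_equal(rows$K[i], length(intersect(members, universe)))
    expect_equal(rows$n[i], length(query))
    expect_equal(rows$N[i], length(universe))
    expect_equal(rows$p_value[i],
                 oracle_upper_tail(rows$k[i], rows$K[i], rows$n[i],
                                   rows$N[i]),
                 tolerance = 1e-12)
  }
  expect_true(all(rows$fdr >= rows$p_value))
  expect_equal(rows$rank, seq_len(nrow(rows)))
})

test_that("a fully covered term gets the minimum p-value", {
  coll <- make_collection()
  rows <- ora(c("E", "F", "G"), coll, universe = LETTERS[1:10])
  expect_equal(rows$term_id[1], "t3")
  expect_equal(rows$k[1], 3)
})

test_that("FDR is adjusted within category by default, globally on request", {
  coll <- make_collection()
  universe <- LETTERS[1:10]
  query <- c("A", "B", "C", "D", "E")
  rows <- ora(query, coll, universe = universe, include_zero = TRUE)
  for (cat in unique(rows$category)) {
    sub <- rows[rows$category == cat, ]
    expect_equal(sub$fdr, unname(bh_adjust(sub$p_value)))
  }
  rows_g <- ora(query, coll, universe = universe, by_category = FALSE,
                include_zero = TRUE)
  expect_equal(sort(rows_g$fdr), sort(unname(bh_adjust(rows_g$p_value))))
})

test_that("top_terms filters strictly by FDR then truncates", {
  rows <- data.frame(term_id = sprintf("t%02d", 1:30),
                     fdr = seq(0.001, 0.30, length.out = 30))
  expect_equal(nrow(top_terms(rows, top_n = 20, fdr_cutoff = 1e-4)), 0)
  expect_equal(nrow(top_terms(rows, top_n = 20, fdr_cutoff = 1)), 20)
  expect_identical(top_terms(rows, top_n = 40, fdr_cutoff = 1.01), rows)
  ## boundary is strict
  one <- data.frame(term_id = "t", fdr = 0.05)
  expect_equal(nrow(top_terms(one, fdr_cutoff = 0.05)), 0)
})

test_that("GMT round trip preserves the collection and fgsea agrees", {
  dir <- withr::local_tempdir()
  coll <- make_collection()
  gmt <- file.path(dir, "sets.gmt")
  cats <- file.path(dir, "cats.tsv")
  write_gmt(coll, gmt, category_path = cats)
  back <- read_gmt(gmt, cats)
  expect_equal(back$term_id, coll$term_id)
  expect_equal(back$category, coll$category)
  expect_equal(back$members, coll$members)
  ## independent parser sees the same member sets
  ref <- fgsea::gmtPathways(gmt)
  expect_equal(ref[coll$term_id], setNames(coll$members, coll$term_id))
  ## without the sidecar every term falls back to the pathway category
  expect_true(all(read_gmt(gmt)$category == "pathway"))
})

test_that("collection constructor enforces its invariants", {
  expect_error(gene_set_collection(c("a", "a"), members = list("X", "Y")),
               class = "herbnet_validation_error")
  expect_error(gene_set_collection("a", category = "XX",
                                   members = list("X")),
               class = "herbnet_validation_error")
  expect_error(gene_set_collection("a", members = list(character(0))),
               class = "herbnet_validation_error")
})
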
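## Overrepresentation analysis: gene-set collections, the one-sided
## hypergeometric test, BH-FDR adjustment, and top-N reporting.

#' Construct a gene-set collection
#'
#' A lightweight container for annotation terms: parallel vectors of term
#' id, display name and category (`BP`, `CC`, `MF` or `pathway`), plus a
#' list of member gene sets.
#'
#' @param term_id Character vector of unique term identifiers.
#' @param name Character vector of term names.
#' @param category Character vector of categories.
#' @param members List of non-empty character vectors of member genes.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(term_id, name = term_id,
                                category = rep("pathway", length(term_id)),
                                members) {
  term_id <- as.character(term_id)
  if (anyDuplicated(term_id)) validation_error("term ids must be unique")
  if (length(name) != length(term_id) ||
      length(category) != length(term_id) ||
      length(members) != length(term_id)) {
    validation_error("term_id, name, category and members must be parallel")
  }
  if (!all(category %in% c("BP", "CC", "MF", "pathway"))) {
    validation_error("categories must be among BP, CC, MF, pathway")
  }
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(vapply(members, length, integer(1)) == 0L)) {
    validation_error("member sets must be non-empty")
  }
  structure(
    list(term_id = term_id, name = as.character(name),
         category = as.character(category), members = members),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$members, length, integer(1))
  cat(sprintf("Gene-set collection: %d terms (%d-%d genes each)\n",
              length(x$term_id), min(sizes), max(sizes)))
  print(table(x$category))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$term_id)

collection_universe <- function(collection) {
  sort(unique(unlist(collection$members, use.names = FALSE)))
}

#' Write / read a gene-set collection as GMT
#'
#' Standard GMT (one term per line: id, description, member genes,
#' tab-separated).  GMT carries no category, so categories are written to a
#' two-column sidecar TSV (`term_id`, `category`); reading without a
#' sidecar assigns `pathway` to every term.
#'
#' @param collection A [gene_set_collection()].
#' @param path GMT file path.
#' @param category_path Optional sidecar TSV path.
#' @return `write_gmt` invisibly returns `path`; `read_gmt` returns a
#'   [gene_set_collection()].
#' @export
write_gmt <- function(collection, path, category_path = NULL) {
  lines <- vapply(seq_along(collection$term_id), function(i) {
    paste(c(collection$term_id[i], collection$name[i],
            collection$members[[i]]), collapse = "\t")
  }, character(1))
  write_lines(lines, path)
  if (!is.null(category_path)) {
    write_tsv(data.frame(term_id = collection$term_id,
                         category = collection$category,
                         stringsAsFactors = FALSE),
              category_path)
  }
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, category_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3L
  if (any(bad)) {
    validation_error(sprintf("malformed GMT line(s): %s",
                             paste(which(bad), collapse = ", ")))
  }
  term_id <- vapply(fields, `[`, character(1), 1L)
  name <- vapply(fields, `[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  category <- rep("pathway", length(term_id))
  if (!is.null(category_path)) {
    cats <- read_tsv(category_path)
    category <- cats$category[match(term_id, cats$term_id)]
    category[is.na(category)] <- "pathway"
  }
  gene_set_collection(term_id, name, category, members)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` annotated genes in a query of size `n` drawn from
#' a universe of `N` genes of which `K` carry the annotation.  Evaluated
#' through the stable log-space tail of [stats::phyper()]; `k = 0` returns
#' exactly 1.
#'
#' @param k Observed overlap count.
#' @param K Term size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The one-sided p-value in `(0, 1]`.
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10)  # 5/210
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < 0 || v != round(v)) {
      validation_error("k, K, n, N must be single non-negative integers")
    }
  }
  if (K > N || n > N || k > min(K, n)) {
    validation_error(sprintf(
      "inconsistent counts: need k <= min(K, n) and K, n <= N (got k=%d K=%d n=%d N=%d)",
      k, K, n, N))
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `adjusted_i = min_{j >= i} (m * p_(j) / j)` over the sorted p-values,
#' capped at 1 and returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    validation_error("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Overrepresentation analysis of a gene set against a collection
#'
#' For every term, counts the overlap `k` between the query and the term
#' (both restricted to the universe), computes the one-sided hypergeometric
#' p-value and adjusts for multiple testing with Benjamini-Hochberg —
#' within each category by default, mirroring how GO tools treat BP/CC/MF
#' separately.  Rows are ranked by FDR, then p, then term id.
#'
#' @param query Character vector of query genes.
#' @param collection A [gene_set_collection()].
#' @param universe Background gene set; defaults to all genes appearing in
#'   the collection.  Query genes outside the universe are dropped.
#' @param by_category Adjust FDR within each category (default) or
#'   globally.
#' @param include_zero Keep terms with zero overlap (default drops them).
#' @return data.frame with columns `term_id`, `name`, `category`, `k`, `K`,
#'   `n`, `N`, `p_value`, `fdr`, `rank`, plus list-columns `genes` (the
#'   overlap) and `members` (term genes in the universe).
#' @export
ora <- function(query, collection, universe = NULL, by_category = TRUE,
                include_zero = FALSE) {
  if (!inherits(collection, "gene_set_collection")) {
    validation_error("collection must be a gene_set_collection")
  }
  if (is.null(universe)) universe <- collection_universe(collection)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) input_error("universe is empty")
  query <- unique(as.character(query))
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0L) {
    message(sprintf("ora: dropping %d query gene(s) absent from the universe",
                    length(dropped)))
  }
  query <- intersect(query, universe)
  if (length(query) == 0L) input_error("query is empty within the universe")

  members_u <- lapply(collection$members, intersect, universe)
  overlap <- lapply(members_u, intersect, query)
  rows <- data.frame(
    term_id = collection$term_id,
    name = collection$name,
    category = collection$category,
    k = vapply(overlap, length, integer(1)),
    K = vapply(members_u, length, integer(1)),
    n = length(query),
    N = length(universe),
    stringsAsFactors = FALSE
  )
  rows$genes <- I(lapply(overlap, sort))
  rows$members <- I(lapply(members_u, sort))
  rows <- rows[rows$K > 0L, , drop = FALSE]
  if (!include_zero) rows <- rows[rows$k > 0L, , drop = FALSE]
  if (nrow(rows) == 0L) {
    rows$p_value <- numeric(0)
    rows$fdr <- numeric(0)
    rows$rank <- integer(0)
    return(rows)
  }
  rows$p_value <- mapply(hypergeom_upper_tail, rows$k, rows$K, rows$n, rows$N)
  rows$fdr <- if (by_category) {
    stats::ave(rows$p_value, rows$category, FUN = bh_adjust)
  } else {
    bh_adjust(rows$p_value)
  }
  ord <- order(rows$fdr, rows$p_value, rows$term_id)
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}

#' Top significant enrichment terms
#'
#' The first `top_n` ranked rows with `fdr < fdr_cutoff` (strict, matching
#' the usual "FDR < 0.05" reporting rule).
#'
#' @param rows Ranked output of [ora()].
#' @param top_n Maximum number of rows to keep.
#' @param fdr_cutoff Strict FDR cutoff.
#' @return The filtered, ranked subset.
#' @export
top_terms <- function(rows, top_n = 20L, fdr_cutoff = 0.05) {
  if (!is.data.frame(rows)) validation_error("rows must be a data.frame")
  out <- rows[rows$fdr < fdr_cutoff, , drop = FALSE]
  head(out, top_n)
}

#' Write an enrichment table as TSV
#'
#' Flattens the list-columns (overlap genes joined by `;`) so the table can
#' be shared with spreadsheet or plotting tools.
#'
#' @param rows Output of [ora()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_enrichment_tsv <- function(rows, path) {
  flat <- rows[, c("term_id", "name", "category", "k", "K", "n", "N",
                   "p_value", "fdr", "rank")]
  flat$p_value <- sprintf("%.6g", flat$p_value)
  flat$fdr <- sprintf("%.6g", flat$fdr)
  flat$genes <- vapply(rows$genes, paste, character(1), collapse = ";")
  write_tsv(flat, path)
}
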
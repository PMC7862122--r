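## Target mapping: identifier normalisation, per-compound unions, and the
## intersection with a disease gene set (the compound-targets -> potential
## disease targets step of the funnel).

#' Normalise gene identifiers to deduplicated upper-case symbols
#'
#' Trims whitespace, upper-cases, resolves synonyms through an optional
#' mapping (applied transitively; cycles are rejected), drops empty strings
#' and deduplicates keeping the first occurrence.  The operation is
#' idempotent.
#'
#' @param raw_ids Character vector of raw identifiers.
#' @param synonym_table Optional named character vector `c(alias = symbol)`;
#'   matching is case-insensitive on the alias side.
#' @return Character vector of normalised symbols, in order of first
#'   occurrence.
#' @examples
#' normalize_ids(c(" tp53", "TP53", "p53"), c(P53 = "TP53"))
#' @export
normalize_ids <- function(raw_ids, synonym_table = NULL) {
  ids <- toupper(trimws(as.character(raw_ids)))
  if (!is.null(synonym_table)) {
    if (is.null(names(synonym_table)) || any(names(synonym_table) == "")) {
      validation_error("synonym_table must be a named character vector")
    }
    map <- toupper(trimws(as.character(synonym_table)))
    names(map) <- toupper(trimws(names(synonym_table)))
    map <- map[names(map) != map]  # identity rows are no-ops, not cycles
    ## resolve transitively (alias -> alias -> symbol); a cycle never
    ## terminates, so detect it up front by walking each chain
    for (start in names(map)) {
      seen <- character(0)
      cur <- start
      while (cur %in% names(map)) {
        if (cur %in% seen) {
          validation_error(paste0("synonym cycle detected at '", start, "'"))
        }
        seen <- c(seen, cur)
        cur <- map[[cur]]
      }
    }
    repeat {
      hit <- ids %in% names(map)
      if (!any(hit)) break
      ids[hit] <- unname(map[ids[hit]])
    }
  }
  ids <- ids[nzchar(ids)]
  unique(ids)
}

#' Per-compound target sets and their union
#'
#' Collapses an association table into normalised per-compound target sets,
#' their sorted union, and per-compound counts — the "all targets combined
#' and deduplicated" step applied after multi-source target prediction.
#'
#' @param associations data.frame with columns `compound_id`, `target_id`.
#' @param synonym_table Passed to [normalize_ids()].
#' @return List with `per_compound` (named list of sorted gene sets),
#'   `union` (sorted character vector) and `counts` (named integer vector).
#' @export
union_compound_targets <- function(associations, synonym_table = NULL) {
  if (!is.data.frame(associations) ||
      !all(c("compound_id", "target_id") %in% names(associations))) {
    validation_error("associations must have columns compound_id and target_id")
  }
  per_compound <- lapply(
    split(associations$target_id, associations$compound_id),
    function(x) sort(normalize_ids(x, synonym_table))
  )
  union_set <- sort(unique(unlist(per_compound, use.names = FALSE)))
  if (is.null(union_set)) union_set <- character(0)
  list(
    per_compound = per_compound,
    union = union_set,
    counts = vapply(per_compound, length, integer(1))
  )
}

#' Intersect compound targets with a disease gene set
#'
#' Computes the overlap (Venn intersection) between the union of compound
#' targets and a disease gene list — the step that turns predicted targets
#' into potential disease targets.
#'
#' @param compound_targets Character vector of normalised target symbols.
#' @param disease_genes Character vector of normalised disease genes.
#' @return A `venn_summary` list: `n_compound_targets`, `n_disease_genes`,
#'   `n_overlap`, and the sorted `overlap` gene set.
#' @export
intersect_with_disease <- function(compound_targets, disease_genes) {
  ct <- unique(as.character(compound_targets))
  dg <- unique(as.character(disease_genes))
  overlap <- sort(intersect(ct, dg))
  structure(
    list(
      n_compound_targets = length(ct),
      n_disease_genes = length(dg),
      n_overlap = length(overlap),
      overlap = overlap
    ),
    class = "venn_summary"
  )
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf(
    "Venn summary: %d compound targets, %d disease genes, %d overlapping\n",
    x$n_compound_targets, x$n_disease_genes, x$n_overlap))
  invisible(x)
}

#' Count key targets per compound
#'
#' For each compound, the number of its targets that belong to a key-target
#' set (e.g. the hubs surviving PPI screening) — the per-compound degree in
#' the key-target compound-target network.
#'
#' @param associations data.frame with columns `compound_id`, `target_id`.
#' @param key_targets Character vector of key target symbols.
#' @param synonym_table Passed to [normalize_ids()].
#' @return Named integer vector of counts, one per compound.
#' @export
per_compound_key_counts <- function(associations, key_targets,
                                    synonym_table = NULL) {
  sets <- union_compound_targets(associations, synonym_table)$per_compound
  key <- unique(normalize_ids(key_targets, synonym_table))
  vapply(sets, function(s) length(intersect(s, key)), integer(1))
}
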
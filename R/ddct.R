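#' Livak 2^-ddCt relative expression
#'
#' Implements the standard relative-quantification arithmetic for qPCR:
#' for each sample `s`, `dCt_s = Ct(target, s) - Ct(reference, s)`;
#' `ddCt_s = dCt_s - mean(dCt over control samples)`; the relative fold is
#' `2^(-ddCt_s)`.  Normalising against the control-group mean makes the
#' geometric mean of the control folds exactly 1, and adding a constant to
#' both genes of a sample leaves the result unchanged (the reference
#' subtraction cancels it).
#'
#' @param records data.frame with columns `sample_id`, `group`, `gene`,
#'   `ct` (one row per measurement; technical replicates of the same
#'   sample/gene are averaged).
#' @param target_gene,reference_gene Gene labels to compare; every sample
#'   must carry both.
#' @param control_group Label of the calibrator group.
#' @return A list of class `ddct_result`: `per_sample` (data.frame with
#'   `sample_id`, `group`, `delta_ct`, `delta_delta_ct`, `fold`) and
#'   `summary` (per group: `n`, `mean_fold`, `sem`).
#' @examples
#' tab <- data.frame(
#'   sample_id = rep(c("c1", "t1"), each = 2),
#'   group = rep(c("control", "treated"), each = 2),
#'   gene = rep(c("ACTA2", "GAPDH"), 2),
#'   ct = c(25, 20, 24, 20))
#' delta_delta_ct(tab, "ACTA2", "GAPDH")$per_sample$fold
#' @export
delta_delta_ct <- function(records, target_gene, reference_gene,
                           control_group = "control") {
  required <- c("sample_id", "group", "gene", "ct")
  if (!is.data.frame(records) || !all(required %in% names(records))) {
    validation_error("records must have columns sample_id, group, gene, ct")
  }
  if (any(!is.finite(records$ct) | records$ct <= 0)) {
    validation_error("Ct values must be finite and positive")
  }
  mean_ct <- function(gene) {
    sub <- records[records$gene == gene, , drop = FALSE]
    tapply(sub$ct, sub$sample_id, mean)
  }
  ct_t <- mean_ct(target_gene)
  ct_r <- mean_ct(reference_gene)
  samples <- unique(records[, c("sample_id", "group")])
  missing_ref <- samples$sample_id[!(samples$sample_id %in% names(ct_r))]
  missing_tgt <- samples$sample_id[!(samples$sample_id %in% names(ct_t))]
  if (length(missing_ref) > 0L || length(missing_tgt) > 0L) {
    validation_error(paste0(
      "sample(s) lacking a measurement: ",
      paste(unique(c(missing_ref, missing_tgt)), collapse = ", ")))
  }
  if (!control_group %in% samples$group) {
    validation_error(paste0("control group '", control_group,
                            "' has no samples"))
  }
  dct <- ct_t[samples$sample_id] - ct_r[samples$sample_id]
  calibrator <- mean(dct[samples$group == control_group])
  ddct <- dct - calibrator
  per_sample <- data.frame(
    sample_id = samples$sample_id,
    group = samples$group,
    delta_ct = unname(dct),
    delta_delta_ct = unname(ddct),
    fold = unname(2^(-ddct)),
    stringsAsFactors = FALSE
  )
  rownames(per_sample) <- NULL
  groups <- split(per_sample$fold, per_sample$group)
  summary <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean_fold = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(x)
      if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_,
      numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  structure(list(per_sample = per_sample, summary = summary,
                 target_gene = target_gene, reference_gene = reference_gene,
                 control_group = control_group),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("2^-ddCt relative expression of %s vs %s (calibrator: %s)\n",
              x$target_gene, x$reference_gene, x$control_group))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Classify docking affinities as strong or weak binders
#'
#' Docking scores are binding free energies in kcal/mol: lower (more
#' negative) means stronger binding.  A score strictly below the cutoff
#' (default -7 kcal/mol) is labelled `strong`, otherwise `weak`.
#'
#' @param records data.frame with a numeric `score` column (kcal/mol);
#'   extra columns such as `ligand_id`, `receptor_id` are carried through.
#' @param strong_cutoff Strict threshold, kcal/mol.
#' @return The input with a `label` factor column (`strong` / `weak`).
#' @examples
#' classify_binding(data.frame(ligand_id = "Que", score = -8.2))$label
#' @export
classify_binding <- function(records, strong_cutoff = -7) {
  if (!is.data.frame(records) || !"score" %in% names(records)) {
    validation_error("records must be a data.frame with a score column")
  }
  if (any(!is.finite(records$score))) {
    validation_error("scores must be finite")
  }
  records$label <- factor(ifelse(records$score < strong_cutoff,
                                 "strong", "weak"),
                          levels = c("strong", "weak"))
  records
}
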
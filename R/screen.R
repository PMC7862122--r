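#' Filter candidate compounds by ADME thresholds
#'
#' Applies the oral-bioavailability / drug-likeness screen used to select
#' active compounds from a candidate table: a compound is kept when
#' `ob >= ob_min` and `dl >= dl_min` (strict `>` with `inclusive = FALSE`).
#' The defaults (OB 30%, DL 0.18) are the conventional cutoffs for
#' herbal-compound ADME screening.  Input order is preserved and the input
#' is never modified, so the filter is idempotent and monotone in both
#' thresholds.
#'
#' @param compounds data.frame with columns `id`, `ob` (percent, 0-100) and
#'   `dl` (unitless, >= 0); extra columns are carried through.
#' @param ob_min Minimum oral bioavailability, percent.
#' @param dl_min Minimum drug-likeness score.
#' @param inclusive Compare with `>=` (default) or strict `>`.
#' @return The subset of rows passing both thresholds.
#' @examples
#' tab <- data.frame(id = c("a", "b"), ob = c(30, 29.9), dl = c(0.18, 0.5))
#' filter_adme(tab)$id
#' filter_adme(tab, inclusive = FALSE)$id
#' @export
filter_adme <- function(compounds, ob_min = 30, dl_min = 0.18,
                        inclusive = TRUE) {
  if (!is.data.frame(compounds)) {
    validation_error("`compounds` must be a data.frame")
  }
  required <- c("id", "ob", "dl")
  missing_cols <- setdiff(required, names(compounds))
  if (length(missing_cols) > 0L) {
    validation_error(paste0("compound table lacks column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  if (!is_scalar_number(ob_min) || !is_scalar_number(dl_min)) {
    validation_error("ob_min and dl_min must be finite numbers")
  }
  if (nrow(compounds) == 0L) {
    return(compounds)
  }
  bad <- !is.finite(compounds$ob) | compounds$ob < 0 | compounds$ob > 100 |
    !is.finite(compounds$dl) | compounds$dl < 0
  if (any(bad)) {
    validation_error(paste0(
      "invalid OB/DL values for record(s): ",
      paste(compounds$id[bad], collapse = ", "),
      " (OB must lie in [0, 100], DL must be >= 0)"))
  }
  if (anyDuplicated(compounds$id)) {
    validation_error("compound ids must be unique")
  }
  keep <- if (inclusive) {
    compounds$ob >= ob_min & compounds$dl >= dl_min
  } else {
    compounds$ob > ob_min & compounds$dl > dl_min
  }
  out <- compounds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
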
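## Internal helpers shared across modules.

herbnet_error <- function(msg, class) {
  stop(structure(
    class = c(class, "herbnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error <- function(msg) herbnet_error(msg, "herbnet_config_error")
input_error <- function(msg) herbnet_error(msg, "herbnet_input_error")
validation_error <- function(msg) herbnet_error(msg, "herbnet_validation_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_proportion <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Deterministic per-stage seed derivation so each generator draws from its
## own stream and stages can be regenerated independently.  Kept well below
## .Machine$integer.max.
.stage_offsets <- c(
  compounds = 101L, targets = 211L, disease = 307L,
  ppi = 401L, annotation = 503L, ct = 601L
)

stage_seed <- function(seed, stage) {
  if (!stage %in% names(.stage_offsets)) {
    stop("unknown simulation stage: ", stage)
  }
  (as.integer(seed) %% 1000003L) * 1009L + .stage_offsets[[stage]]
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}

## TSV written with fixed conventions so reruns are byte-identical.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}

write_lines <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(x), con, sep = "\n")
  invisible(path)
}

#' Retrieve the planted ground truth attached to a synthetic object
#'
#' Every synthetic-data generator records the structure it planted (passing
#' compound ids, true overlap genes, hub ids, enriched term, true fold) as a
#' `ground_truth` attribute so downstream recovery can be verified.
#'
#' @param x An object returned by a `generate_*()` function or
#'   [simulate_inputs()].
#' @return A named list, or `NULL` if `x` carries no ground truth.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)
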
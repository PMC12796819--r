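#' @keywords internal
"_PACKAGE"

# Error helpers: validation/user errors get their own condition class so the
# CLI can map them to exit code 2 while genuine bugs stay exit code 1.
stop_user <- function(...) {
  stop(errorCondition(paste0(..., collapse = ", "),
                      class = c("lfq_user_error", "error")))
}

is_user_error <- function(e) inherits(e, "lfq_user_error")

#' Derive a per-step RNG seed from the pipeline seed
#'
#' One user-supplied seed governs a whole run; each stochastic step draws its
#' own substream seed deterministically from it so that inserting or removing
#' an unrelated step does not perturb the others.
#'
#' @param seed integer master seed.
#' @param label character tag of the step (e.g. "impute").
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) + h * 7919) %% 2147483629)
}

# Strip the ".1", ".2", ... uniquification suffix from a display id.
strip_suffix <- function(ids) sub("\\.[0-9]+$", "", ids)

# Write a data.frame as TSV with fixed formatting so identical inputs give
# byte-identical files.
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.6g", x))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                    stringsAsFactors = FALSE)
}
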
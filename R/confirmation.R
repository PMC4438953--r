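#' Cross-cohort direction-concordance check
#'
#' Maps candidate genes (e.g. the mRNA nodes of the regulatory network) onto
#' an independent confirmation cohort and compares the direction of
#' differential expression. A gene counts as "detected" if it is present in
#' the confirmation DE table at all, regardless of significance there: the
#' check is about direction of change, not about re-reaching significance in
#' a smaller or noisier series.
#'
#' @param candidates character vector of gene ids.
#' @param de_test gene-level `DEResult` from the test cohort.
#' @param de_confirm gene-level `DEResult` from the confirmation cohort.
#' @return an object of class `ConcordanceReport`: list with `candidates`,
#'   `detected`, `concordant`, `discordant` (data frame `gene`, `dir_test`,
#'   `dir_confirm`), `n_detected`, `n_concordant`.
#' @export
confirm_directions <- function(candidates, de_test, de_confirm) {
  candidates <- unique(as.character(candidates))
  if (!length(candidates)) stop("empty candidate list")
  ti <- match(candidates, de_test$feature_id)
  if (anyNA(ti))
    stop("candidate(s) absent from the test cohort DE table: ",
         paste(utils::head(candidates[is.na(ti)], 5L), collapse = ", "))
  detected <- candidates[candidates %in% de_confirm$feature_id]
  ci <- match(detected, de_confirm$feature_id)
  dir_test <- ifelse(de_test$log_fc[match(detected, de_test$feature_id)] >= 0,
                     "up", "down")
  dir_confirm <- ifelse(de_confirm$log_fc[ci] >= 0, "up", "down")
  same <- dir_test == dir_confirm
  structure(list(
    candidates = candidates,
    detected = detected,
    concordant = detected[same],
    discordant = data.frame(gene = detected[!same],
                            dir_test = dir_test[!same],
                            dir_confirm = dir_confirm[!same],
                            stringsAsFactors = FALSE),
    n_detected = length(detected),
    n_concordant = sum(same)
  ), class = "ConcordanceReport")
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat(sprintf(
    "ConcordanceReport: %d candidates, %d detected, %d concordant (%.1f%%)\n",
    length(x$candidates), x$n_detected, x$n_concordant,
    if (x$n_detected) 100 * x$n_concordant / x$n_detected else NA_real_))
  if (nrow(x$discordant)) {
    cat("  discordant:",
        paste(x$discordant$gene, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a concordance report as JSON
#' @param report a `ConcordanceReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(report, path) {
  stopifnot(inherits(report, "ConcordanceReport"))
  obj <- list(
    candidates = report$candidates,
    n_detected = report$n_detected,
    n_concordant = report$n_concordant,
    discordant = report$discordant
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
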
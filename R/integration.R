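#' Collapse probe-level DE results to gene level
#'
#' Microarrays measure probes, not genes; when several probes map to the same
#' gene the probe with the largest absolute log fold-change represents it.
#' Probes absent from the platform map are dropped (their count is reported
#' via a message).
#'
#' @param results probe-level `DEResult` data frame.
#' @param platform_map data frame with columns `probe`, `gene` (see
#'   [read_platform_map()]).
#' @return gene-level `DEResult` data frame (`feature_id` holds gene symbols).
#' @export
collapse_probes <- function(results, platform_map) {
  stopifnot(all(c("probe", "gene") %in% colnames(platform_map)))
  # a probe can map to several genes: expand via merge instead of match
  merged <- merge(results, platform_map,
                  by.x = "feature_id", by.y = "probe")
  dropped <- sum(!results$feature_id %in% platform_map$probe)
  if (dropped > 0)
    message(dropped, " probe(s) without a gene mapping dropped")
  if (!nrow(merged)) {
    out <- results[0, , drop = FALSE]
    class(out) <- c("DEResult", "data.frame")
    return(out)
  }
  merged <- merged[order(merged$gene, -abs(merged$log_fc),
                         merged$feature_id), , drop = FALSE]
  best <- merged[!duplicated(merged$gene), , drop = FALSE]
  best$feature_id <- best$gene
  best$gene <- NULL
  best <- best[order(best$feature_id), , drop = FALSE]
  rownames(best) <- NULL
  class(best) <- c("DEResult", "data.frame")
  best
}

#' Intersect predicted targets with DE lists and keep anti-correlated pairs
#'
#' The "negative correlation" filter: since the miRNA and mRNA cohorts come
#' from different patients, anti-correlation is assessed on direction of
#' differential expression, not per-sample correlation. A predicted pair
#' (miRNA m, gene g) is retained iff m is a differentially expressed miRNA,
#' g a differentially expressed gene, and their log fold-changes have
#' strictly opposite signs (a zero log fold-change has no direction and the
#' pair is dropped). The association weight is the product of absolute log
#' fold-changes; network degree computations use binary adjacency instead.
#'
#' @param pairs a `TargetPair` data frame (predicted or imported).
#' @param de_mirnas threshold-filtered miRNA `DEResult`.
#' @param de_genes threshold-filtered gene-level `DEResult`.
#' @return data frame of class `RegulatoryPair` with columns `mirna_id`,
#'   `mirna_direction`, `mirna_log_fc`, `gene_id`, `gene_direction`,
#'   `gene_log_fc`, `weight`.
#' @export
intersect_and_filter <- function(pairs, de_mirnas, de_genes) {
  mi <- match(pairs$mirna_id, de_mirnas$feature_id)
  gi <- match(pairs$gene_id, de_genes$feature_id)
  keep <- !is.na(mi) & !is.na(gi)
  mlfc <- de_mirnas$log_fc[mi]
  glfc <- de_genes$log_fc[gi]
  keep <- keep & !is.na(mlfc * glfc) & sign(mlfc) * sign(glfc) < 0
  keep[is.na(keep)] <- FALSE
  out <- data.frame(
    mirna_id = pairs$mirna_id[keep],
    mirna_direction = ifelse(mlfc[keep] > 0, "up", "down"),
    mirna_log_fc = mlfc[keep],
    gene_id = pairs$gene_id[keep],
    gene_direction = ifelse(glfc[keep] > 0, "up", "down"),
    gene_log_fc = glfc[keep],
    weight = abs(mlfc[keep]) * abs(glfc[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RegulatoryPair", "data.frame")
  out
}

#' Write a regulatory-pair table as TSV
#' @param pairs a `RegulatoryPair` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("mirna_id", "mirna_direction", "gene_id", "gene_direction",
              "weight")
  miss <- setdiff(needed, colnames(df))
  if (length(miss))
    stop("pair table missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("RegulatoryPair", "data.frame")
  df
}
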
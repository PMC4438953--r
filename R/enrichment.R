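check_counts <- function(nf, n, Nf, N) {
  if (any(c(nf, n, Nf, N) < 0) || nf > min(n, Nf) || n > N || Nf > N)
    stop("invalid 2x2 counts: need 0 <= nf <= min(n, Nf), n <= N, Nf <= N ",
         sprintf("(got nf=%d n=%d Nf=%d N=%d)", nf, n, Nf, N))
}

#' One-sided Fisher over-representation p-value
#'
#' P(X >= nf) for X ~ hypergeometric(N, Nf, n): the chance that a random
#' query of size n from a universe of N genes, Nf of which carry the term,
#' hits the term at least nf times.
#'
#' @param nf query genes carrying the term.
#' @param n query size.
#' @param Nf universe genes carrying the term.
#' @param N universe size.
#' @return p-value in \[0, 1\].
#' @export
fisher_enrichment <- function(nf, n, Nf, N) {
  check_counts(nf, n, Nf, N)
  if (nf == 0) return(1)
  stats::phyper(nf - 1, Nf, N - Nf, n, lower.tail = FALSE)
}

#' Pearson chi-squared p-value for the 2x2 enrichment table
#'
#' Two-sided, 1 df, no continuity correction, on the table
#' \[\[nf, n-nf\], \[Nf-nf, N-n-Nf+nf\]\]. A zero marginal makes the table
#' degenerate; p = 1 is returned with a warning.
#'
#' @inheritParams fisher_enrichment
#' @return p-value in \[0, 1\].
#' @export
chi2_enrichment <- function(nf, n, Nf, N) {
  check_counts(nf, n, Nf, N)
  tab <- matrix(c(nf, Nf - nf, n - nf, N - n - Nf + nf), nrow = 2L)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate 2x2 table (zero marginal); returning p = 1")
    return(1)
  }
  expected <- outer(rs, cs) / N
  stat <- sum((tab - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Paired-test run-level FDR
#'
#' FDR = 1 - Nk / T, where T is the number of term tests in the run and Nk
#' the number of terms whose Fisher exact p-value is strictly below the
#' paired chi-squared p-value. This is a single value per enrichment run,
#' reported alongside every term of that run; it is not a per-term adjusted
#' p-value.
#'
#' @param fisher_ps Fisher p-values, one per term.
#' @param chi2_ps chi-squared p-values, parallel to `fisher_ps`.
#' @return a single FDR value in \{0, 1/T, ..., 1\}.
#' @export
paper_fdr <- function(fisher_ps, chi2_ps) {
  if (length(fisher_ps) != length(chi2_ps))
    stop("fisher_ps and chi2_ps must have equal length")
  if (!length(fisher_ps)) stop("need at least one term test")
  Nk <- sum(fisher_ps < chi2_ps)
  1 - Nk / length(fisher_ps)
}

#' Gene-set enrichment of a query gene list
#'
#' For every set with at least one query member: Fisher exact and
#' chi-squared p-values, fold enrichment Re = (nf/n)/(Nf/N), a per-term
#' Benjamini-Hochberg adjustment of the Fisher p (practical ranking aid),
#' and the single run-level paired-test FDR. Query genes outside the
#' universe are dropped (count reported via a message). The default
#' universe is every gene annotated to at least one set.
#'
#' @param query_genes character vector of gene ids.
#' @param gene_sets a `GeneSetCollection`.
#' @param universe explicit background gene list; default: union of all set
#'   members (or the collection's own `universe` if present).
#' @param max_p significance cut on the Fisher p-value.
#' @param max_fdr significance cut on the run-level FDR.
#' @return data frame of class `EnrichmentResult`, sorted by Fisher p
#'   ascending (ties: fold enrichment descending, then term id), columns
#'   `term_id`, `term_name`, `nf`, `n`, `Nf`, `N`, `fisher_p`, `chi2_p`,
#'   `fold_enrichment`, `bh_p`, `run_fdr`, `significant`, `neg_log10_p`.
#' @export
enrich <- function(query_genes, gene_sets, universe = NULL,
                   max_p = 0.05, max_fdr = 0.05) {
  stopifnot(inherits(gene_sets, "GeneSetCollection"))
  if (is.null(universe)) universe <- gene_sets$universe
  if (is.null(universe))
    universe <- unique(unlist(lapply(gene_sets$sets, `[[`, "members"),
                              use.names = FALSE))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query_genes))
  outside <- setdiff(query, universe)
  if (length(outside))
    message(length(outside), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  if (!length(query))
    stop("empty query after intersecting with the universe")
  n <- length(query); N <- length(universe)
  rows <- lapply(names(gene_sets$sets), function(id) {
    s <- gene_sets$sets[[id]]
    members <- intersect(s$members, universe)
    nf <- length(intersect(query, members))
    if (nf < 1L) return(NULL)
    Nf <- length(members)
    data.frame(term_id = id, term_name = s$name, nf = nf, n = n,
               Nf = Nf, N = N,
               fisher_p = fisher_enrichment(nf, n, Nf, N),
               chi2_p = suppressWarnings(chi2_enrichment(nf, n, Nf, N)),
               fold_enrichment = (nf / n) / (Nf / N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      nf = integer(0), n = integer(0), Nf = integer(0),
                      N = integer(0), fisher_p = numeric(0),
                      chi2_p = numeric(0), fold_enrichment = numeric(0),
                      bh_p = numeric(0), run_fdr = numeric(0),
                      significant = logical(0), neg_log10_p = numeric(0))
    class(out) <- c("EnrichmentResult", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$bh_p <- bh_adjust(out$fisher_p)
  run_fdr <- paper_fdr(out$fisher_p, out$chi2_p)
  out$run_fdr <- run_fdr
  # max_fdr >= 1 disables the run-level FDR cut (the GO default applies the
  # P cut only; the paired-test FDR equals 1 whenever no Fisher p undercuts
  # its chi-squared partner, which would otherwise veto every term)
  out$significant <- out$fisher_p < max_p &
    (max_fdr >= 1 | run_fdr < max_fdr)
  out$neg_log10_p <- -log10(pmax(out$fisher_p, .Machine$double.xmin))
  out <- out[order(out$fisher_p, -out$fold_enrichment, out$term_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Write an enrichment table as TSV
#' @param result an `EnrichmentResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
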
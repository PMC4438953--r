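RNA_ALPHABET <- c("A", "C", "G", "U")

assert_rna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string")
  if (grepl("T", seq, fixed = TRUE))
    stop(what, " contains T; normalize DNA to RNA first (see read_fasta)")
  if (!grepl("^[ACGU]+$", seq))
    stop(what, " contains characters outside {A,C,G,U}")
  invisible(seq)
}

# reverse complement on the RNA alphabet (Watson-Crick only, no wobble)
rc_rna <- function(seq) {
  comp <- chartr("ACGU", "UGCA", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Seed region of a mature miRNA
#'
#' The seed is nucleotides 2-8 (1-based) of the mature miRNA, the primary
#' determinant of target recognition.
#'
#' @param mirna_sequence mature miRNA sequence, RNA alphabet, length >= 8.
#' @return 7-nucleotide seed string.
#' @export
seed_of <- function(mirna_sequence) {
  assert_rna(mirna_sequence, "miRNA sequence")
  if (nchar(mirna_sequence) < 8L)
    stop("miRNA sequence shorter than 8 nt")
  substr(mirna_sequence, 2L, 8L)
}

# All seed-match sites of one miRNA across a character vector of UTRs.
# Site classes (strongest wins per position):
#   8mer     = Watson-Crick complement of seed 2-8 followed by A on the UTR
#   7mer-m8  = complement of seed 2-8 (no trailing A)
#   7mer-A1  = complement of seed 2-7 followed by A, not already part of an
#              8mer (the 6-mer core is the tail of the 7mer m8 match)
# Overlapping occurrences are found with a zero-width lookahead so repeated
# seeds (e.g. poly-U complements) are not missed.
scan_positions_vec <- function(mirna_sequence, utrs) {
  seed7 <- seed_of(mirna_sequence)
  m8_site <- rc_rna(seed7)
  a1_core <- substr(m8_site, 2L, 7L)  # complement of seed 2-7, 5'->3'
  m8_hits <- gregexpr(paste0("(?=", m8_site, ")"), utrs, perl = TRUE)
  a1_hits <- gregexpr(paste0("(?=", a1_core, "A)"), utrs, perl = TRUE)
  lens <- nchar(utrs)
  lapply(seq_along(utrs), function(j) {
    s8 <- as.integer(m8_hits[[j]]); s8 <- s8[s8 > 0L]
    sa <- as.integer(a1_hits[[j]]); sa <- sa[sa > 0L]
    has_a <- if (length(s8))
      s8 + 7L <= lens[j] & substring(utrs[j], s8 + 7L, s8 + 7L) == "A"
    else logical(0)
    list(eight = s8[has_a], m7 = s8[!has_a],
         a1 = sa[!(sa - 1L) %in% s8])  # m8 match upstream makes it 8mer
  })
}

scan_sites_vec <- function(mirna_sequence, utrs) {
  pos <- scan_positions_vec(mirna_sequence, utrs)
  lapply(seq_along(utrs), function(j) {
    p <- pos[[j]]
    df <- data.frame(
      site_type = c(rep("8mer", length(p$eight)),
                    rep("7mer-m8", length(p$m7)),
                    rep("7mer-A1", length(p$a1))),
      utr_start = c(p$eight - 1L, p$m7 - 1L, p$a1 - 1L),
      utr_end = c(p$eight + 7L, p$m7 + 6L, p$a1 + 6L),
      stringsAsFactors = FALSE
    )
    df <- df[order(df$utr_start, df$site_type), , drop = FALSE]
    df$matched_sequence <- if (nrow(df))
      substring(utrs[j], df$utr_start + 1L, df$utr_end) else character(0)
    rownames(df) <- NULL
    df
  })
}

#' Find seed-match sites of a miRNA in a 3'UTR
#'
#' Scans every window of the UTR (5' to 3') for TargetScan-style canonical
#' sites: `8mer` (perfect complement of seed positions 2-8 followed by an A
#' in the UTR), `7mer-m8` (complement of 2-8), and `7mer-A1` (complement of
#' 2-7 followed by an A). The A at target position 1 must be a literal A in
#' the UTR, regardless of the miRNA's first nucleotide. G:U wobble pairs are
#' not allowed. Where classifications overlap, only the strongest class is
#' reported per position (8mer > 7mer-m8 > 7mer-A1).
#'
#' @param mirna_sequence mature miRNA sequence (RNA, length >= 8).
#' @param utr_sequence 3'UTR sequence (RNA).
#' @return data frame with columns `site_type`, `utr_start`, `utr_end`
#'   (0-based half-open on the UTR), `matched_sequence`; zero rows when no
#'   site exists.
#' @export
find_sites <- function(mirna_sequence, utr_sequence) {
  assert_rna(utr_sequence, "UTR sequence")
  scan_sites_vec(mirna_sequence, utr_sequence)[[1L]]
}

#' Predict miRNA target genes by seed matching
#'
#' Runs [find_sites()] for every (miRNA, UTR) combination and returns one
#' target pair per combination with at least one site, with per-class site
#' counts. Ordering is deterministic by (miRNA id, gene id).
#'
#' @param mirnas named character vector of mature miRNA sequences (from
#'   [read_fasta()]).
#' @param utrs named character vector of 3'UTR sequences; names are gene ids.
#' @return data frame of class `TargetPair` with columns `mirna_id`,
#'   `gene_id`, `n_8mer`, `n_7mer_m8`, `n_7mer_a1`, `n_sites`, `source`.
#' @export
predict_targets <- function(mirnas, utrs) {
  if (!length(mirnas) || !length(utrs))
    stop("both miRNA and UTR maps must be non-empty")
  stopifnot(length(names(mirnas)) == length(mirnas),
            length(names(utrs)) == length(utrs))
  bad <- !grepl("^[ACGU]+$", utrs)
  if (any(bad))
    stop("UTR sequence(s) with invalid alphabet: ",
         paste(utils::head(names(utrs)[bad], 5L), collapse = ", "))
  rows <- list()
  for (m in sort(names(mirnas))) {
    pos <- scan_positions_vec(mirnas[[m]], unname(utrs))
    counts <- vapply(pos, function(p)
      c(length(p$eight), length(p$m7), length(p$a1)), numeric(3L))
    total <- colSums(counts)
    hit <- which(total > 0)
    if (length(hit)) {
      rows[[m]] <- data.frame(
        mirna_id = m, gene_id = names(utrs)[hit],
        n_8mer = counts[1L, hit], n_7mer_m8 = counts[2L, hit],
        n_7mer_a1 = counts[3L, hit], n_sites = total[hit],
        source = "predicted", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), gene_id = character(0),
               n_8mer = numeric(0), n_7mer_m8 = numeric(0),
               n_7mer_a1 = numeric(0), n_sites = numeric(0),
               source = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("TargetPair", "data.frame")
  out
}

#' Import a precomputed miRNA-target prediction table
#'
#' Accepts any TSV with at least `mirna` and `gene` columns (e.g. an export
#' from an external prediction tool); duplicate (mirna, gene) rows collapse
#' to one pair.
#'
#' @param path TSV path.
#' @return a `TargetPair` data frame with `source = "imported"` (site counts
#'   set to `NA` unless provided as `n_sites`).
#' @export
import_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("mirna", "gene"), colnames(df))
  if (length(miss))
    stop("prediction table missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$mirna, df$gene, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  k <- nrow(df)
  out <- data.frame(
    mirna_id = as.character(df$mirna), gene_id = as.character(df$gene),
    n_8mer = rep(NA_real_, k), n_7mer_m8 = rep(NA_real_, k),
    n_7mer_a1 = rep(NA_real_, k),
    n_sites = if ("n_sites" %in% colnames(df)) df$n_sites
      else rep(NA_real_, k),
    source = rep("imported", k), stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("TargetPair", "data.frame")
  out
}

#' Export predictions / site tables as TSV
#' @param pairs a `TargetPair` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_predictions <- function(pairs, path) {
  df <- data.frame(mirna = pairs$mirna_id, gene = pairs$gene_id,
                   n_sites = pairs$n_sites, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
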
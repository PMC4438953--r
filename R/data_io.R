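#' Construct an expression matrix
#'
#' The central container of the pipeline: a features x samples numeric matrix
#' with per-sample group labels (tumor / normal) and a declared scale.
#' Duplicate feature identifiers are permitted (probe-level arrays routinely
#' carry several probes per gene); duplicate sample identifiers are not.
#'
#' @param values numeric matrix, rows = features, columns = samples. `NA`
#'   encodes a missing measurement (never zero).
#' @param feature_ids character vector, one per row.
#' @param sample_ids character vector, one per column; must be unique.
#' @param groups character vector parallel to `sample_ids`, each element one
#'   of `group_levels`.
#' @param scale either `"linear"` (raw intensities) or `"log2"`.
#' @param platform_tag free-text platform annotation.
#' @param group_levels the admissible group labels.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, feature_ids, sample_ids, groups,
                              scale = c("linear", "log2"),
                              platform_tag = "",
                              group_levels = c("tumor", "normal")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  groups <- as.character(groups)
  em <- structure(list(
    values = values,
    feature_ids = feature_ids,
    sample_ids = sample_ids,
    groups = groups,
    group_levels = group_levels,
    scale = scale,
    platform_tag = platform_tag
  ), class = "ExpressionMatrix")
  validate_expression_matrix(em)
  em
}

#' Validate ExpressionMatrix invariants
#'
#' @param em an `ExpressionMatrix`.
#' @return `em`, invisibly; stops on violation.
#' @export
validate_expression_matrix <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (nrow(em$values) != length(em$feature_ids))
    stop("row count (", nrow(em$values), ") != number of feature ids (",
         length(em$feature_ids), ")")
  if (ncol(em$values) != length(em$sample_ids))
    stop("column count (", ncol(em$values), ") != number of sample ids (",
         length(em$sample_ids), ")")
  if (length(em$groups) != length(em$sample_ids))
    stop("group labels and sample ids differ in length")
  if (anyDuplicated(em$sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(em$sample_ids[duplicated(em$sample_ids)]), collapse = ", "))
  bad <- setdiff(unique(em$groups), em$group_levels)
  if (length(bad))
    stop("group label(s) outside declared set: ", paste(bad, collapse = ", "))
  if (!em$scale %in% c("linear", "log2"))
    stop("scale must be 'linear' or 'log2'")
  invisible(em)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$groups)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (nzchar(x$platform_tag)) cat("  platform:", x$platform_tag, "\n")
  invisible(x)
}

#' Number of features / samples
#' @param em an `ExpressionMatrix`.
#' @return integer count.
#' @export
n_features <- function(em) nrow(em$values)

#' @rdname n_features
#' @export
n_samples <- function(em) ncol(em$values)

#' Read an expression matrix from disk
#'
#' Supports plain TSV (a feature-id column followed by one numeric column per
#' sample) and the GEO Series-Matrix table block delimited by
#' `!series_matrix_table_begin` / `!series_matrix_table_end` sentinels with
#' optionally quoted identifiers. Only the table block and the
#' `!Sample_title` / `!Sample_geo_accession` header lines of a series-matrix
#' file are interpreted; full SOFT parsing is out of scope.
#'
#' Empty fields, `NA`, `null` and `NULL` become missing values (`NA`), never
#' zero.
#'
#' @param path file path.
#' @param format `"tsv"` or `"series_matrix"`.
#' @param group_spec named character vector mapping every sample id in the
#'   file to a group label.
#' @param scale declared scale of the stored values.
#' @param platform_tag free-text platform annotation.
#' @return an `ExpressionMatrix`.
#' @export
read_expression <- function(path, format = c("tsv", "series_matrix"),
                            group_spec, scale = c("linear", "log2"),
                            platform_tag = "") {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin)
      stop("malformed series-matrix file: table sentinels not found in ", path)
    lines <- lines[(begin + 1L):(end - 1L)]
    lines <- gsub('"', "", lines, fixed = TRUE)
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no data in ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("malformed header in ", path, ": expected id column plus >=1 sample")
  sample_ids <- header[-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header)))
    stop("malformed data line(s) in ", path, ": line(s) ",
         paste(which(nfield != length(header)) + 1L, collapse = ", "),
         " do not have ", length(header), " fields")
  feature_ids <- vapply(body, `[[`, character(1L), 1L)
  raw <- vapply(body, function(f) f[-1L], character(length(sample_ids)))
  raw <- matrix(raw, nrow = length(sample_ids))  # guards 1-sample edge case
  raw[raw %in% c("", "NA", "na", "null", "NULL")] <- NA_character_
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = length(sample_ids)))
  if (any(is.na(vals) & !is.na(raw)))
    stop("non-numeric expression value(s) in ", path)
  vals <- t(vals)
  if (missing(group_spec) || is.null(group_spec))
    stop("group_spec is required: every sample needs a group label")
  missing_samples <- setdiff(sample_ids, names(group_spec))
  if (length(missing_samples))
    stop("sample(s) in file absent from group_spec: ",
         paste(missing_samples, collapse = ", "))
  expression_matrix(vals, feature_ids, sample_ids,
                    unname(group_spec[sample_ids]),
                    scale = scale, platform_tag = platform_tag)
}

#' Write an expression matrix as TSV
#'
#' @param em an `ExpressionMatrix`.
#' @param path output path.
#' @param id_column header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, id_column = "feature_id") {
  validate_expression_matrix(em)
  df <- data.frame(id = em$feature_ids, em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, em$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Drop high-missingness features and mean-impute the rest
#'
#' Features with more than `max_missing` of their values absent are removed;
#' remaining missing values are imputed by the within-group mean (falling back
#' to the overall feature mean when a whole group is absent).
#'
#' @param em an `ExpressionMatrix`.
#' @param max_missing maximum tolerated fraction of missing values per feature.
#' @return an `ExpressionMatrix` without missing values.
#' @export
clean_missing <- function(em, max_missing = 0.2) {
  validate_expression_matrix(em)
  frac <- rowMeans(is.na(em$values))
  keep <- frac <= max_missing
  vals <- em$values[keep, , drop = FALSE]
  ids <- em$feature_ids[keep]
  if (anyNA(vals)) {
    for (g in unique(em$groups)) {
      cols <- em$groups == g
      sub <- vals[, cols, drop = FALSE]
      gm <- rowMeans(sub, na.rm = TRUE)
      gm[is.nan(gm)] <- rowMeans(vals, na.rm = TRUE)[is.nan(gm)]
      idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(idx)) sub[idx] <- gm[idx[, 1L]]
      vals[, cols] <- sub
    }
  }
  expression_matrix(vals, ids, em$sample_ids, em$groups, scale = em$scale,
                    platform_tag = em$platform_tag,
                    group_levels = em$group_levels)
}

#' Construct a gene-set collection
#'
#' @param sets named list; each element a list with `name` (character) and
#'   `members` (character vector of gene ids, deduplicated).
#' @param universe optional explicit background gene list.
#' @return an object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  sets <- lapply(sets, function(s) {
    members <- unique(as.character(s$members))
    if (!length(members)) stop("empty gene set")
    list(name = as.character(s$name), members = members)
  })
  structure(list(sets = sets, universe = universe),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$members), integer(1L))
  cat(sprintf("GeneSetCollection: %d sets, member counts %d-%d\n",
              length(x$sets), if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: `id <tab> name <tab> member1 <tab> member2 ...`.
#' Duplicate member symbols within a line are deduplicated.
#'
#' @param path GMT file path.
#' @return a `GeneSetCollection`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("malformed GMT line(s) ", paste(short, collapse = ", "),
         " in ", path, ": fewer than 3 tab-separated fields")
  sets <- lapply(fields, function(f)
    list(name = f[[2L]], members = unique(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  gene_set_collection(sets)
}

#' Write gene sets as GMT
#' @param gsc a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gsc, path) {
  stopifnot(inherits(gsc, "GeneSetCollection"))
  lines <- vapply(names(gsc$sets), function(id) {
    s <- gsc$sets[[id]]
    paste(c(id, s$name, s$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Identifiers are the first whitespace-delimited token after `>`. Sequences
#' are upper-cased and T is normalized to U so that downstream seed matching
#' operates on RNA uniformly.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(names(seqs)) == length(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a probe-to-gene platform map
#'
#' Two-column TSV (probe id, gene symbol), possibly many-to-one and
#' one-to-many. Empty probe ids or symbols are rejected.
#'
#' @param path TSV path with header columns `probe` and `gene`.
#' @return data frame with columns `probe`, `gene`.
#' @export
read_platform_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% colnames(df)))
    stop("platform map needs columns 'probe' and 'gene'")
  df <- df[, c("probe", "gene")]
  df$probe <- as.character(df$probe)
  df$gene <- as.character(df$gene)
  if (any(!nzchar(df$probe)) || any(!nzchar(df$gene)))
    stop("platform map contains empty probe ids or gene symbols")
  unique(df)
}

#' Normalize miRNA identifiers
#'
#' Feature identifiers are compared case-sensitively throughout, except miRNA
#' names, which follow the lower-case `hsa-...` convention; this helper
#' lower-cases identifiers bearing a species prefix such as `hsa-` / `HSA-`.
#'
#' @param ids character vector of identifiers.
#' @return normalized character vector.
#' @export
normalize_mirna_ids <- function(ids) {
  hit <- grepl("^[A-Za-z]{3}-", ids)
  ids[hit] <- tolower(ids[hit])
  ids
}

#' Write a bipartite network to disk
#'
#' `edge_tsv` is one edge per line (`mirna`, `partner`, `weight`). `graphml`
#' declares a node `type` attribute (miRNA vs partner class), a `direction`
#' regulation attribute where known, and edge `weight`.
#'
#' @param network a `BipartiteNetwork` (see [bipartite_network()]).
#' @param path output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("edge_tsv", "graphml")) {
  stopifnot(inherits(network, "BipartiteNetwork"))
  format <- match.arg(format)
  edges <- network_edges(network)
  if (format == "edge_tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge TSV written by [write_network()]
#' @param path edge TSV path.
#' @return data frame with columns `mirna`, `partner`, `weight`.
#' @export
read_network_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "partner", "weight") %in% colnames(df)))
    stop("edge table needs columns 'mirna', 'partner', 'weight'")
  df
}
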
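#' Construct a bipartite network
#'
#' Adjacency A = (a_i,j) between miRNAs (left side) and partners — GO terms
#' or genes (right side). Degrees are computed on binary adjacency (edge
#' counts), matching integer degree listings; weighted strength is available
#' separately via the adjacency itself.
#'
#' @param adjacency numeric matrix, rows = miRNAs, columns = partners, with
#'   dimnames; nonzero entries are edges.
#' @param left_direction named character vector (`up`/`down`) for miRNAs.
#' @param right_direction named character vector for partners where known.
#' @param partner_type `"go_term"` or `"gene"`.
#' @return an object of class `BipartiteNetwork`.
#' @export
bipartite_network <- function(adjacency, left_direction = NULL,
                              right_direction = NULL,
                              partner_type = c("gene", "go_term")) {
  partner_type <- match.arg(partner_type)
  adjacency <- as.matrix(adjacency)
  left <- rownames(adjacency)
  right <- colnames(adjacency)
  if (is.null(left)) {
    if (nrow(adjacency)) stop("adjacency needs row names (miRNA ids)")
    left <- character(0)
  }
  if (is.null(right)) {
    if (ncol(adjacency)) stop("adjacency needs column names (partner ids)")
    right <- character(0)
  }
  if (length(intersect(left, right)))
    stop("network must be strictly bipartite: shared node ids found")
  structure(list(
    adjacency = adjacency,
    left_nodes = left,
    right_nodes = right,
    left_direction = left_direction,
    right_direction = right_direction,
    partner_type = partner_type
  ), class = "BipartiteNetwork")
}

#' @export
print.BipartiteNetwork <- function(x, ...) {
  cat(sprintf("BipartiteNetwork: %d miRNAs x %d %ss, %d edges\n",
              length(x$left_nodes), length(x$right_nodes),
              sub("_", " ", x$partner_type), network_edge_count(x)))
  invisible(x)
}

#' Degrees, edge counts and edge lists of a bipartite network
#'
#' @param network a `BipartiteNetwork`.
#' @param side `"left"` (miRNAs) or `"right"` (partners).
#' @return `network_degrees`: named integer vector of binary degrees.
#'   `network_edge_count`: number of edges. `network_edges`: data frame
#'   `mirna`, `partner`, `weight`.
#' @export
network_degrees <- function(network, side = c("left", "right")) {
  side <- match.arg(side)
  b <- network$adjacency != 0
  if (side == "left") rowSums(b) else colSums(b)
}

#' @rdname network_degrees
#' @export
network_edge_count <- function(network) sum(network$adjacency != 0)

#' @rdname network_degrees
#' @export
network_edges <- function(network) {
  idx <- which(network$adjacency != 0, arr.ind = TRUE)
  df <- data.frame(
    mirna = network$left_nodes[idx[, 1L]],
    partner = network$right_nodes[idx[, 2L]],
    weight = network$adjacency[idx],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$mirna, df$partner), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the miRNA-GO bipartite network
#'
#' Edge (m, t) iff at least one gene g exists with (m, g) in the filtered
#' regulatory pairs and g annotated to the significant term t. Only genes
#' that themselves survived the anti-correlation filter contribute edges.
#'
#' @param pairs a `RegulatoryPair` data frame.
#' @param significant_terms term ids (must exist in `gene_sets`).
#' @param gene_sets a `GeneSetCollection`.
#' @param weighted if `TRUE`, a_i,j is the summed pair weight over shared
#'   genes; default binary.
#' @return a `BipartiteNetwork` with `partner_type = "go_term"`.
#' @export
build_mirna_go <- function(pairs, significant_terms, gene_sets,
                           weighted = FALSE) {
  stopifnot(inherits(gene_sets, "GeneSetCollection"))
  missing_terms <- setdiff(significant_terms, names(gene_sets$sets))
  if (length(missing_terms))
    stop("term(s) absent from the collection: ",
         paste(missing_terms, collapse = ", "))
  mirnas <- sort(unique(pairs$mirna_id))
  terms <- sort(unique(as.character(significant_terms)))
  A <- matrix(0, length(mirnas), length(terms),
              dimnames = list(mirnas, terms))
  for (t in terms) {
    members <- gene_sets$sets[[t]]$members
    hit <- pairs[pairs$gene_id %in% members, , drop = FALSE]
    if (nrow(hit)) {
      w <- if (weighted) tapply(hit$weight, hit$mirna_id, sum) else
        tapply(rep(1, nrow(hit)), hit$mirna_id, max)
      A[names(w), t] <- as.numeric(w)
    }
  }
  keep_l <- rowSums(A != 0) > 0
  keep_r <- colSums(A != 0) > 0
  A <- A[keep_l, keep_r, drop = FALSE]
  ld <- direction_lookup(pairs, "mirna")
  bipartite_network(A, left_direction = ld[rownames(A)],
                    right_direction = NULL, partner_type = "go_term")
}

#' Build the miRNA-mRNA bipartite network
#'
#' One edge per distinct (miRNA, gene) regulatory pair.
#'
#' @param pairs a `RegulatoryPair` data frame.
#' @param weighted if `TRUE`, a_i,j carries the pair weight; default binary.
#' @return a `BipartiteNetwork` with `partner_type = "gene"`.
#' @export
build_mirna_mrna <- function(pairs, weighted = FALSE) {
  key <- paste(pairs$mirna_id, pairs$gene_id, sep = "\r")
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  mirnas <- sort(unique(pairs$mirna_id))
  genes <- sort(unique(pairs$gene_id))
  A <- matrix(0, length(mirnas), length(genes),
              dimnames = list(mirnas, genes))
  A[cbind(pairs$mirna_id, pairs$gene_id)] <-
    if (weighted) pairs$weight else 1
  bipartite_network(A,
                    left_direction = direction_lookup(pairs, "mirna"),
                    right_direction = direction_lookup(pairs, "gene"),
                    partner_type = "gene")
}

direction_lookup <- function(pairs, what = c("mirna", "gene")) {
  what <- match.arg(what)
  id <- pairs[[paste0(what, "_id")]]
  dir <- pairs[[paste0(what, "_direction")]]
  if (is.null(dir)) return(NULL)
  stats::setNames(dir, id)[!duplicated(id)]
}

#' Rank network nodes by degree
#'
#' Key nodes are those with the highest degree; ties break lexicographically
#' by node id so listings are deterministic.
#'
#' @param network a `BipartiteNetwork`.
#' @param side `"left"` (miRNAs) or `"right"` (partners).
#' @return data frame `node`, `degree`, descending by degree.
#' @export
rank_key_nodes <- function(network, side = c("left", "right")) {
  side <- match.arg(side)
  deg <- network_degrees(network, side)
  if (!length(deg))
    return(data.frame(node = character(0), degree = integer(0)))
  df <- data.frame(node = names(deg), degree = as.integer(deg),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$node), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Convert a bipartite network to an igraph graph
#'
#' Nodes carry `type` (`"miRNA"` vs the partner class) and `direction`
#' attributes; edges carry `weight`. Used for GraphML export.
#'
#' @param network a `BipartiteNetwork`.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(network) {
  edges <- network_edges(network)
  dir_of <- function(ids, lookup) {
    if (is.null(lookup)) rep(NA_character_, length(ids))
    else unname(lookup[ids])
  }
  nodes <- data.frame(
    name = c(network$left_nodes, network$right_nodes),
    type = c(rep("miRNA", length(network$left_nodes)),
             rep(network$partner_type, length(network$right_nodes))),
    direction = c(dir_of(network$left_nodes, network$left_direction),
                  dir_of(network$right_nodes, network$right_direction)),
    stringsAsFactors = FALSE
  )
  nodes$direction[is.na(nodes$direction)] <- "unknown"
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
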
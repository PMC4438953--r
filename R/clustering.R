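#' Pearson-correlation distance matrix
#'
#' d(x, y) = 1 - r(x, y), the distance metric conventional for expression
#' heat maps: values in \[0, 2\], 0 for identical profiles, 2 for perfect
#' anti-correlation.
#'
#' @param em an `ExpressionMatrix` (or plain numeric matrix with observations
#'   in columns when `axis = "samples"`, rows when `axis = "features"`).
#' @param axis cluster `"samples"` (columns) or `"features"` (rows).
#' @return symmetric distance matrix with zero diagonal, dimnames set to the
#'   clustered ids.
#' @export
pearson_distance <- function(em, axis = c("samples", "features")) {
  axis <- match.arg(axis)
  if (inherits(em, "ExpressionMatrix")) {
    vals <- em$values
    ids <- if (axis == "samples") em$sample_ids else em$feature_ids
  } else {
    vals <- as.matrix(em)
    ids <- if (axis == "samples") colnames(vals) else rownames(vals)
  }
  obs <- if (axis == "samples") vals else t(vals)  # observations in columns
  if (ncol(obs) < 2L) stop("need at least 2 vectors to compute distances")
  sds <- apply(obs, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- if (is.null(ids)) which(sds == 0) else ids[sds == 0]
    stop("zero-variance vector(s): ", paste(bad, collapse = ", "))
  }
  d <- 1 - stats::cor(obs)
  d[d < 0] <- 0  # clamp numerical noise
  diag(d) <- 0
  if (!is.null(ids)) dimnames(d) <- list(ids, ids)
  d
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Cluster-to-cluster distance is the unweighted mean of all member pairwise
#' distances. Merge ties are broken deterministically by smallest pair under
#' (distance, lexicographic member ids), so results are platform-independent.
#'
#' @param d symmetric distance matrix with dimnames (e.g. from
#'   [pearson_distance()]).
#' @return an object of class `Dendrogram`: list with `merges` (data frame
#'   `node_a`, `node_b`, `height`; nodes named by their lexicographically
#'   smallest leaf), `members` (leaf sets per merge), `leaf_order`, `labels`.
#' @export
average_linkage <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 leaves")
  # active clusters: list of member index vectors, keyed by representative id
  clusters <- lapply(seq_len(n), identity)
  reps <- labels
  cur <- d
  merges <- data.frame(node_a = character(0), node_b = character(0),
                       height = numeric(0), stringsAsFactors = FALSE)
  members <- list()
  order_tree <- lapply(seq_len(n), identity)  # leaf orders per cluster
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      cand <- list(i = i, j = j, h = cur[i, j])
      if (is.null(best) || cand$h < best$h ||
          (cand$h == best$h &&
           paste(sort(c(reps[i], reps[j])), collapse = "\1") <
           paste(sort(c(reps[best$i], reps[best$j])), collapse = "\1"))) {
        best <- cand
      }
    }
    i <- best$i; j <- best$j
    a <- reps[i]; b <- reps[j]
    if (b < a) { tmp <- a; a <- b; b <- tmp; tmp <- i; i <- j; j <- tmp }
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    merged <- c(clusters[[i]], clusters[[j]])
    merges <- rbind(merges, data.frame(node_a = a, node_b = b,
                                       height = best$h,
                                       stringsAsFactors = FALSE))
    members[[length(members) + 1L]] <- list(
      a = sort(labels[clusters[[i]]]),   # after swap, reps[i] == a
      b = sort(labels[clusters[[j]]]),
      all = sort(labels[merged]))
    # UPGMA update: unweighted mean over member pairs
    newd <- (cur[i, ] * ni + cur[j, ] * nj) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    cur <- cur[keep, keep, drop = FALSE]
    cur <- rbind(cbind(cur, newd[keep]), c(newd[keep], 0))
    order_new <- c(order_tree[[i]], order_tree[[j]])
    clusters <- c(clusters[keep], list(merged))
    order_tree <- c(order_tree[keep], list(order_new))
    reps <- c(reps[keep], a)
  }
  structure(list(merges = merges, members = members,
                 leaf_order = labels[order_tree[[1L]]], labels = labels),
            class = "Dendrogram")
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram: %d leaves, %d merges, root height %.4g\n",
              length(x$labels), nrow(x$merges),
              x$merges$height[nrow(x$merges)]))
  invisible(x)
}

#' Two-cluster cut at the dendrogram root
#'
#' Removes the final (root) merge and labels the component containing the
#' lexicographically smallest normal-sample id as `cluster1` (falling back to
#' the smallest leaf overall when no normal id is supplied or present).
#'
#' @param dend a `Dendrogram`.
#' @param normal_ids sample ids of the normal group, used to anchor the
#'   `cluster1` label.
#' @return named character vector mapping each leaf to `"cluster1"` /
#'   `"cluster2"`.
#' @export
cut_two <- function(dend, normal_ids = character()) {
  stopifnot(inherits(dend, "Dendrogram"))
  n <- length(dend$labels)
  if (n < 2L) stop("need at least 2 leaves")
  root <- dend$members[[n - 1L]]
  comp1 <- root$a
  comp2 <- root$b
  anchor <- if (length(normal_ids) && any(normal_ids %in% dend$labels))
    min(intersect(normal_ids, dend$labels)) else min(dend$labels)
  first <- if (anchor %in% comp1) comp1 else comp2
  second <- setdiff(dend$labels, first)
  out <- c(stats::setNames(rep("cluster1", length(first)), first),
           stats::setNames(rep("cluster2", length(second)), second))
  out[dend$labels]
}

#' Newick export of a dendrogram
#' @param dend a `Dendrogram`.
#' @return single Newick string with branch lengths derived from merge
#'   heights (ultrametric: leaf depth = root height / 2).
#' @export
as_newick <- function(dend) {
  stopifnot(inherits(dend, "Dendrogram"))
  n <- length(dend$labels)
  # rebuild subtree strings bottom-up following the merge order
  node <- as.list(dend$labels)
  names(node) <- dend$labels
  height <- stats::setNames(rep(0, n), dend$labels)
  for (k in seq_len(nrow(dend$merges))) {
    a <- dend$merges$node_a[k]; b <- dend$merges$node_b[k]
    h <- dend$merges$height[k] / 2
    str <- sprintf("(%s:%g,%s:%g)", node[[a]], h - height[[a]],
                   node[[b]], h - height[[b]])
    node[[a]] <- str
    height[[a]] <- h
    node[[b]] <- NULL
  }
  paste0(node[[1L]], ";")
}
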
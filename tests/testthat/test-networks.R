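sample_pairs <- function(n_mir = 5, n_gene = 10, n = 15) {
  mirnas <- sprintf("m%02d", seq_len(n_mir))
  genes <- sprintf("g%02d", seq_len(n_gene))
  df <- unique(data.frame(
    mirna_id = sample(mirnas, n, TRUE), gene_id = sample(genes, n, TRUE),
    stringsAsFactors = FALSE))
  df$mirna_direction <- sample(c("up", "down"), nrow(df), TRUE)
  df$mirna_log_fc <- ifelse(df$mirna_direction == "up", 2, -2)
  df$gene_direction <- ifelse(df$mirna_direction == "up", "down", "up")
  df$gene_log_fc <- -df$mirna_log_fc / 2
  df$weight <- abs(df$mirna_log_fc * df$gene_log_fc)
  class(df) <- c("RegulatoryPair", "data.frame")
  df
}

test_that("miRNA-mRNA network has one edge per distinct pair", {
  pairs <- sample_pairs(3, 4, 6)
  net <- build_mirna_mrna(pairs)
  expect_equal(network_edge_count(net), nrow(pairs))
  # duplicated input rows do not duplicate edges
  net2 <- build_mirna_mrna(rbind(pairs, pairs[1, ]))
  expect_equal(network_edge_count(net2), nrow(pairs))
  # three distinct pairs -> three edges
  p3 <- sample_pairs(3, 3, 3)
  expect_equal(network_edge_count(build_mirna_mrna(p3)), nrow(p3))
})

test_that("miRNA-GO edges require a shared filtered gene", {
  pairs <- sample_pairs(1, 1, 1)   # single pair (m01, g01)
  gsc <- gene_set_collection(list(
    T1 = list(name = "with gene", members = c("g01", "other")),
    T2 = list(name = "without", members = "other")))
  net <- build_mirna_go(pairs, c("T1", "T2"), gsc)
  expect_equal(network_edge_count(net), 1L)
  expect_equal(unname(network_degrees(net, "left")["m01"]), 1)
  expect_equal(unname(network_degrees(net, "right")["T1"]), 1)
  expect_false("T2" %in% net$right_nodes)
  expect_error(build_mirna_go(pairs, "missing_term", gsc), "absent")
})

test_that("GO-network edge count equals the brute-force double loop", {
  withr::local_seed(41)
  for (rep in 1:5) {
    pairs <- sample_pairs(6, 12, 25)
    genes <- sprintf("g%02d", 1:12)
    sets <- lapply(1:6, function(i)
      list(name = paste0("t", i), members = sample(genes, sample(2:6, 1))))
    names(sets) <- sprintf("T%d", 1:6)
    gsc <- gene_set_collection(sets)
    net <- build_mirna_go(pairs, names(sets), gsc)
    # oracle: explicit loop over (miRNA, term)
    want <- 0L
    for (m in unique(pairs$mirna_id)) for (t in names(sets)) {
      shared <- intersect(pairs$gene_id[pairs$mirna_id == m],
                          sets[[t]]$members)
      if (length(shared)) want <- want + 1L
    }
    expect_equal(network_edge_count(net), want)
  }
})

test_that("degree sums balance and edge removal decrements one per side", {
  withr::local_seed(42)
  for (rep in 1:5) {
    net <- build_mirna_mrna(sample_pairs(5, 10, 20))
    l <- network_degrees(net, "left"); r <- network_degrees(net, "right")
    expect_equal(sum(l), network_edge_count(net))
    expect_equal(sum(r), network_edge_count(net))
    # drop one edge
    idx <- which(net$adjacency != 0, arr.ind = TRUE)[1, , drop = FALSE]
    adj <- net$adjacency; adj[idx] <- 0
    net2 <- bipartite_network(adj, partner_type = "gene")
    l2 <- network_degrees(net2, "left"); r2 <- network_degrees(net2, "right")
    expect_equal(sum(l) - sum(l2), 1)
    expect_equal(sum(abs(l - l2[names(l)])), 1)
    expect_equal(sum(abs(r - r2[names(r)])), 1)
  }
})

test_that("rank_key_nodes orders by degree with lexicographic ties", {
  adj <- matrix(c(1, 1, 1, 0,
                  0, 1, 0, 0,
                  1, 1, 1, 0), 3, 4, byrow = TRUE,
                dimnames = list(c("a", "c", "b"), paste0("t", 1:4)))
  net <- bipartite_network(adj, partner_type = "go_term")
  ranked <- rank_key_nodes(net, "left")
  expect_equal(ranked$node, c("a", "b", "c"))
  expect_equal(ranked$degree, c(3L, 3L, 1L))
  empty <- bipartite_network(matrix(0, 0, 0))
  expect_equal(nrow(rank_key_nodes(empty, "left")), 0L)
})

test_that("strict bipartiteness is enforced", {
  adj <- matrix(1, 1, 1, dimnames = list("x", "x"))
  expect_error(bipartite_network(adj), "strictly bipartite")
})

test_that("published degree listings balance across the two sides", {
  # the printed characteristics tables of both networks: miRNA-side and
  # partner-side degree columns must sum to the same edge count
  for (f in c("go_network_degrees.tsv", "mirna_mrna_network_degrees.tsv")) {
    tab <- read.delim(system.file("extdata", f, package = "mirmrna"))
    sums <- tapply(tab$degree, tab$side == "miRNA", sum)
    expect_equal(unname(sums[["TRUE"]]), unname(sums[["FALSE"]]),
                 info = f)
  }
  go <- read.delim(system.file("extdata", "go_network_degrees.tsv",
                               package = "mirmrna"))
  expect_equal(sum(go$degree[go$side == "miRNA"]), 100L)
  mrna <- read.delim(system.file("extdata", "mirna_mrna_network_degrees.tsv",
                                 package = "mirmrna"))
  expect_equal(sum(mrna$degree[mrna$side == "miRNA"]), 88L)
  # node counts of the published miRNA-mRNA network: 19 miRNAs, 68 mRNAs
  expect_equal(sum(mrna$side == "miRNA"), 19L)
  expect_equal(sum(mrna$side == "gene"), 68L)
})
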
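test_that("TSV expression parsing handles fixtures, missing values and errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1\tS2",
               "g1\t1.5\t2.5",
               "g2\t\t4.0",
               "g3\t0.25\t8"), path)
  em <- read_expression(path, "tsv",
                        group_spec = c(S1 = "tumor", S2 = "normal"))
  expect_equal(n_features(em), 3L)
  expect_equal(n_samples(em), 2L)
  expect_equal(em$values[1, ], c(1.5, 2.5), ignore_attr = TRUE)
  expect_true(is.na(em$values[2, 1]))  # absent, not zero
  expect_equal(em$groups, c("tumor", "normal"))

  # sample missing from group_spec
  expect_error(read_expression(path, "tsv", c(S1 = "tumor")),
               "absent from group_spec")
  # malformed line
  writeLines(c("feature_id\tS1\tS2", "g1\t1.0"), path)
  expect_error(read_expression(path, "tsv",
                               c(S1 = "tumor", S2 = "normal")),
               "malformed")
})

test_that("expression TSV round trip is the identity and drops no rows", {
  withr::local_seed(11)
  for (rep in 1:3) {
    nf <- sample(3:20, 1); ns <- sample(2:8, 1)
    em <- make_em(nf, ceiling(ns / 2), floor(ns / 2) + 1)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_expression(em, path)
    spec <- setNames(em$groups, em$sample_ids)
    back <- read_expression(path, "tsv", spec, scale = "log2")
    expect_equal(back$values, em$values, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(back$feature_ids, em$feature_ids)
    expect_equal(back$sample_ids, em$sample_ids)
    # no silent row drops: data lines == features
    expect_equal(length(readLines(path)) - 1L, n_features(em))
  }
})

test_that("series-matrix block parses to the same values as plain TSV", {
  withr::local_seed(5)
  em <- make_em(4, 2, 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression(em, tsv)
  sm <- withr::local_tempfile(fileext = ".txt")
  body <- readLines(tsv)
  quoted <- vapply(strsplit(body, "\t"), function(f)
    paste0('"', f[1L], '"\t', paste(f[-1L], collapse = "\t")),
    character(1L))
  writeLines(c("!Sample_title\t\"a\"\t\"b\"",
               "!series_matrix_table_begin", quoted,
               "!series_matrix_table_end"), sm)
  spec <- setNames(em$groups, em$sample_ids)
  a <- read_expression(tsv, "tsv", spec, scale = "log2")
  b <- read_expression(sm, "series_matrix", spec, scale = "log2")
  expect_equal(a$values, b$values, ignore_attr = TRUE)
  expect_equal(a$feature_ids, b$feature_ids)
})

test_that("ExpressionMatrix invariants are enforced", {
  expect_error(expression_matrix(matrix(1, 2, 2), c("a", "b"),
                                 c("s", "s"), c("tumor", "normal")),
               "duplicate sample ids")
  expect_error(expression_matrix(matrix(1, 2, 2), c("a", "b"),
                                 c("s1", "s2"), c("tumor", "other")),
               "outside declared set")
  expect_error(expression_matrix(matrix(1, 2, 2), "a",
                                 c("s1", "s2"), c("tumor", "normal")),
               "feature ids")
  # duplicate feature ids are allowed (probe-level data)
  em <- expression_matrix(matrix(1, 2, 2), c("p", "p"), c("s1", "s2"),
                          c("tumor", "normal"))
  expect_s3_class(em, "ExpressionMatrix")
})

test_that("GMT reading, deduplication, errors and round trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tfirst set\ta\tb\tc",
               "S2\tsecond set\tx\ty\tz\tw\tv"), path)
  gsc <- read_gene_sets(path)
  expect_length(gsc$sets, 2L)
  expect_length(gsc$sets$S1$members, 3L)
  expect_length(gsc$sets$S2$members, 5L)

  writeLines("S1\tdup\ta\tb\ta", path)
  expect_length(read_gene_sets(path)$sets$S1$members, 2L)

  writeLines(c("OK\tname\tg1", "BAD\tonly-name"), path)
  expect_error(read_gene_sets(path), "line\\(s\\) 2")

  withr::local_seed(3)
  sets <- lapply(1:5, function(i) list(
    name = paste("set", i),
    members = sample(letters, sample(2:10, 1))))
  names(sets) <- paste0("T", 1:5)
  gsc <- gene_set_collection(sets)
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(gsc, out)
  back <- read_gene_sets(out)
  expect_equal(back$sets, gsc$sets)
})

test_that("FASTA reading normalizes case and T/U and handles wrapping", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">mir-1 some description", "acgu",
               ">utr-1", "ACGT", "ACGT"), path)
  seqs <- read_fasta(path)
  expect_length(seqs, 2L)
  expect_equal(seqs[["mir-1"]], "ACGU")          # uppercased, id first token
  expect_equal(seqs[["utr-1"]], "ACGUACGU")      # wrapped lines joined, T->U

  # multi-line wrapped record equals its single-line encoding
  single <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGUACGUACGU"), single)
  wrapped <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGU", "ACGU", "ACGU"), wrapped)
  expect_equal(read_fasta(single), read_fasta(wrapped))

  # write/read round trip
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, out, width = 3)
  expect_equal(read_fasta(out), seqs)
})

test_that("network edge TSV writes, degenerates and round trips", {
  pairs <- data.frame(
    mirna_id = c("m1", "m1", "m2"), gene_id = c("gA", "gB", "gA"),
    mirna_direction = "up", mirna_log_fc = 2,
    gene_direction = "down", gene_log_fc = -2, weight = 4,
    stringsAsFactors = FALSE)
  class(pairs) <- c("RegulatoryPair", "data.frame")
  net <- build_mirna_mrna(pairs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path, "edge_tsv")
  edges <- read_network_edges(path)
  expect_equal(nrow(edges), 3L)
  expect_setequal(paste(edges$mirna, edges$partner),
                  c("m1 gA", "m1 gB", "m2 gA"))

  # empty network: header-only file, no error
  empty <- bipartite_network(matrix(0, 0, 0))
  write_network(empty, path, "edge_tsv")
  expect_equal(length(readLines(path)), 1L)
  expect_error(write_network(net, path, "nonsense"))

  # graphml export carries type and direction attributes
  gpath <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gpath, "graphml")
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_setequal(igraph::V(g)$type[igraph::V(g)$name %in% c("m1", "m2")],
                  "miRNA")
  expect_true("direction" %in% igraph::vertex_attr_names(g))
})

test_that("clean_missing drops high-missingness features and imputes within group", {
  vals <- matrix(c(1, 2, 3, 4,
                   NA, NA, NA, 8,
                   1, NA, 5, 7), nrow = 3, byrow = TRUE)
  em <- expression_matrix(vals, c("keep", "drop", "impute"),
                          paste0("s", 1:4),
                          c("tumor", "tumor", "normal", "normal"))
  cleaned <- clean_missing(em, max_missing = 0.5)
  expect_equal(cleaned$feature_ids, c("keep", "impute"))
  # s2 of 'impute' is a tumor sample: imputed with the tumor-group mean (1)
  expect_equal(cleaned$values[2, 2], 1)
  expect_false(anyNA(cleaned$values))
})

test_that("miRNA id normalization lower-cases species-prefixed names only", {
  expect_equal(normalize_mirna_ids(c("HSA-MiR-21", "hsa-let-7f", "GENE1")),
               c("hsa-mir-21", "hsa-let-7f", "GENE1"))
})
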
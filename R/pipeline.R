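#' Pipeline run configuration
#'
#' A flat key/value configuration for the end-to-end run. All published
#' threshold defaults live here, never inside stage logic: miRNA DE at
#' fold-change > 4, P < 0.01, FDR < 0.01; mRNA DE at P < 0.01, FDR < 0.01
#' (no fold-change cut: `mrna_fc = 1`); GO enrichment at P < 0.01; pathway
#' enrichment at P < 0.05 with run-level FDR < 0.05. The default blacklist
#' carries hsa-miR-923, an array probe retracted from miRBase.
#'
#' @param mirna_expr,mrna_expr,confirm_expr expression TSV paths.
#' @param groups_file sample-to-group TSV with columns `sample`, `group`
#'   (and optionally `cohort`).
#' @param mirna_fasta,utr_fasta sequence FASTA paths (de-novo prediction).
#' @param go_gmt,pathway_gmt gene-set GMT paths (`pathway_gmt` optional).
#' @param predictions_file precomputed miRNA-target TSV (import mode).
#' @param platform_map_file optional probe-to-gene TSV.
#' @param expression_scale scale of the stored expression values.
#' @param mirna_fc,mirna_p,mirna_fdr miRNA DE thresholds.
#' @param mrna_fc,mrna_p,mrna_fdr mRNA DE thresholds (`mrna_fc = 1` means
#'   direction only, no fold cut).
#' @param go_p,go_fdr,pathway_p,pathway_fdr enrichment cuts.
#' @param blacklist miRNA ids excluded regardless of statistics.
#' @param prediction_mode `"de-novo"` (seed matching) or `"import"`.
#' @param universe_mode `"annotation"` (genes with >= 1 annotation) or
#'   `"all_genes"` (every gene on the array).
#' @param out_dir output directory.
#' @param seed random seed.
#' @return a `RunConfig` list.
#' @export
run_config <- function(mirna_expr = NULL, mrna_expr = NULL,
                       confirm_expr = NULL, groups_file = NULL,
                       mirna_fasta = NULL, utr_fasta = NULL,
                       go_gmt = NULL, pathway_gmt = NULL,
                       predictions_file = NULL, platform_map_file = NULL,
                       expression_scale = c("linear", "log2"),
                       mirna_fc = 4, mirna_p = 0.01, mirna_fdr = 0.01,
                       mrna_fc = 1, mrna_p = 0.01, mrna_fdr = 0.01,
                       go_p = 0.01, go_fdr = 1,
                       pathway_p = 0.05, pathway_fdr = 0.05,
                       blacklist = "hsa-mir-923",
                       prediction_mode = c("de-novo", "import"),
                       universe_mode = c("annotation", "all_genes"),
                       out_dir = "mirmrna_out", seed = 1) {
  structure(list(
    mirna_expr = mirna_expr, mrna_expr = mrna_expr,
    confirm_expr = confirm_expr, groups_file = groups_file,
    mirna_fasta = mirna_fasta, utr_fasta = utr_fasta,
    go_gmt = go_gmt, pathway_gmt = pathway_gmt,
    predictions_file = predictions_file,
    platform_map_file = platform_map_file,
    expression_scale = match.arg(expression_scale),
    mirna_fc = mirna_fc, mirna_p = mirna_p, mirna_fdr = mirna_fdr,
    mrna_fc = mrna_fc, mrna_p = mrna_p, mrna_fdr = mrna_fdr,
    go_p = go_p, go_fdr = go_fdr,
    pathway_p = pathway_p, pathway_fdr = pathway_fdr,
    blacklist = normalize_mirna_ids(blacklist),
    prediction_mode = match.arg(prediction_mode),
    universe_mode = match.arg(universe_mode),
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "RunConfig")
}

#' Read / write a flat key=value run-configuration file
#'
#' Unknown keys are rejected; numeric-looking values are converted. The
#' `blacklist` value is comma-separated.
#'
#' @param path configuration file path.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[[`, character(1L), 1L))
  vals <- trimws(vapply(kv, function(f)
    paste(f[-1L], collapse = "="), character(1L)))
  defaults <- run_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  numeric_keys <- c("mirna_fc", "mirna_p", "mirna_fdr", "mrna_fc", "mrna_p",
                    "mrna_fdr", "go_p", "go_fdr", "pathway_p",
                    "pathway_fdr", "seed")
  for (k in intersect(keys, numeric_keys)) args[[k]] <- as.numeric(args[[k]])
  if ("blacklist" %in% keys)
    args$blacklist <- trimws(strsplit(args$blacklist, ",")[[1L]])
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config a `RunConfig`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (is.null(v)) v <- ""
    paste0(k, " = ", paste(v, collapse = ","))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

stage_path <- function(config, name) file.path(config$out_dir, name)

require_stage_file <- function(config, name, stage) {
  p <- stage_path(config, name)
  if (!file.exists(p))
    stop("missing '", name, "'; run the '", stage, "' stage first")
  p
}

load_groups <- function(config, cohort) {
  df <- utils::read.delim(config$groups_file, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(df)))
    stop("groups file needs columns 'sample' and 'group'")
  if ("cohort" %in% colnames(df) && cohort %in% df$cohort)
    df <- df[df$cohort == cohort, , drop = FALSE]
  stats::setNames(df$group, df$sample)
}

load_cohort <- function(config, path, cohort) {
  em <- read_expression(path, "tsv", load_groups(config, cohort),
                        scale = config$expression_scale)
  em <- clean_missing(em)
  if (em$scale == "linear") em <- log_transform(em, offset = 0) else em
}

de_stage_one <- function(config, path, cohort, thresholds, blacklist,
                         normalize_ids = FALSE, tag) {
  em <- load_cohort(config, path, cohort)
  if (normalize_ids) em$feature_ids <- normalize_mirna_ids(em$feature_ids)
  full <- moderated_t_test(em)
  filtered <- apply_thresholds(full, thresholds, blacklist)
  write_de_table(full, stage_path(config, paste0("de_", tag, "_full.tsv")))
  write_de_table(filtered,
                 stage_path(config, paste0("de_", tag, "_filtered.tsv")))
  list(em = em, full = full, filtered = filtered)
}

#' Run the complete integrated analysis
#'
#' Executes differential expression on the miRNA and both mRNA cohorts,
#' hierarchical clustering of the mRNA test cohort on its differential
#' features, target prediction (de novo seed matching or table import),
#' anti-correlation integration, GO and pathway enrichment, both bipartite
#' networks, and cross-cohort direction confirmation. All stage outputs are
#' written under `config$out_dir`; the machine-readable contract is
#' `report.json` with counts at every stage.
#'
#' An empty differential miRNA list is not an error: the pipeline completes
#' with empty downstream outputs and a warning.
#'
#' @param config a `RunConfig`.
#' @return the run report, invisibly (a named list, also written as JSON).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  report <- list(seed = config$seed)

  message("stage de: miRNA cohort")
  mir <- de_stage_one(config, config$mirna_expr, "mirna",
                      de_thresholds(config$mirna_fc, config$mirna_p,
                                    config$mirna_fdr),
                      config$blacklist, normalize_ids = TRUE, tag = "mirna")
  report$n_de_mirna <- nrow(mir$filtered)
  report$n_de_mirna_up <- sum(mir$filtered$direction == "up")
  report$n_de_mirna_down <- sum(mir$filtered$direction == "down")
  if (!nrow(mir$filtered))
    warning("no miRNA passed the thresholds; downstream outputs are empty")

  message("stage de: mRNA test cohort")
  mrna <- de_stage_one(config, config$mrna_expr, "mrna_test",
                       de_thresholds(max(config$mrna_fc, 1), config$mrna_p,
                                     config$mrna_fdr),
                       character(), tag = "mrna")
  de_genes <- mrna$filtered
  if (!is.null(config$platform_map_file)) {
    pm <- read_platform_map(config$platform_map_file)
    de_genes <- collapse_probes(de_genes, pm)
  }
  report$n_de_mrna <- nrow(de_genes)
  report$n_de_mrna_up <- sum(de_genes$direction == "up")
  report$n_de_mrna_down <- sum(de_genes$direction == "down")

  message("stage cluster: mRNA test cohort on DE features")
  cl <- cluster_stage(config, mrna$em, mrna$filtered$feature_id)
  report$cluster_sizes <- cl

  message("stage targets (", config$prediction_mode, ")")
  if (config$prediction_mode == "import") {
    if (is.null(config$predictions_file))
      stop("prediction_mode 'import' needs predictions_file")
    predicted <- import_predictions(config$predictions_file)
  } else {
    mirnas <- read_fasta(config$mirna_fasta)
    names(mirnas) <- normalize_mirna_ids(names(mirnas))
    utrs <- read_fasta(config$utr_fasta)
    keep <- names(mirnas) %in% mir$filtered$feature_id
    predicted <- if (any(keep))
      predict_targets(mirnas[keep], utrs)
    else
      predict_targets(mirnas, utrs)[0, , drop = FALSE]
  }
  export_predictions(predicted, stage_path(config, "predicted_pairs.tsv"))
  report$n_predicted_associations <- nrow(predicted)

  message("stage integrate")
  pairs <- intersect_and_filter(predicted, mir$filtered, de_genes)
  write_pairs(pairs, stage_path(config, "regulatory_pairs.tsv"))
  report$n_regulatory_pairs <- nrow(pairs)

  message("stage enrich")
  go_sets <- read_gene_sets(config$go_gmt)
  universe <- if (config$universe_mode == "all_genes")
    unique(de_stage_universe(mrna$em)) else NULL
  go_res <- enrich_or_empty(unique(pairs$gene_id), go_sets, universe,
                            config$go_p, config$go_fdr)
  write_enrichment(go_res, stage_path(config, "enrichment_go.tsv"))
  report$n_significant_go <- sum(go_res$significant)
  if (!is.null(config$pathway_gmt)) {
    pw_sets <- read_gene_sets(config$pathway_gmt)
    pw_res <- enrich_or_empty(unique(pairs$gene_id), pw_sets, universe,
                              config$pathway_p, config$pathway_fdr)
    write_enrichment(pw_res, stage_path(config, "enrichment_pathway.tsv"))
    report$n_significant_pathway <- sum(pw_res$significant)
  }

  message("stage network")
  sig_terms <- go_res$term_id[go_res$significant]
  go_net <- build_mirna_go(pairs, sig_terms, go_sets)
  mrna_net <- build_mirna_mrna(pairs)
  for (spec in list(list(net = go_net, tag = "go"),
                    list(net = mrna_net, tag = "mrna"))) {
    write_network(spec$net,
                  stage_path(config, paste0("network_", spec$tag,
                                            "_edges.tsv")), "edge_tsv")
    write_network(spec$net,
                  stage_path(config, paste0("network_", spec$tag,
                                            ".graphml")), "graphml")
    side_block <- function(side, df) {
      if (!nrow(df))
        return(data.frame(side = character(0), node = character(0),
                          degree = integer(0)))
      cbind(side = side, df)
    }
    chars <- rbind(
      side_block("miRNA", rank_key_nodes(spec$net, "left")),
      side_block(spec$net$partner_type, rank_key_nodes(spec$net, "right")))
    utils::write.table(chars,
                       stage_path(config, paste0("network_", spec$tag,
                                                 "_characteristics.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report$go_network <- list(n_mirnas = length(go_net$left_nodes),
                            n_terms = length(go_net$right_nodes),
                            n_edges = network_edge_count(go_net))
  report$mrna_network <- list(n_mirnas = length(mrna_net$left_nodes),
                              n_genes = length(mrna_net$right_nodes),
                              n_edges = network_edge_count(mrna_net))

  message("stage confirm")
  confirm <- de_stage_one(config, config$confirm_expr, "mrna_confirm",
                          de_thresholds(max(config$mrna_fc, 1),
                                        config$mrna_p, config$mrna_fdr),
                          character(), tag = "confirm")
  candidates <- mrna_net$right_nodes
  if (length(candidates)) {
    conc <- confirm_directions(candidates, mrna$full, confirm$full)
    write_concordance(conc, stage_path(config, "concordance.json"))
    report$confirmation <- list(n_candidates = length(candidates),
                                n_detected = conc$n_detected,
                                n_concordant = conc$n_concordant)
  } else {
    report$confirmation <- list(n_candidates = 0L, n_detected = 0L,
                                n_concordant = 0L)
  }

  jsonlite::write_json(report, stage_path(config, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

de_stage_universe <- function(em) em$feature_ids

enrich_or_empty <- function(query, sets, universe, max_p, max_fdr) {
  if (!length(query)) {
    out <- enrich("placeholder", gene_set_collection(list(
      T0 = list(name = "t", members = "placeholder"))),
      universe = "placeholder")[0, , drop = FALSE]
    class(out) <- c("EnrichmentResult", "data.frame")
    return(out)
  }
  enrich(query, sets, universe, max_p = max_p, max_fdr = max_fdr)
}

cluster_stage <- function(config, em, feature_ids) {
  idx <- which(em$feature_ids %in% feature_ids)
  if (length(idx) < 2L || ncol(em$values) < 2L) {
    writeLines("too few differential features for clustering",
               stage_path(config, "clusters_mrna.txt"))
    return(list(cluster1 = 0L, cluster2 = 0L))
  }
  sub <- em$values[idx, , drop = FALSE]
  keep <- apply(sub, 2L, stats::sd) > 0
  d <- pearson_distance(
    expression_matrix(sub[, keep, drop = FALSE], em$feature_ids[idx],
                      em$sample_ids[keep], em$groups[keep],
                      scale = em$scale), "samples")
  dend <- average_linkage(d)
  writeLines(as_newick(dend), stage_path(config, "dendrogram_mrna.newick"))
  cut <- cut_two(dend, normal_ids = em$sample_ids[em$groups == "normal"])
  utils::write.table(
    data.frame(sample = names(cut), cluster = unname(cut),
               group = em$groups[match(names(cut), em$sample_ids)]),
    stage_path(config, "clusters_mrna.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  # heat-map analog: reordered matrix export
  ord <- match(dend$leaf_order, em$sample_ids)
  utils::write.table(
    data.frame(feature_id = em$feature_ids[idx],
               sub[, ord, drop = FALSE], check.names = FALSE),
    stage_path(config, "heatmap_mrna.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  as.list(table(cut))
}

#' Command-line entry point
#'
#' Dispatches the per-stage subcommands (`simulate`, `run-all`, `de`,
#' `targets`, `integrate`, `enrich`, `network`, `confirm`, `config-init`).
#' Stage subcommands read predecessor outputs from the configured output
#' directory and fail with a usage error naming the required prior stage
#' when they are missing. Installed as `inst/cli/mirmrna`.
#'
#' @param args command-line arguments (default: `commandArgs(trailingOnly =
#'   TRUE)`).
#' @return exit status 0 on success, invisibly; stops on error.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: mirmrna <simulate|run-all|de|targets|integrate|enrich|",
         "network|confirm|config-init> [--config FILE] [--seed N] ",
         "[--out DIR]")
  cmd <- args[[1L]]
  opts <- parse_cli_opts(args[-1L])
  if (cmd == "config-init") {
    cfg <- run_config()
    path <- if (!is.null(opts$out)) opts$out else "mirmrna.config"
    write_run_config(cfg, path)
    message("wrote default configuration to ", path)
    return(invisible(0L))
  }
  config <- if (!is.null(opts$config)) read_run_config(opts$config)
  else run_config()
  if (!is.null(opts$out)) config$out_dir <- opts$out
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(cmd,
    simulate = {
      ds <- synth_generate(synth_config(seed = config$seed))
      paths <- synth_write(ds, file.path(config$out_dir, "input"))
      message("synthetic inputs written under ",
              file.path(config$out_dir, "input"))
    },
    `run-all` = {
      run_all(resolve_simulated_inputs(config))
    },
    de = {
      config <- resolve_simulated_inputs(config)
      thr <- de_thresholds(config$mirna_fc, config$mirna_p, config$mirna_fdr)
      de_stage_one(config, config$mirna_expr, "mirna", thr,
                   config$blacklist, normalize_ids = TRUE, tag = "mirna")
      de_stage_one(config, config$mrna_expr, "mrna_test",
                   de_thresholds(max(config$mrna_fc, 1), config$mrna_p,
                                 config$mrna_fdr), character(),
                   tag = "mrna")
      message("DE tables written under ", config$out_dir)
    },
    targets = {
      config <- resolve_simulated_inputs(config)
      de_path <- require_stage_file(config, "de_mirna_filtered.tsv", "de")
      de_mir <- read_de_table(de_path)
      mirnas <- read_fasta(config$mirna_fasta)
      names(mirnas) <- normalize_mirna_ids(names(mirnas))
      keep <- names(mirnas) %in% de_mir$feature_id
      pred <- if (any(keep)) predict_targets(mirnas[keep],
                                             read_fasta(config$utr_fasta))
        else stop("no differential miRNA has a sequence in the FASTA")
      export_predictions(pred, stage_path(config, "predicted_pairs.tsv"))
    },
    integrate = {
      config <- resolve_simulated_inputs(config)
      pred <- import_predictions(
        require_stage_file(config, "predicted_pairs.tsv", "targets"))
      de_mir <- read_de_table(
        require_stage_file(config, "de_mirna_filtered.tsv", "de"))
      de_gene <- read_de_table(
        require_stage_file(config, "de_mrna_filtered.tsv", "de"))
      write_pairs(intersect_and_filter(pred, de_mir, de_gene),
                  stage_path(config, "regulatory_pairs.tsv"))
    },
    enrich = {
      config <- resolve_simulated_inputs(config)
      pairs <- read_pairs(
        require_stage_file(config, "regulatory_pairs.tsv", "integrate"))
      res <- enrich_or_empty(unique(pairs$gene_id),
                             read_gene_sets(config$go_gmt), NULL,
                             config$go_p, config$go_fdr)
      write_enrichment(res, stage_path(config, "enrichment_go.tsv"))
    },
    network = {
      config <- resolve_simulated_inputs(config)
      pairs <- read_pairs(
        require_stage_file(config, "regulatory_pairs.tsv", "integrate"))
      net <- build_mirna_mrna(pairs)
      write_network(net, stage_path(config, "network_mrna_edges.tsv"),
                    "edge_tsv")
      write_network(net, stage_path(config, "network_mrna.graphml"),
                    "graphml")
    },
    confirm = {
      config <- resolve_simulated_inputs(config)
      pairs <- read_pairs(
        require_stage_file(config, "regulatory_pairs.tsv", "integrate"))
      de_test <- read_de_table(
        require_stage_file(config, "de_mrna_full.tsv", "de"))
      confirm <- de_stage_one(config, config$confirm_expr, "mrna_confirm",
                              de_thresholds(max(config$mrna_fc, 1),
                                            config$mrna_p, config$mrna_fdr),
                              character(), tag = "confirm")
      conc <- confirm_directions(unique(pairs$gene_id), de_test,
                                 confirm$full)
      write_concordance(conc, stage_path(config, "concordance.json"))
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}

# when inputs are unset but a simulate stage has run in out_dir, pick up its
# conventional file layout
resolve_simulated_inputs <- function(config) {
  input <- file.path(config$out_dir, "input")
  fill <- function(key, name) {
    if (is.null(config[[key]]) && file.exists(file.path(input, name)))
      config[[key]] <<- file.path(input, name)
  }
  fill("mirna_expr", "mirna_expression.tsv")
  fill("mrna_expr", "mrna_test_expression.tsv")
  fill("confirm_expr", "mrna_confirm_expression.tsv")
  fill("mirna_fasta", "mirna.fasta")
  fill("utr_fasta", "utr.fasta")
  fill("go_gmt", "terms.gmt")
  fill("groups_file", "groups.tsv")
  for (key in c("mirna_expr", "mrna_expr", "confirm_expr", "groups_file"))
    if (is.null(config[[key]]))
      stop("input '", key, "' is not configured; run 'simulate' first or ",
           "set it in the config file")
  config
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(args)) stop("missing value for --", key)
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}
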
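#' Configuration for the synthetic miRNA/mRNA cohort generator
#'
#' Defaults emulate the shapes of the original study cohorts: a miRNA series
#' with 15 tumor / 3 normal samples, an mRNA test series with 26 / 12 and an
#' mRNA confirmation series with 37 / 20. Expression is generated directly on
#' the log2 scale as baseline + Gaussian noise, with planted log2 effects
#' added to tumor samples of the differential features; planted targets of an
#' up-miRNA are down-regulated and vice versa.
#'
#' @param n_mirnas,n_genes feature counts.
#' @param mirna_samples,mrna_samples,confirm_samples named vectors
#'   `c(tumor=, normal=)` of per-group sample counts.
#' @param n_de_mirnas number of miRNAs given a planted effect.
#' @param targets_per_de_mirna planted targets per differential miRNA
#'   (targets are disjoint across miRNAs).
#' @param mirna_effect,mrna_effect planted |log2 fold-change|.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param n_terms,term_size,n_true_terms annotation sets: total number of
#'   terms, (min, max) members per term, and how many terms are enriched for
#'   planted target genes.
#' @param enrichment_strength fraction of a true term's members drawn from
#'   planted target genes.
#' @param utr_length,mirna_length sequence lengths (nt).
#' @param baseline_range (min, max) of per-feature baseline log2 means.
#' @param seed random seed; the full output is reproducible from it.
#' @return a `SynthConfig` list.
#' @export
synth_config <- function(n_mirnas = 200, n_genes = 2000,
                         mirna_samples = c(tumor = 15, normal = 3),
                         mrna_samples = c(tumor = 26, normal = 12),
                         confirm_samples = c(tumor = 37, normal = 20),
                         n_de_mirnas = 20, targets_per_de_mirna = 5,
                         mirna_effect = 3.0, mrna_effect = 3.0,
                         noise_sd = 0.5,
                         n_terms = 50, term_size = c(10, 40),
                         n_true_terms = 3, enrichment_strength = 0.8,
                         utr_length = 60, mirna_length = 22,
                         baseline_range = c(6, 12), seed = 1) {
  cfg <- list(n_mirnas = n_mirnas, n_genes = n_genes,
              mirna_samples = mirna_samples, mrna_samples = mrna_samples,
              confirm_samples = confirm_samples,
              n_de_mirnas = n_de_mirnas,
              targets_per_de_mirna = targets_per_de_mirna,
              mirna_effect = mirna_effect, mrna_effect = mrna_effect,
              noise_sd = noise_sd, n_terms = n_terms,
              term_size = term_size, n_true_terms = n_true_terms,
              enrichment_strength = enrichment_strength,
              utr_length = utr_length, mirna_length = mirna_length,
              baseline_range = baseline_range, seed = seed)
  if (n_de_mirnas > n_mirnas)
    stop("n_de_mirnas must not exceed n_mirnas")
  if (n_de_mirnas * targets_per_de_mirna > n_genes)
    stop("planted targets exceed the number of genes")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (enrichment_strength < 0 || enrichment_strength > 1)
    stop("enrichment_strength must lie in [0, 1]")
  if (utr_length < 10) stop("utr_length too short to host a seed site")
  structure(cfg, class = "SynthConfig")
}

rand_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(RNA_ALPHABET, len, replace = TRUE), collapse = ""),
    character(1L))
}

# miRNA sequences with pairwise "non-conflicting" seeds: no miRNA's 7mer
# site string (or 6mer core + A) may occur inside another miRNA's implanted
# 8mer, otherwise a planted site for one miRNA would unavoidably create a
# site for another and screening could never converge.
sample_mirna_seqs <- function(n, len) {
  seqs <- character(n)
  sites <- character(n)    # 7mer m8-site strings
  implants <- character(n) # 8mer implant strings (site + A)
  i <- 1L
  attempts <- 0L
  while (i <= n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n)
      stop("could not sample non-conflicting miRNA seeds")
    s <- rand_rna(1L, len)
    site <- rc_rna(substr(s, 2L, 8L))
    imp <- paste0(site, "A")
    core_a <- paste0(substr(site, 2L, 7L), "A")
    prev <- seq_len(i - 1L)
    clash <- site %in% sites[prev] ||
      any(grepl(site, implants[prev], fixed = TRUE)) ||
      any(grepl(core_a, implants[prev], fixed = TRUE)) ||
      any(vapply(prev, function(k)
        grepl(sites[k], imp, fixed = TRUE) ||
        grepl(paste0(substr(sites[k], 2L, 7L), "A"), imp, fixed = TRUE),
        logical(1L)))
    if (!clash) {
      seqs[i] <- s; sites[i] <- site; implants[i] <- imp
      i <- i + 1L
    }
  }
  seqs
}

# one expression cohort: baseline + noise, planted log2 shifts on tumor
make_cohort <- function(feature_ids, baseline, samples, effects, noise_sd,
                        prefix, platform_tag) {
  n_t <- samples[["tumor"]]; n_n <- samples[["normal"]]
  sample_ids <- c(sprintf("%s_T%02d", prefix, seq_len(n_t)),
                  sprintf("%s_N%02d", prefix, seq_len(n_n)))
  groups <- c(rep("tumor", n_t), rep("normal", n_n))
  vals <- baseline +
    matrix(stats::rnorm(length(feature_ids) * (n_t + n_n), 0, noise_sd),
           nrow = length(feature_ids))
  if (any(effects != 0))
    vals[, seq_len(n_t)] <- vals[, seq_len(n_t)] + effects
  expression_matrix(vals, feature_ids, sample_ids, groups, scale = "log2",
                    platform_tag = platform_tag)
}

#' Generate a fully synthetic integrated dataset with known ground truth
#'
#' Produces a miRNA cohort, two mRNA cohorts sharing the planted truth (test
#' and confirmation, independent noise), miRNA and 3'UTR sequences in which
#' every planted (miRNA, target) pair carries an exact implanted 8mer seed
#' site and every non-planted pair is screened to carry no canonical site at
#' all, and a gene-set collection whose "true" terms oversample the planted
#' target genes.
#'
#' Screening works by repeatedly scanning all (miRNA, UTR) combinations and
#' masking a flank base inside any spurious site window (implanted regions
#' are never touched); miRNA seeds are chosen pairwise non-conflicting so
#' this always converges.
#'
#' @param config a [synth_config()] object.
#' @return list of class `SynthDataset` with elements `mirna_expr`,
#'   `mrna_test`, `mrna_confirm` (ExpressionMatrix, log2 scale),
#'   `mirna_seqs`, `utr_seqs` (named character), `gene_sets`
#'   (GeneSetCollection with full-gene universe), `truth` (`SynthTruth`:
#'   `de_mirnas`/`de_genes` named sign vectors, `target_map` data frame,
#'   `true_terms`), and `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)
  mirna_ids <- sprintf("hsa-mir-%03d", seq_len(config$n_mirnas))
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))

  # a zero effect size means nothing is actually differential: the planted
  # truth is empty and the data are pure null
  n_de <- if (config$mirna_effect == 0 || config$mrna_effect == 0) 0L
  else config$n_de_mirnas
  de_mirnas <- sort(sample(mirna_ids, n_de))
  mirna_sign <- stats::setNames(sample(c(-1, 1), n_de, replace = TRUE),
                                de_mirnas)
  n_targets <- n_de * config$targets_per_de_mirna
  target_genes <- sort(sample(gene_ids, n_targets))
  target_map <- data.frame(
    mirna_id = rep(de_mirnas, each = config$targets_per_de_mirna),
    gene_id = if (n_targets) sample(target_genes) else character(0),
    stringsAsFactors = FALSE
  )
  target_map <- target_map[order(target_map$mirna_id, target_map$gene_id), ]
  rownames(target_map) <- NULL
  gene_sign <- stats::setNames(
    -mirna_sign[target_map$mirna_id], target_map$gene_id)
  gene_sign <- gene_sign[order(names(gene_sign))]

  # expression cohorts
  mirna_base <- stats::runif(config$n_mirnas, config$baseline_range[1L],
                             config$baseline_range[2L])
  gene_base <- stats::runif(config$n_genes, config$baseline_range[1L],
                            config$baseline_range[2L])
  mirna_eff <- stats::setNames(rep(0, config$n_mirnas), mirna_ids)
  mirna_eff[de_mirnas] <- mirna_sign * config$mirna_effect
  gene_eff <- stats::setNames(rep(0, config$n_genes), gene_ids)
  gene_eff[names(gene_sign)] <- gene_sign * config$mrna_effect
  mirna_expr <- make_cohort(mirna_ids, mirna_base, config$mirna_samples,
                            mirna_eff, config$noise_sd, "mi",
                            "synthetic miRNA array")
  mrna_test <- make_cohort(gene_ids, gene_base, config$mrna_samples,
                           gene_eff, config$noise_sd, "mt",
                           "synthetic mRNA array (test)")
  mrna_confirm <- make_cohort(gene_ids, gene_base, config$confirm_samples,
                              gene_eff, config$noise_sd, "mc",
                              "synthetic mRNA array (confirmation)")

  # sequences: implant one 8mer site per planted pair, screen the rest
  mirna_seqs <- stats::setNames(
    sample_mirna_seqs(config$n_mirnas, config$mirna_length), mirna_ids)
  utrs <- stats::setNames(rand_rna(config$n_genes, config$utr_length),
                          gene_ids)
  implant_at <- stats::setNames(rep(NA_integer_, config$n_genes), gene_ids)
  for (k in seq_len(nrow(target_map))) {
    g <- target_map$gene_id[k]
    m <- target_map$mirna_id[k]
    imp <- paste0(rc_rna(substr(mirna_seqs[[m]], 2L, 8L)), "A")
    p <- sample.int(config$utr_length - 8L, 1L)  # 1-based start
    substr(utrs[[g]], p, p + 7L) <- imp
    implant_at[g] <- p
  }
  utrs <- screen_utrs(utrs, mirna_seqs, target_map, implant_at)

  # annotation: true terms oversample planted target genes
  term_ids <- sprintf("TERM%03d", seq_len(config$n_terms))
  true_terms <- utils::head(term_ids, config$n_true_terms)
  sets <- lapply(seq_len(config$n_terms), function(t) {
    size <- sample(config$term_size[1L]:config$term_size[2L], 1L)
    if (t <= config$n_true_terms) {
      n_planted <- min(length(target_genes),
                       ceiling(size * config$enrichment_strength))
      members <- c(sample(target_genes, n_planted),
                   sample(setdiff(gene_ids, target_genes),
                          size - n_planted))
    } else {
      members <- sample(setdiff(gene_ids, target_genes), size)
    }
    list(name = sprintf("synthetic term %03d", t), members = members)
  })
  names(sets) <- term_ids
  gsc <- gene_set_collection(sets, universe = gene_ids)

  truth <- structure(list(
    de_mirnas = mirna_sign,
    de_genes = gene_sign,
    target_map = target_map,
    true_terms = true_terms
  ), class = "SynthTruth")
  structure(list(mirna_expr = mirna_expr, mrna_test = mrna_test,
                 mrna_confirm = mrna_confirm, mirna_seqs = mirna_seqs,
                 utr_seqs = utrs, gene_sets = gsc, truth = truth,
                 config = config), class = "SynthDataset")
}

# Remove spurious seed sites: any site of a non-planted (miRNA, UTR) pair is
# destroyed by mutating one flank base inside its window; implanted site
# regions are never modified. Decoy terms, masking and rescanning iterate
# until clean (bounded).
screen_utrs <- function(utrs, mirna_seqs, target_map, implant_at,
                        max_rounds = 60L) {
  planted_key <- paste(target_map$mirna_id, target_map$gene_id, sep = "\r")
  gene_ids <- names(utrs)
  sites <- vapply(mirna_seqs, function(s) rc_rna(substr(s, 2L, 8L)),
                  character(1L))
  cores_a <- paste0(substr(sites, 2L, 7L), "A")
  for (round in seq_len(max_rounds)) {
    dirty <- FALSE
    for (mi in seq_along(mirna_seqs)) {
      # cheap prefilter: a canonical site exists iff the 7mer m8-site string
      # or the 6mer core followed by A occurs anywhere in the UTR
      hit <- which(grepl(sites[mi], utrs, fixed = TRUE) |
                     grepl(cores_a[mi], utrs, fixed = TRUE))
      if (!length(hit)) next
      hit <- hit[!paste(names(mirna_seqs)[mi], gene_ids[hit],
                        sep = "\r") %in% planted_key]
      if (!length(hit)) next
      dirty <- TRUE
      for (j in hit) {
        utr <- utrs[[j]]
        imp <- implant_at[[j]]
        starts <- c(
          as.integer(gregexpr(paste0("(?=", sites[mi], ")"), utr,
                              perl = TRUE)[[1L]]),
          as.integer(gregexpr(paste0("(?=", cores_a[mi], ")"), utr,
                              perl = TRUE)[[1L]]))
        for (s in starts[starts > 0L]) {
          window <- s:(s + 6L)  # both match kinds span 7 positions
          if (!is.na(imp)) window <- setdiff(window, imp:(imp + 7L))
          if (!length(window)) next  # fully inside an implant: excluded by
                                     # the non-conflicting seed construction
          w <- window[sample.int(length(window), 1L)]
          old <- substr(utr, w, w)
          substr(utr, w, w) <- sample(setdiff(RNA_ALPHABET, old), 1L)
        }
        utrs[[j]] <- utr
      }
    }
    if (!dirty) return(utrs)
  }
  stop("UTR screening did not converge in ", max_rounds, " rounds")
}

#' Write a synthetic dataset in all pipeline input formats
#'
#' @param dataset a `SynthDataset`.
#' @param dir output directory (created if needed).
#' @param linear_expression if `TRUE`, expression TSVs are exponentiated to
#'   the linear scale so that the pipeline's [log_transform()] path is
#'   exercised.
#' @return named vector of written paths, invisibly.
#' @export
synth_write <- function(dataset, dir, linear_expression = TRUE) {
  stopifnot(inherits(dataset, "SynthDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  to_disk <- function(em) {
    if (!linear_expression) return(em)
    expression_matrix(2^em$values, em$feature_ids, em$sample_ids, em$groups,
                      scale = "linear", platform_tag = em$platform_tag)
  }
  paths <- c(
    mirna_expr = file.path(dir, "mirna_expression.tsv"),
    mrna_test = file.path(dir, "mrna_test_expression.tsv"),
    mrna_confirm = file.path(dir, "mrna_confirm_expression.tsv"),
    mirna_fasta = file.path(dir, "mirna.fasta"),
    utr_fasta = file.path(dir, "utr.fasta"),
    gene_sets = file.path(dir, "terms.gmt"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression(to_disk(dataset$mirna_expr), paths[["mirna_expr"]])
  write_expression(to_disk(dataset$mrna_test), paths[["mrna_test"]])
  write_expression(to_disk(dataset$mrna_confirm), paths[["mrna_confirm"]])
  write_fasta(dataset$mirna_seqs, paths[["mirna_fasta"]])
  write_fasta(dataset$utr_seqs, paths[["utr_fasta"]])
  write_gene_sets(dataset$gene_sets, paths[["gene_sets"]])
  groups <- rbind(
    data.frame(sample = dataset$mirna_expr$sample_ids,
               group = dataset$mirna_expr$groups, cohort = "mirna"),
    data.frame(sample = dataset$mrna_test$sample_ids,
               group = dataset$mrna_test$groups, cohort = "mrna_test"),
    data.frame(sample = dataset$mrna_confirm$sample_ids,
               group = dataset$mrna_confirm$groups, cohort = "mrna_confirm"))
  utils::write.table(groups, paths[["groups"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(
    de_mirnas = as.list(dataset$truth$de_mirnas),
    de_genes = as.list(dataset$truth$de_genes),
    target_map = dataset$truth$target_map,
    true_terms = dataset$truth$true_terms
  ), paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Set-overlap recovery metrics against the planted truth
#'
#' @param recovered list with any of `de_mirnas`, `de_genes` (character
#'   vectors of recovered feature ids), `pairs` (data frame with `mirna_id`,
#'   `gene_id`), `terms` (character vector of recovered term ids).
#' @param truth a `SynthTruth`.
#' @return nested list of `sensitivity` / `precision` per stage; precision
#'   is `NA` when nothing was recovered.
#' @export
score_recovery <- function(recovered, truth) {
  stopifnot(inherits(truth, "SynthTruth"))
  metric <- function(got, want) {
    got <- unique(got); want <- unique(want)
    hits <- length(intersect(got, want))
    list(sensitivity = if (length(want)) hits / length(want) else NA_real_,
         precision = if (length(got)) hits / length(got) else NA_real_)
  }
  out <- list()
  if (!is.null(recovered$de_mirnas))
    out$de_mirna <- metric(recovered$de_mirnas, names(truth$de_mirnas))
  if (!is.null(recovered$de_genes))
    out$de_gene <- metric(recovered$de_genes, names(truth$de_genes))
  if (!is.null(recovered$pairs))
    out$pairs <- metric(
      paste(recovered$pairs$mirna_id, recovered$pairs$gene_id, sep = "\r"),
      paste(truth$target_map$mirna_id, truth$target_map$gene_id, sep = "\r"))
  if (!is.null(recovered$terms))
    out$terms <- metric(recovered$terms, truth$true_terms)
  out
}
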
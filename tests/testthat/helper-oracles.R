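# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations from first principles (loops, direct
# formulas) and never call the code paths they check.

# hypergeometric upper tail P(X >= nf) by explicit binomial coefficients
oracle_hyper_tail <- function(nf, n, Nf, N) {
  ks <- max(0L, n + Nf - N):min(n, Nf)
  dens <- choose(Nf, ks) * choose(N - Nf, n - ks) / choose(N, n)
  sum(dens[ks >= nf])
}

# brute-force seed-site scanner: windows + complement table + definitional
# classification precedence (8mer > 7mer-m8 > 7mer-A1)
oracle_sites <- function(mirna, utr) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  mir <- strsplit(mirna, "")[[1L]]
  u <- strsplit(utr, "")[[1L]]
  L <- length(u)
  m8_starts <- integer(0)   # 7-nt complement of seed 2-8 starting here
  for (s in seq_len(max(0L, L - 6L))) {
    ok <- TRUE
    for (i in 0:6) if (u[s + i] != comp[[mir[8L - i]]]) { ok <- FALSE; break }
    if (ok) m8_starts <- c(m8_starts, s)
  }
  a1_starts <- integer(0)   # 6-nt complement of seed 2-7 plus A starting here
  for (s in seq_len(max(0L, L - 6L))) {
    ok <- u[s + 6L] == "A"
    if (ok) for (i in 0:5) if (u[s + i] != comp[[mir[7L - i]]]) {
      ok <- FALSE; break
    }
    if (ok) a1_starts <- c(a1_starts, s)
  }
  rows <- list()
  for (s in m8_starts) {
    if (s + 7L <= L && u[s + 7L] == "A") {
      rows[[length(rows) + 1L]] <- data.frame(
        site_type = "8mer", utr_start = s - 1L, utr_end = s + 7L)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        site_type = "7mer-m8", utr_start = s - 1L, utr_end = s + 6L)
    }
  }
  for (s in a1_starts) {
    if (!(s - 1L) %in% m8_starts) {
      rows[[length(rows) + 1L]] <- data.frame(
        site_type = "7mer-A1", utr_start = s - 1L, utr_end = s + 6L)
    }
  }
  if (!length(rows))
    return(data.frame(site_type = character(0), utr_start = integer(0),
                      utr_end = integer(0)))
  df <- do.call(rbind, rows)
  df <- df[order(df$utr_start, df$site_type), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ordinary pooled two-sample t by the textbook formula
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2,
       p = 2 * pt(abs(tt), n1 + n2 - 2, lower.tail = FALSE))
}

rand_rna_str <- function(len)
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")

# small two-group log2 ExpressionMatrix with optional planted effects;
# baseline_sd spreads per-feature baselines, giving samples the shared
# profile structure that correlation-based clustering needs
make_em <- function(n_features = 10, n_tumor = 3, n_normal = 3,
                    effect = 0, de_rows = integer(0), sd = 1,
                    baseline_sd = 0, scale = "log2") {
  base <- rnorm(n_features, 8, baseline_sd)
  vals <- base + matrix(rnorm(n_features * (n_tumor + n_normal), 0, sd),
                        nrow = n_features)
  if (length(de_rows))
    vals[de_rows, seq_len(n_tumor)] <- vals[de_rows, seq_len(n_tumor)] +
      effect
  expression_matrix(
    if (scale == "linear") 2^vals else vals,
    sprintf("f%03d", seq_len(n_features)),
    c(sprintf("T%02d", seq_len(n_tumor)), sprintf("N%02d", seq_len(n_normal))),
    c(rep("tumor", n_tumor), rep("normal", n_normal)),
    scale = scale)
}

# quick DEResult builder for filter/integration tests
make_de <- function(ids, log_fc, p = rep(1e-6, length(ids)),
                    fdr = p) {
  structure(data.frame(
    feature_id = ids, log_fc = log_fc, fold_change = 2^log_fc,
    mean_tumor = 8 + log_fc, mean_normal = 8, t_stat = log_fc * 10,
    p_value = p, fdr = fdr,
    direction = ifelse(log_fc >= 0, "up", "down"),
    stringsAsFactors = FALSE), class = c("DEResult", "data.frame"))
}

make_pairs <- function(mirnas, genes) {
  structure(data.frame(
    mirna_id = mirnas, gene_id = genes,
    n_8mer = 1, n_7mer_m8 = 0, n_7mer_a1 = 0, n_sites = 1,
    source = "predicted", stringsAsFactors = FALSE),
    class = c("TargetPair", "data.frame"))
}

small_synth_config <- function(seed = 1, ...) {
  args <- list(n_mirnas = 30, n_genes = 200,
               mirna_samples = c(tumor = 8, normal = 3),
               mrna_samples = c(tumor = 10, normal = 6),
               confirm_samples = c(tumor = 10, normal = 6),
               n_de_mirnas = 5, targets_per_de_mirna = 4,
               n_terms = 15, term_size = c(8, 20), seed = seed)
  user <- list(...)
  args[names(user)] <- user
  do.call(synth_config, args)
}
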
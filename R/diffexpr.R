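#' Log2-transform a linear-scale expression matrix
#'
#' Microarray intensities are routinely log-transformed before linear
#' modeling so that fold-changes become additive and variances stabilize.
#' Double transformation is guarded: the input must declare `scale ==
#' "linear"`.
#'
#' @param em an `ExpressionMatrix` on the linear scale.
#' @param offset nonnegative constant added before taking log2 (use 1 for
#'   count-like data containing zeros).
#' @return an `ExpressionMatrix` with `scale == "log2"`.
#' @export
log_transform <- function(em, offset = 0) {
  validate_expression_matrix(em)
  if (em$scale != "linear")
    stop("matrix is already on the log2 scale; refusing to transform twice")
  shifted <- em$values + offset
  bad <- which(shifted <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("nonpositive value (after offset ", offset, ") for feature '",
         em$feature_ids[bad[1L, 1L]], "'")
  expression_matrix(log2(shifted), em$feature_ids, em$sample_ids, em$groups,
                    scale = "log2", platform_tag = em$platform_tag,
                    group_levels = em$group_levels)
}

#' Moderated two-group t-test (empirical-Bayes variance shrinkage)
#'
#' Per-feature two-sample comparison of tumor versus normal on log2 data.
#' Residual (pooled) variances are shrunk toward a common prior estimated
#' from the observed distribution of per-feature variances by moment
#' matching: under the standard hierarchical model the sample variances
#' follow a scaled F distribution with (d, d0) degrees of freedom, and the
#' first two moments identify the prior variance s0^2 and prior degrees of
#' freedom d0. The moderated statistic uses the posterior variance
#' (d*s^2 + d0*s0^2)/(d + d0) and a t reference with d + d0 degrees of
#' freedom. With `prior_df_mode = "none"` no shrinkage is applied and the
#' statistic reduces exactly to the ordinary pooled two-sample t.
#'
#' @param em an `ExpressionMatrix` with `scale == "log2"` and no missing
#'   values (see [clean_missing()]).
#' @param prior_df_mode `"moment"` (empirical-Bayes shrinkage, default) or
#'   `"none"` (ordinary pooled t, used for oracle testing).
#' @param tumor,normal the group labels contrasted (tumor minus normal).
#' @return data frame of class `DEResult` with columns `feature_id`,
#'   `log_fc`, `fold_change`, `mean_tumor`, `mean_normal`, `t_stat`,
#'   `p_value`, `fdr`, `direction`.
#' @export
moderated_t_test <- function(em, prior_df_mode = c("moment", "none"),
                             tumor = "tumor", normal = "normal") {
  validate_expression_matrix(em)
  prior_df_mode <- match.arg(prior_df_mode)
  if (em$scale != "log2")
    stop("moderated_t_test expects log2-scale data; call log_transform first")
  if (anyNA(em$values))
    stop("missing values present; call clean_missing first")
  ct <- em$groups == tumor
  cn <- em$groups == normal
  n1 <- sum(ct); n2 <- sum(cn)
  if (n1 == 0L || n2 == 0L)
    stop("both groups need at least one sample (tumor: ", n1,
         ", normal: ", n2, ")")
  if (n1 < 2L || n2 < 2L)
    warning("a group has a single sample; variance is pooled across the ",
            "other group only")
  x <- em$values[, ct, drop = FALSE]
  y <- em$values[, cn, drop = FALSE]
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  ss1 <- if (n1 > 1L) rowSums((x - m1)^2) else numeric(nrow(x))
  ss2 <- if (n2 > 1L) rowSums((y - m2)^2) else numeric(nrow(y))
  df_resid <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / df_resid
  log_fc <- m1 - m2

  if (prior_df_mode == "none") {
    post_var <- s2
    df_total <- rep(df_resid, length(s2))
  } else {
    prior <- fit_variance_prior(s2, df_resid)
    if (is.finite(prior$df_prior)) {
      post_var <- (df_resid * s2 + prior$df_prior * prior$var_prior) /
        (df_resid + prior$df_prior)
      df_total <- rep(df_resid + prior$df_prior, length(s2))
    } else {
      post_var <- rep(prior$var_prior, length(s2))
      df_total <- rep(Inf, length(s2))
    }
  }
  se <- sqrt(post_var * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, log_fc / se, ifelse(log_fc == 0, 0, sign(log_fc) * Inf))
  p <- 2 * stats::pt(abs(t_stat), df = df_total, lower.tail = FALSE)
  res <- data.frame(
    feature_id = em$feature_ids,
    log_fc = log_fc,
    fold_change = 2^log_fc,
    mean_tumor = m1,
    mean_normal = m2,
    t_stat = t_stat,
    p_value = p,
    fdr = bh_adjust(p),
    direction = ifelse(log_fc >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("DEResult", "data.frame")
  res
}

# Moment-matched scaled-F prior for per-feature variances: with c = var/mean^2
# of the observed s2 and d residual df, c = 2*(d + d0 - 2)/(d*(d0 - 4))
# solves to d0 = (2*(d - 2) + 4*c*d)/(c*d - 2); c*d <= 2 means the variances
# are less dispersed than chi-square sampling noise alone, i.e. d0 = Inf
# (complete shrinkage to the common variance).
fit_variance_prior <- function(s2, df_resid) {
  s2 <- s2[is.finite(s2) & s2 >= 0]
  if (length(s2) < 2L || mean(s2) == 0)
    return(list(var_prior = if (length(s2)) mean(s2) else 1, df_prior = Inf))
  m <- mean(s2)
  v <- stats::var(s2)
  cc <- v / m^2
  if (cc * df_resid <= 2)
    return(list(var_prior = m, df_prior = Inf))
  d0 <- (2 * (df_resid - 2) + 4 * cc * df_resid) / (cc * df_resid - 2)
  if (!is.finite(d0) || d0 <= 0)
    return(list(var_prior = m, df_prior = Inf))
  var_prior <- if (d0 > 2) m * (d0 - 2) / d0 else m
  list(var_prior = var_prior, df_prior = d0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up procedure: p * m / rank with monotonicity enforced from
#' the largest p downward, capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Differential-expression threshold set
#'
#' The fold-change cut is symmetric on the linear scale: a feature passes if
#' `fold_change > min_fold_change` or `fold_change < 1/min_fold_change`.
#' `min_fold_change = 1` disables the fold cut (direction only), the
#' convention for mRNA series filtered on P and FDR alone.
#'
#' @param min_fold_change linear-scale fold-change threshold (>= 1).
#' @param max_p raw p-value cut.
#' @param max_fdr adjusted p-value cut.
#' @return a `DEThresholds` list.
#' @export
de_thresholds <- function(min_fold_change = 4, max_p = 0.01, max_fdr = 0.01) {
  if (min_fold_change < 1) stop("min_fold_change must be at least 1")
  if (max_p <= 0 || max_p > 1 || max_fdr <= 0 || max_fdr > 1)
    stop("max_p and max_fdr must lie in (0, 1]")
  structure(list(min_fold_change = min_fold_change, max_p = max_p,
                 max_fdr = max_fdr), class = "DEThresholds")
}

#' Filter a DE table by fold-change, P and FDR thresholds
#'
#' Keeps features with (`fold_change > fc` or `< 1/fc`) and `p_value < max_p`
#' and `fdr < max_fdr`, excluding any blacklisted identifiers (e.g. array
#' probes retracted from miRBase). Output is sorted by FDR ascending, ties by
#' absolute log fold-change descending, then feature id.
#'
#' @param results a `DEResult` data frame.
#' @param thresholds a [de_thresholds()] object.
#' @param blacklist feature ids to drop regardless of statistics.
#' @return filtered, sorted `DEResult` data frame (possibly empty).
#' @export
apply_thresholds <- function(results, thresholds = de_thresholds(),
                             blacklist = character()) {
  stopifnot(inherits(thresholds, "DEThresholds"))
  if (!nrow(results)) stop("empty DE result table")
  fc <- thresholds$min_fold_change
  keep <- (results$fold_change > fc | results$fold_change < 1 / fc) &
    results$p_value < thresholds$max_p &
    results$fdr < thresholds$max_fdr &
    !(results$feature_id %in% blacklist)
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$fdr, -abs(out$log_fc), out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Write / read a DE table as TSV
#' @param results a `DEResult` data frame.
#' @param path output path.
#' @return `path` (write) or a `DEResult` (read).
#' @export
write_de_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("feature_id", "log_fc", "fold_change", "p_value", "fdr",
              "direction")
  miss <- setdiff(needed, colnames(df))
  if (length(miss))
    stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("DEResult", "data.frame")
  df
}
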
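test_that("log_transform computes log2(value + offset) and guards misuse", {
  em <- expression_matrix(matrix(c(8, 0), 2, 1), c("a", "b"), "s1", "tumor",
                          scale = "linear")
  expect_error(log_transform(em), "nonpositive value.*'b'")
  shifted <- log_transform(
    expression_matrix(matrix(c(8, 0), 2, 1), c("a", "b"), "s1", "tumor",
                      scale = "linear"), offset = 1)
  expect_equal(shifted$values[1, 1], log2(9))
  expect_equal(shifted$values[2, 1], 0)
  expect_equal(shifted$scale, "log2")
  only8 <- expression_matrix(matrix(8, 1, 1), "a", "s1", "tumor", "linear")
  expect_equal(log_transform(only8)$values[1, 1], 3)
  expect_error(log_transform(shifted), "already on the log2 scale")
})

test_that("no-shrinkage mode equals the ordinary pooled two-sample t", {
  withr::local_seed(42)
  em <- make_em(20, 3, 3)
  res <- moderated_t_test(em, prior_df_mode = "none")
  for (i in c(1, 7, 20)) {
    o <- oracle_pooled_t(em$values[i, 1:3], em$values[i, 4:6])
    expect_equal(res$t_stat[i], o$t, tolerance = 1e-12)
    expect_equal(res$p_value[i], o$p, tolerance = 1e-12)
  }
  expect_equal(res$log_fc, rowMeans(em$values[, 1:3]) -
                 rowMeans(em$values[, 4:6]), ignore_attr = TRUE)
})

test_that("identical group means give log_fc 0 and p near 1", {
  vals <- matrix(rep(c(5, 6, 7), 2), nrow = 1)
  em <- expression_matrix(vals, "f", paste0("s", 1:6),
                          rep(c("tumor", "normal"), each = 3), "log2")
  res <- moderated_t_test(em, prior_df_mode = "none")
  expect_equal(res$log_fc, 0)
  expect_equal(res$p_value, 1, tolerance = 1e-10)
  expect_equal(res$fold_change, 1)
})

test_that("moderated t is calibrated on null data and flags usage errors", {
  withr::local_seed(2024)
  em <- make_em(1000, 5, 5)
  res <- moderated_t_test(em)
  frac <- mean(res$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  bad <- expression_matrix(matrix(1:4, 2, 2), c("a", "b"), c("s1", "s2"),
                           c("tumor", "tumor"), "log2")
  expect_error(moderated_t_test(bad), "both groups need")
  lin <- make_em(5, 2, 2, scale = "linear")
  expect_error(moderated_t_test(lin), "log2")
})

test_that("swapping group labels negates log_fc and keeps p-values", {
  withr::local_seed(8)
  em <- make_em(50, 4, 3, effect = 2, de_rows = 1:10)
  swapped <- expression_matrix(em$values, em$feature_ids, em$sample_ids,
                               ifelse(em$groups == "tumor", "normal",
                                      "tumor"), "log2")
  a <- moderated_t_test(em)
  b <- moderated_t_test(swapped)
  expect_equal(b$log_fc, -a$log_fc, tolerance = 1e-12)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
})

test_that("shrinkage contracts the spread of variance estimates", {
  withr::local_seed(77)
  em <- make_em(300, 3, 3)
  none <- moderated_t_test(em, prior_df_mode = "none")
  mod <- moderated_t_test(em, prior_df_mode = "moment")
  # posterior variances back-solved from the t statistics
  se2 <- function(r) (r$log_fc / r$t_stat)^2
  expect_lt(var(se2(mod)[is.finite(se2(mod))]),
            var(se2(none)[is.finite(se2(none))]))
})

test_that("moderated results agree with an established reference on a toy", {
  skip_if_not_installed("limma")
  withr::local_seed(31)
  em <- make_em(200, 4, 4, effect = 1.5, de_rows = 1:20)
  design <- cbind(1, em$groups == "tumor")
  fit <- limma::eBayes(limma::lmFit(em$values, design))
  res <- moderated_t_test(em)
  expect_equal(res$log_fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  # priors are estimated differently (moment matching vs profile fit);
  # expect close agreement, not identity
  expect_gt(cor(res$t_stat, fit$t[, 2]), 0.99)
})

test_that("bh_adjust matches the direct step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::local_seed(4)
  p <- runif(50)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
})

test_that("apply_thresholds keeps exactly the enumerated survivors", {
  # hand enumeration: pass requires |fc| cut AND p AND fdr
  res <- make_de(
    ids = c("f1", "f2", "f3", "f4", "f5"),
    log_fc = c(2.5, 2.5, -2.5, 0.5, 3.0),          # fold 5.7, 5.7, 0.18, 1.4, 8
    p = c(0.001, 0.5, 0.002, 0.001, 0.001),
    fdr = c(0.005, 0.5, 0.006, 0.005, 0.5))
  # f1 passes all; f2 fails p; f3 passes (down); f4 fails fold; f5 fails fdr
  out <- apply_thresholds(res, de_thresholds(4, 0.01, 0.01))
  expect_setequal(out$feature_id, c("f1", "f3"))
  # sorted by fdr ascending
  expect_equal(out$feature_id, c("f1", "f3"))

  # blacklisted feature is excluded even when it passes
  out2 <- apply_thresholds(res, de_thresholds(4, 0.01, 0.01),
                           blacklist = "f1")
  expect_equal(out2$feature_id, "f3")

  # min_fold_change = 1 disables the fold cut
  out3 <- apply_thresholds(res, de_thresholds(1, 0.01, 0.01))
  expect_true("f4" %in% out3$feature_id)
  expect_error(de_thresholds(0.5), "at least 1")
})

test_that("DE tables survive a write/read round trip", {
  res <- make_de(c("a", "b"), c(1.5, -2), p = c(0.01, 0.002))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(res, path)
  back <- read_de_table(path)
  expect_equal(back$feature_id, res$feature_id)
  expect_equal(back$log_fc, res$log_fc)
  expect_equal(back$direction, res$direction)
})
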
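test_that("BH adjustment matches the step-up definition", {
  # hand-applied BH on p = {0.01, 0.02, 0.03}
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("differential association routes kinds to the right tests", {
  set.seed(23)
  n <- 40
  y <- rep(c(TRUE, FALSE), each = n / 2)
  expr <- rnorm(n) + 2 * y
  mut <- as.numeric(runif(n) < ifelse(y, 0.7, 0.2))
  const <- rep(5, n)
  V <- rbind(expr = expr, mut = mut, const = const)
  da <- differential_association(V, y, kinds = c("expression", "mutation",
                                                 "expression"))
  da <- da[match(c("expr", "mut", "const"), da$feature_id), ]
  expect_equal(da$p_value[1],
               t.test(expr[y], expr[!y])$p.value, tolerance = 1e-10)
  tab <- table(factor(mut != 0, c(TRUE, FALSE)), factor(y, c(TRUE, FALSE)))
  expect_equal(da$p_value[2], fisher.test(tab)$p.value, tolerance = 1e-12)
  expect_equal(da$p_value[3], 1)     # constant feature
  expect_true(da$degenerate[3])
  expect_equal(da$bh_fdr, p.adjust(da$p_value, "BH")[order(order(da$p_value))],
               tolerance = 1e-12)
})

test_that("two-gene rule calls strictly above both training medians", {
  X <- rbind(A = c(1, 2, 3, 4), B = c(4, 3, 2, 1), C = c(5, 5, 5, 5))
  colnames(X) <- paste0("s", 1:4)
  m <- two_gene_classifier(X, c("sensitive", "sensitive", "insensitive",
                                "insensitive"), "A", "B")
  pr <- predict(m, X)
  # medians: A = 2.5, B = 2.5; only s2 (A=2, no) ... check boundary sample
  Xq <- cbind(s9 = c(A = 2.5, B = 2.5, C = 5))
  expect_identical(predict(m, Xq)$call, "insensitive")  # at medians -> no
  Xhi <- cbind(s8 = c(A = 4, B = 4, C = 5))
  expect_identical(predict(m, Xhi)$call, "sensitive")
  expect_error(two_gene_classifier(X, NULL, "A", "ZZ"), "ZZ")
})

test_that("oracle-aligned data gives the two-gene rule perfect PPV", {
  set.seed(29)
  n <- 60
  X <- rbind(A = exp(rnorm(n, 6)), B = exp(rnorm(n, 6)),
             noise = exp(rnorm(n, 6)))
  colnames(X) <- sprintf("s%02d", 1:n)
  labels <- ifelse(X["A", ] > median(X["A", ]) & X["B", ] > median(X["B", ]),
                   "sensitive", "insensitive")
  m <- two_gene_classifier(X, labels, "A", "B")
  pr <- predict(m, X)
  me <- compute_metrics(as.numeric(pr$score > 0), labels, threshold = 0.5)
  expect_equal(me$ppv, 1)
  # random labels: PPV near prevalence
  set.seed(31)
  ppvs <- replicate(20, {
    lab <- sample(c("sensitive", "insensitive"), n, TRUE, prob = c(0.4, 0.6))
    p <- predict(two_gene_classifier(X, lab, "A", "B"), X)
    me <- compute_metrics(as.numeric(p$score > 0), lab, threshold = 0.5)
    me$ppv - mean(lab == "sensitive")
  })
  expect_lt(abs(mean(ppvs)), 0.15)
})

test_that("the ablation suite compares five classifiers on shared folds", {
  cfg <- synthetic_config(n_samples = 100, n_genes = 60,
                          hypothesis_set_size = 16, n_true_ratios = 2,
                          effect_size = 2, prevalence = 0.3, seed = 41)
  d <- generate_expression(cfg)
  suite <- ablation_suite(d$X, d$labels, d$hypothesis_genes,
                          grep_config(seed = 41), k = 5)
  expect_identical(nrow(suite), 5L)
  expect_setequal(suite$model, c("grep", "gene_all", "gene_hyp",
                                 "ratio_select_gene", "two_gene"))
  oof <- attr(suite, "oof")
  expect_false(anyNA(oof))
  expect_true(all(suite$auc_lo <= suite$auc & suite$auc <= suite$auc_hi))
  expect_gt(suite$auc[suite$model == "grep"], 0.75)  # planted ratio signal
})

test_that("random gene sets excluding the signal perform at chance", {
  cfg <- synthetic_config(n_samples = 80, n_genes = 60,
                          hypothesis_set_size = 16, n_true_ratios = 2,
                          effect_size = 2.5, prevalence = 0.3, seed = 43)
  d <- generate_expression(cfg)
  signal_genes <- unique(unlist(d$truth))
  res <- random_geneset_control(d$X, d$labels, set_size = 10, n_sets = 4,
                                config = grep_config(seed = 43), k = 4,
                                exclude = unlist(d$hypothesis_genes))
  expect_identical(nrow(res), 4L)
  expect_lt(mean(res$auc), 0.65)
  empty <- random_geneset_control(d$X, d$labels, 10, n_sets = 0)
  expect_identical(nrow(empty), 0L)
})

test_that("downsampling recovers a strong marker and stays calibrated on noise", {
  cfg <- synthetic_config(n_samples = 150, n_genes = 60,
                          hypothesis_set_size = 10, n_true_ratios = 1,
                          effect_size = 4, prevalence = 0.3,
                          pair_coupling_sd = 0,
                          per_sample_scale_range = c(1, 1), seed = 47)
  d <- generate_expression(cfg)
  strong <- d$truth$gene_num[1]
  # degenerate subset = full data: the planted marker ranks first every time
  res_full <- downsampling_rank_simulation(d$X, d$labels, strong,
                                           subset_sizes = 150, n_reps = 3,
                                           seed = 1)
  expect_lte(res_full$mean_rank, 2)
  expect_equal(res_full$frac_significant, 1)
  # a pure-noise gene is significant ~5% of the time
  noise_gene <- setdiff(rownames(d$X), unlist(d$hypothesis_genes))[1]
  res_null <- downsampling_rank_simulation(d$X, d$labels, noise_gene,
                                           subset_sizes = 100, n_reps = 40,
                                           seed = 2)
  expect_lt(res_null$frac_significant, 0.25)
  expect_error(downsampling_rank_simulation(d$X, d$labels, "nope", 50, 2),
               "absent")
})
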
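test_that("rank-based AUC handles separation, ties and reversal", {
  expect_equal(auc_rank(c(1, 2, 3, 4), c("A", "A", "B", "B")), 1)
  expect_equal(auc_rank(c(4, 3, 2, 1), c("A", "A", "B", "B")), 0)
  expect_equal(auc_rank(c(5, 5, 5, 5), c("A", "A", "B", "B")), 0.5)
  # midrank tie handling agrees with the Mann-Whitney statistic via pROC
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- round(rnorm(40), 1)  # coarse scores force ties
  labels <- rep(c("A", "B"), 20)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("A", "B"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-12)
  expect_error(auc_rank(1:3, c("A", "A", "A")), "both phenotypes")
})

test_that("logistic classifier separates and stays calibrated on noise", {
  # perfectly separable single feature
  v <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), 1,
              dimnames = list("pw1", paste0("s", 1:6)))
  act <- labeled_matrix(v, rep(c("A", "B"), each = 3))
  clf <- fit_logistic(act)
  expect_equal(auc_rank(predict_scores(clf, act), act$labels), 1)

  # label-independent feature: near-zero coefficient, AUC ~ 0.5
  set.seed(12)
  vn <- matrix(rnorm(200), 1, dimnames = list("pw1", paste0("s", 1:200)))
  actn <- labeled_matrix(vn, rep(c("A", "B"), 100))
  clfn <- fit_logistic(actn)
  expect_lt(abs(clfn$coefficients[2]), 0.5)
  expect_lt(abs(auc_rank(predict_scores(clfn, actn), actn$labels) - 0.5),
            0.15)

  # duplicating every sample leaves the decision function unchanged
  vd <- cbind(vn, vn)
  colnames(vd) <- paste0("s", 1:400)
  act2 <- labeled_matrix(vd, rep(as.character(actn$labels), 2))
  clf2 <- fit_logistic(act2)
  expect_equal(clf2$coefficients, clfn$coefficients, tolerance = 1e-6)

  expect_error(predict_scores(clf, labeled_matrix(
    matrix(1:4, 1, dimnames = list("pwX", paste0("t", 1:4))),
    c("A", "A", "B", "B"))), "lacks feature")
})

test_that("greedy selection keeps informative features and drops noise", {
  set.seed(2)
  n <- 40
  labels <- rep(c("A", "B"), each = n)
  informative <- ifelse(labels == "B", 2, 0) + rnorm(2 * n, sd = 1)
  noise <- rnorm(2 * n)
  v <- rbind(pw_info = informative, pw_noise = noise)
  colnames(v) <- paste0("s", seq_len(2 * n))
  act <- labeled_matrix(v, labels)
  in_eval <- rep(c(TRUE, FALSE), times = c(n / 2, n / 2))
  in_eval <- c(in_eval, in_eval)  # stratified half/half
  gs <- greedy_select(subset_samples(act, which(in_eval)),
                      subset_samples(act, which(!in_eval)))
  expect_equal(gs$features, "pw_info")

  # single feature: trivially selected
  act1 <- labeled_matrix(v["pw_info", , drop = FALSE], labels)
  gs1 <- greedy_select(subset_samples(act1, which(in_eval)),
                       subset_samples(act1, which(!in_eval)))
  expect_equal(gs1$features, "pw_info")

  # an identical copy cannot strictly increase the AUC
  v2 <- rbind(pw_info = informative, pw_copy = informative)
  colnames(v2) <- colnames(v)
  act_dup <- labeled_matrix(v2, labels)
  gs2 <- greedy_select(subset_samples(act_dup, which(in_eval)),
                       subset_samples(act_dup, which(!in_eval)))
  expect_equal(length(gs2$features), 1)
})

test_that("protocol arithmetic: 15 within / 5 cross AUCs per repeat", {
  study <- simulate_study(sim_spec(seed = 6, n_pathways = 4,
                                   n_risk_pathways = 2,
                                   n_samples_per_class = 15))
  graph <- build_global_graph(study$reactions)
  cfg <- eval_config(n_repeats = 1, seed = 5, min_diff_genes = 1)
  rep_w <- within_dataset_eval(study$expr, study$met, graph, cfg)
  expect_length(rep_w$aucs, 15)
  expect_length(rep_w$accuracies, 15)
  expect_true(all(rep_w$aucs >= 0 & rep_w$aucs <= 1))
  expect_equal(rep_w$mean_auc, mean(rep_w$aucs))

  study2 <- simulate_study(sim_spec(seed = 7, n_pathways = 4,
                                    n_risk_pathways = 2,
                                    n_samples_per_class = 15))
  rep_c <- cross_dataset_eval(study$expr, study$met, study2$expr, graph, cfg)
  expect_length(rep_c$aucs, 5)

  # three repeats: 45 and 15
  cfg3 <- eval_config(n_repeats = 3, seed = 5, min_diff_genes = 1)
  expect_length(within_dataset_eval(study$expr, study$met, graph,
                                    cfg3)$aucs, 45)
  expect_length(cross_dataset_eval(study$expr, study$met, study2$expr,
                                   graph, cfg3)$aucs, 15)
})

test_that("evaluation is deterministic under a fixed seed", {
  study <- simulate_study(sim_spec(seed = 9, n_pathways = 3,
                                   n_samples_per_class = 12))
  graph <- build_global_graph(study$reactions)
  cfg <- eval_config(n_repeats = 2, seed = 123, min_diff_genes = 1)
  r1 <- within_dataset_eval(study$expr, study$met, graph, cfg)
  r2 <- within_dataset_eval(study$expr, study$met, graph, cfg)
  expect_identical(r1$aucs, r2$aucs)
  expect_identical(r1$selected, r2$selected)
})

test_that("the minimum-differential-genes guard aborts sparse signals", {
  study <- simulate_study(sim_spec(seed = 10, n_pathways = 3,
                                   n_samples_per_class = 10))
  graph <- build_global_graph(study$reactions)
  cfg <- eval_config(n_repeats = 1, seed = 1, min_diff_genes = 50)
  expect_error(within_dataset_eval(study$expr, study$met, graph, cfg),
               "below the minimum of 50")
})

test_that("stratification guards against undersized phenotypes", {
  labels <- factor(rep(c("A", "B"), times = c(3, 12)))
  expect_error(stratified_folds(labels, 5), "phenotype A")
  expect_error(stratified_split(factor(rep(c("A", "B"), times = c(3, 20)))),
               "too small")
})

test_that("c_score ranks by training |t| and multiplies paired t-scores", {
  set.seed(55)
  n <- 20
  labels <- rep(c("A", "B"), each = n)
  mk <- function(shifts) {
    v <- t(sapply(shifts, function(s)
      ifelse(labels == "B", s, 0) + rnorm(2 * n, sd = 1)))
    rownames(v) <- paste0("pw", seq_along(shifts))
    colnames(v) <- paste0("s", seq_len(2 * n))
    labeled_matrix(v, labels)
  }
  a_tr <- mk(c(2, 1, 0))
  a_te <- mk(c(2, 1, 0))
  t_tr <- gene_ttests(a_tr)
  t_te <- gene_ttests(a_te)
  cs <- c_score(a_tr, a_te, 1)
  top <- t_tr$feature_id[which.max(abs(t_tr$t_score))]
  expect_equal(cs$c_score,
               t_tr$t_score[t_tr$feature_id == top] *
                 t_te$t_score[t_te$feature_id == top],
               tolerance = 1e-12)

  # identical train/test activities: mean of top-N squared t >= 0
  cs_same <- c_score(a_tr, a_tr, 3)
  expect_equal(cs_same$c_score,
               mean(sort(t_tr$t_score^2, decreasing = TRUE)),
               tolerance = 1e-12)
  expect_gte(cs_same$c_score, 0)

  # flipping the test phenotype labels negates the score
  a_te_flip <- labeled_matrix(a_te$values,
                              ifelse(a_te$labels == "A", "B", "A"))
  expect_equal(c_score(a_tr, a_te_flip, 3)$c_score,
               -c_score(a_tr, a_te, 3)$c_score, tolerance = 1e-12)

  expect_error(c_score(a_tr, a_te, 4), "exceeds")
})

test_that("shuffled labels cannot be classified above chance", {
  # leakage canary: null data, the full protocol, expect mean AUC ~ 0.5
  study <- simulate_study(sim_spec(seed = 31, n_pathways = 4,
                                   n_samples_per_class = 15,
                                   effect_size_hub = 0,
                                   effect_size_peripheral = 0,
                                   frac_differential_metabolites = 0))
  graph <- build_global_graph(study$reactions)
  cfg <- eval_config(n_repeats = 4, seed = 17, min_diff_genes = 1)
  rep_null <- within_dataset_eval(study$expr, study$met, graph, cfg)
  expect_gt(rep_null$mean_auc, 0.3)
  expect_lt(rep_null$mean_auc, 0.7)
})
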
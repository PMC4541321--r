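#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midrank tie handling: the probability that a random second-phenotype
#' sample scores above a random first-phenotype sample.
#'
#' @param scores numeric classifier scores, higher = more second-phenotype
#' @param labels two-level factor/character vector aligned to `scores`
#' @return AUC in `[0, 1]`
#' @export
auc_rank <- function(scores, labels) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2)
    stop("AUC requires both phenotypes present")
  pos <- labels == levels(labels)[2]
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logistic-regression classifier over pathway activities
#'
#' Maximum-likelihood logistic fit of phenotype on the feature rows of a
#' [labeled_matrix()]. When iteratively reweighted least squares fails to
#' converge (typically quasi-separable activity profiles) the fit falls
#' back to a vanishingly small ridge penalty, which leaves the decision
#' function essentially unpenalized but finite.
#'
#' @param act features x samples [labeled_matrix()] of pathway activities
#' @return classifier of class `pathway_classifier` holding the
#'   coefficient vector (intercept + one per feature)
#' @export
fit_logistic <- function(act) {
  y <- as.integer(act$labels == levels(act$labels)[2])
  if (length(unique(y)) != 2) stop("both phenotypes required for fitting")
  X <- cbind(1, t(act$values))
  colnames(X)[1] <- "(Intercept)"
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(), control = list(maxit = 100)))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  if (!fit$converged && nrow(act$values) >= 2) {
    # quasi/complete separation: tiny ridge keeps the coefficients finite
    coefs <- ridge_logistic(X, y, lambda = 1e-6)
  }
  structure(list(coefficients = coefs,
                 features = rownames(act$values),
                 levels = levels(act$labels)),
            class = "pathway_classifier")
}

# Newton iterations for L2-penalized logistic regression (intercept
# unpenalized); only used as the separability fallback of fit_logistic.
ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  stats::setNames(beta, colnames(X))
}

#' @param classifier a `pathway_classifier`
#' @param act activities of the cohort to score (must contain the
#'   classifier's features as rows)
#' @return `predict_scores`: numeric vector of predicted second-phenotype
#'   probabilities per sample
#' @rdname fit_logistic
#' @export
predict_scores <- function(classifier, act) {
  missing <- setdiff(classifier$features, rownames(act$values))
  if (length(missing))
    stop("activity matrix lacks feature(s): ", paste(missing, collapse = ", "))
  X <- cbind(1, t(act$values[classifier$features, , drop = FALSE]))
  as.numeric(stats::plogis(X %*% classifier$coefficients))
}

#' Greedy forward selection of pathway features
#'
#' Features are ranked by the p-value of a two-tailed t-test of their
#' activities on the feature-evaluation split. The top-ranked feature
#' always enters (an empty model has no AUC to improve on); each further
#' feature, taken in rank order, is kept only if refitting the logistic
#' model on the evaluation split strictly increases the AUC measured on
#' the feature-selection split.
#'
#' @param act_eval activities on the feature-evaluation samples
#' @param act_sel activities on the feature-selection samples (same
#'   feature rows)
#' @return list with `features` (selected pathway ids in acceptance
#'   order), `classifier` (fitted on the evaluation split) and `auc_sel`
#'   (its AUC on the selection split)
#' @export
greedy_select <- function(act_eval, act_sel) {
  if (nrow(act_eval$values) == 0) stop("no features to select from")
  gd <- gene_ttests(act_eval)
  ranked <- gd$feature_id[order(gd$p_value, gd$feature_id, method = "radix")]
  selected <- ranked[1]
  clf <- fit_logistic(lm_features(act_eval, selected))
  best <- auc_rank(predict_scores(clf, lm_features(act_sel, selected)),
                   act_sel$labels)
  for (f in ranked[-1]) {
    cand <- c(selected, f)
    clf_c <- fit_logistic(lm_features(act_eval, cand))
    auc_c <- auc_rank(predict_scores(clf_c, lm_features(act_sel, cand)),
                      act_sel$labels)
    if (auc_c > best) {
      selected <- cand
      clf <- clf_c
      best <- auc_c
    }
  }
  list(features = selected, classifier = clf, auc_sel = best)
}

lm_features <- function(m, features) {
  labeled_matrix(m$values[features, , drop = FALSE], m$labels)
}

#' Evaluation configuration
#'
#' @param n_repeats number of repetitions of the whole protocol (100 in the
#'   reference protocols)
#' @param n_folds cross-validation folds (within-dataset) or partition
#'   subsets (cross-dataset); default 5
#' @param inner_splits feature-evaluation/selection splits per training set
#'   (within-dataset only); default 3
#' @param seed master seed; per-repeat sub-seeds are drawn from it
#' @param restart_prob,tol walk parameters, see [walk_config()]
#' @param gene_alpha differential-gene cut-off for pathway models (0.05)
#' @param met_alpha differential-metabolite cut-off for walk seeding (0.01)
#' @param min_diff_genes abort when fewer graph genes than this pass
#'   `gene_alpha` on the training cohort (default 50); lower it for small
#'   simulated graphs
#' @param method activity inference method: `"drw-gm"`, `"drw-gm-nm"`,
#'   `"drw"` (pass the gene-only graph), `"mean"`, `"median"`, `"pac"`
#' @param metabolite_weighting see [initial_weights()]
#' @return a list of class `eval_config`
#' @export
eval_config <- function(n_repeats = 100L, n_folds = 5L, inner_splits = 3L,
                        seed = 1L, restart_prob = 0.7, tol = 1e-10,
                        gene_alpha = 0.05, met_alpha = 0.01,
                        min_diff_genes = 50L, method = "drw-gm",
                        metabolite_weighting = "cutoff") {
  stopifnot(n_repeats >= 1, n_folds >= 2, inner_splits >= 1)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 inner_splits = as.integer(inner_splits),
                 seed = as.integer(seed), restart_prob = restart_prob,
                 tol = tol, gene_alpha = gene_alpha, met_alpha = met_alpha,
                 min_diff_genes = as.integer(min_diff_genes),
                 method = method,
                 metabolite_weighting = metabolite_weighting),
            class = "eval_config")
}

# Stratified fold assignment: within each phenotype, shuffled samples are
# dealt to folds in turn, keeping fold sizes and class balance even.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < k)
      stop("phenotype ", lv, " has ", length(idx),
           " samples; need >= ", k, " for ", k, "-fold stratification")
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Stratified two-way split: frac of each phenotype to the first part,
# clamped so both parts keep >= min_each samples per phenotype.
stratified_split <- function(labels, frac = 2 / 3, min_each = 2L) {
  first <- logical(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n1 <- round(frac * length(idx))
    n1 <- max(min_each, min(length(idx) - min_each, n1))
    if (n1 < min_each || length(idx) - n1 < min_each)
      stop("phenotype ", lv, " too small (", length(idx),
           ") for a ", signif(frac, 3), " split with >= ", min_each,
           " per side")
    first[sample(idx, n1)] <- TRUE
  }
  first
}

# One training fit of the whole pipeline: z-normalize, differential
# statistics, guard, walk, per-pathway activity models, training activities.
# met_diff is precomputed because the metabolite cohort is independent of
# the expression-training subset.
train_pipeline <- function(expr_train, met_diff, graph, cfg) {
  expr_z <- suppressWarnings(z_normalize(expr_train))
  gene_diff <- gene_ttests(expr_z)
  graph_genes <- igraph::V(graph)$name[igraph::V(graph)$kind == "gene"]
  gd_graph <- gene_diff[gene_diff$feature_id %in% graph_genes, , drop = FALSE]
  n_diff <- sum(gd_graph$p_value < cfg$gene_alpha)
  if (n_diff < cfg$min_diff_genes)
    stop("only ", n_diff, " differential graph gene(s) at p < ",
         cfg$gene_alpha, "; below the minimum of ", cfg$min_diff_genes)
  w_inf <- NULL
  if (cfg$method %in% c("drw-gm", "drw-gm-nm", "drw")) {
    w0 <- initial_weights(graph, gene_diff, met_diff, variant = cfg$method,
                          met_alpha = cfg$met_alpha,
                          metabolite_weighting = cfg$metabolite_weighting)
    tm <- transition_matrix(graph)
    w_inf <- drw_walk(tm, w0, walk_config(cfg$restart_prob, cfg$tol))
  }
  models <- fit_all_models(graph, gene_diff, w_inf, expr_z,
                           alpha = cfg$gene_alpha, method = cfg$method)
  if (length(models) == 0)
    models <- fallback_model(graph, gene_diff, w_inf, expr_z, cfg)
  act <- activity_matrix(models, expr_z)
  list(models = models, expr_z = expr_z, gene_diff = gene_diff,
       w_inf = w_inf, act = act)
}

# When no pathway clears the differential-gene filter (plausible on
# near-null data), keep the single pathway whose best member p-value is
# smallest so the protocol still yields a (single-feature) classifier.
fallback_model <- function(graph, gene_diff, w_inf, expr_z, cfg) {
  idx <- pathway_members(graph)
  best_p <- vapply(idx, function(genes) {
    p <- gene_diff$p_value[gene_diff$feature_id %in% genes]
    if (length(p)) min(p) else Inf
  }, 0)
  pid <- names(best_p)[which.min(best_p)]
  if (!is.finite(best_p[pid])) stop("no pathway has any measured gene")
  alpha2 <- best_p[[pid]] * (1 + 1e-9) + 1e-300
  m <- if (cfg$method == "pac") {
    pac_activity(pid, idx[[pid]], expr_z)
  } else if (cfg$method %in% c("mean", "median")) {
    fit_activity_model(pid, idx[[pid]], gene_diff, method = cfg$method)
  } else {
    fit_activity_model(pid, idx[[pid]], gene_diff, w_inf, alpha2, cfg$method)
  }
  stats::setNames(list(m), pid)
}

new_eval_report <- function(aucs, accs, selected, mode, cfg) {
  freq <- sort(table(unlist(selected)), decreasing = TRUE)
  structure(list(aucs = aucs, accuracies = accs,
                 mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
                 selected = selected, selection_freq = freq,
                 mode = mode, config = cfg),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s, %s]: %d AUCs, mean %.4f (sd %.4f)\n",
              x$mode, x$config$method, length(x$aucs), x$mean_auc,
              x$sd_auc))
  invisible(x)
}

#' Within-dataset cross-validated evaluation
#'
#' For each repeat: a stratified split of the cohort into `n_folds` folds;
#' each fold in turn is the test set and the remainder the training set.
#' Differential statistics, the random walk and the activity models are
#' fitted on the training set only. The training set is then split
#' `inner_splits` times (stratified, two thirds / one third) into a
#' feature-evaluation set, used to rank features and fit classifiers, and
#' a feature-selection set, used to accept or reject features greedily.
#' Each optimized classifier is scored on the held-out fold, giving
#' `n_folds * inner_splits` AUCs per repeat (15 under the default 5 x 3).
#'
#' @param expr expression [labeled_matrix()] (raw; z-normalization happens
#'   per training/test subset inside the protocol)
#' @param met metabolite [labeled_matrix()] of the matched metabolomic
#'   cohort, or `NULL` for gene-only methods
#' @param graph grounded global igraph (gene-metabolite, or gene-only for
#'   method `"drw"`)
#' @param cfg an [eval_config()]
#' @return an `eval_report` with `n_repeats * n_folds * inner_splits` AUCs
#' @export
within_dataset_eval <- function(expr, met, graph, cfg = eval_config()) {
  met_diff <- if (!is.null(met)) metabolite_tests(met) else NULL
  set.seed(cfg$seed)
  repeat_seeds <- sample.int(.Machine$integer.max, cfg$n_repeats)
  aucs <- numeric(0); accs <- numeric(0); selected <- list()
  for (rep_i in seq_len(cfg$n_repeats)) {
    set.seed(repeat_seeds[rep_i])
    folds <- stratified_folds(expr$labels, cfg$n_folds)
    for (k in seq_len(cfg$n_folds)) {
      test_ids <- colnames(expr$values)[folds == k]
      train_ids <- colnames(expr$values)[folds != k]
      fitted <- train_pipeline(subset_samples(expr, train_ids), met_diff,
                               graph, cfg)
      test_z <- suppressWarnings(z_normalize(subset_samples(expr, test_ids)))
      act_test <- suppressWarnings(
        activity_matrix(fitted$models, test_z, frozen = TRUE))
      for (s in seq_len(cfg$inner_splits)) {
        in_eval <- stratified_split(fitted$act$labels, 2 / 3)
        gs <- greedy_select(
          subset_samples(fitted$act, which(in_eval)),
          subset_samples(fitted$act, which(!in_eval)))
        scores <- predict_scores(gs$classifier,
                                 lm_features(act_test, gs$features))
        aucs <- c(aucs, auc_rank(scores, act_test$labels))
        accs <- c(accs, mean((scores > 0.5) ==
                               (act_test$labels ==
                                  levels(act_test$labels)[2])))
        selected[[length(selected) + 1L]] <- gs$features
      }
    }
  }
  new_eval_report(aucs, accs, selected, "within-dataset", cfg)
}

#' Cross-dataset evaluation on an independent cohort
#'
#' The whole first cohort is the training set: differential statistics,
#' the walk, the activity models and the training activities come from it
#' alone. Per repeat, the training samples are partitioned into `n_folds`
#' stratified subsets; each subset in turn is the feature-selection set
#' and the remaining subsets the feature-evaluation set. Each optimized
#' classifier is evaluated on the full independent test cohort, whose
#' activities use the frozen models with test-side z-normalization. One
#' partition gives `n_folds` AUCs (5 by default).
#'
#' @param expr_train training expression cohort
#' @param met metabolite cohort matched to the training cohort (or `NULL`)
#' @param expr_test independent test expression cohort; must share at
#'   least one model gene per usable pathway with the training platform
#' @param graph grounded global igraph
#' @param cfg an [eval_config()]
#' @return an `eval_report` with `n_repeats * n_folds` AUCs
#' @export
cross_dataset_eval <- function(expr_train, met, expr_test, graph,
                               cfg = eval_config()) {
  met_diff <- if (!is.null(met)) metabolite_tests(met) else NULL
  set.seed(cfg$seed)
  repeat_seeds <- sample.int(.Machine$integer.max, cfg$n_repeats)
  fitted <- train_pipeline(expr_train, met_diff, graph, cfg)
  test_z <- suppressWarnings(z_normalize(expr_test))
  act_test <- suppressWarnings(
    activity_matrix(fitted$models, test_z, frozen = TRUE))
  if (is.null(act_test))
    stop("no pathway model has any gene measured in the test cohort")
  shared <- intersect(rownames(fitted$act$values), rownames(act_test$values))
  act_train <- lm_features(fitted$act, shared)
  aucs <- numeric(0); accs <- numeric(0); selected <- list()
  for (rep_i in seq_len(cfg$n_repeats)) {
    set.seed(repeat_seeds[rep_i])
    folds <- stratified_folds(act_train$labels, cfg$n_folds)
    for (k in seq_len(cfg$n_folds)) {
      gs <- greedy_select(subset_samples(act_train, which(folds != k)),
                          subset_samples(act_train, which(folds == k)))
      scores <- predict_scores(gs$classifier,
                               lm_features(act_test, gs$features))
      aucs <- c(aucs, auc_rank(scores, act_test$labels))
      accs <- c(accs, mean((scores > 0.5) ==
                             (act_test$labels ==
                                levels(act_test$labels)[2])))
      selected[[length(selected) + 1L]] <- gs$features
    }
  }
  new_eval_report(aucs, accs, selected, "cross-dataset", cfg)
}

#' Reproducibility power of pathway activities
#'
#' Pathway activities are ranked by the magnitude of their t-score in the
#' training cohort (descending); the score of the top `N` is the mean of
#' the products of each pathway's training and test t-scores. Large values
#' mean the most discriminative training features stay discriminative, in
#' the same direction, on the independent cohort.
#'
#' @param act_train,act_test pathway-activity [labeled_matrix()]s of the
#'   two cohorts (paired by pathway id)
#' @param N number of top-ranked pathways to average over
#' @return list of class `c_score_result` with `N`, `c_score`,
#'   `pathway_ids` (ranked) and `products` (`t_train * t_test` per
#'   pathway)
#' @export
c_score <- function(act_train, act_test, N) {
  shared <- intersect(rownames(act_train$values), rownames(act_test$values))
  if (N > length(shared))
    stop("N = ", N, " exceeds the ", length(shared), " shared pathways")
  t_tr <- gene_ttests(lm_features(act_train, shared))
  t_te <- gene_ttests(lm_features(act_test, shared))
  o <- order(-abs(t_tr$t_score), t_tr$feature_id, method = "radix")
  products <- (t_tr$t_score * t_te$t_score)[o]
  structure(list(N = as.integer(N),
                 c_score = mean(products[seq_len(N)]),
                 pathway_ids = t_tr$feature_id[o],
                 products = products),
            class = "c_score_result")
}

#' @export
print.c_score_result <- function(x, ...) {
  cat(sprintf("c_score(N = %d) = %.4f over %d pathways\n",
              x$N, x$c_score, length(x$products)))
  invisible(x)
}
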
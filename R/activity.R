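#' Fit a pathway activity model
#'
#' For the random-walk methods, the model of pathway `P_j` keeps its
#' differential member genes (two-tailed t-test `p < alpha` on the training
#' cohort), their stationary walk weights and the signs of their training
#' t-scores. For the `mean` and `median` baselines all measured member
#' genes are kept (no significance filter, matching the classical
#' mean/median pathway summaries). Returns `NULL` when no usable member
#' gene remains, in which case the pathway is dropped.
#'
#' @param pathway_id pathway identifier
#' @param member_genes character vector of the pathway's member gene ids
#' @param gene_diff data.frame from [gene_ttests()] on the training cohort
#' @param w_inf stationary weights from [drw_walk()] (ignored by baselines)
#' @param alpha differential-gene cut-off (default 0.05)
#' @param method `"drw-gm"`, `"drw-gm-nm"`, `"drw"`, `"mean"` or `"median"`
#' @return a `pathway_activity_model` (list with `pathway_id`, `genes`,
#'   `weights`, `signs`, `method`) or `NULL`
#' @export
fit_activity_model <- function(pathway_id, member_genes, gene_diff,
                               w_inf = NULL, alpha = 0.05,
                               method = c("drw-gm", "drw-gm-nm", "drw",
                                          "mean", "median")) {
  method <- match.arg(method)
  gd <- gene_diff[gene_diff$feature_id %in% member_genes, , drop = FALSE]
  if (nrow(gd) == 0) return(NULL)
  if (method %in% c("mean", "median")) {
    genes <- sort_c(gd$feature_id)
    model <- list(pathway_id = pathway_id, genes = genes,
                  weights = NULL, signs = NULL, method = method)
    return(structure(model, class = "pathway_activity_model"))
  }
  gd <- gd[gd$p_value < alpha, , drop = FALSE]
  if (nrow(gd) == 0) return(NULL)
  if (is.null(w_inf)) stop("random-walk methods require w_inf")
  missing_w <- setdiff(gd$feature_id, names(w_inf))
  if (length(missing_w))
    stop("gene(s) absent from the walk vector: ",
         paste(missing_w, collapse = ", "))
  w <- unname(w_inf[gd$feature_id])
  o <- order(-w, gd$feature_id, method = "radix")
  structure(list(pathway_id = pathway_id,
                 genes = gd$feature_id[o],
                 weights = w[o],
                 signs = sign(gd$t_score)[o],
                 method = method),
            class = "pathway_activity_model")
}

#' @export
print.pathway_activity_model <- function(x, ...) {
  cat(sprintf("pathway_activity_model [%s] %s: %d gene(s)\n",
              x$method, x$pathway_id, length(x$genes)))
  invisible(x)
}

#' Pathway activity of a cohort under a fitted model
#'
#' Training-cohort activity: the weighted, sign-aligned combination of the
#' model genes' z-scores,
#' `a(P_j) = sum_i W(g_i) * sgn(t_i) * z(g_i) / sqrt(sum_i W(g_i)^2)`,
#' which reduces to `+/- z(g)` for a single-gene model and is invariant to
#' rescaling all weights. The `mean`/`median` baselines take the per-sample
#' mean or median of the member z-rows; the CORG baseline is the same
#' weighted form with unit weights over its greedy gene set.
#'
#' `activity_test` applies the frozen model (weights and signs from
#' training) to an independent cohort z-normalized over its own samples.
#' Model genes missing from the test platform are dropped with a warning
#' and the denominator recomputed over the remaining genes.
#'
#' @param model a `pathway_activity_model`
#' @param expr_z z-normalized [labeled_matrix()]
#' @return named numeric vector of per-sample activities, or `NULL` from
#'   `activity_test` when no model gene is measured
#' @export
activity_train <- function(model, expr_z) {
  absent <- setdiff(model$genes, rownames(expr_z$values))
  if (length(absent))
    stop("model gene(s) missing from the matrix: ",
         paste(absent, collapse = ", "))
  activity_combine(model, expr_z)
}

#' @rdname activity_train
#' @export
activity_test <- function(model, expr_z) {
  present <- intersect(model$genes, rownames(expr_z$values))
  if (length(present) == 0) {
    warning("pathway ", model$pathway_id,
            ": no model gene measured in the test cohort; dropped")
    return(NULL)
  }
  if (length(present) < length(model$genes)) {
    warning("pathway ", model$pathway_id, ": dropping ",
            length(model$genes) - length(present),
            " model gene(s) absent from the test cohort")
    keep <- model$genes %in% present
    model$genes <- model$genes[keep]
    if (!is.null(model$weights)) model$weights <- model$weights[keep]
    if (!is.null(model$signs)) model$signs <- model$signs[keep]
  }
  activity_combine(model, expr_z)
}

activity_combine <- function(model, expr_z) {
  z <- expr_z$values[model$genes, , drop = FALSE]
  if (model$method == "mean") return(colMeans(z))
  if (model$method == "median") return(apply(z, 2, stats::median))
  w <- model$weights * model$signs
  stats::setNames(as.numeric(w %*% z) / sqrt(sum(model$weights^2)),
                  colnames(z))
}

#' CORG-style greedy pathway activity model
#'
#' The condition-responsive-genes baseline: member genes are ranked by the
#' magnitude of their t-score on the training cohort; starting from the top
#' gene, each next-ranked gene is added if the t-statistic of the
#' sign-aligned averaged profile (`sum sgn(t_i) z_i / sqrt(k)`) strictly
#' increases in magnitude, and the search stops at the first failure.
#'
#' @param pathway_id pathway identifier
#' @param member_genes the pathway's member gene ids
#' @param expr_train_z z-normalized training [labeled_matrix()]
#' @return a `pathway_activity_model` with method `"pac"` and unit weights
#'   over the greedy gene set, or `NULL` if no member gene is measured
#' @export
pac_activity <- function(pathway_id, member_genes, expr_train_z) {
  present <- intersect(member_genes, rownames(expr_train_z$values))
  if (length(present) == 0) return(NULL)
  sub <- labeled_matrix(expr_train_z$values[present, , drop = FALSE],
                        expr_train_z$labels)
  gd <- gene_ttests(sub)
  o <- order(-abs(gd$t_score), gd$feature_id, method = "radix")
  gd <- gd[o, , drop = FALSE]
  activity_t <- function(genes, signs) {
    a <- as.numeric(signs %*% sub$values[genes, , drop = FALSE]) /
      sqrt(length(genes))
    am <- labeled_matrix(matrix(a, 1, dimnames = list("a", names(sub$labels))),
                         sub$labels)
    abs(gene_ttests(am)$t_score)
  }
  corg <- gd$feature_id[1]
  signs <- sign(gd$t_score[1])
  best <- activity_t(corg, signs)
  for (i in seq_len(nrow(gd))[-1]) {
    cand_genes <- c(corg, gd$feature_id[i])
    cand_signs <- c(signs, sign(gd$t_score[i]))
    cand <- activity_t(cand_genes, cand_signs)
    if (cand > best) {
      corg <- cand_genes
      signs <- cand_signs
      best <- cand
    } else break
  }
  structure(list(pathway_id = pathway_id, genes = corg,
                 weights = rep(1, length(corg)), signs = signs,
                 method = "pac"),
            class = "pathway_activity_model")
}

#' Fit activity models for every pathway of a global graph
#'
#' Applies [fit_activity_model()] (or [pac_activity()]) to each pathway in
#' the graph's membership index and drops pathways without usable genes.
#'
#' @param graph global igraph carrying a `pathway_index` attribute
#' @param gene_diff data.frame from [gene_ttests()] on the training cohort
#' @param w_inf stationary walk weights (random-walk methods)
#' @param expr_train_z z-normalized training matrix (needed by `"pac"`)
#' @param alpha differential-gene cut-off
#' @param method activity inference method
#' @return named list of `pathway_activity_model`s (possibly empty)
#' @export
fit_all_models <- function(graph, gene_diff, w_inf = NULL,
                           expr_train_z = NULL, alpha = 0.05,
                           method = "drw-gm") {
  idx <- pathway_members(graph)
  models <- list()
  for (pid in names(idx)) {
    m <- if (method == "pac") {
      pac_activity(pid, idx[[pid]], expr_train_z)
    } else {
      fit_activity_model(pid, idx[[pid]], gene_diff, w_inf, alpha, method)
    }
    if (!is.null(m)) models[[pid]] <- m
  }
  models
}

#' Pathway-activity profile of a cohort
#'
#' Stacks per-pathway activities into a pathways x samples
#' [labeled_matrix()].
#'
#' @param models list of `pathway_activity_model`s
#' @param expr_z z-normalized cohort
#' @param frozen apply models as frozen ([activity_test()] semantics,
#'   dropping unmeasured genes) rather than requiring all genes present
#' @return a `labeled_matrix` of activities (pathways dropped when no model
#'   gene is measured), or `NULL` if none remain
#' @export
activity_matrix <- function(models, expr_z, frozen = FALSE) {
  rows <- list()
  for (m in models) {
    a <- if (frozen) activity_test(m, expr_z) else activity_train(m, expr_z)
    if (!is.null(a)) rows[[m$pathway_id]] <- a
  }
  if (length(rows) == 0) return(NULL)
  v <- do.call(rbind, rows)
  labeled_matrix(v, expr_z$labels)
}
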
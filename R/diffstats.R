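#' Row-wise z-score normalization
#'
#' Rescales every feature to mean 0 and standard deviation 1 over the
#' samples of the matrix (sample sd, n - 1 denominator). Constant features
#' cannot be scaled; their rows are set to all zeros with a warning rather
#' than an error, since dropping them silently would desynchronize feature
#' sets between cohorts.
#'
#' @param m a [labeled_matrix()]
#' @return a `labeled_matrix` of the same shape with normalized rows
#' @export
z_normalize <- function(m) {
  v <- m$values
  mu <- rowMeans(v)
  sdev <- apply(v, 1, stats::sd)
  flat <- sdev == 0 | !is.finite(sdev)
  if (any(flat)) {
    warning("zero-variance feature(s) set to 0: ",
            paste(utils::head(rownames(v)[flat], 5), collapse = ", "),
            if (sum(flat) > 5) ", ...")
    sdev[flat] <- 1
  }
  z <- (v - mu) / sdev
  z[flat, ] <- 0
  labeled_matrix(z, m$labels)
}

#' Per-gene two-sample t-tests
#'
#' Two-tailed t-test of each feature between the two phenotypes, vectorized
#' over rows. The pooled-variance Student form is the default; Welch is
#' available. The sign convention is second-phenotype minus first (factor
#' level order), so a positive score means higher expression in the second
#' phenotype.
#'
#' @param m a [labeled_matrix()] with at least two samples per phenotype
#' @param var_equal pooled-variance Student t (default) or Welch if `FALSE`
#' @return data.frame with columns `feature_id`, `t_score`, `p_value`,
#'   `test` (`"t"`), one row per feature in matrix order
#' @export
gene_ttests <- function(m, var_equal = TRUE) {
  ia <- m$labels == levels(m$labels)[1]
  ib <- !ia
  na <- sum(ia); nb <- sum(ib)
  if (na < 2 || nb < 2)
    stop("each phenotype needs >= 2 samples for a t-test (got ",
         na, " and ", nb, ")")
  va <- m$values[, ia, drop = FALSE]
  vb <- m$values[, ib, drop = FALSE]
  ma <- rowMeans(va); mb <- rowMeans(vb)
  ssa <- rowSums((va - ma)^2)
  ssb <- rowSums((vb - mb)^2)
  if (var_equal) {
    sp2 <- (ssa + ssb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(m$values))
  } else {
    s2a <- ssa / (na - 1); s2b <- ssb / (nb - 1)
    se <- sqrt(s2a / na + s2b / nb)
    df <- (s2a / na + s2b / nb)^2 /
      ((s2a / na)^2 / (na - 1) + (s2b / nb)^2 / (nb - 1))
  }
  t <- (mb - ma) / se
  t[se == 0] <- 0                      # identical constant groups
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[se == 0] <- 1
  data.frame(feature_id = rownames(m$values), t_score = t, p_value = p,
             test = "t", row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-metabolite Wilcoxon rank-sum tests
#'
#' Two-sided rank-sum test per feature: exact when both groups have at most
#' 25 samples (and no ties), normal approximation with continuity
#' correction otherwise. The reported score is the rank-biserial
#' correlation, signed second-phenotype minus first, so its sign carries
#' the direction of the shift.
#'
#' @param m a [labeled_matrix()] with at least two samples per phenotype
#' @return data.frame with columns `feature_id`, `t_score` (rank-biserial),
#'   `p_value`, `test` (`"wilcoxon"`)
#' @export
metabolite_tests <- function(m) {
  ia <- m$labels == levels(m$labels)[1]
  ib <- !ia
  na <- sum(ia); nb <- sum(ib)
  if (na < 2 || nb < 2)
    stop("each phenotype needs >= 2 samples for a rank-sum test (got ",
         na, " and ", nb, ")")
  exact <- na <= 25 && nb <= 25
  res <- apply(m$values, 1, function(row) {
    wt <- suppressWarnings(
      stats::wilcox.test(row[ib], row[ia], exact = exact, correct = TRUE))
    u <- unname(wt$statistic)              # Mann-Whitney U for phenotype B
    c(rb = 2 * u / (na * nb) - 1, p = wt$p.value)
  })
  data.frame(feature_id = rownames(m$values), t_score = res["rb", ],
             p_value = pmin(res["p", ], 1), test = "wilcoxon",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Initial weight vector of the random walk
#'
#' Builds the restart distribution over the grounded global graph from the
#' differential statistics. Measured genes get `-log(p)` weights, min-max
#' rescaled to `[0, 1]` over the measured genes; measured metabolites with
#' `p < met_alpha` get weight 1 (others 0). The `drw-gm-nm` and `drw`
#' variants zero all metabolite weights, using only the gene evidence. The
#' concatenated vector is L1-normalized; the ground node and any node
#' absent from the profiles start at 0 (such nodes still accumulate walk
#' mass through their neighbors).
#'
#' @param graph grounded global igraph (node order defines the vector index)
#' @param gene_diff data.frame from [gene_ttests()] on the training cohort
#' @param met_diff data.frame from [metabolite_tests()], or `NULL`
#' @param variant `"drw-gm"` (gene + metabolite evidence), `"drw-gm-nm"`
#'   (gene-metabolite graph, gene evidence only) or `"drw"` (gene-only graph)
#' @param met_alpha significance cut-off for calling a metabolite
#'   differential (default 0.01)
#' @param metabolite_weighting `"cutoff"` (0/1 at `met_alpha`, default) or
#'   `"pvalue"` (`-log(p)` min-max rescaled, no cut-off)
#' @return named numeric vector over the graph's nodes, nonnegative,
#'   summing to 1, ground entry 0
#' @export
initial_weights <- function(graph, gene_diff, met_diff = NULL,
                            variant = c("drw-gm", "drw-gm-nm", "drw"),
                            met_alpha = 0.01,
                            metabolite_weighting = c("cutoff", "pvalue")) {
  variant <- match.arg(variant)
  metabolite_weighting <- match.arg(metabolite_weighting)
  ids <- igraph::V(graph)$name
  kinds <- igraph::V(graph)$kind
  w <- stats::setNames(numeric(length(ids)), ids)

  gene_nodes <- ids[kinds == "gene"]
  gd <- gene_diff[gene_diff$feature_id %in% gene_nodes, , drop = FALSE]
  if (nrow(gd) == 0)
    stop("no measured gene matches any gene node of the graph")
  wg <- -log(gd$p_value)
  rng <- range(wg)
  if (rng[2] > rng[1]) {
    wg <- (wg - rng[1]) / (rng[2] - rng[1])
  } else {
    warning("all gene p-values identical; giving measured genes equal weight")
    wg <- rep(1, length(wg))
  }
  w[gd$feature_id] <- wg

  if (variant == "drw-gm" && !is.null(met_diff)) {
    met_nodes <- ids[kinds == "metabolite"]
    md <- met_diff[met_diff$feature_id %in% met_nodes, , drop = FALSE]
    if (nrow(md)) {
      if (metabolite_weighting == "cutoff") {
        w[md$feature_id] <- as.numeric(md$p_value < met_alpha)
      } else {
        wm <- -log(md$p_value)
        rngm <- range(wm)
        wm <- if (rngm[2] > rngm[1]) (wm - rngm[1]) / (rngm[2] - rngm[1])
              else rep(1, length(wm))
        w[md$feature_id] <- wm
      }
    }
  }

  w[ids[kinds == "ground"]] <- 0
  total <- sum(w)
  if (total == 0)
    stop("degenerate initial weights: all zero")
  w / total
}
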
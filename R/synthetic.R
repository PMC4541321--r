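#' Simulation specification
#'
#' Describes a synthetic two-phenotype study: metabolic pathways built as
#' reaction chains with designated hub enzymes (high-degree genes
#' catalyzing many steps), an expression cohort and an independent
#' metabolite cohort. In risk pathways the hub genes carry a small-variance
#' consistent shift, an equal number of peripheral genes carry an equally
#' significant but noisier shift, and a fraction of the pathway's
#' metabolites (preferring hub-adjacent ones) is shifted detectably.
#' Effect sizes are standardized (units of each feature's own sd), so
#' equal `effect_size_hub` and `effect_size_peripheral` plant equally
#' significant genes that differ only in topology and noise level.
#'
#' @param n_pathways number of pathways (default 10)
#' @param n_risk_pathways pathways carrying planted signal (default 3)
#' @param genes_per_pathway,metabolites_per_pathway pathway sizes (10, 10)
#' @param hub_fraction fraction of each pathway's genes that are hubs (0.2)
#' @param n_samples_per_class expression samples per phenotype (30)
#' @param met_samples_per_class metabolite-cohort samples per phenotype (15)
#' @param effect_size_hub standardized shift of hub genes in risk pathways
#'   (1.5)
#' @param effect_size_peripheral standardized shift of the planted
#'   peripheral genes (1.5)
#' @param noise_sd_hub,noise_sd_peripheral expression noise sd for hub and
#'   non-hub genes (0.5, 1.0); hubs are low-variance by construction
#' @param frac_differential_metabolites fraction of a risk pathway's
#'   metabolites that shift (0.5)
#' @param effect_size_metabolite standardized log-scale metabolite shift
#'   (2.0)
#' @param met_log_sd log-scale sd of the log-normal abundances (0.5)
#' @param seed integer seed fixing every random draw
#' @return a validated list of class `sim_spec`
#' @export
sim_spec <- function(n_pathways = 10L, n_risk_pathways = 3L,
                     genes_per_pathway = 10L, metabolites_per_pathway = 10L,
                     hub_fraction = 0.2, n_samples_per_class = 30L,
                     met_samples_per_class = 15L, effect_size_hub = 1.5,
                     effect_size_peripheral = 1.5, noise_sd_hub = 0.5,
                     noise_sd_peripheral = 1.0,
                     frac_differential_metabolites = 0.5,
                     effect_size_metabolite = 2.0, met_log_sd = 0.5,
                     seed = 1L) {
  spec <- list(n_pathways = as.integer(n_pathways),
               n_risk_pathways = as.integer(n_risk_pathways),
               genes_per_pathway = as.integer(genes_per_pathway),
               metabolites_per_pathway = as.integer(metabolites_per_pathway),
               hub_fraction = hub_fraction,
               n_samples_per_class = as.integer(n_samples_per_class),
               met_samples_per_class = as.integer(met_samples_per_class),
               effect_size_hub = effect_size_hub,
               effect_size_peripheral = effect_size_peripheral,
               noise_sd_hub = noise_sd_hub,
               noise_sd_peripheral = noise_sd_peripheral,
               frac_differential_metabolites = frac_differential_metabolites,
               effect_size_metabolite = effect_size_metabolite,
               met_log_sd = met_log_sd,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_pathways >= 1, n_risk_pathways >= 0,
              n_risk_pathways <= n_pathways, genes_per_pathway >= 2,
              metabolites_per_pathway >= 3, hub_fraction > 0,
              hub_fraction < 1, n_samples_per_class >= 3,
              met_samples_per_class >= 3, effect_size_hub >= 0,
              effect_size_peripheral >= 0,
              frac_differential_metabolites >= 0,
              frac_differential_metabolites <= 1)
    if (noise_sd_hub > noise_sd_peripheral)
      stop("hubs must not be noisier than peripheral genes ",
           "(noise_sd_hub <= noise_sd_peripheral)")
    if (ceiling(hub_fraction * genes_per_pathway) >= genes_per_pathway)
      stop("hub_fraction leaves no peripheral genes")
  })
  structure(spec, class = "sim_spec")
}

pad2 <- function(i) formatC(i, width = 2, flag = "0")

#' Simulate a synthetic gene-metabolite study
#'
#' Builds the reaction table, the expression cohort and the independent
#' metabolite cohort described by a [sim_spec()], with the planted ground
#' truth. Each pathway is a chain of reactions through its metabolites:
#' peripheral genes catalyze single steps while hub genes catalyze steps
#' across the whole chain, so edge reversal and upstream promotion are
#' exercised. The first `n_risk_pathways` pathways carry the signal.
#'
#' @param spec a [sim_spec()]
#' @return a list of class `sim_study`: `reactions` (a `reaction_table`),
#'   `expr` and `met` ([labeled_matrix()]s), and `truth` — a list with
#'   `risk_pathways`, `hub_genes`, `diff_hub_genes`,
#'   `diff_peripheral_genes`, `diff_metabolites`
#' @export
simulate_study <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  g <- spec$genes_per_pathway
  m <- spec$metabolites_per_pathway
  n_hub <- max(1L, ceiling(spec$hub_fraction * g))
  if (n_hub >= g) stop("hub_fraction leaves no peripheral genes")

  pw <- list(pathway_id = character(0), reaction_id = character(0),
             gene_ids = list(), substrate_ids = list(),
             product_ids = list(), reversible = logical(0))
  add_rxn <- function(pid, rid, gene, sub, prod) {
    pw$pathway_id <<- c(pw$pathway_id, pid)
    pw$reaction_id <<- c(pw$reaction_id, rid)
    pw$gene_ids[[length(pw$gene_ids) + 1L]] <<- gene
    pw$substrate_ids[[length(pw$substrate_ids) + 1L]] <<- sub
    pw$product_ids[[length(pw$product_ids) + 1L]] <<- prod
    pw$reversible <<- c(pw$reversible, FALSE)
  }

  hub_genes <- list(); periph_genes <- list(); hub_products <- list()
  for (p in seq_len(spec$n_pathways)) {
    pid <- paste0("pw", pad2(p))
    mets <- paste0("c", pad2(p), "_", pad2(seq_len(m)))
    genes <- paste0("g", pad2(p), "_", pad2(seq_len(g)))
    hubs <- genes[seq_len(n_hub)]
    periph <- genes[-seq_len(n_hub)]
    hub_genes[[pid]] <- hubs
    periph_genes[[pid]] <- periph
    # backbone chain: peripheral genes catalyze single consecutive steps
    for (k in seq_len(m - 1)) {
      gene <- periph[(k - 1) %% length(periph) + 1]
      add_rxn(pid, paste0("r", pad2(p), "_", pad2(k)),
              gene, mets[k], mets[k + 1])
    }
    # hubs catalyze steps spread across the chain -> high degree
    hub_steps <- unique(round(seq(1, m - 1,
                                  length.out = max(3, (m - 1) %/% 2))))
    prods <- character(0)
    for (j in seq_along(hubs)) {
      for (k in hub_steps) {
        step <- (k + j - 1 - 1) %% (m - 1) + 1
        add_rxn(pid, paste0("rh", pad2(p), "_", j, "_", pad2(k)),
                hubs[j], mets[step], mets[step + 1])
        prods <- c(prods, mets[step + 1])
      }
    }
    hub_products[[pid]] <- unique(prods)
  }
  reactions <- reaction_table(pw$pathway_id, pw$reaction_id, pw$gene_ids,
                              pw$substrate_ids, pw$product_ids,
                              pw$reversible)

  risk <- paste0("pw", pad2(seq_len(spec$n_risk_pathways)))
  diff_hub <- unlist(hub_genes[risk], use.names = FALSE)
  diff_periph <- unlist(lapply(periph_genes[risk], utils::head, n_hub),
                        use.names = FALSE)

  # expression cohort
  n <- spec$n_samples_per_class
  samples <- c(paste0("A", pad2(seq_len(n))), paste0("B", pad2(seq_len(n))))
  labels <- stats::setNames(rep(c("A", "B"), each = n), samples)
  all_genes <- sort_c(unique(c(unlist(hub_genes, use.names = FALSE),
                               unlist(periph_genes, use.names = FALSE))))
  is_hub <- all_genes %in% unlist(hub_genes, use.names = FALSE)
  sd_g <- ifelse(is_hub, spec$noise_sd_hub, spec$noise_sd_peripheral)
  ev <- matrix(stats::rnorm(length(all_genes) * 2 * n, sd = sd_g),
               nrow = length(all_genes), dimnames = list(all_genes, samples))
  shift <- numeric(length(all_genes))
  shift[all_genes %in% diff_hub] <-
    spec$effect_size_hub * spec$noise_sd_hub
  shift[all_genes %in% diff_periph] <-
    spec$effect_size_peripheral * spec$noise_sd_peripheral
  ev[, labels == "B"] <- ev[, labels == "B"] + shift
  expr <- labeled_matrix(ev, labels)

  # independent metabolite cohort (log-normal abundances)
  all_mets <- sort_c(paste0("c", pad2(rep(seq_len(spec$n_pathways),
                                          each = m)), "_",
                            pad2(rep(seq_len(m), spec$n_pathways))))
  diff_mets <- character(0)
  n_diff_m <- ceiling(spec$frac_differential_metabolites * m)
  for (pid in risk) {
    cand <- c(sort_c(hub_products[[pid]]),
              setdiff(sort_c(grep(paste0("^c", substr(pid, 3, 4), "_"),
                                  all_mets, value = TRUE)),
                      hub_products[[pid]]))
    diff_mets <- c(diff_mets, utils::head(cand, n_diff_m))
  }
  nm <- spec$met_samples_per_class
  msamples <- c(paste0("MA", pad2(seq_len(nm))),
                paste0("MB", pad2(seq_len(nm))))
  mlabels <- stats::setNames(rep(c("A", "B"), each = nm), msamples)
  lv <- matrix(stats::rnorm(length(all_mets) * 2 * nm,
                            sd = spec$met_log_sd),
               nrow = length(all_mets), dimnames = list(all_mets, msamples))
  mshift <- numeric(length(all_mets))
  mshift[all_mets %in% diff_mets] <-
    spec$effect_size_metabolite * spec$met_log_sd
  lv[, mlabels == "B"] <- lv[, mlabels == "B"] + mshift
  met <- labeled_matrix(exp(lv), mlabels)

  structure(list(spec = spec, reactions = reactions, expr = expr, met = met,
                 truth = list(risk_pathways = risk,
                              hub_genes = hub_genes,
                              peripheral_genes = periph_genes,
                              diff_hub_genes = diff_hub,
                              diff_peripheral_genes = diff_periph,
                              diff_metabolites = diff_mets)),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(paste0("sim_study: %d pathways (%d risk), %d genes x %d",
                     " samples, %d metabolites x %d samples\n"),
              x$spec$n_pathways, x$spec$n_risk_pathways,
              nrow(x$expr$values), ncol(x$expr$values),
              nrow(x$met$values), ncol(x$met$values)))
  invisible(x)
}

#' Write a simulated study to a directory
#'
#' Emits the reaction table, expression and metabolite matrices, the two
#' label files and the planted ground truth (JSON).
#'
#' @param study a `sim_study` from [simulate_study()]
#' @param dir output directory (created if needed)
#' @return the directory path, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reaction_table(study$reactions, file.path(dir, "reactions.tsv"))
  write_matrix_tsv(study$expr$values, file.path(dir, "expression.tsv"),
                   feature_col = "gene_id")
  write_labels_tsv(stats::setNames(as.character(study$expr$labels),
                                   names(study$expr$labels)),
                   file.path(dir, "expression_labels.tsv"))
  write_matrix_tsv(study$met$values, file.path(dir, "metabolites.tsv"),
                   feature_col = "metabolite_id")
  write_labels_tsv(stats::setNames(as.character(study$met$labels),
                                   names(study$met$labels)),
                   file.path(dir, "metabolite_labels.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}
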
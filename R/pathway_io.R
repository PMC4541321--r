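#' Read a pathway reaction table
#'
#' Reads the tab-separated reaction dialect used to describe metabolic
#' pathways: one row per reaction with columns `pathway_id`, `reaction_id`,
#' `gene_ids`, `substrate_ids`, `product_ids` and `reversible` (0/1). The
#' list-valued cells (`gene_ids`, `substrate_ids`, `product_ids`) hold
#' `;`-separated identifiers: the genes implementing the catalyzing enzyme
#' and the compounds consumed and produced.
#'
#' @param path path to the TSV file
#' @return a data.frame of class `reaction_table` with list columns
#'   `gene_ids`, `substrate_ids`, `product_ids` (character vectors) and a
#'   logical `reversible` column, rows in file order.
#' @export
read_reaction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("pathway_id", "reaction_id", "gene_ids",
                "substrate_ids", "product_ids", "reversible")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("reaction table is missing column(s): ",
         paste(missing, collapse = ", "))
  reaction_table(
    pathway_id    = trimws(df$pathway_id),
    reaction_id   = trimws(df$reaction_id),
    gene_ids      = split_ids(df$gene_ids, "gene_ids"),
    substrate_ids = split_ids(df$substrate_ids, "substrate_ids"),
    product_ids   = split_ids(df$product_ids, "product_ids"),
    reversible    = parse_reversible(df$reversible)
  )
}

#' Assemble a reaction table in memory
#'
#' @param pathway_id,reaction_id character vectors
#' @param gene_ids,substrate_ids,product_ids lists of character vectors
#' @param reversible logical vector
#' @return a validated `reaction_table` data.frame
#' @export
reaction_table <- function(pathway_id, reaction_id, gene_ids, substrate_ids,
                           product_ids, reversible) {
  if (is.character(gene_ids)) gene_ids <- strsplit(gene_ids, ";", fixed = TRUE)
  if (is.character(substrate_ids))
    substrate_ids <- strsplit(substrate_ids, ";", fixed = TRUE)
  if (is.character(product_ids))
    product_ids <- strsplit(product_ids, ";", fixed = TRUE)
  df <- data.frame(pathway_id = as.character(pathway_id),
                   reaction_id = as.character(reaction_id),
                   stringsAsFactors = FALSE)
  df$gene_ids <- lapply(gene_ids, trimws)
  df$substrate_ids <- lapply(substrate_ids, trimws)
  df$product_ids <- lapply(product_ids, trimws)
  df$reversible <- as.logical(reversible)
  for (i in seq_len(nrow(df))) {
    if (!nzchar(df$pathway_id[i]))
      stop("row ", i, ": empty pathway_id")
    for (col in c("gene_ids", "substrate_ids", "product_ids")) {
      ids <- df[[col]][[i]]
      if (length(ids) == 0 || any(!nzchar(ids)))
        stop("row ", i, ": empty identifier in ", col)
      if (anyDuplicated(ids))
        stop("row ", i, ": duplicated identifier in ", col)
    }
  }
  class(df) <- c("reaction_table", "data.frame")
  df
}

split_ids <- function(x, col) {
  out <- strsplit(x, ";", fixed = TRUE)
  empty <- !nzchar(trimws(x))
  if (any(empty))
    stop("empty identifier cell in ", col, " at data row ",
         which(empty)[1], " (file line ", which(empty)[1] + 1L, ")")
  out
}

parse_reversible <- function(x) {
  x <- trimws(x)
  if (!all(x %in% c("0", "1")))
    stop("reversible column must be 0 or 1; offending value: ",
         x[!x %in% c("0", "1")][1])
  x == "1"
}

#' Write a reaction table as TSV
#'
#' @param records a `reaction_table`
#' @param path output path
#' @export
write_reaction_table <- function(records, path) {
  df <- data.frame(
    pathway_id = records$pathway_id,
    reaction_id = records$reaction_id,
    gene_ids = vapply(records$gene_ids, paste, "", collapse = ";"),
    substrate_ids = vapply(records$substrate_ids, paste, "", collapse = ";"),
    product_ids = vapply(records$product_ids, paste, "", collapse = ";"),
    reversible = as.integer(records$reversible),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop selected compounds from a reaction table
#'
#' Removes the given compound ids (e.g. currency metabolites such as water
#' or ATP, which are not filtered by default anywhere in the pipeline) from
#' every substrate and product list. Reactions left without substrates or
#' products are dropped entirely.
#'
#' @param records a `reaction_table`
#' @param exclude character vector of compound ids to remove
#' @return the filtered `reaction_table`
#' @export
filter_compounds <- function(records, exclude) {
  if (length(exclude) == 0) return(records)
  subs <- lapply(records$substrate_ids, setdiff, exclude)
  prods <- lapply(records$product_ids, setdiff, exclude)
  keep <- lengths(subs) > 0 & lengths(prods) > 0
  reaction_table(records$pathway_id[keep], records$reaction_id[keep],
                 records$gene_ids[keep], subs[keep], prods[keep],
                 records$reversible[keep])
}

#' Read a reduced KGML pathway description
#'
#' Minimal reader for the KEGG pathway XML dialect covering exactly what
#' graph construction needs: `<reaction>` elements with their substrates,
#' products and `type` (reversible or irreversible), and gene `<entry>`
#' elements linking reactions to gene ids. Map layout, relations and
#' non-metabolic semantics are ignored.
#'
#' @param path path to a KGML file
#' @return a `reaction_table` with one row per gene-annotated reaction
#' @export
read_kgml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  pid <- xml2::xml_attr(doc, "name")
  if (is.na(pid)) stop("KGML root lacks a pathway name attribute")
  entries <- xml2::xml_find_all(doc, ".//entry[@type='gene'][@reaction]")
  rxn_genes <- list()
  for (e in entries) {
    rids <- strsplit(xml2::xml_attr(e, "reaction"), " ", fixed = TRUE)[[1]]
    genes <- strsplit(xml2::xml_attr(e, "name"), " ", fixed = TRUE)[[1]]
    for (rid in rids)
      rxn_genes[[rid]] <- union(rxn_genes[[rid]], genes)
  }
  rows <- list(reaction_id = character(0), gene_ids = list(),
               substrate_ids = list(), product_ids = list(),
               reversible = logical(0))
  for (rx in xml2::xml_find_all(doc, ".//reaction")) {
    rid <- xml2::xml_attr(rx, "name")
    genes <- rxn_genes[[rid]]
    if (is.null(genes)) next  # reaction without annotated genes
    subs <- xml2::xml_attr(xml2::xml_find_all(rx, "./substrate"), "name")
    prods <- xml2::xml_attr(xml2::xml_find_all(rx, "./product"), "name")
    if (length(subs) == 0 || length(prods) == 0) next
    rows$reaction_id <- c(rows$reaction_id, rid)
    rows$gene_ids[[length(rows$gene_ids) + 1L]] <- genes
    rows$substrate_ids[[length(rows$substrate_ids) + 1L]] <- unique(subs)
    rows$product_ids[[length(rows$product_ids) + 1L]] <- unique(prods)
    rows$reversible <- c(rows$reversible,
                         identical(xml2::xml_attr(rx, "type"), "reversible"))
  }
  reaction_table(rep(pid, length(rows$reaction_id)), rows$reaction_id,
                 rows$gene_ids, rows$substrate_ids, rows$product_ids,
                 rows$reversible)
}

#' Build a directed gene-metabolite graph for one pathway
#'
#' Converts reaction records into a directed bipartite graph: an edge runs
#' from a compound to each catalyzing gene when the compound is a substrate,
#' and from the gene to each product compound. Reversible reactions add the
#' opposite edges as well, so every substrate/product pair is connected in
#' both directions. Enzymes mapping to several genes yield one gene node per
#' gene, each with identical connectivity.
#'
#' @param records a `reaction_table` whose rows all share one `pathway_id`
#' @return an igraph with vertex attribute `kind` (`"gene"` or
#'   `"metabolite"`) and graph attribute `pathway_id`; the pathway's member
#'   genes are exactly its gene-kind vertices.
#' @export
build_pathway_graph <- function(records) {
  pid <- unique(records$pathway_id)
  if (length(pid) != 1)
    stop("records must belong to a single pathway, got: ",
         paste(pid, collapse = ", "))
  genes <- unique(unlist(records$gene_ids))
  mets <- unique(unlist(c(records$substrate_ids, records$product_ids)))
  clash <- intersect(genes, mets)
  if (length(clash))
    stop("identifier(s) used both as gene and compound: ",
         paste(clash, collapse = ", "))
  from <- character(0); to <- character(0)
  for (i in seq_len(nrow(records))) {
    gs <- records$gene_ids[[i]]
    subs <- records$substrate_ids[[i]]
    prods <- records$product_ids[[i]]
    for (g in gs) {
      from <- c(from, subs, rep(g, length(prods)))
      to <- c(to, rep(g, length(subs)), prods)
      if (records$reversible[i]) {
        from <- c(from, rep(g, length(subs)), prods)
        to <- c(to, subs, rep(g, length(prods)))
      }
    }
  }
  make_kind_graph(genes, mets, from, to, pathway_id = pid)
}

#' Build a directed gene-gene graph by contracting metabolites
#'
#' The gene-only variant used by the gene-expression-only random-walk
#' baseline: gene g1 is linked to gene g2 when some product compound of a
#' reaction catalyzed by g1 is a substrate compound of a reaction catalyzed
#' by g2. Reversible reactions contribute their compounds in both roles.
#' Records may span several pathways; the resulting graph then corresponds
#' to the merged gene-gene graph.
#'
#' @param records a `reaction_table`
#' @return an igraph of gene nodes only, with graph attribute
#'   `pathway_index` mapping pathway id to member gene ids.
#' @export
build_gene_gene_graph <- function(records) {
  n <- nrow(records)
  produced <- vector("list", n)  # compounds each reaction can emit
  consumed <- vector("list", n)  # compounds each reaction can take up
  for (i in seq_len(n)) {
    produced[[i]] <- records$product_ids[[i]]
    consumed[[i]] <- records$substrate_ids[[i]]
    if (records$reversible[i]) {
      produced[[i]] <- union(produced[[i]], records$substrate_ids[[i]])
      consumed[[i]] <- union(consumed[[i]], records$product_ids[[i]])
    }
  }
  genes <- unique(unlist(records$gene_ids))
  from <- character(0); to <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (length(intersect(produced[[i]], consumed[[j]])) == 0) next
    pairs <- expand.grid(g1 = records$gene_ids[[i]],
                         g2 = records$gene_ids[[j]],
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$g1 != pairs$g2, , drop = FALSE]
    from <- c(from, pairs$g1)
    to <- c(to, pairs$g2)
  }
  g <- make_kind_graph(genes, character(0), from, to)
  idx <- lapply(split(records$gene_ids, records$pathway_id),
                function(x) sort_c(unique(unlist(x))))
  igraph::graph_attr(g, "pathway_index") <- idx
  pid <- unique(records$pathway_id)
  if (length(pid) == 1) igraph::graph_attr(g, "pathway_id") <- pid
  g
}

make_kind_graph <- function(genes, mets, from, to, pathway_id = NULL) {
  genes <- sort_c(genes)
  mets <- sort_c(mets)
  nodes <- c(genes, mets)
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  g <- igraph::set_vertex_attr(g, "kind", value = c(
    rep("gene", length(genes)), rep("metabolite", length(mets))))
  if (length(from)) {
    el <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
    el <- el[order(el$from, el$to, method = "radix"), ]
    g <- igraph::add_edges(g, rbind(el$from, el$to))
  }
  if (!is.null(pathway_id))
    igraph::graph_attr(g, "pathway_id") <- pathway_id
  g
}

# C-locale sort for reproducible node orderings regardless of platform locale
sort_c <- function(x) x[order(x, method = "radix")]

#' Serialize / deserialize pathway graphs as GraphML
#'
#' Round-trips nodes, the `kind` vertex attribute, edges and the pathway
#' membership index (stored as a JSON graph attribute in the file).
#'
#' @param graph an igraph produced by the graph-construction functions
#' @param path file path
#' @return `read_pathway_graphml`: the reconstructed igraph.
#' @export
write_pathway_graphml <- function(graph, path) {
  idx <- igraph::graph_attr(graph, "pathway_index")
  if (!is.null(idx)) {
    graph <- igraph::delete_graph_attr(graph, "pathway_index")
    igraph::graph_attr(graph, "pathway_index_json") <-
      as.character(jsonlite::toJSON(idx))
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_pathway_graphml
#' @export
read_pathway_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  # igraph's GraphML reader may add its own bookkeeping id attribute
  if ("id" %in% igraph::vertex_attr_names(g) &&
      "name" %in% igraph::vertex_attr_names(g))
    g <- igraph::delete_vertex_attr(g, "id")
  json <- igraph::graph_attr(g, "pathway_index_json")
  if (!is.null(json)) {
    g <- igraph::delete_graph_attr(g, "pathway_index_json")
    idx <- jsonlite::fromJSON(json, simplifyVector = TRUE)
    igraph::graph_attr(g, "pathway_index") <- lapply(idx, as.character)
  }
  g
}
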
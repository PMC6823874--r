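#' Assemble the cancer / DDR-gene / SL-gene / drug association network
#'
#' Builds the typed network from validated SL records: an
#' \code{sl_interaction} edge (weight = RF probability) for every final-list
#' pair, \code{mutated_in} edges linking each primary DDR gene to the cancer
#' types where its record was made (when records carry a
#' \code{cancer_type} column), \code{drug_targets} edges from drugs to
#' included SL genes, and \code{drug_sensitive} edges (weight = one-sided
#' p-value) from drugs to the primary genes whose mutations sensitize. A drug
#' enters the network only if it targets an included SL gene \emph{and} shows
#' sensitivity to a connected primary-gene mutation (set
#' \code{require_sensitivity = FALSE} for target-only inclusion).
#'
#' @param records Validation records from \code{\link{validate_pairs}}.
#' @param drug_targets Data frame with columns \code{drug}, \code{target}.
#' @param cluster_annotation Optional named vector: DDR gene -> cluster label.
#' @param drug_whitelist Optional character vector restricting admissible
#'   drugs (e.g. an approved-drug list).
#' @param require_sensitivity Require the sensitivity flag for drug inclusion
#'   (default TRUE).
#' @return Object of class \code{sl_drug_network}: list of \code{nodes}
#'   (id, type, cluster) and \code{edges} (source, target, edge_type,
#'   weight).
#' @export
assemble_network <- function(records, drug_targets,
                             cluster_annotation = NULL,
                             drug_whitelist = NULL,
                             require_sensitivity = TRUE) {
  nodes <- data.frame(id = character(0), type = character(0),
                      cluster = character(0), stringsAsFactors = FALSE)
  edges <- data.frame(source = character(0), target = character(0),
                      edge_type = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  final <- records[records$final_list, , drop = FALSE]
  add_node <- function(id, type) {
    if (!id %in% nodes$id) {
      cl <- if (type == "ddr_gene" && !is.null(cluster_annotation) &&
                id %in% names(cluster_annotation)) {
        as.character(cluster_annotation[[id]])
      } else NA_character_
      nodes <<- rbind(nodes, data.frame(id = id, type = type, cluster = cl,
                                        stringsAsFactors = FALSE))
    }
  }
  for (i in seq_len(nrow(final))) {
    g1 <- final$gene1[[i]]
    g2 <- final$gene2[[i]]
    add_node(g1, "ddr_gene")
    add_node(g2, "sl_gene")
    edges <- rbind(edges, data.frame(
      source = g1, target = g2, edge_type = "sl_interaction",
      weight = final$sl_prob[[i]], stringsAsFactors = FALSE))
    if ("cancer_type" %in% colnames(final) && !is.na(final$cancer_type[[i]])) {
      ct <- final$cancer_type[[i]]
      add_node(ct, "cancer_type")
      edges <- rbind(edges, data.frame(
        source = g1, target = ct, edge_type = "mutated_in", weight = 1,
        stringsAsFactors = FALSE))
    }
  }
  # drugs: must target an included SL gene; sensitivity flag gates by default
  sl_genes <- nodes$id[nodes$type == "sl_gene"]
  for (i in seq_len(nrow(final))) {
    g2 <- final$gene2[[i]]
    if (!g2 %in% sl_genes) next
    d <- final$drug[[i]]
    if (is.na(d)) next
    if (!is.null(drug_whitelist) && !(d %in% drug_whitelist)) next
    if (!d %in% drug_targets$drug) {
      warning(sprintf("drug %s has no known target mapping; excluded", d))
      next
    }
    if (require_sensitivity && !isTRUE(final$drug_sensitive[[i]])) next
    add_node(d, "drug")
    if (!any(edges$source == d & edges$target == g2 &
               edges$edge_type == "drug_targets")) {
      edges <- rbind(edges, data.frame(
        source = d, target = g2, edge_type = "drug_targets", weight = 1,
        stringsAsFactors = FALSE))
    }
    edges <- rbind(edges, data.frame(
      source = d, target = final$gene1[[i]], edge_type = "drug_sensitive",
      weight = final$drug_p[[i]], stringsAsFactors = FALSE))
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "sl_drug_network")
}

node_types_known <- c("cancer_type", "ddr_gene", "sl_gene", "drug")

#' Write a network as an edge-list TSV
#'
#' Serializes the edge list with the endpoint node types and cluster
#' attributes inlined so the matching reader can reconstruct the network from
#' one file. An empty network yields a header-only TSV.
#'
#' @param network An \code{sl_drug_network}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "sl_drug_network"))
  bad <- setdiff(network$nodes$type, node_types_known)
  if (length(bad) > 0L) {
    stop("unknown node type(s): ", paste(bad, collapse = ", "))
  }
  e <- network$edges
  idx_s <- match(e$source, network$nodes$id)
  idx_t <- match(e$target, network$nodes$id)
  out <- data.frame(
    source = e$source, target = e$target, edge_type = e$edge_type,
    weight = e$weight,
    source_type = network$nodes$type[idx_s],
    target_type = network$nodes$type[idx_t],
    source_cluster = network$nodes$cluster[idx_s],
    target_cluster = network$nodes$cluster[idx_t],
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network written by \code{\link{write_network}}
#' @param path Edge-list TSV path.
#' @return An \code{sl_drug_network}.
#' @export
read_network <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(weight = "numeric"))
  if (nrow(e) == 0L) {
    return(structure(list(
      nodes = data.frame(id = character(0), type = character(0),
                         cluster = character(0), stringsAsFactors = FALSE),
      edges = data.frame(source = character(0), target = character(0),
                         edge_type = character(0), weight = numeric(0),
                         stringsAsFactors = FALSE)), class = "sl_drug_network"))
  }
  nodes <- unique(rbind(
    data.frame(id = e$source, type = e$source_type,
               cluster = as.character(e$source_cluster),
               stringsAsFactors = FALSE),
    data.frame(id = e$target, type = e$target_type,
               cluster = as.character(e$target_cluster),
               stringsAsFactors = FALSE)))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- e[, c("source", "target", "edge_type", "weight")]
  structure(list(nodes = nodes, edges = edges), class = "sl_drug_network")
}
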
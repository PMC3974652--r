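#' Build a tissue-specific bipartite regulatory network
#'
#' Node state in a tissue is the sign of `log2(tissue value / across-tissue
#' mean)` (a configurable dead-zone around zero treats near-average nodes
#' as unchanged and excludes them). The network is the union of
#' protein-interaction edges among expressed mRNAs and the passing
#' targeting edges, partitioned by the regulatory logic:
#'
#' * *permissive*: down-regulated miRNA -> up-regulated mRNA target (the
#'   target is released);
#' * *repressive*: up-regulated miRNA -> down-regulated mRNA target.
#'
#' Targeting edges matching neither sign pattern are dropped for the
#' tissue. mRNA-mRNA interaction edges are assigned to the side of their
#' incident mRNAs' state (both up -> permissive side, both down ->
#' repressive side; mixed edges are dropped so the two sides stay clean).
#' Multiple sites on one transcript collapse to one targeting edge with a
#' site-count attribute. Below-detection (`NA`) nodes are excluded.
#'
#' @param filtered_targets an [anticorrelation_filter()] result; only rows
#'   with `passes` contribute targeting edges.
#' @param interaction_edges data.frame with columns a, b (mRNA ids).
#' @param mirna_matrix,mrna_matrix expression matrices (shared tissue
#'   columns; NAs are below-detection).
#' @param tissue tissue column name.
#' @param dead_zone |log2 ratio| below which a node is treated as
#'   unchanged (default 0: pure sign).
#' @return object of class `regulatory_network`: list with `graph` (an
#'   igraph object; vertex attributes type, log2_ratio, state, partition;
#'   edge attributes type, partition, n_sites), `tissue`, `nodes`, `edges`
#'   data.frames.
#' @export
build_tissue_network <- function(filtered_targets, interaction_edges,
                                 mirna_matrix, mrna_matrix, tissue,
                                 dead_zone = 0) {
  if (!tissue %in% colnames(mirna_matrix) ||
      !tissue %in% colnames(mrna_matrix)) {
    stop("tissue not present in matrices: ", tissue)
  }
  state_of <- function(mat) {
    lr <- log2(mat[, tissue] / rowMeans(mat, na.rm = TRUE))
    st <- ifelse(is.na(lr), NA, ifelse(lr > dead_zone, "up",
                 ifelse(lr < -dead_zone, "down", "flat")))
    data.frame(id = rownames(mat), log2_ratio = lr, state = st,
               stringsAsFactors = FALSE)
  }
  mir_state <- state_of(mirna_matrix)
  mrna_state <- state_of(mrna_matrix)

  ft <- filtered_targets[filtered_targets$passes, , drop = FALSE]
  agg <- if (nrow(ft)) {
    stats::aggregate(list(n_sites = ft$position),
                     by = list(mirna = ft$mirna_id,
                               target = ft$transcript_id), FUN = length)
  } else {
    data.frame(mirna = character(0), target = character(0),
               n_sites = integer(0), stringsAsFactors = FALSE)
  }
  t_edges <- list()
  for (i in seq_len(nrow(agg))) {
    ms <- mir_state$state[match(agg$mirna[i], mir_state$id)]
    ts <- mrna_state$state[match(agg$target[i], mrna_state$id)]
    if (is.na(ms) || is.na(ts)) next  # below detection: grey semantics
    side <- if (ms == "down" && ts == "up") "permissive" else
      if (ms == "up" && ts == "down") "repressive" else next
    t_edges[[length(t_edges) + 1L]] <- data.frame(
      from = agg$mirna[i], to = agg$target[i], type = "targeting",
      partition = side, n_sites = agg$n_sites[i], stringsAsFactors = FALSE)
  }
  i_edges <- list()
  for (i in seq_len(nrow(interaction_edges))) {
    a <- interaction_edges$a[i]; b <- interaction_edges$b[i]
    sa <- mrna_state$state[match(a, mrna_state$id)]
    sb <- mrna_state$state[match(b, mrna_state$id)]
    if (is.na(sa) || is.na(sb)) next
    side <- if (sa == "up" && sb == "up") "permissive" else
      if (sa == "down" && sb == "down") "repressive" else next
    i_edges[[length(i_edges) + 1L]] <- data.frame(
      from = a, to = b, type = "interaction", partition = side,
      n_sites = NA_integer_, stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, c(t_edges, i_edges))
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        type = character(0), partition = character(0),
                        n_sites = integer(0), stringsAsFactors = FALSE)
  }
  node_ids <- unique(c(edges$from, edges$to))
  states <- rbind(cbind(mir_state, type = "miRNA"),
                  cbind(mrna_state, type = "mRNA"))
  nodes <- states[match(node_ids, states$id), , drop = FALSE]
  # a node's partition is the side of its incident edges
  nodes$partition <- vapply(nodes$id, function(id) {
    sides <- unique(edges$partition[edges$from == id | edges$to == id])
    if (length(sides) == 1) sides else "both"
  }, character(1))
  rownames(nodes) <- NULL

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, tissue = tissue, nodes = nodes, edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Regulatory network (", x$tissue, "): ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (",
      sum(x$edges$partition == "permissive"), " permissive / ",
      sum(x$edges$partition == "repressive"), " repressive)\n", sep = "")
  invisible(x)
}

#' Decompose a network into modules
#'
#' Modules are the connected components of each partition side, ordered by
#' node count (descending), then edge count (descending), then
#' lexicographically smallest member — a deterministic labeling.
#'
#' @param network a [build_tissue_network()] result.
#' @return data.frame: node, partition, module (1-based integer label per
#'   side).
#' @export
decompose_modules <- function(network) {
  out <- list()
  for (side in c("permissive", "repressive")) {
    e <- network$edges[network$edges$partition == side, , drop = FALSE]
    if (!nrow(e)) next
    g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE)
    comp <- igraph::components(g)
    members <- split(names(comp$membership), comp$membership)
    n_edges <- vapply(members, function(m) {
      sum(e$from %in% m & e$to %in% m)
    }, integer(1))
    sizes <- lengths(members)
    first <- vapply(members, function(m) sort(m)[1], character(1))
    ord <- order(-sizes, -n_edges, first)
    for (rank in seq_along(ord)) {
      m <- members[[ord[rank]]]
      out[[length(out) + 1L]] <- data.frame(
        node = sort(m), partition = side, module = rank,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(node = character(0), partition = character(0),
               module = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Export a regulatory network as text
#'
#' Writes a node table and an edge table (TSV), and optionally a GraphML
#' file carrying the node attributes (type, log2 ratio, state, partition,
#' module), so the network can be re-imported into any graph tool.
#'
#' @param network a `regulatory_network`.
#' @param node_path,edge_path output files.
#' @param graphml_path optional GraphML output file.
#' @export
write_network <- function(network, node_path, edge_path,
                          graphml_path = NULL) {
  modules <- decompose_modules(network)
  nodes <- merge(network$nodes, modules, by.x = "id", by.y = "node",
                 all.x = TRUE)
  write_tsv(nodes, node_path)
  write_tsv(network$edges, edge_path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = FALSE,
      vertices = nodes[!duplicated(nodes$id), , drop = FALSE])
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(network)
}
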
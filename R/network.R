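#' STRING evidence channels
#'
#' The seven interaction-evidence channels of the STRING database, in the
#' order of the detailed download format. `DEFAULT_EXCLUDED_CHANNELS` are the
#' low-direct-evidence channels removed before network construction
#' (text mining, genomic neighborhood, gene fusion, co-occurrence);
#' `DEFAULT_ALLOWED_CHANNELS` is their complement (co-expression,
#' experimental, curated database).
#'
#' @export
STRING_CHANNELS <- c("neighborhood", "fusion", "cooccurrence",
                     "coexpression", "experimental", "database", "textmining")

#' @rdname STRING_CHANNELS
#' @export
DEFAULT_EXCLUDED_CHANNELS <- c("textmining", "neighborhood", "fusion", "cooccurrence")

#' @rdname STRING_CHANNELS
#' @export
DEFAULT_ALLOWED_CHANNELS <- setdiff(STRING_CHANNELS, DEFAULT_EXCLUDED_CHANNELS)

#' Read a STRING detailed-dialect edge list
#'
#' Parses a tab-separated edge list with columns `protein1`, `protein2` and
#' the seven per-channel scores (the historical STRING column spelling
#' `cooccurence` is accepted and normalised to `cooccurrence`). Integer
#' scores (0-1000 dialect) are mapped to \[0,1\]; files already on \[0,1\] are
#' left as is. Symmetric duplicate rows are collapsed onto one canonical
#' (lexicographically ordered) edge keeping the maximum score per channel;
#' self-loops are dropped and counted.
#'
#' @param path TSV file path.
#' @return data.frame of class `channel_edges` with columns `gene_a`,
#'   `gene_b`, the seven channels, and `combined_score` (if present in the
#'   file), plus attribute `n_self_loops`.
#' @export
read_string_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "cooccurence"] <- "cooccurrence"
  req <- c("protein1", "protein2", STRING_CHANNELS)
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_input("missing required columns: ", paste(miss, collapse = ", "))
  }
  score_cols <- intersect(c(STRING_CHANNELS, "combined_score"), names(df))
  for (cc in score_cols) {
    if (!is.numeric(df[[cc]])) stop_input("non-numeric score in column '", cc, "'")
  }
  if (max(unlist(df[score_cols]), na.rm = TRUE) > 1) {
    df[score_cols] <- lapply(df[score_cols], function(x) x / 1000)
  }
  if (any(unlist(df[score_cols]) < 0 | unlist(df[score_cols]) > 1)) {
    stop_input("channel scores outside [0,1] after scaling")
  }

  self <- df$protein1 == df$protein2
  n_self <- sum(self)
  df <- df[!self, , drop = FALSE]
  cp <- canonical_pair(as.character(df$protein1), as.character(df$protein2))
  key <- paste(cp$a, cp$b)
  o <- order(key)
  df <- df[o, , drop = FALSE]
  ka <- cp$a[o]; kb <- cp$b[o]; key <- key[o]
  first <- !duplicated(key)
  idx <- cumsum(first)
  agg <- data.frame(gene_a = ka[first], gene_b = kb[first],
                    stringsAsFactors = FALSE)
  for (cc in score_cols) {
    agg[[cc]] <- as.numeric(tapply(df[[cc]], idx, max))
  }
  rownames(agg) <- NULL
  class(agg) <- c("channel_edges", "data.frame")
  attr(agg, "n_self_loops") <- n_self
  agg
}

#' Recombine a STRING combined score from a subset of evidence channels
#'
#' STRING's combined score assumes each channel is an independent noisy
#' detector sharing a common prior probability `prior` that a random protein
#' pair interacts. To restrict the evidence to a subset of channels, each
#' allowed channel score s is first stripped of the prior,
#' `s' = max(0, (s - prior) / (1 - prior))`, the stripped scores are combined
#' as `1 - prod(1 - s')`, and the prior is re-added:
#' `combined = combined' + prior * (1 - combined')`. With a single allowed
#' channel this recovers that channel's score (up to rounding); with no
#' evidence it returns the prior.
#'
#' @param channel_scores a named numeric vector, a matrix with channel
#'   columns, or a data.frame (e.g. `channel_edges`) with channel columns;
#'   scores in \[0,1\].
#' @param allowed_channels channels to combine (default: co-expression,
#'   experimental, database).
#' @param prior baseline interaction probability, in \[0,1) (STRING uses
#'   0.041).
#' @return numeric vector of recombined scores, one per row.
#' @export
recombine_score <- function(channel_scores,
                            allowed_channels = DEFAULT_ALLOWED_CHANNELS,
                            prior = 0.041) {
  if (!is.numeric(prior) || length(prior) != 1L || prior < 0 || prior >= 1) {
    stop_input("'prior' must lie in [0,1)")
  }
  if (is.null(dim(channel_scores)) && !is.data.frame(channel_scores)) {
    channel_scores <- as.data.frame(as.list(channel_scores))
  }
  unknown <- setdiff(allowed_channels, STRING_CHANNELS)
  if (length(unknown)) stop_input("unknown channels: ", paste(unknown, collapse = ", "))
  miss <- setdiff(allowed_channels, colnames(channel_scores))
  if (length(miss)) stop_input("missing channel columns: ", paste(miss, collapse = ", "))
  s <- as.matrix(as.data.frame(channel_scores)[, allowed_channels, drop = FALSE])
  check_prob(s, "channel scores")
  sprime <- pmax((s - prior) / (1 - prior), 0)  # matrix first: pmax keeps dim
  comb <- 1 - apply(1 - sprime, 1, prod)
  unname(comb + prior * (1 - comb))
}

#' Build the DEG-restricted high-confidence interaction network
#'
#' Keeps edges whose two endpoints are both differentially expressed genes
#' and whose combined score, recomputed from the allowed evidence channels
#' only, reaches the confidence threshold (default 0.900, STRING's "highest
#' confidence" band; comparison is inclusive). All DEGs appear as vertices,
#' so DEGs without a surviving interaction are isolated degree-0 nodes, as in
#' a STRING network of a gene list.
#'
#' @param edges a `channel_edges` data.frame (see [read_string_edges()]).
#' @param deg_genes character vector of DEG symbols.
#' @param threshold combined-score threshold in (0,1\].
#' @param allowed_channels evidence channels retained (default: coexpression,
#'   experimental, database).
#' @param prior channel recombination prior.
#' @param regulation optional named vector (`"up"`/`"down"`) used to annotate
#'   vertices.
#' @return an undirected simple `igraph` graph whose vertices are the DEGs;
#'   surviving edges carry a `score` attribute.
#' @export
build_network <- function(edges, deg_genes, threshold = 0.900,
                          allowed_channels = DEFAULT_ALLOWED_CHANNELS,
                          prior = 0.041, regulation = NULL) {
  deg_genes <- unique(as.character(deg_genes))
  if (length(deg_genes) == 0L) stop_input("empty DEG list")
  if (threshold <= 0 || threshold > 1) stop_input("'threshold' must lie in (0,1]")
  score <- recombine_score(edges, allowed_channels, prior)
  keep <- edges$gene_a %in% deg_genes & edges$gene_b %in% deg_genes &
    score >= threshold
  el <- data.frame(from = edges$gene_a[keep], to = edges$gene_b[keep],
                   score = score[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = sort(deg_genes)))
  g <- igraph::simplify(g, edge.attr.comb = "max")
  if (!is.null(regulation)) {
    igraph::V(g)$regulation <- unname(regulation[igraph::V(g)$name])
  }
  g
}

#' Connected components and their diameters
#'
#' Components are found by breadth-first search; the diameter of a component
#' is the largest unweighted shortest-path length between any two of its
#' nodes (0 for singletons).
#'
#' @param net an undirected `igraph` graph.
#' @return data.frame with columns `component`, `n_nodes`, `diameter`, plus
#'   attribute `membership` (named component index per vertex).
#' @export
component_diameters <- function(net) {
  comps <- igraph::components(net)
  n <- comps$no
  if (n == 0L) {
    out <- data.frame(component = integer(0), n_nodes = integer(0),
                      diameter = integer(0))
    attr(out, "membership") <- comps$membership
    return(out)
  }
  diam <- vapply(seq_len(n), function(i) {
    sub <- igraph::induced_subgraph(net, which(comps$membership == i))
    if (igraph::vcount(sub) == 1L) return(0)
    igraph::diameter(sub, directed = FALSE, unconnected = FALSE, weights = NA)
  }, numeric(1))
  out <- data.frame(component = seq_len(n),
                    n_nodes = as.integer(comps$csize),
                    diameter = as.integer(diam))
  attr(out, "membership") <- comps$membership
  out
}

#' Extract the component with the largest diameter
#'
#' Ties are broken deterministically: larger node count first, then the
#' lexicographically smallest sorted node-name set.
#'
#' @param net an undirected `igraph` graph with at least one vertex.
#' @return the selected component as an induced `igraph` subgraph.
#' @export
select_max_diameter_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop_input("empty graph")
  cd <- component_diameters(net)
  membership <- attr(cd, "membership")
  keys <- vapply(cd$component, function(i) {
    paste(sort(names(membership)[membership == i]), collapse = "\036")
  }, character(1))
  o <- order(-cd$diameter, -cd$n_nodes, keys)
  best <- cd$component[o[1L]]
  igraph::induced_subgraph(net, which(membership == best))
}

#' Remove a gene group (e.g. ribosomal proteins) from a network
#'
#' Induced subgraph on the vertices outside `group_genes`. The graph may
#' disconnect; no component re-selection is performed afterwards. The number
#' of removed vertices is attached as the graph attribute `n_removed`.
#'
#' @param net an `igraph` graph.
#' @param group_genes gene symbols to remove.
#' @return the pruned `igraph` graph.
#' @export
remove_group_nodes <- function(net, group_genes) {
  hit <- igraph::V(net)$name %in% group_genes
  g <- igraph::induced_subgraph(net, which(!hit))
  g <- igraph::set_graph_attr(g, "n_removed", sum(hit))
  g
}

#' Degree and normalized betweenness centrality
#'
#' Degree is the number of incident edges. Betweenness is computed over
#' unweighted shortest paths (Brandes' algorithm), path endpoints excluded,
#' and normalized by `(n-1)(n-2)/2` where n is the number of vertices of the
#' analyzed graph, so that values lie in \[0,1\]. Vertices in components of
#' size <= 2 (and all vertices when n < 3) have betweenness 0.
#'
#' @param net an undirected `igraph` graph.
#' @return data.frame with columns `gene`, `degree`, `betweenness`, ordered
#'   by gene symbol.
#' @export
centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) {
    return(data.frame(gene = character(0), degree = integer(0),
                      betweenness = numeric(0)))
  }
  deg <- igraph::degree(net)
  bt <- if (n < 3L) {
    rep(0, n)
  } else {
    igraph::betweenness(net, directed = FALSE, weights = NA, normalized = TRUE)
  }
  out <- data.frame(gene = igraph::V(net)$name, degree = as.integer(deg),
                    betweenness = as.numeric(bt),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}

#' Select hub nodes by centrality thresholds
#'
#' Hubs are the nodes that strictly exceed both thresholds
#' (betweenness > `bt_min` and degree > `deg_min`), returned sorted by
#' betweenness descending, then degree descending, then symbol.
#'
#' @param records centrality table from [centrality()].
#' @param bt_min betweenness threshold (strict, default 0.5).
#' @param deg_min degree threshold (strict, default 2).
#' @return character vector of hub gene symbols.
#' @export
select_hubs <- function(records, bt_min = 0.5, deg_min = 2) {
  hit <- records$betweenness > bt_min & records$degree > deg_min
  sel <- records[hit, , drop = FALSE]
  sel <- sel[order(-sel$betweenness, -sel$degree, sel$gene), , drop = FALSE]
  sel$gene
}

#' Global network summary statistics
#'
#' Node and edge counts, average degree (2E/N), and the mean local
#' clustering coefficient (nodes of degree < 2 contribute 0).
#'
#' @param net an undirected `igraph` graph.
#' @return list with `n_nodes`, `n_edges`, `avg_degree`, `avg_clustering`.
#' @export
network_summary <- function(net) {
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  if (n == 0L) {
    return(list(n_nodes = 0L, n_edges = 0L, avg_degree = 0, avg_clustering = 0))
  }
  cl <- igraph::transitivity(net, type = "local", isolates = "zero")
  list(n_nodes = n, n_edges = e, avg_degree = 2 * e / n,
       avg_clustering = mean(cl))
}

#' @rdname write_synthetic
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  utils::write.table(el[, c("from", "to")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_synthetic
#' @export
write_centrality_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
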
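# Co-predictive networks: nodes are (feature, discretization level) pairs,
# edges connect conditions that co-occur in rules, weighted by the sum of
# RS_RHS * RA over the rules containing both conditions.

node_key <- function(feature, level) paste0(feature, "=", level)

#' Build a co-predictive network from a rule model's rules
#'
#' Every rule with at least two conditions contributes `RS_RHS * RA` to the
#' edge between each unordered pair of its (feature, level) conditions; the
#' raw connection of a node is the sum over its incident edges. Rules with a
#' single condition contribute isolated zero-weight nodes, dropped unless
#' `keep_isolated = TRUE`. Filter to one decision class with `class_filter`
#' to obtain per-class (or per-subgroup) networks.
#'
#' @param rules list of `rule` objects with statistics filled (FDR-filter
#'   upstream when mirroring the significant-rule networks).
#' @param class_filter optional decision class to restrict to.
#' @param keep_isolated keep zero-weight single-condition nodes.
#' @param label provenance label stored on the network.
#' @return object of class `copred_network` with data frames `nodes` (id,
#'   feature, level, raw, norm, is_hub, class) and `edges` (from, to, raw,
#'   norm).
#' @export
build_network <- function(rules, class_filter = NULL, keep_isolated = FALSE,
                          label = class_filter %||% "all") {
  if (!is.null(class_filter))
    rules <- Filter(function(r) r$decision == class_filter, rules)
  efrom <- character(0); eto <- character(0); ew <- numeric(0)
  iso <- character(0); iso_class <- character(0)
  node_class <- list()
  for (r in rules) {
    keys <- sort(node_key(names(r$conditions), r$conditions))
    w <- r$rs_rhs * r$ra
    for (k in keys)
      node_class[[k]] <- c(node_class[[k]] %||% numeric(0),
                           setNames(w, r$decision))
    if (length(keys) < 2) {
      iso <- c(iso, keys)
      iso_class <- c(iso_class, r$decision)
      next
    }
    pr <- utils::combn(keys, 2)
    efrom <- c(efrom, pr[1, ]); eto <- c(eto, pr[2, ])
    ew <- c(ew, rep(w, ncol(pr)))
  }
  if (length(ew)) {
    pair <- paste(efrom, eto, sep = "\r")
    agg <- rowsum(ew, pair)
    keys <- strsplit(rownames(agg), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(keys, `[`, "", 1),
                        to = vapply(keys, `[`, "", 2),
                        raw = as.numeric(agg), norm = NA_real_,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        raw = numeric(0), norm = numeric(0))
  }
  ids <- sort(unique(c(edges$from, edges$to)))
  if (keep_isolated) ids <- sort(unique(c(ids, iso)))
  raw <- setNames(numeric(length(ids)), ids)
  for (i in seq_len(nrow(edges))) {
    raw[edges$from[i]] <- raw[edges$from[i]] + edges$raw[i]
    raw[edges$to[i]] <- raw[edges$to[i]] + edges$raw[i]
  }
  cls <- vapply(ids, function(k) {
    contrib <- node_class[[k]]
    if (is.null(contrib)) return(NA_character_)
    tot <- tapply(contrib, names(contrib), sum)
    names(tot)[which.max(tot)]
  }, character(1))
  parts <- strsplit(ids, "=", fixed = TRUE)
  nodes <- data.frame(
    id = ids,
    feature = vapply(parts, `[`, "", 1),
    level = as.integer(vapply(parts, function(p) p[length(p)], "")),
    raw = as.numeric(raw), norm = rep(NA_real_, length(ids)),
    is_hub = logical(length(ids)),
    class = unname(cls), stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, label = label),
            class = "copred_network")
}

#' @export
print.copred_network <- function(x, ...) {
  cat("copred_network [", x$label, "]: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Unity-based (min-max) normalization of connection values
#'
#' Edge norms are `(raw - min)/(max - min)` over the network's edges, node
#' norms likewise over nodes; when all values coincide every norm is 1.
#'
#' @param net a `copred_network`.
#' @return the network with `norm` columns filled.
#' @export
normalize_connections <- function(net) {
  stopifnot(inherits(net, "copred_network"))
  mm <- function(x) {
    if (!length(x)) return(numeric(0))
    if (max(x) == min(x)) return(rep(1, length(x)))
    (x - min(x)) / (max(x) - min(x))
  }
  net$edges$norm <- mm(net$edges$raw)
  net$nodes$norm <- mm(net$nodes$raw)
  net
}

#' Keep the most strongly connected nodes
#'
#' Retains the `n` nodes of highest raw connection (ties to the
#' lexicographically smallest id) and the induced edges; optionally keeps
#' only the top `fraction` of those edges by raw connection.
#'
#' @param net a `copred_network`.
#' @param n number of nodes to keep.
#' @param fraction optional fraction (0, 1] of induced edges to keep.
#' @return the filtered `copred_network`.
#' @export
top_nodes <- function(net, n, fraction = NULL) {
  stopifnot(inherits(net, "copred_network"), n >= 1)
  if (n >= nrow(net$nodes)) {
    if (n > nrow(net$nodes)) warning("`n` exceeds node count: whole network")
    n <- nrow(net$nodes)
  }
  ord <- order(-net$nodes$raw, net$nodes$id)
  keep <- net$nodes$id[ord[seq_len(n)]]
  nodes <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
  edges <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ,
                     drop = FALSE]
  if (!is.null(fraction) && nrow(edges)) {
    ne <- max(1L, ceiling(fraction * nrow(edges)))
    eord <- order(-edges$raw, edges$from, edges$to)
    edges <- edges[sort(eord[seq_len(ne)]), , drop = FALSE]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, label = net$label),
            class = "copred_network")
}

node_degrees <- function(net) {
  deg <- setNames(integer(nrow(net$nodes)), net$nodes$id)
  tab <- table(c(net$edges$from, net$edges$to))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Flag hub nodes
#'
#' A hub connects to many other nodes: `is_hub` is set for nodes whose
#' degree is positive and at least the `degree_quantile` quantile
#' (median-unbiased, interpolating) of the network's degree distribution,
#' so ties at the threshold are included.
#'
#' @param net a non-empty `copred_network`.
#' @param degree_quantile quantile defining the hub threshold (default 0.9).
#' @return the network with `is_hub` filled.
#' @export
detect_hubs <- function(net, degree_quantile = 0.9) {
  stopifnot(inherits(net, "copred_network"), nrow(net$nodes) > 0)
  deg <- node_degrees(net)
  thr <- quantile(deg, degree_quantile, type = 8, names = FALSE)
  net$nodes$is_hub <- deg >= thr & deg > 0
  net
}

#' Top co-predictors by exact one-dimensional 2-means
#'
#' Splits node connection values into two clusters at the exact optimum of
#' the within-cluster sum of squares (full sweep over all split points of
#' the sorted values) and returns the features of the higher-mean cluster,
#' discretization levels collapsed.
#'
#' @param node_connections named numeric vector (names are node ids of the
#'   form `feature=level`, or bare feature ids).
#' @return character vector of feature ids in the top cluster.
#' @export
kmeans_top_copredictors <- function(node_connections) {
  stopifnot(length(node_connections) >= 2, !is.null(names(node_connections)))
  v <- sort(node_connections)
  n <- length(v)
  if (max(v) == min(v)) stop("all connection values identical: no threshold separable")
  ss <- vapply(seq_len(n - 1L), function(s) {
    lo <- v[seq_len(s)]; hi <- v[(s + 1L):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  s <- which.min(ss)
  top_ids <- names(v)[(s + 1L):n]
  unique(vapply(strsplit(top_ids, "=", fixed = TRUE), `[`, "", 1))
}

#' Fraction of a gene set annotated to a functional term
#'
#' @param gene_set non-empty character vector (e.g. top co-predictors).
#' @param term_genes character vector of the term's member genes.
#' @return `|gene_set intersect term_genes| / |gene_set|`.
#' @export
term_fraction <- function(gene_set, term_genes) {
  gene_set <- unique(gene_set)
  if (!length(gene_set)) stop("`gene_set` must be non-empty")
  length(intersect(gene_set, term_genes)) / length(gene_set)
}

#' Convert a co-predictive network to an igraph graph
#' @param net a `copred_network`.
#' @return an undirected `igraph` graph with node and edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "copred_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a network as GraphML and as a flat edge-list TSV
#' @param net a `copred_network`.
#' @param prefix output path prefix (writes `<prefix>.graphml` and
#'   `<prefix>_edges.tsv`).
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "copred_network"))
  g <- as_igraph(net)
  graphml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  edges <- paste0(prefix, "_edges.tsv")
  write.table(net$edges, edges, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml, edges))
}
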
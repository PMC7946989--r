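# Subgroup dissimilarity: rules are mapped to clinical subgroups through
# their support sets, subgroup subnetworks are compared by the Euclidean
# distance between betweenness-centrality vectors on the union node set,
# and significance comes from a balanced permutation null.

#' Assign rules to clinical subgroups via support sets
#'
#' A rule belongs to subgroup g iff its support set contains at least one
#' sample of subtype g (control rules land in the control subgroup since
#' control samples carry the control subtype); a rule may belong to several
#' subgroups. Samples with missing subtype are excluded with a warning.
#'
#' @param model a `rule_model` with support sets populated on the merged
#'   cohort.
#' @param sample_meta data frame with `sample_id` and `subtype` columns.
#' @param subtype_column metadata column to group by (default `"subtype"`;
#'   any categorical column such as `sex` works).
#' @return named list: subgroup label -> list of `rule`s.
#' @export
assign_rules_to_subgroups <- function(model, sample_meta,
                                      subtype_column = "subtype") {
  stopifnot(inherits(model, "rule_model"))
  sub <- setNames(as.character(sample_meta[[subtype_column]]),
                  sample_meta$sample_id)
  if (anyNA(sub)) {
    warning(sum(is.na(sub)), " samples with missing subtype excluded")
    sub <- sub[!is.na(sub)]
  }
  out <- list()
  for (r in model$rules) {
    groups <- unique(sub[intersect(r$support_set, names(sub))])
    for (g in groups) out[[g]] <- c(out[[g]], list(r))
  }
  out[order(names(out))]
}

#' Per-subtype support distribution of a rule
#'
#' For each subtype, 100 times the number of supporting samples of that
#' subtype divided by the subtype's total size in the cohort; subtypes with
#' zero cohort members are excluded.
#'
#' @param rule a `rule` with its support set populated.
#' @param sample_meta data frame with `sample_id` and `subtype`.
#' @return named numeric vector of percentages.
#' @export
subtype_support_distribution <- function(rule, sample_meta) {
  stopifnot(inherits(rule, "rule"))
  totals <- table(sample_meta$subtype)
  totals <- totals[totals > 0]
  supp <- sample_meta$subtype[sample_meta$sample_id %in% rule$support_set]
  vapply(names(totals), function(st)
    100 * sum(supp == st) / as.numeric(totals[[st]]), numeric(1))
}

# ---- fast topology helpers -------------------------------------------------
# The permutation null rebuilds thousands of subnetworks; only the
# unweighted topology matters for betweenness, so rules are pre-expanded to
# their condition-pair edges once and unioned per resample.

rule_pairs <- function(rules) {
  lapply(rules, function(r) {
    if (length(r$conditions) < 2) return(NULL)
    keys <- sort(node_key(names(r$conditions), r$conditions))
    t(utils::combn(keys, 2))
  })
}

betw_from_pairs <- function(pair_list) {
  edges <- do.call(rbind, pair_list)
  if (is.null(edges) || !nrow(edges)) return(numeric(0))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  setNames(as.numeric(b), igraph::V(g)$name)
}

dist_betw_vectors <- function(bA, bB) {
  nodes <- union(names(bA), names(bB))
  a <- setNames(numeric(length(nodes)), nodes)
  b <- a
  a[names(bA)] <- bA
  b[names(bB)] <- bB
  sqrt(sum((a - b)^2))
}

#' Betweenness-centrality distance between two networks
#'
#' Node betweenness (shortest-path pair counting, unnormalized) is computed
#' on the unweighted undirected topology of each network; vectors are
#' aligned on the union node set with absent nodes at 0 and compared by the
#' Euclidean norm.
#'
#' @param netA,netB `copred_network` objects (node sets may differ).
#' @return non-negative distance (0 with a warning when both are empty).
#' @export
betweenness_distance <- function(netA, netB) {
  stopifnot(inherits(netA, "copred_network"), inherits(netB, "copred_network"))
  if (!nrow(netA$nodes) && !nrow(netB$nodes)) {
    warning("both networks empty: distance 0")
    return(0)
  }
  bv <- function(net) {
    if (!nrow(net$edges))
      return(setNames(numeric(nrow(net$nodes)), net$nodes$id))
    g <- as_igraph(net)
    setNames(as.numeric(igraph::betweenness(g, directed = FALSE,
                                            normalized = FALSE)),
             igraph::V(g)$name)
  }
  dist_betw_vectors(bv(netA), bv(netB))
}

#' Balanced betweenness distance between two rule sets
#'
#' With m the smaller rule count, repeatedly samples m rules without
#' replacement from each side, builds the two subnetworks and computes the
#' betweenness distance; returns the mean over `n_balance` resamples. This
#' compensates for unequal numbers of rules per subgroup.
#'
#' @param rulesA,rulesB non-empty lists of `rule`s.
#' @param n_balance number of balanced resamples (default 20).
#' @param seed integer RNG seed.
#' @return mean distance over the resamples.
#' @export
balanced_distance <- function(rulesA, rulesB, n_balance = 20L, seed = 1L) {
  if (!length(rulesA) || !length(rulesB))
    stop("both rule lists must be non-empty")
  pA <- rule_pairs(rulesA)
  pB <- rule_pairs(rulesB)
  m <- min(length(rulesA), length(rulesB))
  with_seed(seed, {
    mean(vapply(seq_len(n_balance), function(i) {
      ia <- sample.int(length(pA), m)
      ib <- sample.int(length(pB), m)
      dist_betw_vectors(betw_from_pairs(pA[ia]), betw_from_pairs(pB[ib]))
    }, numeric(1)))
  })
}

#' Permutation test of subgroup network dissimilarity
#'
#' For every pair of subgroups the observed statistic is the balanced
#' betweenness distance between their rule subnetworks. The null shuffles
#' subgroup labels across the pooled rule-to-subgroup assignments
#' (preserving per-subgroup rule counts), rebuilds subnetworks and
#' recomputes the balanced distance `n_perm` times. Random networks are
#' expected not to exceed the original distances, so significance sits in
#' the upper tail: `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param model a `rule_model` with support sets on the merged cohort.
#' @param sample_meta metadata with `sample_id` and the subgroup column.
#' @param subgroups subgroup labels to compare; default all with >= 2 rules.
#' @param n_perm permutations (default 500).
#' @param n_balance balanced resamples per distance (default 20).
#' @param seed integer RNG seed.
#' @param subtype_column metadata column defining subgroups.
#' @return a `distance_result` data frame: one row per pair with observed
#'   distance, raw permutation p (add-one estimator, never below
#'   `1/(n_perm+1)`), BH-adjusted p, and the resampling parameters.
#' @export
permutation_test <- function(model, sample_meta, subgroups = NULL,
                             n_perm = 500L, n_balance = 20L, seed = 1L,
                             subtype_column = "subtype") {
  assign <- assign_rules_to_subgroups(model, sample_meta, subtype_column)
  sizes <- lengths(assign)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("subgroups with < 2 rules excluded: ",
            paste(small, collapse = ", "))
    assign <- assign[sizes >= 2]
  }
  subgroups <- subgroups %||% names(assign)
  subgroups <- intersect(subgroups, names(assign))
  if (length(subgroups) < 2) stop("need >= 2 subgroups with >= 2 rules")
  assign <- assign[subgroups]
  # pooled (rule, subgroup) assignment list used by the subgroup-shuffle null
  pool_rules <- unlist(assign, recursive = FALSE)
  pool_labels <- rep(names(assign), lengths(assign))
  pool_pairs <- rule_pairs(pool_rules)
  pairs <- utils::combn(subgroups, 2)
  res <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    observed = NA_real_, p_value = NA_real_,
                    p_adjusted = NA_real_, n_permutations = n_perm,
                    n_balance_resamples = n_balance, seed = seed,
                    stringsAsFactors = FALSE)
  bal_from_pool <- function(idxA, idxB, bseed) {
    m <- min(length(idxA), length(idxB))
    with_seed(bseed, {
      mean(vapply(seq_len(n_balance), function(i) {
        ia <- idxA[sample.int(length(idxA), m)]
        ib <- idxB[sample.int(length(idxB), m)]
        dist_betw_vectors(betw_from_pairs(pool_pairs[ia]),
                          betw_from_pairs(pool_pairs[ib]))
      }, numeric(1)))
    })
  }
  for (k in seq_len(ncol(pairs))) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    obs <- bal_from_pool(which(pool_labels == ga), which(pool_labels == gb),
                         derive_seed(seed, paste0("obs_", ga, "_", gb)))
    null <- with_seed(derive_seed(seed, paste0("perm_", ga, "_", gb)), {
      vapply(seq_len(n_perm), function(p) {
        lab <- sample(pool_labels)
        bal_from_pool(which(lab == ga), which(lab == gb),
                      derive_seed(seed, paste0("bal", p, ga, gb)))
      }, numeric(1))
    })
    res$observed[k] <- obs
    res$p_value[k] <- (1 + sum(null >= obs)) / (1 + n_perm)
  }
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  class(res) <- c("distance_result", class(res))
  res
}

#' Kendall-correlation distance matrix between subgroup connection profiles
#'
#' Each subgroup's node-connection vector is min-max scaled to [0, 1]
#' (scaling is monotone, so the Kendall statistic is unchanged) and the
#' distance between two subgroups is `1 - tau_b` of their vectors. A
#' constant vector leaves tau undefined; its distances are set to 1 with a
#' warning.
#'
#' @param connection_table numeric matrix, subgroups x nodes (0 where a
#'   node is absent from a subgroup's network); see [connection_table()].
#' @return symmetric distance matrix with zero diagonal (range [0, 2]).
#' @export
kendall_distance_matrix <- function(connection_table) {
  stopifnot(is.matrix(connection_table), nrow(connection_table) >= 2)
  x <- t(apply(connection_table, 1, function(v) {
    if (max(v) == min(v)) v else (v - min(v)) / (max(v) - min(v))
  }))
  tau <- suppressWarnings(cor(t(x), method = "kendall"))
  if (anyNA(tau)) {
    warning("constant connection vector: tau undefined, distance set to 1")
    tau[is.na(tau)] <- 0
  }
  d <- 1 - tau
  diag(d) <- 0
  dimnames(d) <- list(rownames(connection_table), rownames(connection_table))
  d
}

#' Node-connection table across subgroup networks
#'
#' @param networks named list of `copred_network`s (one per subgroup).
#' @param value node column to tabulate (`"raw"` or `"norm"`).
#' @return numeric matrix, subgroups x union-of-nodes, 0 where absent.
#' @export
connection_table <- function(networks, value = "raw") {
  stopifnot(length(networks) >= 1, !is.null(names(networks)))
  nodes <- sort(unique(unlist(lapply(networks, function(n) n$nodes$id))))
  out <- matrix(0, length(networks), length(nodes),
                dimnames = list(names(networks), nodes))
  for (g in names(networks)) {
    nd <- networks[[g]]$nodes
    out[g, nd$id] <- nd[[value]]
  }
  out
}
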
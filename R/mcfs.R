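# Monte Carlo feature selection: relative importance aggregated over many
# small decision trees trained on random attribute subsets and random 2/3
# object splits, followed by critical-angle thresholding, model-quality
# adjustment of the cut-off, and cross-cohort ranking merging.

new_feature_ranking <- function(feature_id, ri, provenance = "unknown",
                                params = list()) {
  ord <- order(-ri, feature_id)
  structure(list(feature_id = feature_id[ord], ri = ri[ord],
                 provenance = provenance, params = params),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("feature_ranking (", x$provenance, "): ", length(x$feature_id),
      " features; top: ",
      paste(head(x$feature_id, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Entropy (base 2) of a label vector.
entropy <- function(y) {
  p <- tabulate(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Grow an information-gain binary decision tree on numeric columns.
# Returns a nested list of nodes; internal nodes carry the split attribute
# (column index into the full matrix), the information gain and the object
# count, which is all the RI formula needs.
grow_tree <- function(X, y, cols, depth = 0L, max_depth = 10L,
                      min_split = 2L) {
  n <- length(y)
  counts <- tabulate(y)
  if (n < min_split || depth >= max_depth || sum(counts > 0) < 2)
    return(list(leaf = TRUE, class = which.max(counts), n = n))
  h0 <- entropy(y)
  K <- length(counts)
  plogp <- function(M, tot) {
    P <- M / tot
    P[P <= 0] <- 1  # log term vanishes
    -rowSums(P * log2(P))
  }
  best <- NULL; best_gain <- 1e-12
  for (j in cols) {
    xv <- X[, j]
    ord <- order(xv, method = "radix")
    xs <- xv[ord]; ys <- y[ord]
    pos <- which(xs[-n] < xs[-1])  # legal split positions
    if (!length(pos)) next
    C <- vapply(seq_len(K), function(k) cumsum(ys == k), numeric(n))
    L <- C[pos, , drop = FALSE]
    R <- matrix(counts, length(pos), K, byrow = TRUE) - L
    nl <- pos; nr <- n - pos
    gain <- h0 - (nl * plogp(L, nl) + nr * plogp(R, nr)) / n
    b <- which.max(gain)
    if (gain[b] > best_gain + 1e-12) {
      best_gain <- gain[b]
      t <- (xs[pos[b]] + xs[pos[b] + 1]) / 2
      best <- list(j = j, t = t, l = xv <= t)
    }
  }
  if (is.null(best))
    return(list(leaf = TRUE, class = which.max(counts), n = n))
  list(leaf = FALSE, attr = best$j, thr = best$t, ig = best_gain, n = n,
       left = grow_tree(X[best$l, , drop = FALSE], y[best$l], cols,
                        depth + 1L, max_depth, min_split),
       right = grow_tree(X[!best$l, , drop = FALSE], y[!best$l], cols,
                         depth + 1L, max_depth, min_split))
}

predict_tree <- function(node, X) {
  out <- integer(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    l <- X[idx, node$attr] <= node$thr
    rec(node$left, idx[l]); rec(node$right, idx[!l])
  }
  rec(node, seq_len(nrow(X)))
  out
}

# Accumulate wAcc^u * IG * (n_node/n_root)^v over the internal nodes.
tree_ri <- function(node, wacc, u, v, n_root, acc) {
  if (node$leaf) return(acc)
  contrib <- (wacc^u) * node$ig * (node$n / n_root)^v
  acc[node$attr] <- acc[node$attr] + contrib
  acc <- tree_ri(node$left, wacc, u, v, n_root, acc)
  tree_ri(node$right, wacc, u, v, n_root, acc)
}

#' Monte Carlo feature ranking
#'
#' Draws `s` random attribute subsets of size `m`; on each, trains `t`
#' information-gain decision trees on random 2/3 object splits. The
#' relative importance of feature g sums, over every tree node where g
#' splits, `wAcc^u * IG * (n_node/n_tree)^v`, with `wAcc` the tree's
#' class-balanced accuracy on the held-out third. Features never selected
#' (or never useful as splits) score 0.
#'
#' @param x numeric matrix (samples x features) or a `decision_table`
#'   (levels are treated as ordered numeric values).
#' @param labels class labels (ignored when `x` is a `decision_table`).
#' @param s number of attribute subsets (default 100).
#' @param t trees per subset (default 5).
#' @param m attributes per subset; default `ceiling(sqrt(n_features))`.
#' @param u,v weighting exponents (default 1).
#' @param seed integer RNG seed.
#' @param provenance cohort id recorded on the ranking.
#' @return a `feature_ranking`: features sorted by decreasing RI.
#' @export
mcfs_rank <- function(x, labels = NULL, s = 100L, t = 5L, m = NULL,
                      u = 1, v = 1, seed = 1L, provenance = "unknown") {
  if (inherits(x, "decision_table")) {
    labels <- x$decision
    x <- x$values
    mode(x) <- "double"
  }
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (is.null(labels) || length(unique(labels)) < 2)
    stop("need labels with >= 2 classes")
  nf <- ncol(x)
  m <- m %||% ceiling(sqrt(nf))
  if (m > nf) stop("`m` exceeds the number of features")
  y <- as.integer(factor(labels))
  n <- nrow(x)
  ri <- setNames(numeric(nf), colnames(x))
  with_seed(seed, {
    for (si in seq_len(s)) {
      cols <- sort(sample.int(nf, m))
      for (ti in seq_len(t)) {
        tr <- sort(sample.int(n, floor(2 * n / 3)))
        te <- setdiff(seq_len(n), tr)
        tree <- grow_tree(x[tr, , drop = FALSE], y[tr], cols)
        pred <- predict_tree(tree, x[te, , drop = FALSE])
        recall <- vapply(unique(y[te]), function(cl)
          mean(pred[y[te] == cl] == cl), numeric(1))
        wacc <- mean(recall)
        ri <- tree_ri(tree, wacc, u, v, length(tr), ri)
      }
    }
  })
  new_feature_ranking(names(ri), unname(ri), provenance,
                      params = list(s = s, t = t, m = m, u = u, v = v,
                                    seed = seed))
}

#' Critical-angle (knee) threshold on an RI curve
#'
#' With ranks and RI both min-max scaled to the unit square, the exterior
#' (turning) angle of the RI curve is computed at every interior rank. The
#' knee is the vertex of the strongest downward (clockwise) bend — the last
#' point of the high-importance cluster before the curve falls away; when
#' the curve bends nowhere downward (a purely convex decay) the vertex with
#' the largest absolute turn is used instead. Ties break to the smallest
#' index; a flat curve keeps everything (with a warning).
#'
#' @param ranking a `feature_ranking` of length >= 3.
#' @return integer k: number of top features kept.
#' @export
critical_angle_threshold <- function(ranking) {
  stopifnot(inherits(ranking, "feature_ranking"))
  L <- length(ranking$ri)
  if (L < 3) stop("ranking must have >= 3 features")
  y <- ranking$ri
  if (max(y) == min(y)) {
    warning("flat RI curve: keeping all features")
    return(L)
  }
  xs <- (seq_len(L) - 1) / (L - 1)
  ys <- (y - min(y)) / (max(y) - min(y))
  turn <- vapply(2:(L - 1), function(i) {
    v1 <- c(xs[i] - xs[i - 1], ys[i] - ys[i - 1])
    v2 <- c(xs[i + 1] - xs[i], ys[i + 1] - ys[i])
    # signed turning angle; negative = clockwise (downward bend)
    atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2))
  }, numeric(1))
  turn[abs(turn) < 1e-9] <- 0  # numerically straight
  idx <- if (any(turn < 0)) which.min(turn) else which.max(abs(turn))
  as.integer(1 + idx)
}

#' Adjust the feature cut-off by model quality
#'
#' Starting from the critical-angle threshold `k0`, fits a cross-validated
#' rule model on the top-k features for every k up to `k_max` and returns
#' the k of the local maximum of quality nearest to `k0` scanning upward.
#' Quality is `(accuracy/100 + AUC)/2`; a plateau counts as a maximum at
#' its smallest k, and a monotonically rising curve yields `k_max`.
#'
#' @param ranking a `feature_ranking`.
#' @param em the `expression_matrix` to learn on (ignored when
#'   `learner_config$quality_fn` is supplied).
#' @param k0 starting number of features (e.g. from
#'   [critical_angle_threshold()]).
#' @param k_max largest number of features scanned (default 50).
#' @param learner_config list: `quality_fn(k)` to override the learner, or
#'   `folds`, `seed`, `n_bins` forwarded to [crossvalidate()].
#' @return integer `k_adj`, with the quality sequence attached as attribute
#'   `"quality"`.
#' @export
adjust_fr <- function(ranking, em = NULL, k0, k_max = 50L,
                      learner_config = list()) {
  stopifnot(inherits(ranking, "feature_ranking"))
  L <- length(ranking$feature_id)
  if (k0 > L) stop("`k0` exceeds the ranking length")
  k_max <- min(k_max, L)
  if (k0 > k_max) stop("`k0` must be <= `k_max`")
  quality_fn <- learner_config$quality_fn %||% function(k) {
    mdl <- crossvalidate(em, features = ranking$feature_id[seq_len(k)],
                         folds = learner_config$folds %||% 10L,
                         seed = learner_config$seed %||% 1L,
                         n_bins = learner_config$n_bins %||% 3L)
    (mdl$quality$accuracy / 100 + mdl$quality$auc) / 2
  }
  ks <- k0:k_max
  q <- vapply(ks, quality_fn, numeric(1))
  # run-length compression; first run that beats its successor (>) and is
  # not below its predecessor (>=) is the nearest local maximum
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pick <- length(r$values)
  for (i in seq_along(r$values)) {
    up_ok <- i == 1 || r$values[i] >= r$values[i - 1]
    down_ok <- i == length(r$values) || r$values[i] > r$values[i + 1]
    if (up_ok && down_ok) { pick <- i; break }
  }
  k_adj <- ks[starts[pick]]
  attr(k_adj, "quality") <- setNames(q, ks)
  k_adj
}

#' Truncate a ranking to its top k features
#' @param ranking a `feature_ranking`.
#' @param k number of features kept.
#' @return the truncated `feature_ranking`.
#' @export
truncate_ranking <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"), k >= 1,
            k <= length(ranking$feature_id))
  new_feature_ranking(ranking$feature_id[seq_len(k)], ranking$ri[seq_len(k)],
                      ranking$provenance, ranking$params)
}

#' Merge per-cohort feature rankings
#'
#' Each ranking's RI is rescaled so its maximum equals 1 (cross-cohort
#' comparability), ids are translated through `id_map` when given, features
#' appearing in several rankings keep their maximum rescaled RI, and the
#' union is sorted by decreasing RI.
#'
#' @param rankings list of (already truncated) `feature_ranking`s.
#' @param id_map optional data frame with columns `source`, `target`
#'   remapping feature ids across platforms; a source id mapped to more
#'   than one target is an error.
#' @return a merged `feature_ranking` with provenance `"merged"`.
#' @export
merge_rankings <- function(rankings, id_map = NULL) {
  stopifnot(length(rankings) >= 1)
  if (!is.null(id_map)) {
    id_map <- as.data.frame(id_map)
    stopifnot(all(c("source", "target") %in% names(id_map)))
    conf <- tapply(id_map$target, id_map$source,
                   function(t) length(unique(t)))
    if (any(conf > 1))
      stop("id_map collision: a source id maps to conflicting targets")
  }
  ids <- character(0); ri <- numeric(0)
  for (r in rankings) {
    stopifnot(inherits(r, "feature_ranking"))
    sc <- if (max(r$ri) > 0) r$ri / max(r$ri) else r$ri
    f <- r$feature_id
    if (!is.null(id_map)) {
      hit <- match(f, id_map$source)
      f[!is.na(hit)] <- id_map$target[hit[!is.na(hit)]]
    }
    ids <- c(ids, f); ri <- c(ri, sc)
  }
  agg <- tapply(ri, ids, max)
  new_feature_ranking(names(agg), as.numeric(agg), "merged",
                      params = list(n_inputs = length(rankings)))
}

#' Write a feature ranking as a two-column TSV (feature_id, RI)
#' @param ranking a `feature_ranking`.
#' @param path output file.
#' @export
write_ranking <- function(ranking, path) {
  write.table(data.frame(feature_id = ranking$feature_id, RI = ranking$ri),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature ranking TSV
#' @param path file written by [write_ranking()].
#' @param provenance provenance label.
#' @return a `feature_ranking`.
#' @export
read_ranking <- function(path, provenance = "file") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  new_feature_ranking(df$feature_id, df$RI, provenance)
}
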
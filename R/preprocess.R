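# Discretization of continuous expression into decision tables, and class
# balancing by undersampling. Cuts are always learned on training data and
# applied unchanged to test data so no information leaks across CV folds.

#' Equal-frequency cut points
#'
#' Places `n_bins - 1` cuts at midpoints between consecutive sorted values so
#' bin occupancies differ by at most one when all values are distinct. A
#' nominal boundary falling inside a run of tied values is shifted to the
#' nearest midpoint between distinct values (a cut never splits equal
#' values), so ties can reduce the effective number of bins.
#'
#' @param values numeric vector (non-empty).
#' @param n_bins target number of bins (>= 2).
#' @return strictly increasing numeric vector of cuts (possibly empty for a
#'   constant vector, with a warning).
#' @export
equal_frequency_cuts <- function(values, n_bins = 3L) {
  if (!length(values)) stop("`values` must be non-empty")
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  v <- sort(values)
  n <- length(v)
  jumps <- which(v[-n] < v[-1])  # positions k where a cut v[k]|v[k+1] is legal
  if (!length(jumps)) {
    warning("constant vector: no cuts, single level")
    return(numeric(0))
  }
  cuts <- vapply(seq_len(n_bins - 1L), function(b) {
    k <- floor(b * n / n_bins)
    k <- max(1L, min(n - 1L, k))
    j <- jumps[which.min(abs(jumps - k))]  # nearest legal boundary
    (v[j] + v[j + 1L]) / 2
  }, numeric(1))
  sort(unique(cuts))
}

#' Apply cuts to a numeric vector
#'
#' Level of a value = 1 + number of cuts strictly below it; values outside
#' the training range clamp to the extreme levels. With the default
#' three-level scheme the levels read 1 = low, 2 = medium, 3 = high.
#'
#' @param values numeric vector.
#' @param cuts strictly increasing cut points (possibly empty).
#' @return integer vector of levels in `1..(length(cuts) + 1)`.
#' @export
apply_cuts <- function(values, cuts) {
  if (length(cuts) > 1 && any(diff(cuts) <= 0))
    stop("`cuts` must be strictly increasing")
  if (!length(cuts)) return(rep(1L, length(values)))
  findInterval(values, cuts, left.open = TRUE) + 1L
}

#' Fit a per-attribute equal-frequency discretization scheme
#'
#' @param values numeric matrix, samples x attributes (column names required).
#' @param n_bins bins per attribute (default 3).
#' @return object of class `discretization_scheme`: named list of cut
#'   vectors plus the level count.
#' @export
fit_discretization <- function(values, n_bins = 3L) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  cuts <- lapply(seq_len(ncol(values)), function(j)
    suppressWarnings(equal_frequency_cuts(values[, j], n_bins)))
  names(cuts) <- colnames(values)
  structure(list(cuts = cuts, n_levels = as.integer(n_bins)),
            class = "discretization_scheme")
}

#' Discretize a matrix under a fitted scheme
#' @param values numeric matrix, samples x attributes.
#' @param scheme a [fit_discretization()] scheme; attributes absent from the
#'   scheme are dropped.
#' @return integer matrix of levels with the same row names.
#' @export
apply_discretization <- function(values, scheme) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  keep <- intersect(colnames(values), names(scheme$cuts))
  out <- vapply(keep, function(a) apply_cuts(values[, a], scheme$cuts[[a]]),
                integer(nrow(values)))
  out <- matrix(out, nrow = nrow(values),
                dimnames = list(rownames(values), keep))
  out
}

#' Construct a decision table
#'
#' The universe of rough-set learning: objects (samples) x discrete-valued
#' attributes with a decision (class) column. `values` may contain `NA` for
#' attributes a cohort does not measure; rules conditioning on them can
#' never fire for those objects.
#'
#' @param values integer matrix (objects x attributes) with dimnames.
#' @param decision character vector of class labels, one per object.
#' @return object of class `decision_table` with fields `objects`,
#'   `attributes`, `values`, `decision`.
#' @export
decision_table <- function(values, decision) {
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            length(decision) == nrow(values))
  if (is.null(rownames(values))) {
    if (nrow(values) > 0) stop("`values` must have row names (object ids)")
    rownames(values) <- character(0)
  }
  structure(list(objects = rownames(values), attributes = colnames(values),
                 values = values, decision = as.character(decision)),
            class = "decision_table")
}

#' @export
print.decision_table <- function(x, ...) {
  cat("decision_table:", length(x$objects), "objects x",
      length(x$attributes), "attributes; classes:",
      paste(sprintf("%s=%d", names(table(x$decision)), table(x$decision)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Discretize an expression matrix into a decision table
#'
#' @param em an `expression_matrix`.
#' @param features attribute (gene) subset; default all genes.
#' @param scheme optional pre-fitted scheme; fitted on `em` when `NULL`.
#' @param n_bins bins when fitting.
#' @param decision metadata column used as the decision (default `"class"`).
#' @return a `decision_table`; the scheme used is attached as attribute
#'   `"scheme"`.
#' @export
as_decision_table <- function(em, features = NULL, scheme = NULL,
                              n_bins = 3L, decision = "class") {
  stopifnot(inherits(em, "expression_matrix"))
  features <- features %||% em$gene_ids
  missing_f <- setdiff(features, colnames(em$values))
  present <- intersect(features, colnames(em$values))
  vals <- em$values[, present, drop = FALSE]
  if (is.null(scheme)) scheme <- fit_discretization(vals, n_bins)
  disc <- apply_discretization(vals, scheme)
  if (length(missing_f)) {
    na_block <- matrix(NA_integer_, nrow(disc), length(missing_f),
                       dimnames = list(rownames(disc), missing_f))
    disc <- cbind(disc, na_block)[, features, drop = FALSE]
  }
  tab <- decision_table(disc, em$sample_meta[[decision]])
  attr(tab, "scheme") <- scheme
  tab
}

#' Undersample a decision table to the minority-class size
#'
#' Every class is downsampled without replacement to the size of the
#' smallest class. The sampled-out objects are retained on the result as
#' attribute `"unsampled"` so rule statistics can later be recalculated on
#' the full object set.
#'
#' @param table a `decision_table` with >= 2 classes.
#' @param seed integer RNG seed.
#' @return balanced `decision_table` (attribute `"unsampled"` holds the
#'   left-out `decision_table`, possibly with 0 objects).
#' @export
undersample <- function(table, seed = 1L) {
  stopifnot(inherits(table, "decision_table"))
  sizes <- table(table$decision)
  if (length(sizes) < 2) stop("undersampling needs >= 2 classes")
  m <- min(sizes)
  keep <- with_seed(seed, {
    unlist(lapply(names(sizes), function(cl) {
      idx <- which(table$decision == cl)
      if (length(idx) == m) idx else sort(sample(idx, m))
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  out <- decision_table(table$values[keep, , drop = FALSE],
                        table$decision[keep])
  left <- setdiff(seq_along(table$objects), keep)
  attr(out, "unsampled") <- decision_table(
    table$values[left, , drop = FALSE], table$decision[left])
  attr(out, "scheme") <- attr(table, "scheme")
  out
}

#' Write a decision table as CSV (object id, attributes, decision last)
#' @param table a `decision_table`.
#' @param path output file.
#' @export
write_decision_table <- function(table, path) {
  df <- data.frame(object_id = table$objects, table$values,
                   decision = table$decision, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a decision table written by [write_decision_table()]
#' @param path CSV file.
#' @return a `decision_table`.
#' @export
read_decision_table <- function(path) {
  df <- read.delim(path, sep = ",", check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), c("object_id", "decision")),
                       drop = FALSE])
  mode(vals) <- "integer"
  rownames(vals) <- df$object_id
  decision_table(vals, df$decision)
}
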
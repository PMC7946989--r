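# Cross-cohort integration: stack per-cohort discretized tables (each
# cohort keeps its own equal-frequency cuts, so levels are rank-comparable
# rather than comparable in absolute expression) and aggregate rule models
# with statistics renormalized to the merged cohort.

#' Combine cohorts into one stacked decision table
#'
#' Each cohort is discretized with its own equal-frequency cuts (or a
#' supplied per-cohort scheme) and the resulting tables are stacked over the
#' union of features. Features a cohort does not measure are `NA` for its
#' objects, so rules conditioning on them can never fire there.
#'
#' @param matrices list of `expression_matrix` objects with globally unique
#'   sample ids.
#' @param features feature union to keep; default: union of all cohorts'
#'   genes.
#' @param schemes optional list of `discretization_scheme`s, one per cohort;
#'   fitted per cohort when `NULL`.
#' @param n_bins discretization levels when fitting.
#' @param decision metadata column used as the decision.
#' @return a `decision_table` over all samples; per-cohort schemes are
#'   attached as attribute `"schemes"`, the stacked metadata as
#'   `"sample_meta"`.
#' @export
combine_tables <- function(matrices, features = NULL, schemes = NULL,
                           n_bins = 3L, decision = "class") {
  stopifnot(length(matrices) >= 1)
  features <- features %||%
    Reduce(union, lapply(matrices, function(m) m$gene_ids))
  tabs <- lapply(seq_along(matrices), function(i)
    as_decision_table(matrices[[i]], features,
                      scheme = if (is.null(schemes)) NULL else schemes[[i]],
                      n_bins = n_bins, decision = decision))
  ids <- unlist(lapply(tabs, `[[`, "objects"))
  if (anyDuplicated(ids))
    stop("sample ids must be globally unique across cohorts")
  vals <- do.call(rbind, lapply(tabs, `[[`, "values"))
  out <- decision_table(vals, unlist(lapply(tabs, `[[`, "decision")))
  attr(out, "schemes") <- lapply(tabs, attr, "scheme")
  attr(out, "sample_meta") <- do.call(
    rbind, lapply(matrices, `[[`, "sample_meta"))
  out
}

#' Merge rule models across cohorts
#'
#' Rules identical in both conditions and decision are unified: their RS
#' counts are summed and support sets unioned (disjoint because sample ids
#' are cohort-namespaced). With `recalculate = TRUE` (default) RA, RC_RHS
#' and p-values are then recomputed against the merged cohort's class
#' totals by [rule_stats()] on `merged_table`; rules unique to one model
#' are retained and recalculated the same way.
#'
#' @param models list of `rule_model`s sharing a feature-ID space.
#' @param merged_table combined `decision_table` from [combine_tables()];
#'   required when `recalculate = TRUE`.
#' @param recalculate recompute statistics on the merged cohort.
#' @return a `rule_model` over the merged cohort (CV quality is not defined
#'   for a merged model and is `NA`).
#' @export
merge_models <- function(models, merged_table = NULL, recalculate = TRUE) {
  stopifnot(length(models) >= 1)
  if (recalculate && is.null(merged_table))
    stop("`merged_table` is required to recalculate merged statistics")
  pool <- new.env(parent = emptyenv())
  order_keys <- character(0)
  for (m in models) {
    for (r in m$rules) {
      key <- rule_key(r$conditions, r$decision)
      if (is.null(pool[[key]])) {
        pool[[key]] <- r
        order_keys <- c(order_keys, key)
      } else {
        agg <- pool[[key]]
        dup <- intersect(agg$support_set, r$support_set)
        if (length(dup))
          stop("support sets overlap across models; sample ids must be namespaced")
        agg$rs_lhs <- agg$rs_lhs + r$rs_lhs
        agg$rs_rhs <- agg$rs_rhs + r$rs_rhs
        agg$support_set <- c(agg$support_set, r$support_set)
        agg$provenance <- union(agg$provenance, r$provenance)
        pool[[key]] <- agg
      }
    }
  }
  rules <- lapply(order_keys, function(k) pool[[k]])
  if (recalculate) {
    totals <- table(merged_table$decision)
    rules <- lapply(rules, function(r) {
      prov <- r$provenance
      r2 <- rule_stats(r, merged_table, class_totals = totals)
      if (!is.null(r2)) r2$provenance <- prov
      r2
    })
    rules <- rules[!vapply(rules, is.null, logical(1))]
    class_totals <- totals
  } else {
    class_totals <- Reduce(`+`, lapply(models, `[[`, "class_totals"))
  }
  structure(list(
    rules = rules,
    class_totals = class_totals,
    quality = list(accuracy = NA_real_, auc = NA_real_),
    provenance = Reduce(union, lapply(models, `[[`, "provenance")),
    scheme = NULL,
    table = merged_table,
    cv = NULL), class = "rule_model")
}
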
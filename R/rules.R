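# Rough-set rule induction: object-related Johnson reducts, IF-THEN rules
# with support/accuracy/coverage statistics, standard-voting classification
# under stratified 10-fold CV, and Benjamini-Hochberg rule filtering.

rule_key <- function(conditions, decision) {
  paste0(paste(sort(paste0(names(conditions), "=", conditions)),
               collapse = "&"), "=>", decision)
}

#' Construct a rule
#'
#' An IF-THEN formula: IF every (attribute, level) condition holds THEN
#' predict `decision`. Statistics are filled by [rule_stats()].
#'
#' @param conditions named integer vector: attribute -> discrete level.
#' @param decision predicted class label.
#' @return object of class `rule`.
#' @export
new_rule <- function(conditions, decision) {
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)))
  structure(list(conditions = conditions, decision = decision,
                 rs_lhs = NA_integer_, rs_rhs = NA_integer_,
                 ra = NA_real_, rc_rhs = NA_real_, p_value = NA_real_,
                 support_set = character(0), provenance = character(0)),
            class = "rule")
}

#' @export
print.rule <- function(x, ...) {
  cat(sprintf("IF %s THEN %s  (RS_LHS=%s RS_RHS=%s RA=%.3g RC=%.3g p=%.3g)\n",
              paste(paste0(names(x$conditions), "=", x$conditions),
                    collapse = " AND "),
              x$decision, x$rs_lhs, x$rs_rhs, x$ra, x$rc_rhs, x$p_value))
  invisible(x)
}

#' Object-related Johnson reducts
#'
#' For every object, the discernibility function modulo decision (one clause
#' per object of a different class, listing the attributes on which the two
#' objects differ) is covered greedily: repeatedly pick the attribute
#' occurring in the most uncovered clauses, ties broken to the
#' lexicographically smallest attribute id, then pruning attributes whose
#' removal leaves every clause covered (a reduct is irredundant by
#' definition). `NA` values never discern.
#' Objects indiscernible from an object of another class produce an empty
#' clause and are flagged inconsistent (the remaining clauses are still
#' covered).
#'
#' @param table a `decision_table` (normally with >= 2 classes; a
#'   single-class table yields empty reducts).
#' @return list per object: `attributes` (the reduct, possibly empty) and
#'   `inconsistent` flag.
#' @export
johnson_reducts <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  V <- table$values
  n <- nrow(V)
  attrs <- colnames(V)
  ord <- order(attrs)  # lexicographic tie-break order
  lapply(seq_len(n), function(i) {
    others <- which(table$decision != table$decision[i])
    D <- V[others, , drop = FALSE] !=
      matrix(V[i, ], length(others), ncol(V), byrow = TRUE)
    D[is.na(D)] <- FALSE
    inconsistent <- any(rowSums(D) == 0)
    D <- D[rowSums(D) > 0, , drop = FALSE]
    D <- unique(D)
    chosen <- character(0)
    DD <- D
    while (nrow(DD) > 0) {
      counts <- colSums(DD)[ord]
      best <- names(counts)[which.max(counts)]  # first max in lexicographic order
      chosen <- c(chosen, best)
      DD <- DD[!DD[, best], , drop = FALSE]
    }
    # a reduct must be irredundant: drop attributes (latest picks first)
    # whose removal still leaves every clause covered
    for (a in rev(chosen)) {
      rest <- setdiff(chosen, a)
      if (length(rest) && all(rowSums(D[, rest, drop = FALSE]) > 0))
        chosen <- rest
    }
    list(attributes = sort(chosen), inconsistent = inconsistent)
  })
}

#' Induce rules from per-object reducts
#'
#' Each object and its reduct yield a rule whose conditions are the object's
#' values on the reduct attributes and whose decision is the object's class;
#' duplicates are collapsed and statistics computed on the table via
#' [rule_stats()].
#'
#' @param table a `decision_table`.
#' @param reducts output of [johnson_reducts()] for the same table.
#' @param stats_table table on which to count the rule statistics; defaults
#'   to `table` (pass the full pre-undersampling table to recalculate).
#' @return list of `rule` objects.
#' @export
induce_rules <- function(table, reducts = johnson_reducts(table),
                         stats_table = table) {
  stopifnot(length(reducts) == length(table$objects))
  seen <- new.env(parent = emptyenv())
  rules <- list()
  for (i in seq_along(reducts)) {
    red <- reducts[[i]]$attributes
    if (!length(red)) {
      # nothing to discern (single-class table, or an object indiscernible
      # from every other-class object): fall back to the object's full
      # non-NA description so the object still yields a rule
      red <- table$attributes[!is.na(table$values[i, ])]
      if (!length(red)) next
    }
    cond <- table$values[i, red]
    names(cond) <- red
    if (anyNA(cond)) next
    key <- rule_key(cond, table$decision[i])
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    rules[[length(rules) + 1L]] <- new_rule(cond, table$decision[i])
  }
  totals <- table(stats_table$decision)
  out <- lapply(rules, rule_stats, table = stats_table, class_totals = totals)
  out[!vapply(out, is.null, logical(1))]
}

#' Fill a rule's support, accuracy, coverage and p-value on a table
#'
#' `RS_LHS` counts objects matching all conditions; `RS_RHS` those also of
#' the rule's class; `RA = RS_RHS / RS_LHS`; `RC_RHS = RS_RHS / n_d` with
#' `n_d` the class total. The p-value is the hypergeometric upper tail
#' `P(X >= RS_RHS)` drawing `RS_LHS` objects from `N` with `n_d` successes.
#'
#' @param rule a `rule`.
#' @param table the `decision_table` to count on.
#' @param class_totals optional named class totals (`n_d`); defaults to the
#'   table's own class counts.
#' @return the rule with statistics filled, or `NULL` (with a warning) when
#'   no object matches the conditions.
#' @export
rule_stats <- function(rule, table, class_totals = NULL) {
  stopifnot(inherits(rule, "rule"), inherits(table, "decision_table"))
  if (is.null(class_totals)) class_totals <- table(table$decision)
  m <- matches_conditions(rule$conditions, table$values)
  rs_lhs <- sum(m)
  if (rs_lhs == 0) {
    warning("rule matches no object; discarded")
    return(NULL)
  }
  hit <- m & table$decision == rule$decision
  rs_rhs <- sum(hit)
  n_d <- as.integer(class_totals[[rule$decision]])
  N <- sum(class_totals)
  rule$rs_lhs <- rs_lhs
  rule$rs_rhs <- rs_rhs
  rule$ra <- rs_rhs / rs_lhs
  rule$rc_rhs <- rs_rhs / n_d
  rule$p_value <- phyper(rs_rhs - 1L, n_d, N - n_d, rs_lhs, lower.tail = FALSE)
  rule$support_set <- table$objects[hit]
  rule
}

# Logical vector: which rows of `values` satisfy all conditions (NA never
# matches).
matches_conditions <- function(conditions, values) {
  m <- rep(TRUE, nrow(values))
  for (a in names(conditions)) {
    if (!a %in% colnames(values)) return(rep(FALSE, nrow(values)))
    v <- values[, a]
    m <- m & !is.na(v) & v == conditions[[a]]
  }
  m
}

#' Classify an object by standard voting
#'
#' Every rule whose conditions all match casts `RS_RHS` votes for its
#' decision; votes are summed per class and normalized to fractions, and the
#' largest fraction wins (ties to the lexicographically smallest class).
#' When no rule fires the object falls back to `fallback` (typically the
#' training majority class) and is flagged `unclassified`.
#'
#' @param rules list of `rule` objects with statistics filled.
#' @param object named integer vector of discrete attribute levels.
#' @param fallback class used when no rule fires.
#' @return list: `class`, `votes` (normalized per-class fractions),
#'   `unclassified` flag.
#' @export
classify <- function(rules, object, fallback = NULL) {
  stopifnot(length(rules) >= 1)
  classes <- sort(unique(vapply(rules, `[[`, character(1), "decision")))
  votes <- setNames(numeric(length(classes)), classes)
  for (r in rules) {
    ok <- all(vapply(names(r$conditions), function(a)
      !is.na(object[a]) && object[a] == r$conditions[[a]], logical(1)))
    if (ok) votes[r$decision] <- votes[r$decision] + r$rs_rhs
  }
  if (sum(votes) == 0) {
    cls <- fallback %||% NA_character_
    return(list(class = cls, votes = votes, unclassified = TRUE))
  }
  votes <- votes / sum(votes)
  list(class = names(votes)[which.max(votes)], votes = votes,
       unclassified = FALSE)
}

# Vote fractions for a whole discrete matrix at once; returns a matrix
# (objects x classes) of normalized votes, NA rows where no rule fired.
vote_matrix <- function(rules, values, classes) {
  V <- matrix(0, nrow(values), length(classes),
              dimnames = list(rownames(values), sort(classes)))
  for (r in rules) {
    m <- matches_conditions(r$conditions, values)
    V[m, r$decision] <- V[m, r$decision] + r$rs_rhs
  }
  tot <- rowSums(V)
  out <- V / ifelse(tot == 0, 1, tot)
  out[tot == 0, ] <- NA_real_
  out
}

# Mann-Whitney AUC of `scores` for the positive class, ties mid-ranked.
auc_mw <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated rule model
#'
#' Stratified k-fold CV: per fold the training objects are undersampled to
#' the minority-class size, equal-frequency cuts are fitted on the balanced
#' training values and applied unchanged to the held-out fold, Johnson
#' reducts induce rules, and test objects are classified by standard voting.
#' Accuracy is the percentage of correctly classified test objects over all
#' folds; AUC is the area under the ROC of the positive-class vote fraction
#' (objects no rule fires on contribute an uninformative 0.5 score). The
#' final rule set is induced on the balanced full table and its statistics
#' recalculated on all samples.
#'
#' @param em an `expression_matrix`.
#' @param features attribute subset used for learning.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed controlling folds and undersampling.
#' @param n_bins discretization levels (default 3).
#' @param positive class treated as positive for the AUC (default `"case"`,
#'   else the lexicographically last class).
#' @param decision metadata column holding the class label.
#' @return object of class `rule_model`: `rules`, `class_totals`, `quality`
#'   (`accuracy` in percent, `auc`), `provenance`, `scheme`, plus CV details.
#' @export
crossvalidate <- function(em, features = NULL, folds = 10L, seed = 1L,
                          n_bins = 3L, positive = NULL, decision = "class") {
  stopifnot(inherits(em, "expression_matrix"))
  features <- features %||% em$gene_ids
  labels <- em$sample_meta[[decision]]
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  sizes <- table(labels)
  if (min(sizes) < folds)
    stop(sprintf("class '%s' has %d objects < %d folds; lower `folds`",
                 names(sizes)[which.min(sizes)], min(sizes), folds))
  positive <- positive %||% (if ("case" %in% classes) "case"
                             else classes[length(classes)])
  n <- nrow(em$values)
  fold_of <- integer(n)
  with_seed(derive_seed(seed, "folds"), {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  pred <- character(n); score <- numeric(n); unclassified <- logical(n)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    tr_em <- subset_em(em, tr)
    tab <- as_decision_table(tr_em, features, n_bins = n_bins,
                             decision = decision)
    bal <- undersample(tab, seed = derive_seed(seed, paste0("fold", f)))
    rules <- induce_rules(bal)
    scheme <- attr(tab, "scheme")
    te_vals <- apply_discretization(
      em$values[te, intersect(features, colnames(em$values)), drop = FALSE],
      scheme)
    miss <- setdiff(features, colnames(te_vals))
    if (length(miss)) {
      te_vals <- cbind(te_vals, matrix(NA_integer_, length(te), length(miss),
                                       dimnames = list(NULL, miss)))
    }
    maj <- names(sort(table(labels[tr]), decreasing = TRUE))[1]
    if (length(rules)) {
      V <- vote_matrix(rules, te_vals, classes)
      none <- is.na(V[, 1])
      p <- colnames(V)[max.col(replace(V, is.na(V), -1), ties.method = "first")]
      p[none] <- maj
      s <- V[, positive]
      s[none] <- 0.5
    } else {
      p <- rep(maj, length(te)); s <- rep(0.5, length(te)); none <- rep(TRUE, length(te))
    }
    pred[te] <- p; score[te] <- s; unclassified[te] <- none
  }
  accuracy <- 100 * mean(pred == labels)
  auc <- auc_mw(score, labels, positive)
  # final model on the full cohort
  full_tab <- as_decision_table(em, features, n_bins = n_bins,
                                decision = decision)
  bal <- undersample(full_tab, seed = derive_seed(seed, "final"))
  rules <- induce_rules(bal, stats_table = full_tab)
  cohorts <- unique(em$sample_meta$cohort_id)
  rules <- lapply(rules, function(r) { r$provenance <- cohorts; r })
  structure(list(
    rules = rules,
    class_totals = table(full_tab$decision),
    quality = list(accuracy = accuracy, auc = auc),
    provenance = cohorts,
    scheme = attr(full_tab, "scheme"),
    table = full_tab,
    cv = list(folds = folds, seed = seed, predicted = pred,
              unclassified = unclassified, positive = positive)),
    class = "rule_model")
}

subset_em <- function(em, idx) {
  structure(list(values = em$values[idx, , drop = FALSE],
                 sample_meta = em$sample_meta[idx, , drop = FALSE],
                 gene_ids = em$gene_ids), class = "expression_matrix")
}

#' @export
print.rule_model <- function(x, ...) {
  cat(sprintf("rule_model: %d rules; accuracy %.1f%%, AUC %.3f; cohorts: %s\n",
              length(x$rules), x$quality$accuracy, x$quality$auc,
              paste(x$provenance, collapse = ",")))
  invisible(x)
}

#' Benjamini-Hochberg filtering of rules
#'
#' Adjusts all rule p-values jointly and keeps those with adjusted p <=
#' `alpha`; the adjusted value is stored on each surviving rule as
#' `p_adjusted`.
#'
#' @param rules list of `rule` objects with `p_value` filled.
#' @param alpha FDR level (default 0.05).
#' @return filtered list of rules (possibly empty).
#' @export
fdr_filter <- function(rules, alpha = 0.05) {
  if (!length(rules)) return(rules)
  p <- vapply(rules, `[[`, numeric(1), "p_value")
  adj <- p.adjust(p, method = "BH")
  keep <- which(adj <= alpha)
  out <- rules[keep]
  for (i in seq_along(out)) out[[i]]$p_adjusted <- adj[keep[i]]
  out
}
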
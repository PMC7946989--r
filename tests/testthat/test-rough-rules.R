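test_that("Johnson reducts cover the discernibility function greedily", {
  tab <- toy_table()
  red <- johnson_reducts(tab)
  # o1's clauses vs o2 are {a,b} and (via o3... same class) only vs o2;
  # brute force in helper confirms {a} is a minimum cover
  expect_identical(red[[1]]$attributes, "a")
  expect_false(red[[1]]$inconsistent)
  cl <- discernibility_clauses(tab, 1)
  expect_equal(length(red[[1]]$attributes), min_cover_size(cl, tab$attributes))
  # single separating attribute: reduct is that attribute for every object
  V <- cbind(a = c(1L, 1L, 2L, 2L))
  rownames(V) <- sprintf("o%d", 1:4)
  tab1 <- decision_table(V, c("+", "+", "-", "-"))
  for (r in johnson_reducts(tab1)) expect_identical(r$attributes, "a")
  # identical objects with different decisions are inconsistent
  V2 <- cbind(a = c(1L, 1L), b = c(2L, 2L))
  rownames(V2) <- c("o1", "o2")
  red2 <- johnson_reducts(decision_table(V2, c("+", "-")))
  expect_true(all(vapply(red2, `[[`, logical(1), "inconsistent")))
})

test_that("Johnson output always covers the clauses and is irredundant", {
  for (seed in 1:25) {
    tab <- random_table(sample(4:12, 1), sample(3:8, 1), seed = seed)
    red <- johnson_reducts(tab)
    for (o in seq_along(tab$objects)) {
      cl <- discernibility_clauses(tab, o)
      if (!nrow(cl)) next
      att <- red[[o]]$attributes
      expect_true(all(rowSums(cl[, att, drop = FALSE]) > 0))
      for (a in att)  # no attribute is removable
        expect_false(all(rowSums(cl[, setdiff(att, a), drop = FALSE]) > 0))
    }
  }
})

test_that("rules are induced per object-reduct and deduplicated", {
  tab <- toy_table()
  rules <- induce_rules(tab)
  keys <- vapply(rules, function(r)
    rulenet:::rule_key(r$conditions, r$decision), character(1))
  expect_true("a=1=>+" %in% keys)
  r <- rules[[which(keys == "a=1=>+")]]
  expect_equal(r$rs_lhs, 2L)
  expect_equal(r$rs_rhs, 2L)
  expect_equal(r$ra, 1.0)
  expect_equal(anyDuplicated(keys), 0L)
  # one-object table: exactly one rule, fully accurate and covering
  V <- cbind(a = 1L, b = 2L)
  rownames(V) <- "o1"
  one <- induce_rules(decision_table(V, "+"))
  expect_length(one, 1)
  expect_equal(one[[1]]$ra, 1.0)
  expect_equal(one[[1]]$rc_rhs, 1.0)
  # duplicate objects yield one rule, not two
  V3 <- cbind(a = c(1L, 1L, 2L))
  rownames(V3) <- sprintf("o%d", 1:3)
  dup <- induce_rules(decision_table(V3, c("+", "+", "-")))
  expect_length(dup, 2)
})

test_that("rule statistics match the published definitions", {
  # RC_RHS = RS_RHS / n_d: 30 of 100 class members -> 0.3
  V <- cbind(a = rep(c(1L, 2L), c(30, 70)))
  rownames(V) <- sprintf("s%03d", 1:100)
  tab <- decision_table(V, rep("case", 100))
  r <- rule_stats(new_rule(c(a = 1L), "case"), tab)
  expect_equal(r$rc_rhs, 0.3)
  expect_equal(r$rs_rhs, 30L)
  # RA = RS_RHS / RS_LHS: 10 match IF, 9 match IF-and-THEN -> 0.9
  V2 <- cbind(a = rep(c(1L, 2L), c(10, 10)))
  rownames(V2) <- sprintf("s%02d", 1:20)
  tab2 <- decision_table(V2, rep(c("case", "control", "case"), c(9, 1, 10)))
  r2 <- rule_stats(new_rule(c(a = 1L), "case"), tab2)
  expect_equal(r2$rs_lhs, 10L)
  expect_equal(r2$rs_rhs, 9L)
  expect_equal(r2$ra, 0.9)
  expect_identical(r2$support_set, sprintf("s%02d", 1:9))
  # extreme hypergeometric: rule matching exactly its class, n_d = N/2
  V3 <- cbind(a = rep(c(1L, 2L), each = 3))
  rownames(V3) <- sprintf("s%d", 1:6)
  tab3 <- decision_table(V3, rep(c("case", "control"), each = 3))
  r3 <- rule_stats(new_rule(c(a = 1L), "case"), tab3)
  expect_equal(r3$ra, 1.0)
  expect_equal(r3$rc_rhs, 1.0)
  expect_equal(r3$p_value, 1 / choose(6, 3))
  # zero-support rules are discarded with a warning
  expect_warning(out <- rule_stats(new_rule(c(a = 9L), "case"), tab3),
                 "discarded")
  expect_null(out)
})

test_that("standard voting weights rules by RS_RHS with majority fallback", {
  r_pos <- new_rule(c(a = 1L), "+"); r_pos$rs_rhs <- 10L
  r_neg <- new_rule(c(b = 2L), "-"); r_neg$rs_rhs <- 30L
  # single firing rule
  out <- classify(list(r_pos), c(a = 1L, b = 1L))
  expect_equal(out$class, "+")
  expect_equal(unname(out$votes["+"]), 1.0)
  # both fire: 10 vs 30 -> fractions 0.25 / 0.75
  out2 <- classify(list(r_pos, r_neg), c(a = 1L, b = 2L))
  expect_equal(out2$class, "-")
  expect_equal(unname(out2$votes), c(0.25, 0.75))
  # nothing fires: fallback majority
  out3 <- classify(list(r_pos, r_neg), c(a = 3L, b = 3L),
                   fallback = "control")
  expect_equal(out3$class, "control")
  expect_true(out3$unclassified)
})

test_that("cross-validation is exact on separable data and null on noise", {
  em <- separable_em(30, seed = 1)
  mdl <- crossvalidate(em, folds = 10, seed = 4)
  expect_equal(mdl$quality$accuracy, 100)
  expect_equal(mdl$quality$auc, 1.0)
  # determinism
  mdl2 <- crossvalidate(em, folds = 10, seed = 4)
  expect_identical(mdl$quality, mdl2$quality)
  expect_identical(lapply(mdl$rules, `[[`, "conditions"),
                   lapply(mdl2$rules, `[[`, "conditions"))
  # class smaller than fold count
  expect_error(crossvalidate(separable_em(5), folds = 10), "lower `folds`")
})

test_that("quality metrics stay in range and respect model invariants", {
  em <- generate_cohorts(synthetic_spec(
    n_genes = 10, samples_per_subgroup = c(control = 30, autism = 30),
    shift_genes = list(`1` = c(autism = 1.5)), seed = 6))[[1]]
  mdl <- crossvalidate(em, folds = 5, seed = 3)
  expect_true(mdl$quality$accuracy >= 0 && mdl$quality$accuracy <= 100)
  expect_true(mdl$quality$auc >= 0 && mdl$quality$auc <= 1)
  N <- sum(mdl$class_totals)
  for (r in mdl$rules) {
    expect_lte(r$rs_rhs, r$rs_lhs)
    expect_lte(r$rs_lhs, N)
    expect_equal(r$ra * r$rs_lhs, r$rs_rhs)
    expect_equal(length(r$support_set), r$rs_rhs)
  }
})

test_that("statistics recalculated on the full table dominate the
           undersampled counts", {
  set.seed(12)
  V <- matrix(sample(1:3, 90 * 3, replace = TRUE), 90, 3,
              dimnames = list(sprintf("s%02d", 1:90), letters[1:3]))
  tab <- decision_table(V, rep(c("case", "control"), c(60, 30)))
  bal <- undersample(tab, seed = 1)
  rules_bal <- induce_rules(bal)
  rules_full <- induce_rules(bal, stats_table = tab)
  for (i in seq_along(rules_bal)) {
    expect_gte(rules_full[[i]]$rs_lhs, rules_bal[[i]]$rs_lhs)
    expect_gte(rules_full[[i]]$rs_rhs, rules_bal[[i]]$rs_rhs)
  }
})

test_that("FDR filtering follows Benjamini-Hochberg", {
  mk <- function(p) {
    r <- new_rule(c(a = 1L), "+"); r$p_value <- p; r
  }
  expect_length(fdr_filter(lapply(rep(1, 5), mk)), 0)
  expect_length(fdr_filter(list(mk(0.01))), 1)
  # hand BH on (0.01, 0.02, 0.04, 0.9): adjusted (0.04, 0.04, 0.0533, 0.9)
  # -> exactly the first two pass alpha = 0.05
  kept <- fdr_filter(lapply(c(0.01, 0.02, 0.04, 0.9), mk), alpha = 0.05)
  expect_length(kept, 2)
  expect_equal(vapply(kept, `[[`, numeric(1), "p_adjusted"),
               c(0.04, 0.04))
})
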
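mk_supported_rule <- function(conds, decision, support) {
  r <- new_rule(conds, decision)
  r$rs_rhs <- length(support)
  r$rs_lhs <- length(support)
  r$ra <- 1
  r$support_set <- support
  r
}

toy_meta <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:12),
    subtype = rep(c("control", "AS", "autism"), each = 4),
    stringsAsFactors = FALSE)
}

test_that("rules map to subgroups through their support sets", {
  meta <- toy_meta()
  r_aut <- mk_supported_rule(c(a = 1L, b = 1L), "case", c("s09", "s10"))
  r_both <- mk_supported_rule(c(a = 2L, b = 2L), "case", c("s05", "s11"))
  r_ctl <- mk_supported_rule(c(a = 3L, b = 3L), "control", c("s01", "s02"))
  r_none <- mk_supported_rule(c(a = 1L, b = 2L), "case", character(0))
  mdl <- structure(list(rules = list(r_aut, r_both, r_ctl, r_none)),
                   class = "rule_model")
  asg <- assign_rules_to_subgroups(mdl, meta)
  expect_setequal(names(asg), c("AS", "autism", "control"))
  expect_length(asg$autism, 2)   # r_aut and r_both
  expect_length(asg$AS, 1)       # r_both only
  expect_length(asg$control, 1)  # the control rule
  # missing subtype values are dropped with a warning
  meta$subtype[12] <- NA
  expect_warning(assign_rules_to_subgroups(mdl, meta), "missing subtype")
})

test_that("support distributions are normalized per subtype total", {
  meta <- data.frame(
    sample_id = c(sprintf("a%02d", 1:40), sprintf("b%02d", 1:50)),
    subtype = rep(c("autism", "AS"), c(40, 50)))
  full <- mk_supported_rule(c(x = 1L), "case", sprintf("a%02d", 1:40))
  expect_equal(subtype_support_distribution(full, meta)[["autism"]], 100)
  part <- mk_supported_rule(c(x = 1L), "case",
                            c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:5)))
  d <- subtype_support_distribution(part, meta)
  expect_equal(d[["autism"]], 25)
  expect_equal(d[["AS"]], 10)
  none <- mk_supported_rule(c(x = 1L), "case", character(0))
  expect_true(all(subtype_support_distribution(none, meta) == 0))
})

path_net <- function() build_network(list(
  mk_supported_rule(c(A = 1L, B = 1L), "case", "s1"),
  mk_supported_rule(c(B = 1L, C = 1L), "case", "s2")))

triangle_net <- function() build_network(list(
  mk_supported_rule(c(A = 1L, B = 1L), "case", "s1"),
  mk_supported_rule(c(B = 1L, C = 1L), "case", "s2"),
  mk_supported_rule(c(A = 1L, C = 1L), "case", "s3")))

test_that("betweenness distance matches hand-computed small graphs", {
  expect_equal(betweenness_distance(path_net(), path_net()), 0)
  # path A-B-C has betweenness (0,1,0); triangle all zeros -> distance 1
  expect_equal(betweenness_distance(path_net(), triangle_net()), 1.0)
  expect_warning(
    d0 <- betweenness_distance(build_network(list()), build_network(list())),
    "empty")
  expect_equal(d0, 0)
})

test_that("betweenness distance is a symmetric, triangle-obeying metric", {
  nets <- lapply(1:6, function(s) build_network(random_rules(15, seed = s)))
  for (i in 1:5) {
    expect_equal(betweenness_distance(nets[[i]], nets[[i + 1]]),
                 betweenness_distance(nets[[i + 1]], nets[[i]]))
  }
  for (s in 1:4) {
    a <- nets[[s]]; b <- nets[[s + 1]]; c <- nets[[s + 2]]
    expect_lte(betweenness_distance(a, c),
               betweenness_distance(a, b) + betweenness_distance(b, c) + 1e-9)
  }
})

test_that("balanced distance reduces to the plain distance when exhaustive", {
  rulesA <- random_rules(12, seed = 3)
  rulesB <- random_rules(12, seed = 4)
  plain <- betweenness_distance(build_network(rulesA), build_network(rulesB))
  expect_equal(balanced_distance(rulesA, rulesB, n_balance = 1, seed = 5),
               plain)
  expect_equal(balanced_distance(rulesA, rulesA, n_balance = 6, seed = 1), 0)
  expect_identical(balanced_distance(rulesA, rulesB, n_balance = 5, seed = 9),
                   balanced_distance(rulesA, rulesB, n_balance = 5, seed = 9))
  expect_error(balanced_distance(list(), rulesB), "non-empty")
})

test_that("permutation p-values respect the add-one bound and identity", {
  meta <- toy_meta()
  # two subgroups carrying identical rule sets -> observed 0, p = 1
  rules <- lapply(1:6, function(i)
    mk_supported_rule(setNames(c(1L, i), c("a", paste0("g", i))), "case",
                      c("s05", "s09")))  # one AS and one autism supporter each
  mdl <- structure(list(rules = rules), class = "rule_model")
  res <- permutation_test(mdl, meta, subgroups = c("AS", "autism"),
                          n_perm = 30, n_balance = 3, seed = 2)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
  expect_gte(min(res$p_value), 1 / 31)
})

test_that("kendall distances follow 1 - tau_b", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_equal(kendall_distance_matrix(m)["a", "b"], 0)
  m2 <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  expect_equal(kendall_distance_matrix(m2)["a", "b"], 2)
  # brute-force pair counting: tau_b((1,2,3,4),(1,3,2,4)) = 2/3
  m3 <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  expect_equal(kendall_distance_matrix(m3)["a", "b"], 1 / 3)
  expect_warning(d <- kendall_distance_matrix(rbind(a = c(1, 1, 1),
                                                    b = c(1, 2, 3))),
                 "constant")
  expect_equal(d["a", "b"], 1)
  expect_equal(unname(diag(d)), c(0, 0))
})

test_that("connection tables align subgroup networks over union nodes", {
  nets <- list(A = build_network(random_rules(10, seed = 1)),
               B = build_network(random_rules(10, seed = 2)))
  ct <- connection_table(nets)
  expect_setequal(colnames(ct), union(nets$A$nodes$id, nets$B$nodes$id))
  expect_equal(unname(ct["A", nets$A$nodes$id]), nets$A$nodes$raw)
  only_b <- setdiff(nets$B$nodes$id, nets$A$nodes$id)
  expect_true(all(ct["A", only_b] == 0))
})
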
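# Shared fixtures and independent oracles, built in code.

# Spec's three-object toy table: o1:(a=1,b=0,c=0)->+, o2:(a=0,b=1,c=0)->-,
# o3:(a=1,b=1,c=1)->+.
toy_table <- function() {
  V <- rbind(o1 = c(a = 1L, b = 0L, c = 0L),
             o2 = c(a = 0L, b = 1L, c = 0L),
             o3 = c(a = 1L, b = 1L, c = 1L))
  decision_table(V, c("+", "-", "+"))
}

# Random discrete decision table (3 levels, 2 classes, both present).
random_table <- function(n, m, seed) {
  set.seed(seed)
  V <- matrix(sample(1:3, n * m, replace = TRUE), n, m,
              dimnames = list(sprintf("o%02d", seq_len(n)),
                              sprintf("a%02d", seq_len(m))))
  dec <- sample(c("x", "y"), n, replace = TRUE)
  if (length(unique(dec)) < 2) dec[1] <- setdiff(c("x", "y"), dec[1])
  decision_table(V, dec)
}

# Independent oracle: minimum-cardinality cover of discernibility clauses
# by exhaustive subset search.
min_cover_size <- function(clauses, attrs) {
  if (!nrow(clauses)) return(0L)
  for (k in seq_along(attrs)) {
    for (s in utils::combn(attrs, k, simplify = FALSE)) {
      if (all(rowSums(clauses[, s, drop = FALSE]) > 0)) return(k)
    }
  }
  length(attrs)
}

# Discernibility clauses of object `o` (modulo decision), deduplicated.
discernibility_clauses <- function(tab, o) {
  V <- tab$values
  others <- which(tab$decision != tab$decision[o])
  D <- V[others, , drop = FALSE] !=
    matrix(V[o, ], length(others), ncol(V), byrow = TRUE)
  D[is.na(D)] <- FALSE
  unique(D[rowSums(D) > 0, , drop = FALSE])
}

# Random rules over a small feature/level space, statistics prefilled.
random_rules <- function(n, n_features = 8, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1, prob = c(0.2, 0.5, 0.3))
    feats <- sample(sprintf("g%02d", seq_len(n_features)), k)
    r <- new_rule(setNames(sample(1:3, k, replace = TRUE), feats),
                  sample(c("case", "control"), 1))
    r$rs_rhs <- sample(1:40, 1)
    r$rs_lhs <- r$rs_rhs + sample(0:10, 1)
    r$ra <- r$rs_rhs / r$rs_lhs
    r$p_value <- runif(1)
    r
  })
}

# Ranking object straight from an RI vector (internal constructor).
ranking_from_ri <- function(ri) {
  rulenet:::new_feature_ranking(sprintf("f%02d", seq_along(ri)), ri,
                                provenance = "test")
}

# Expression matrix with a single feature holding tied class blocks
# (disjoint class ranges): separable after equal-frequency discretization.
separable_em <- function(n_per_class = 30, seed = 1) {
  spec <- synthetic_spec(n_cohorts = 1, n_genes = 1,
                         samples_per_subgroup = c(control = n_per_class,
                                                  autism = n_per_class),
                         seed = seed)
  em <- generate_cohorts(spec)[[1]]
  em$values[, 1] <- ifelse(em$sample_meta$class == "case", 10, 0)
  em
}
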
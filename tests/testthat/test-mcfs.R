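informative_em <- function(seed) {
  generate_cohorts(synthetic_spec(
    n_genes = 20, samples_per_subgroup = c(control = 50, autism = 50),
    shift_genes = list(`5` = c(autism = 3)), seed = seed))[[1]]
}

test_that("a class-separating feature ranks first across seeds", {
  em <- informative_em(11)
  hits <- 0
  for (s in 1:20) {
    rk <- mcfs_rank(em$values, em$sample_meta$class, s = 50, t = 5, seed = s)
    hits <- hits + (rk$feature_id[1] == "g005")
  }
  expect_gte(hits, 19)
})

test_that("RI is zero for constant features and non-negative everywhere", {
  em <- informative_em(3)
  em$values[, 2] <- 7  # constant: never a useful split
  rk <- mcfs_rank(em$values, em$sample_meta$class, s = 30, t = 3, seed = 1)
  expect_identical(rk$ri[rk$feature_id == "g002"], 0)
  expect_true(all(rk$ri >= 0))
  # deterministic under seed
  rk2 <- mcfs_rank(em$values, em$sample_meta$class, s = 30, t = 3, seed = 1)
  expect_identical(rk$ri, rk2$ri)
})

test_that("permuting labels collapses the top RI", {
  em <- informative_em(5)
  rk <- mcfs_rank(em$values, em$sample_meta$class, s = 30, t = 5, seed = 2)
  set.seed(99)
  perm <- sample(em$sample_meta$class)
  rk0 <- mcfs_rank(em$values, perm, s = 30, t = 5, seed = 2)
  expect_lt(max(rk0$ri), max(rk$ri))
})

test_that("more Monte Carlo sampling stabilizes RI across seeds", {
  em <- informative_em(7)
  ri_at <- function(s, t, seed) {
    rk <- mcfs_rank(em$values, em$sample_meta$class, s = s, t = t, seed = seed)
    rk$ri[rk$feature_id == "g005"] / sum(rk$ri)  # relative share
  }
  lo <- vapply(1:6, function(sd) ri_at(8, 2, sd), numeric(1))
  hi <- vapply(1:6, function(sd) ri_at(60, 5, sd), numeric(1))
  expect_lt(sd(hi), sd(lo))
})

test_that("critical-angle threshold finds the knee", {
  expect_identical(
    critical_angle_threshold(ranking_from_ri(c(1, 0.95, 0.9, 0.1, 0.09, 0.08))),
    3L)
  # strictly linear decay: every turn angle equal, tie to smallest k
  expect_identical(
    critical_angle_threshold(ranking_from_ri(seq(1, 0.4, length.out = 8))),
    2L)
  expect_error(critical_angle_threshold(ranking_from_ri(c(1, 0.5))), ">= 3")
  expect_warning(k <- critical_angle_threshold(ranking_from_ri(rep(1, 5))),
                 "flat")
  expect_identical(k, 5L)
})

test_that("critical-angle threshold is affine-invariant in RI", {
  for (seed in 1:10) {
    set.seed(seed)
    ri <- sort(runif(15), decreasing = TRUE)
    k1 <- critical_angle_threshold(ranking_from_ri(ri))
    k2 <- critical_angle_threshold(ranking_from_ri(3.7 * ri + 11))
    expect_identical(k1, k2)
  }
})

test_that("adjust_fr returns the nearest local quality maximum", {
  rk <- ranking_from_ri(seq(1, 0.1, length.out = 20))
  stub <- function(q) list(quality_fn = function(k) q[k])
  # monotone increase: no interior maximum, take k_max
  q <- seq(0, 1, length.out = 20)
  expect_equal(as.integer(adjust_fr(rk, k0 = 3, k_max = 12,
                                    learner_config = stub(q))), 12L)
  # unique peak at k0 + 3
  q <- rep(0.5, 20); q[9] <- 0.9
  expect_equal(as.integer(adjust_fr(rk, k0 = 6, k_max = 15,
                                    learner_config = stub(q))), 9L)
  # flat: tie to k0
  q <- rep(0.7, 20)
  expect_equal(as.integer(adjust_fr(rk, k0 = 4, k_max = 14,
                                    learner_config = stub(q))), 4L)
  # plateau peak counts at its smallest k
  q <- c(rep(0.2, 6), rep(0.8, 3), rep(0.4, 11))
  expect_equal(as.integer(adjust_fr(rk, k0 = 3, k_max = 16,
                                    learner_config = stub(q))), 7L)
  expect_error(adjust_fr(rk, k0 = 30, learner_config = stub(q)), "exceeds")
})

test_that("adjust_fr drives a real learner end to end", {
  em <- separable_em(20, seed = 2)
  em$values <- cbind(em$values, noise = rnorm(nrow(em$values)))
  colnames(em$values)[1] <- "sig"
  em$gene_ids <- colnames(em$values)
  rk <- rulenet:::new_feature_ranking(c("sig", "noise"), c(1, 0.2), "c1")
  k <- adjust_fr(rk, em, k0 = 1, k_max = 2,
                 learner_config = list(folds = 5, seed = 1))
  q <- attr(k, "quality")
  expect_length(q, 2)
  expect_equal(unname(q["1"]), 1)  # separable single feature is perfect
})

test_that("rankings merge by rescaled maximum RI", {
  r1 <- rulenet:::new_feature_ranking(sprintf("a%02d", 1:19),
                                      seq(10, 1, length.out = 19), "c1")
  r2 <- rulenet:::new_feature_ranking(sprintf("b%02d", 1:13),
                                      seq(4, 1, length.out = 13), "c2")
  merged <- merge_rankings(list(r1, r2))
  expect_length(merged$feature_id, 32)
  expect_equal(max(merged$ri), 1)
  # shared feature keeps its maximum rescaled RI
  r3 <- rulenet:::new_feature_ranking(c("a01", "z"), c(5, 4), "c3")
  m2 <- merge_rankings(list(r1, r3))
  expect_equal(m2$ri[m2$feature_id == "a01"], 1)  # max(1, 1) after rescale
  r4 <- rulenet:::new_feature_ranking(c("a02", "z"), c(10, 6), "c3")
  m3 <- merge_rankings(list(r1, r4))
  expect_equal(m3$ri[m3$feature_id == "a02"],
               max(r1$ri[r1$feature_id == "a02"] / 10, 1))
  # identity on identical id spaces with empty map
  m4 <- merge_rankings(list(r1))
  expect_identical(m4$feature_id, r1$feature_id)
  # id_map translation and collision detection
  map <- data.frame(source = "b01", target = "a01")
  m5 <- merge_rankings(list(r1, r2), id_map = map)
  expect_false("b01" %in% m5$feature_id)
  bad <- data.frame(source = c("b01", "b01"), target = c("a01", "a02"))
  expect_error(merge_rankings(list(r1, r2), id_map = bad), "collision")
})
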
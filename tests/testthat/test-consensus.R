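# Ranking, average-ranking consensus, concordance, tissue profiles and the
# top-quantile prioritization rule.

mk_scores <- function(vals, direction = "higher") {
  score_matrix(vals, direction)
}

random_rank_table <- function(n, m, seed, miss = 0) {
  set.seed(seed)
  vals <- matrix(rnorm(n * m), n, m,
                 dimnames = list(sprintf("v%03d", seq_len(n)),
                                 sprintf("m%02d", seq_len(m))))
  if (miss > 0) vals[sample(length(vals), miss)] <- NA
  rank_scores(mk_scores(vals))
}

test_that("per-method ranking honors ties, direction and missingness", {
  vals <- matrix(c(0.9, 0.5, 0.5, 0.1), 4, 1,
                 dimnames = list(paste0("v", 1:4), "m1"))
  expect_equal(unname(rank_scores(mk_scores(vals))$ranks[, 1]),
               c(1, 2.5, 2.5, 4))
  # lower-is-functional ranks as the negation of the higher case
  low <- rank_scores(mk_scores(-vals, direction = "lower"))
  expect_equal(low$ranks, rank_scores(mk_scores(vals))$ranks)
  # complete columns sum to n(n+1)/2
  rt <- random_rank_table(37, 6, seed = 2)
  expect_equal(unname(colSums(rt$ranks)), rep(37 * 38 / 2, 6))
  # missing scores give missing ranks; the rest still rank 1..k
  vals[2, 1] <- NA
  r <- rank_scores(mk_scores(vals))$ranks[, 1]
  expect_true(is.na(r[2]))
  expect_equal(sort(unname(r[-2])), 1:3)
  vals[] <- NA
  expect_error(rank_scores(mk_scores(vals)), "missing")
})

test_that("average ranking matches direct arithmetic and conserves mass", {
  rt <- random_rank_table(20, 1, seed = 3)
  expect_equal(average_ranking(rt)$average_ranking, unname(rt$ranks[, 1]))
  rt3 <- list(ranks = matrix(c(3, 5, 10), 1, 3,
                             dimnames = list("v1", c("a", "b", "c"))),
              variant_ids = "v1", method_ids = c("a", "b", "c"))
  class(rt3) <- "ranking_table"
  expect_equal(average_ranking(rt3)$average_ranking, 6.0)
  rt2 <- random_rank_table(41, 7, seed = 4)
  expect_equal(mean(average_ranking(rt2)$average_ranking), (41 + 1) / 2)
  # an independent per-row mean oracle agrees exactly
  oracle <- apply(rt2$ranks, 1, function(r) sum(r) / length(r))
  expect_identical(average_ranking(rt2)$average_ranking, unname(oracle))
  # min_methods flags sparse rows
  rtm <- random_rank_table(30, 5, seed = 5, miss = 40)
  ar <- average_ranking(rtm, min_methods = 5)
  expect_identical(ar$included, ar$n_methods_used == 5L)
})

test_that("permutation p-values respect the plus-one bound and relabeling", {
  one <- list(ranks = matrix(1, 1, 3, dimnames = list("v1", c("a", "b", "c"))),
              variant_ids = "v1", method_ids = c("a", "b", "c"))
  class(one) <- "ranking_table"
  expect_equal(permutation_pvalue(one, n_perm = 99, seed = 1)$p_value, 1.0)

  rt <- random_rank_table(25, 4, seed = 6)
  pv <- permutation_pvalue(rt, n_perm = 199, seed = 2)
  expect_true(all(pv$p_value >= 1 / 200))
  expect_true(all(pv$p_value <= 1))
  expect_true(all(pv$adjusted_p >= pv$p_value - 1e-12))
  # relabeling variants leaves seed-aligned p-values unchanged
  rt2 <- rt
  rt2$variant_ids <- paste0("renamed_", rt$variant_ids)
  rownames(rt2$ranks) <- rt2$variant_ids
  pv2 <- permutation_pvalue(rt2, n_perm = 199, seed = 2)
  expect_equal(pv2$p_value, pv$p_value)
  expect_error(permutation_pvalue(rt, n_perm = 0), "n_perm")
})

test_that("Spearman correlation matches worked values and rejects degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_scores(x, x), 1.0)
  expect_equal(spearman_scores(x, rev(x)), -1.0)
  expect_equal(spearman_scores(x, c(1, 3, 2, 5, 4)), 0.8)
  expect_error(spearman_scores(x, rep(2, 5)), "constant")
  expect_error(spearman_scores(c(1, 2), c(3, 4)), ">= 3")
  # agreement with base R's independent implementation, with ties
  set.seed(8)
  for (r in 1:20) {
    a <- round(rnorm(30), 1); b <- round(a + rnorm(30), 1)
    expect_equal(spearman_scores(a, b), cor(a, b, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("rank correlation matrix is symmetric with unit diagonal", {
  rt <- random_rank_table(30, 5, seed = 9)
  cm <- pearson_rank_correlation(rt)
  expect_identical(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 5))
  # complete columns: equals Spearman of the raw scores
  set.seed(10)
  vals <- matrix(rnorm(60), 20, 3,
                 dimnames = list(sprintf("v%02d", 1:20), c("a", "b", "c")))
  sm <- mk_scores(vals)
  cm2 <- pearson_rank_correlation(rank_scores(sm))
  expect_equal(cm2["a", "b"], spearman_scores(vals[, "a"], vals[, "b"]),
               tolerance = 1e-12)
  # insufficient overlap yields NA with a warning
  vals[1:18, "c"] <- NA
  w <- capture_warnings(
    cm3 <- pearson_rank_correlation(rank_scores(mk_scores(vals))))
  expect_true(length(w) >= 1 && all(grepl("fewer than 3", w)))
  expect_true(is.na(cm3["a", "c"]))
})

test_that("tissue-max classification partitions variants by argmax location", {
  vals <- rbind(v1 = c(brain1 = 0.9, brain2 = 0.2, liver = 0.5),
                v2 = c(0.4, 0.4, 0.4),
                v3 = c(0.1, 0.3, 0.8),
                v4 = c(0.7, 0.2, 0.7))
  tp <- tissue_max_profile(mk_scores(vals), group = c("brain1", "brain2"))
  expect_equal(tp$classification,
               c("unique_to_group", "shared_with_group", "outside_group",
                 "shared_with_group"))
  expect_equal(tp$argmax_tissues[2], "brain1,brain2,liver")
  # classifications partition the variant set
  expect_equal(nrow(tp), 4)
  expect_true(all(tp$classification %in%
                    c("unique_to_group", "shared_with_group", "outside_group")))
  expect_error(tissue_max_profile(mk_scores(vals), character(0)), "empty")
  expect_error(tissue_max_profile(mk_scores(vals), "kidney"), "absent")
})

test_that("consensus rule passes exactly the doubly top-ranked variants", {
  # n = 20, q = 0.05 -> top set size 1; one variant rank 1 in the tissue and
  # in 6 of 11 methods
  n <- 20; m <- 11
  set.seed(12)
  ids <- sprintf("v%02d", 1:n)
  cf <- matrix(rnorm(n * m), n, m, dimnames = list(ids, sprintf("m%02d", 1:m)))
  cf[1, 1:6] <- apply(cf[, 1:6, drop = FALSE], 2, max) + 1  # rank 1 in 6 methods
  cf[1, 7:11] <- apply(cf[, 7:11, drop = FALSE], 2, min) - 1 # rank n elsewhere
  ti <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, c("t1", "t2", "t3")))
  ti[1, "t1"] <- max(ti) + 1
  tab <- rank_scores(mk_scores(cf))
  out <- consensus_prioritize(mk_scores(ti), "t1", tab, q = 0.05,
                              min_method_fraction = 0.5)
  expect_equal(out$variant_id[out$pass], "v01")
  expect_equal(sum(out$pass), 1)

  # q near 1 with minimal method fraction: everyone passes
  all_in <- consensus_prioritize(mk_scores(ti), "t1", tab, q = 0.999,
                                 min_method_fraction = 1 / m)
  expect_true(all(all_in$pass))
  expect_error(consensus_prioritize(mk_scores(ti), "t1", tab, q = 1), "q must")
  expect_error(consensus_prioritize(mk_scores(ti), "zz", tab, q = 0.05),
               "absent")

  # decreasing q never adds passers
  passers <- lapply(c(0.3, 0.15, 0.05), function(q) {
    o <- consensus_prioritize(mk_scores(ti), "t1", tab, q = q,
                              min_method_fraction = 0.5)
    o$variant_id[o$pass]
  })
  expect_true(all(passers[[2]] %in% passers[[1]]))
  expect_true(all(passers[[3]] %in% passers[[2]]))

  # invariance to method and tissue column order
  perm_cf <- cf[, sample(m)]; perm_ti <- ti[, c(3, 1, 2)]
  out_perm <- consensus_prioritize(mk_scores(perm_ti), "t1",
                                   rank_scores(mk_scores(perm_cf)),
                                   q = 0.05, min_method_fraction = 0.5)
  expect_equal(out_perm$variant_id[out_perm$pass],
               out$variant_id[out$pass])
})
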
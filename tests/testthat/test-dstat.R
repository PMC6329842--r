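test_that("sister-difference sums match the hand oracle on the 4-tip tree", {
  tr <- balanced4()
  expect_equal(sum_sister_differences(tr, c(A = 1, B = 1, C = 0, D = 0)), 1)
  expect_equal(sum_sister_differences(tr, c(A = 1, B = 0, C = 1, D = 0)), 2)
  expect_error(sum_sister_differences(tr, c(A = 1, B = 1, C = 1, D = 1)),
               "monomorphic")
  expect_error(sum_sister_differences(tr, c(A = 1, B = 0, C = 2, D = 0)),
               "0 or 1")
  expect_error(sum_sister_differences(tr, c(A = 1, B = 0, C = 1)), "tip")
  expect_error(sum_sister_differences(ape::read.tree(text = "(A:1,B:1);"),
                                      c(A = 1, B = 0)), "4 tips")
})

test_that("implementation agrees with the recursive oracle on random trees", {
  withr::with_seed(31, {
    for (rep in 1:8) {
      n <- sample(5:14, 1)
      tr <- ape::rtree(n)
      k <- sample(seq_len(n - 1), 1)
      trait <- setNames(sample(rep(c(1L, 0L), c(k, n - k))), tr$tip.label)
      expect_equal(sum_sister_differences(tr, trait), oracle_sumd(tr, trait))
    }
  })
  # polytomies: node value is the mean over all children
  poly <- ape::read.tree(text = "(A:1,B:1,(C:1,D:1):1);")
  trait <- c(A = 1, B = 0, C = 1, D = 0)
  expect_equal(sum_sister_differences(poly, trait), oracle_sumd(poly, trait))
})

test_that("sum of sister differences has the stated invariances", {
  withr::with_seed(32, {
    tr <- ape::rtree(12)
    trait <- setNames(sample(rep(c(1L, 0L), c(5, 7))), tr$tip.label)
    s <- sum_sister_differences(tr, trait)
    # complement symmetry
    expect_equal(sum_sister_differences(tr, 1L - trait), s)
    # branch-length rescaling (estimator is topology-only)
    tr2 <- tr; tr2$edge.length <- tr$edge.length * 17
    expect_equal(sum_sister_differences(tr2, trait), s)
    # children order
    tr3 <- ape::rotate(tr, 14)
    expect_equal(sum_sister_differences(tr3, trait), s)
  })
})

test_that("null generators are seeded, sized and prevalence-preserving", {
  tr <- simulate_yule_tree(30, seed = 33)
  trait <- simulate_bm_threshold_trait(tr, k = 10, seed = 34)
  r1 <- permutation_null(tr, trait, B = 99, seed = 35)
  expect_length(r1, 99L)
  expect_identical(r1, permutation_null(tr, trait, B = 99, seed = 35))
  b1 <- brownian_null(tr, k = 10, B = 99, seed = 36)
  expect_length(b1, 99L)
  expect_identical(b1, brownian_null(tr, k = 10, B = 99, seed = 36))
  expect_error(permutation_null(tr, trait, B = 0), "at least 1")
  # thresholding yields exactly k ones in every replicate
  vals <- withr::with_seed(37, alcuse:::bm_tip_values(tr, 50))
  states <- alcuse:::threshold_top_k(vals, 10)
  expect_true(all(colSums(states) == 10))
})

test_that("Brownian null is tighter than the shuffle null on a deep two-clade tree", {
  # two deep clades; k equal to one clade's size: BM clusters states
  tr <- ape::read.tree(text = paste0(
    "((a1:1,(a2:1,(a3:1,(a4:1,a5:1):1):1):1):10,",
    "(b1:1,(b2:1,(b3:1,(b4:1,b5:1):1):1):1):10);"))
  b <- brownian_null(tr, k = 5, B = 400, seed = 38)
  r <- permutation_null(tr, setNames(rep(c(1, 0), each = 5), tr$tip.label),
                        B = 400, seed = 39)
  expect_lt(mean(b), mean(r))
})

test_that("D statistic set points, p-value range and determinism hold", {
  tr <- simulate_yule_tree(80, seed = 40)
  trait <- simulate_bm_threshold_trait(tr, k = 24, f = 0.5, seed = 41)
  d <- d_statistic(tr, trait, B = 199, seed = 42)
  expect_s3_class(d, "alc_d")
  # scaling formula and set points on the actual null draws
  expect_equal(scale_d(mean(d$sumd_b), d$sumd_r, d$sumd_b), 0)
  expect_equal(scale_d(mean(d$sumd_r), d$sumd_r, d$sumd_b), 1)
  expect_equal(d$D, (d$sumd_obs - mean(d$sumd_b)) /
                 (mean(d$sumd_r) - mean(d$sumd_b)))
  # add-one correction bounds
  expect_gte(d$p_d0, 1 / 200); expect_lte(d$p_d0, 1)
  expect_gte(d$p_d1, 1 / 200); expect_lte(d$p_d1, 1)
  d2 <- d_statistic(tr, trait, B = 199, seed = 42)
  expect_equal(d$D, d2$D)
  expect_identical(d$sumd_r, d2$sumd_r)
  df <- as.data.frame(d)
  expect_equal(df$D, d$D)
  expect_output(print(d), "D = ")
})

test_that("star trees give an explicit degenerate-denominator error", {
  tr <- star_tree(8)
  trait <- setNames(rep(c(1, 0), each = 4), tr$tip.label)
  # on a pure star both null sums are the same constant
  expect_error(d_statistic(tr, trait, B = 49, seed = 43), "degenerate")
})

test_that("missing branch lengths are an error for signal, fine for sums", {
  tr <- balanced4()
  trait <- c(A = 1, B = 1, C = 0, D = 0)
  nolen <- tr; nolen$edge.length <- NULL
  expect_equal(sum_sister_differences(nolen, trait), 1) # topology-only
  expect_error(d_statistic(nolen, trait, B = 19), "branch lengths")
  expect_error(brownian_null(nolen, k = 2, B = 19), "branch lengths")
})
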
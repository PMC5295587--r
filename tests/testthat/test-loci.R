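test_that("overlap clusters follow chain connectivity per arm", {
  chain <- as_hi_intervals(data.frame(start = c(0, 5, 12), end = c(10, 15, 20)))
  expect_equal(merge_overlapping_hi(chain)$component_count, 1)

  apart <- as_hi_intervals(data.frame(start = c(0, 20), end = c(10, 30)))
  expect_equal(merge_overlapping_hi(apart)$component_count, 2)

  # abutting intervals do not share a base -> separate clusters
  abut <- as_hi_intervals(data.frame(start = c(0, 10), end = c(10, 20)))
  expect_equal(merge_overlapping_hi(abut)$component_count, 2)

  empty <- as_hi_intervals(data.frame(start = numeric(0), end = numeric(0)))
  expect_equal(merge_overlapping_hi(empty)$component_count, 0)

  cl <- merge_overlapping_hi(chain)$clusters
  expect_equal(cl$span_start, 0)
  expect_equal(cl$span_end, 20)
  expect_equal(cl$member_ids, "df001,df002,df003")
})

test_that("minimal causal-region count is the minimum stabbing number", {
  # a chain with no common base needs two loci even though it is one cluster
  chain <- as_hi_intervals(data.frame(start = c(0, 5, 12), end = c(10, 15, 20)))
  est <- minimal_locus_count(chain)
  expect_equal(est$minimal_count, 2)
  expect_equal(est$component_count, 1)
  # every interval contains a representative point
  for (i in seq_len(nrow(chain))) {
    expect_true(any(est$points$position >= chain$start[i] &
                      est$points$position < chain$end[i]))
  }

  disjoint <- as_hi_intervals(data.frame(start = c(0, 20, 40),
                                         end = c(10, 30, 50)))
  expect_equal(minimal_locus_count(disjoint)$minimal_count, 3)

  common <- as_hi_intervals(data.frame(start = c(0, 3, 5), end = c(10, 12, 9)))
  expect_equal(minimal_locus_count(common)$minimal_count, 1)

  expect_equal(minimal_locus_count(chain[0, ])$minimal_count, 0)
})

test_that("greedy stabbing equals the exhaustive oracle on random instances", {
  expect_equal(brute_force_min_cover(data.frame(start = 1, end = 5)[0, ]), 0L)
  expect_equal(brute_force_min_cover(data.frame(start = 1, end = 5)), 1L)
  expect_error(brute_force_min_cover(random_intervals(13)), "12 intervals")

  set.seed(90)
  for (i in seq_len(1000)) {
    ints <- random_intervals(sample.int(12, 1))
    hi <- as_hi_intervals(ints)
    est <- minimal_locus_count(hi)
    expect_identical(est$minimal_count, brute_force_min_cover(ints))
    # sandwich invariant
    expect_lte(est$component_count, est$minimal_count)
    expect_lte(est$minimal_count, nrow(ints))
  }
})

test_that("arm-density statistic and simulated p behave as specified", {
  res <- arm_density_test(c(4, 4, 4, 4, 4), replicates = 99, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_simulated, 1)

  res <- arm_density_test(c(20, 0, 0, 0, 0), replicates = 2000, seed = 1)
  expect_equal(res$statistic, 80)
  expect_lt(res$p_simulated, 0.01)

  expect_error(arm_density_test(c(0, 0, 0)), "at least 1")
  expect_error(arm_density_test(c(5)), "at least two arms")

  # invariant to arm relabeling (counts permuted, same seed)
  x <- c(9, 2, 5, 3, 1)
  a <- arm_density_test(x, replicates = 500, seed = 42)
  b <- arm_density_test(rev(x), replicates = 500, seed = 42)
  expect_equal(a$p_simulated, b$p_simulated)
})

test_that("simulated p tracks the asymptotic chi-square tail at large counts", {
  set.seed(17)
  for (i in 1:6) {
    counts <- as.integer(stats::rmultinom(1, size = 250, prob = rep(0.2, 5)))
    res <- arm_density_test(counts, replicates = 2000, seed = 100 + i)
    p_asym <- stats::pchisq(res$statistic, df = 4, lower.tail = FALSE)
    expect_lt(abs(res$p_simulated - p_asym), 0.05)
  }
})
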
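test_that("parse_panel round-trips well-formed rows and preserves order", {
  path <- write_panel_file(c(
    "# deficiency panel",
    "arm\tstart\tend\tstock_id",
    "A\t0\t60\tdf1",
    "A\t40\t100\tdf2"
  ))
  arms <- file.path(dirname(path), "arms.tsv")
  writeLines(c("arm\tlength\tchromosome", "A\t1000\t1", "B\t800\t2"), arms)
  panel <- parse_panel(path, arm_table = arms)
  expect_s3_class(panel, "deficiency_panel")
  expect_equal(panel$deficiencies$stock_id, c("df1", "df2"))
  expect_equal(panel$deficiencies$start, c(0, 40))
  # overlapping deficiencies on one arm are legal and informative
  expect_true(intervals_overlap(c(0, 60), c(40, 100)))
})

test_that("parse_panel rejects malformed input with the offending line", {
  arms <- toy_arms()
  expect_error(
    parse_panel(write_panel_file(c("A\t10\t10\tdf1")), arm_table = arms),
    "empty or inverted.*line 1"
  )
  expect_error(
    parse_panel(write_panel_file(c("A\t0\t50\tdf1", "Z\t0\t50\tdf2")),
                arm_table = arms),
    "unknown arm 'Z'.*line 2"
  )
  expect_error(
    parse_panel(write_panel_file(c("A\t0\t50\tdf1", "A\t10\t60\tdf1")),
                arm_table = arms),
    "duplicate stock_id 'df1'.*line 2"
  )
  expect_error(
    parse_panel(write_panel_file(c("A\t0\t50")), arm_table = arms),
    "malformed row at line 1"
  )
  expect_error(
    parse_panel(write_panel_file(c("A\t0\t5000\tdf1")), arm_table = arms),
    "outside arm bounds"
  )
})

test_that("interval overlap follows the half-open convention and is symmetric", {
  expect_false(intervals_overlap(c(0, 10), c(10, 20)))  # abutting
  expect_true(intervals_overlap(c(0, 10), c(5, 15)))
  expect_true(intervals_overlap(c(0, 10), c(0, 10)))    # identity
  set.seed(41)
  for (i in 1:50) {
    a <- sort(sample.int(100, 2)); b <- sort(sample.int(100, 2))
    if (a[1] == a[2]) a[2] <- a[2] + 1
    if (b[1] == b[2]) b[2] <- b[2] + 1
    expect_identical(intervals_overlap(a, b), intervals_overlap(b, a))
  }
})

test_that("coverage_fraction computes the euchromatic union fraction", {
  eu <- data.frame(arm = "A", start = 0, end = 200)
  panel <- toy_panel(
    defs = data.frame(arm = c("A", "A"), start = c(0, 40), end = c(60, 100),
                      stock_id = c("df1", "df2")),
    euchromatin = eu
  )
  expect_equal(coverage_fraction(panel), 0.5)  # union [0,100) over [0,200)

  full <- toy_panel(
    defs = data.frame(arm = "A", start = 0, end = 200, stock_id = "df1"),
    euchromatin = eu
  )
  expect_equal(coverage_fraction(full), 1.0)

  none <- toy_panel(defs = toy_panel()$deficiencies[0, ], euchromatin = eu)
  expect_equal(coverage_fraction(none), 0.0)

  expect_error(coverage_fraction(toy_panel()), "euchromatin")
})

test_that("coverage is monotone, order-invariant, and split-invariant", {
  eu <- data.frame(arm = "A", start = 0, end = 500)
  set.seed(7)
  defs <- as_hi_intervals(random_intervals(6, max_coord = 480, max_len = 60))
  cov_of <- function(d) coverage_fraction(toy_panel(defs = d, euchromatin = eu))
  base <- cov_of(defs)
  # adding a deficiency never decreases coverage
  more <- rbind(defs, data.frame(arm = "A", start = 400, end = 470,
                                 stock_id = "extra"))
  expect_gte(cov_of(more), base)
  # row order irrelevant
  expect_equal(cov_of(defs[sample(nrow(defs)), ]), base)
  # splitting one interval into two abutting halves changes nothing
  split1 <- defs
  mid <- floor((split1$start[1] + split1$end[1]) / 2)
  split1 <- rbind(split1,
                  data.frame(arm = "A", start = mid, end = split1$end[1],
                             stock_id = "half2"))
  split1$end[1] <- mid
  expect_equal(cov_of(split1), base)
})
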
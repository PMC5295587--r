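# small complete-case frame built directly: s stocks x 2 species x 2 temps
make_frame <- function(n_stock = 12, mean_fun = function(sp, tp) 0.5,
                       sd = 0, seed = 1, arms = c("X", "2L", "3R")) {
  set.seed(seed)
  grid <- expand.grid(stock_id = sprintf("df%03d", seq_len(n_stock)),
                      species = c("san", "sim"), temperature = c("18", "24"),
                      stringsAsFactors = FALSE)
  arm <- rep(arms, length.out = n_stock)[match(grid$stock_id,
                                               sprintf("df%03d", seq_len(n_stock)))]
  data.frame(
    stock_id = grid$stock_id,
    species = factor(grid$species, levels = c("san", "sim")),
    temperature = factor(grid$temperature, levels = c("18", "24")),
    chromosome = factor(arm_to_chromosome(arm)),
    response = mapply(mean_fun, grid$species, grid$temperature) +
      stats::rnorm(nrow(grid), 0, sd)
  )
}

test_that("model frame applies the complete-case rule and derives chromosomes", {
  records <- expand.grid(stock_id = c("df1", "df2", "df3"),
                         species = c("san", "sim"),
                         temperature = c("18", "24"),
                         stringsAsFactors = FALSE)
  records$n_df <- 40; records$n_bal <- 60
  records$total <- 100
  # df2 loses its sim/24 record entirely
  records <- records[!(records$stock_id == "df2" & records$species == "sim" &
                         records$temperature == "24"), ]
  records <- classify_hi(records)
  panel <- toy_panel(defs = data.frame(
    arm = c("A", "A", "B"), start = c(0, 100, 0), end = c(50, 150, 50),
    stock_id = c("df1", "df2", "df3")))
  frame <- build_model_frame(records, panel)
  expect_equal(nrow(frame), 8)                  # df2 dropped in all 4 cells
  expect_false("df2" %in% frame$stock_id)
  expect_true("df2" %in% attr(frame, "dropped"))
  expect_true(all(frame$response == 0.4))

  empty <- build_model_frame(records[0, ], panel)
  expect_equal(nrow(empty), 0)
  expect_error(fit_factorial_model(empty), "empty")
})

test_that("full synthetic panel yields the balanced 892-row frame and
           the factorial dof structure", {
  sc <- preset_scenario("san_like", seed = 2)
  panel <- generate_panel(sc)
  cls <- classify_hi(aggregate_counts(simulate_screen(panel, sc)))
  frame <- build_model_frame(cls, panel)
  expect_equal(nrow(frame), 223 * 4)

  av <- fit_factorial_model(frame)
  expect_equal(av$df[av$term == "Residuals"], 888)
  expect_equal(av$term[1:3],
               c("temperature", "species", "temperature:species"))

  m4 <- fit_cell_means_model(frame, factors = c("species", "temperature"))
  expect_equal(c(m4$df1, m4$df2), c(3, 888))

  m12 <- fit_cell_means_model(frame,
                              factors = c("chromosome", "species", "temperature"))
  expect_equal(m12$df2, 892 - 12)               # 880
  expect_equal(length(m12$cell_means), 12)
})

test_that("paired t-test matches hand computation and the regression oracle", {
  d <- c(0.1, 0.0, 0.2)
  frame <- make_frame(3, mean_fun = function(sp, tp) 0.5)
  frame$response[frame$species == "san" & frame$temperature == "18"] <- 0.5 + d
  res <- paired_t_test(frame, "san")
  expect_equal(res$mean_difference, 0.1)
  expect_equal(res$t_statistic, sqrt(3), tolerance = 1e-12)
  expect_equal(res$dof, 2)

  # t^2 equals the F of the intercept-only model on the differences
  set.seed(4)
  frame2 <- make_frame(15, sd = 0.05)
  res2 <- paired_t_test(frame2, "sim")
  x <- frame2$response[frame2$species == "sim" & frame2$temperature == "18"]
  y <- frame2$response[frame2$species == "sim" & frame2$temperature == "24"]
  fit <- stats::lm(I(x - y) ~ 1)
  expect_equal(res2$t_statistic^2,
               unname(stats::coef(summary(fit))[1, "t value"]^2),
               tolerance = 1e-10)

  # identical pairs: zero variance -> defined error path
  flat <- make_frame(5)
  expect_error(paired_t_test(flat, "san"), "zero variance")
})

test_that("sequential ANOVA decomposes variance exactly", {
  # pure species shift, no noise: species captures all model sum of squares
  delta <- 0.2
  frame <- make_frame(10, mean_fun = function(sp, tp)
    0.4 + ifelse(sp == "sim", delta, 0))
  av <- suppressWarnings(fit_factorial_model(frame))  # noise-free by design
  expect_equal(av$sum_sq[av$term == "temperature"], 0)
  expect_equal(av$sum_sq[av$term == "temperature:species"], 0)
  expect_equal(av$sum_sq[av$term == "species"], nrow(frame) * delta^2 / 4)

  # conservation: term + residual sums of squares equal total SS
  noisy <- make_frame(20, sd = 0.1, seed = 6)
  av2 <- fit_factorial_model(noisy)
  total_ss <- sum((noisy$response - mean(noisy$response))^2)
  expect_equal(sum(av2$sum_sq), total_ss, tolerance = 1e-9)

  # constant response: every term contributes nothing
  const <- make_frame(6)
  av3 <- suppressWarnings(fit_factorial_model(const))
  expect_true(all(av3$sum_sq[av3$term != "Residuals"] < 1e-20))
})

test_that("cell-means model recovers planted means and F = 0 under equality", {
  truth <- function(sp, tp) 0.35 + 0.1 * (sp == "sim") + 0.05 * (tp == "24")
  frame <- make_frame(40, mean_fun = truth, sd = 0.05, seed = 8)
  m <- fit_cell_means_model(frame, factors = c("species", "temperature"))
  for (cell in names(m$cell_means)) {
    parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
    se <- 0.05 / sqrt(40)
    expect_lt(abs(m$cell_means[cell] - truth(parts[1], parts[2])), 3 * se)
  }
  flat <- make_frame(6)
  mf <- fit_cell_means_model(flat, factors = c("species", "temperature"))
  expect_equal(mf$f_value, 0)
})

test_that("adjusted contrasts difference cell means with monotone adjustment", {
  frame <- make_frame(30, mean_fun = function(sp, tp)
    0.45 + 0.08 * (sp == "sim" & tp == "24"), sd = 0.05, seed = 9)
  m <- fit_cell_means_model(frame,
                            factors = c("chromosome", "species", "temperature"))
  fam <- within_species_temp_contrasts()
  res <- adjusted_contrasts(m, fam, seed = 1)
  expect_equal(nrow(res), 6)
  expect_equal(res$estimate, res$mean_1 - res$mean_2, tolerance = 1e-12)
  # adjusted p never beats the unadjusted two-sided p
  p_unadj <- 2 * stats::pt(-abs(res$t_value), df = m$df2)
  expect_true(all(res$p_adjusted >= p_unadj - 1e-8))

  # contrast of a cell with itself: estimate 0, p 1
  self <- adjusted_contrasts(m, list(c("X.sim.18", "X.sim.18")), seed = 1)
  expect_equal(self$estimate, 0)
  expect_equal(self$p_adjusted, 1)

  expect_error(adjusted_contrasts(m, list(c("X.sim.18", "5.sim.18"))),
               "unestimated cell")
})

test_that("temperature-restricted incompatibilities drive the interaction", {
  f_sim <- interaction_f("sim_like", seed = 101)
  f_san <- interaction_f("san_like", seed = 101)
  expect_gt(f_sim, f_san)
})
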
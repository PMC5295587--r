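# Small in-code fixtures shared across the suite.

toy_arms <- function() {
  data.frame(arm = c("A", "B"), length = c(1000, 800),
             chromosome = c("1", "2"), stringsAsFactors = FALSE)
}

toy_panel <- function(defs = NULL, euchromatin = NULL) {
  if (is.null(defs)) {
    defs <- data.frame(
      arm = c("A", "A", "B"),
      start = c(0, 40, 100),
      end = c(60, 100, 300),
      stock_id = c("df1", "df2", "df3"),
      stringsAsFactors = FALSE
    )
  }
  defscreen:::validate_panel(
    defscreen:::new_deficiency_panel(toy_arms(), defs, euchromatin)
  )
}

write_panel_file <- function(lines) {
  path <- tempfile("panel", fileext = ".tsv")
  writeLines(lines, path)
  path
}

random_intervals <- function(n, max_coord = 50, max_len = 20) {
  start <- sample.int(max_coord, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(start = start, end = start + len)
}

# interval set as an hi_set-shaped data.frame on one arm
as_hi_intervals <- function(ints, arm = "A") {
  data.frame(arm = rep(arm, nrow(ints)), start = ints$start, end = ints$end,
             stock_id = sprintf("df%03d", seq_len(nrow(ints))),
             stringsAsFactors = FALSE)
}

# fraction of crosses called HI in one null (no-locus) simulated screen
null_hi_call_rate <- function(seed, alpha = 0.05) {
  sc <- screen_scenario(seed = seed)
  panel <- generate_panel(sc)
  cls <- classify_hi(aggregate_counts(simulate_screen(panel, sc)),
                     alpha = alpha)
  mean(cls$hi_call[cls$testable])
}

# temperature x species interaction F from one simulated screen
interaction_f <- function(preset, seed) {
  sc <- preset_scenario(preset, seed = seed)
  panel <- generate_panel(sc)
  cls <- classify_hi(aggregate_counts(simulate_screen(panel, sc)))
  frame <- build_model_frame(cls, panel)
  av <- fit_factorial_model(frame)
  av$f_value[av$term == "temperature:species"]
}
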
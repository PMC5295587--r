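#' Assemble a pipeline run configuration
#'
#' Exactly one of `scenario` (a preset name or a `screen_scenario`) or the
#' `panel`/`counts` input paths must be supplied.
#'
#' @param scenario preset name (`"san_like"`, `"sim_like"`) or a
#'   `screen_scenario`, for simulated runs.
#' @param panel,counts paths to a panel TSV and a vial-level counts TSV,
#'   for runs on real data.
#' @param arm_table arm table path or data.frame (default [default_arms()]).
#' @param euchromatin optional euchromatin TSV path or data.frame.
#' @param alpha,min_total HI-call parameters (see [classify_hi()]).
#' @param permutations randomization-test permutations.
#' @param uniformity_replicates replicates for [arm_density_test()].
#' @param seed integer master seed.
#' @param out_dir output directory for the report bundle.
#' @return a `run_config` list.
#' @export
run_config <- function(scenario = NULL, panel = NULL, counts = NULL,
                       arm_table = default_arms(), euchromatin = NULL,
                       alpha = 0.05, min_total = 20L,
                       permutations = 100000L,
                       uniformity_replicates = 2000L,
                       seed = 1L, out_dir = "defscreen-report") {
  simulated <- !is.null(scenario)
  from_files <- !is.null(panel) && !is.null(counts)
  if (simulated == from_files) {
    stop("supply exactly one of: a scenario, or panel + counts paths",
         call. = FALSE)
  }
  structure(
    list(scenario = scenario, panel = panel, counts = counts,
         arm_table = arm_table, euchromatin = euchromatin, alpha = alpha,
         min_total = min_total, permutations = permutations,
         uniformity_replicates = uniformity_replicates,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

stage_log <- function(stage, ...) {
  message(sprintf("[defscreen] %-12s %s", stage, sprintf(...)))
}

#' Run the full deficiency-screen analysis
#'
#' Stages: panel (load or generate) → counts (load or simulate) →
#' per-cross viability and HI calls → per-condition locus resolution and
#' arm-uniformity tests → per-species between-temperature comparison →
#' paired t-tests, factorial ANOVA, cell-means models and adjusted
#' contrasts.  All randomness derives from `config$seed`, so a rerun with
#' the same configuration reproduces every text artifact byte for byte.
#' Results are written to `config$out_dir` via [write_report()].
#'
#' @param config a [run_config()].
#' @return invisibly, the results bundle (also written to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  if (!is.null(config$scenario)) {
    scenario <- config$scenario
    if (is.character(scenario)) {
      scenario <- preset_scenario(scenario, seed = seed)
    }
    panel <- generate_panel(scenario)
    stage_log("panel", "generated %d deficiencies on %d arms",
              nrow(panel$deficiencies), nrow(panel$arms))
    counts <- simulate_screen(panel, scenario)
    stage_log("simulate", "%d producing vials", nrow(counts))
  } else {
    scenario <- NULL
    panel <- parse_panel(config$panel, arm_table = config$arm_table,
                         euchromatin = config$euchromatin)
    stage_log("panel", "loaded %d deficiencies", nrow(panel$deficiencies))
    counts <- read_counts(config$counts)
    stage_log("counts", "loaded %d vial records", nrow(counts))
  }

  agg <- aggregate_counts(counts, panel = panel)
  classified <- classify_hi(agg, alpha = config$alpha,
                            min_total = config$min_total)
  stage_log("classify", "%d crosses, %d HI calls", nrow(classified),
            sum(classified$hi_call))

  species <- sort(unique(classified$species))
  temps <- sort(unique(classified$temperature))
  conditions <- expand.grid(species = species, temperature = temps,
                            stringsAsFactors = FALSE)

  hi_sets <- list()
  loci <- list()
  uniformity <- list()
  for (i in seq_len(nrow(conditions))) {
    sp <- conditions$species[i]; tp <- conditions$temperature[i]
    key <- paste(sp, tp, sep = "_")
    hs <- hi_set(classified, panel, sp, tp)
    hi_sets[[key]] <- hs
    est <- minimal_locus_count(hs)
    loci[[key]] <- est
    counts_per_arm <- table(factor(hs$intervals$arm, levels = panel$arms$arm))
    uniformity[[key]] <- if (sum(counts_per_arm) >= 1) {
      arm_density_test(as.integer(counts_per_arm),
                       replicates = config$uniformity_replicates,
                       seed = seed + i)
    }
    stage_log("loci", "%s: %d HI, %d clusters, %d minimal regions", key,
              est$n_members, est$component_count, est$minimal_count)
  }

  comparisons <- list()
  if (length(temps) == 2L) {
    for (j in seq_along(species)) {
      sp <- species[j]
      cl <- classified[classified$species == sp, , drop = FALSE]
      per_temp_testable <- split(cl$stock_id[cl$testable], cl$temperature[cl$testable])
      universe <- Reduce(intersect, per_temp_testable)
      a <- intersect(hi_sets[[paste(sp, temps[1L], sep = "_")]]$members, universe)
      b <- intersect(hi_sets[[paste(sp, temps[2L], sep = "_")]]$members, universe)
      comparisons[[sp]] <- compare_conditions(
        a, b, universe, permutations = config$permutations,
        seed = seed + 100L + j
      )
      stage_log("compare", "%s: universe %d, overlap %d, p_rand %.4g", sp,
                comparisons[[sp]]$n_universe, comparisons[[sp]]$n_both,
                comparisons[[sp]]$p_randomization)
    }
  }

  models <- list()
  if (length(species) == 2L && length(temps) == 2L) {
    frame <- build_model_frame(classified, panel,
                               species_levels = species,
                               temperature_levels = temps)
    models$frame <- frame
    stage_log("models", "complete-case frame: %d rows (%d stocks)",
              nrow(frame), length(unique(frame$stock_id)))
    if (nrow(frame) >= 8L) {
      models$paired <- lapply(stats::setNames(species, species),
                              function(sp) paired_t_test(frame, sp))
      models$anova <- fit_factorial_model(frame)
      models$cells_ts <- fit_cell_means_model(
        frame, factors = c("species", "temperature"))
      models$cells_cst <- tryCatch(
        fit_cell_means_model(frame,
                             factors = c("chromosome", "species", "temperature")),
        error = function(e) { stage_log("models", "12-cell model skipped: %s",
                                        conditionMessage(e)); NULL }
      )
      if (!is.null(models$cells_cst)) {
        fam <- within_species_temp_contrasts(species_levels = rev(species),
                                             temperature_levels = temps)
        models$contrasts <- adjusted_contrasts(models$cells_cst, fam,
                                               seed = seed + 200L)
      }
    }
  }

  results <- list(config = config, scenario = scenario, panel = panel,
                  counts = counts, classified = classified,
                  hi_sets = hi_sets, loci = loci, uniformity = uniformity,
                  comparisons = comparisons, models = models)
  write_report(results, config$out_dir)
  invisible(results)
}

summary_fields <- function() {
  c("seed", "alpha", "min_total", "n_deficiencies", "n_crosses",
    "hi_counts", "minimal_counts", "component_counts", "comparisons",
    "paired_tests", "anova", "interaction_cells")
}

build_summary <- function(results) {
  cfg <- results$config
  cls <- results$classified
  hi_counts <- lapply(results$hi_sets, function(h) length(h$members))
  summary <- list(
    seed = cfg$seed, alpha = cfg$alpha, min_total = cfg$min_total,
    n_deficiencies = nrow(results$panel$deficiencies),
    n_crosses = nrow(cls),
    hi_counts = hi_counts,
    minimal_counts = lapply(results$loci, `[[`, "minimal_count"),
    component_counts = lapply(results$loci, `[[`, "component_count"),
    comparisons = lapply(results$comparisons, function(cmp) {
      cmp[c("n_universe", "n_a", "n_b", "n_both", "n_only_a", "n_only_b",
            "p_randomization", "permutations", "p_hypergeometric")]
    }),
    paired_tests = lapply(results$models$paired, function(p) {
      p[c("n_pairs", "mean_difference", "t_statistic", "dof", "p_value")]
    }),
    anova = if (!is.null(results$models$anova)) {
      df <- results$models$anova
      lapply(split(df[c("df", "sum_sq", "mean_sq", "f_value", "p_value")],
                   seq_len(nrow(df))), as.list) |>
        stats::setNames(df$term)
    },
    interaction_cells = if (!is.null(results$models$cells_ts)) {
      m <- results$models$cells_ts
      list(f_value = m$f_value, df1 = m$df1, df2 = m$df2,
           p_value = m$p_value, cell_means = as.list(m$cell_means))
    }
  )
  summary
}

#' Validate a report summary against the bundled schema
#'
#' Checks that the machine-readable summary carries every field required by
#' `inst/schema/report-summary.schema.json`.
#'
#' @param summary a summary list (or a path to a summary JSON file).
#' @return `TRUE` invisibly; errors if required fields are missing.
#' @export
validate_summary <- function(summary) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  schema_path <- system.file("schema", "report-summary.schema.json",
                             package = "defscreen")
  schema <- jsonlite::read_json(schema_path)
  required <- unlist(schema$required)
  missing <- setdiff(required, names(summary))
  if (length(missing)) {
    stop("summary missing required fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write the report bundle
#'
#' Emits, under `out_dir`: the viability TSV; per-condition HI interval
#' tracks (BED: `arm  start  end  stock_id`); per-condition cluster tables
#' and representative points; comparison, paired-test, ANOVA and contrast
#' tables; viability histograms (PDF, with mean and mean ± SD lines); a
#' machine-readable `summary.json`; and an echo of the configuration.
#'
#' @param results the bundle returned by [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_viability(results$classified, p("viability.tsv"))
  write_panel(results$panel, p("panel.tsv"))

  for (key in names(results$hi_sets)) {
    hs <- results$hi_sets[[key]]
    bed <- hs$intervals[c("arm", "start", "end", "stock_id")]
    utils::write.table(bed, p(sprintf("hi_track_%s.bed", key)), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    est <- results$loci[[key]]
    utils::write.table(merge_overlapping_hi(hs)$clusters,
                       p(sprintf("clusters_%s.tsv", key)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(est$points, p(sprintf("loci_points_%s.tsv", key)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (length(results$comparisons)) {
    for (sp in names(results$comparisons)) {
      cmp <- results$comparisons[[sp]]
      ids <- data.frame(
        stock_id = c(cmp$shared, cmp$only_a, cmp$only_b),
        class = rep(c("both", "only_first", "only_second"),
                    c(length(cmp$shared), length(cmp$only_a),
                      length(cmp$only_b))),
        stringsAsFactors = FALSE
      )
      utils::write.table(ids, p(sprintf("overlap_members_%s.tsv", sp)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (!is.null(results$models$anova)) {
    utils::write.table(results$models$anova, p("anova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(results$models$contrasts)) {
    utils::write.table(results$models$contrasts, p("contrasts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # viability histograms per condition, mean and mean +/- SD marked
  grDevices::pdf(p("viability_histograms.pdf"), width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  cls <- results$classified
  for (key in names(results$hi_sets)) {
    hs <- results$hi_sets[[key]]
    v <- cls$v_hat[cls$species == hs$species &
                     cls$temperature == hs$temperature & cls$total > 0]
    if (!length(v)) next
    graphics::hist(v, breaks = seq(0, 1, by = 0.05),
                   main = sprintf("Relative viability, %s at %s°",
                                  hs$species, hs$temperature),
                   xlab = "df-class daughters / total daughters",
                   col = "grey85", border = "white")
    graphics::abline(v = mean(v), lwd = 2)
    graphics::abline(v = mean(v) + c(-1, 1) * stats::sd(v), lty = 2)
  }

  summary <- build_summary(results)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  cfg <- results$config
  cfg_echo <- cfg[!vapply(cfg, is.null, TRUE)]
  cfg_echo <- lapply(cfg_echo, function(x) {
    if (inherits(x, "screen_scenario")) "screen_scenario (inline)"
    else if (is.data.frame(x)) "data.frame (inline)" else x
  })
  jsonlite::write_json(cfg_echo, p("config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}
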
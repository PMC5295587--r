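#' Build a complete-case viability model frame
#'
#' One row per stock × species × temperature carrying the pooled relative
#' viability of deficiency-class daughters.  Only stocks with a defined
#' viability in all four condition cells are kept (complete-case rule), so
#' paired tests and the factorial models run on a balanced design.  The
#' chromosome factor is derived from the stock's arm (`2L`/`2R` collapse to
#' `2`, `3L`/`3R` to `3`).
#'
#' @param classified output of [classify_hi()] covering both species and
#'   both temperatures.
#' @param panel the `deficiency_panel` (source of arm annotations).
#' @param species_levels,temperature_levels condition labels, in factor
#'   order.
#' @return data.frame `stock_id`, `species`, `temperature`, `chromosome`
#'   (factors), `response`; attribute `"dropped"` lists incomplete stocks.
#' @export
build_model_frame <- function(classified, panel,
                              species_levels = c("san", "sim"),
                              temperature_levels = c("18", "24")) {
  rec <- classified[classified$total > 0, , drop = FALSE]
  rec <- rec[rec$species %in% species_levels &
               rec$temperature %in% temperature_levels, , drop = FALSE]
  cells_per_stock <- table(rec$stock_id)
  n_cells <- length(species_levels) * length(temperature_levels)
  complete <- names(cells_per_stock)[cells_per_stock == n_cells]
  dropped <- setdiff(unique(rec$stock_id), complete)
  rec <- rec[rec$stock_id %in% complete, , drop = FALSE]
  arm <- panel$deficiencies$arm[match(rec$stock_id,
                                      panel$deficiencies$stock_id)]
  if (anyNA(arm)) {
    stop("stock without arm annotation in the panel: ",
         rec$stock_id[which(is.na(arm))[1L]], call. = FALSE)
  }
  out <- data.frame(
    stock_id = rec$stock_id,
    species = factor(rec$species, levels = species_levels),
    temperature = factor(rec$temperature, levels = temperature_levels),
    chromosome = factor(arm_to_chromosome(arm)),
    response = rec$v_hat,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$stock_id, out$species, out$temperature), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Paired t-test of temperature effect within one species
#'
#' Per-stock viability at the first temperature level minus viability at
#' the second, tested against zero with a two-sided paired t-test.
#'
#' @param frame a model frame from [build_model_frame()].
#' @param species which species' crosses to test.
#' @return list `n_pairs`, `mean_difference`, `ci95`, `t_statistic`, `dof`,
#'   `p_value`.
#' @export
paired_t_test <- function(frame, species) {
  f <- frame[frame$species == species, , drop = FALSE]
  temps <- levels(frame$temperature)
  x <- f$response[f$temperature == temps[1L]][order(f$stock_id[f$temperature == temps[1L]])]
  y <- f$response[f$temperature == temps[2L]][order(f$stock_id[f$temperature == temps[2L]])]
  if (length(x) < 2L || length(x) != length(y)) {
    stop("need at least two complete pairs", call. = FALSE)
  }
  if (stats::sd(x - y) == 0) {
    stop("zero variance of paired differences; t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(n_pairs = length(x),
       mean_difference = unname(tt$estimate),
       ci95 = unname(tt$conf.int),
       t_statistic = unname(tt$statistic),
       dof = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Factorial ANOVA of viability
#'
#' Ordinary least squares on the stated fixed effects with sequential
#' (Type I) sums of squares in formula order; with the balanced
#' complete-case frame the sequential and marginal decompositions
#' coincide.  `F` for each term is its mean square over the residual mean
#' square.
#'
#' @param frame a model frame from [build_model_frame()].
#' @param formula model formula in `response` and the factor columns;
#'   default the temperature-by-species model
#'   `response ~ temperature + species + temperature:species`.
#' @return data.frame with rows per term plus `Residuals`: `term`, `df`,
#'   `sum_sq`, `mean_sq`, `f_value`, `p_value`; the fitted `lm` is attached
#'   as attribute `"model"`.
#' @export
fit_factorial_model <- function(frame,
                                formula = response ~ temperature + species +
                                  temperature:species) {
  if (nrow(frame) == 0L) stop("empty model frame", call. = FALSE)
  fit <- stats::lm(formula, data = frame)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design; aliased coefficients: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  av <- stats::anova(fit)
  out <- data.frame(term = rownames(av), df = av$Df, sum_sq = av$`Sum Sq`,
                    mean_sq = av$`Mean Sq`, f_value = av$`F value`,
                    p_value = av$`Pr(>F)`, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "model") <- fit
  out
}

#' Cell-means model on crossed condition factors
#'
#' Collapses the supplied factors into a single cell factor (4 cells for
#' temperature × species, 12 for chromosome × species × temperature) and
#' fits the one-factor cell-means model, reporting the overall F on
#' `(cells - 1, n - cells)` degrees of freedom.  When `chromosome` is among
#' the factors, stocks outside chromosomes X, 2, 3 are excluded so the
#' chromosome factor has the three canonical levels.
#'
#' @param frame a model frame from [build_model_frame()].
#' @param factors character vector of factor columns to cross, in the order
#'   used for cell labels (e.g. `c("chromosome", "species", "temperature")`).
#' @return list `model` (an `lm` with cell-mean coefficients), `cell_means`
#'   (named), `f_value`, `df1`, `df2`, `p_value`, `n`, `data`.
#' @export
fit_cell_means_model <- function(frame,
                                 factors = c("temperature", "species")) {
  stopifnot(all(factors %in% names(frame)))
  d <- frame
  if ("chromosome" %in% factors) {
    d <- d[d$chromosome %in% c("X", "2", "3"), , drop = FALSE]
    d$chromosome <- factor(as.character(d$chromosome),
                           levels = c("X", "2", "3"))
  }
  if (nrow(d) == 0L) stop("empty model frame", call. = FALSE)
  cell <- interaction(d[factors], sep = ".", lex.order = FALSE)
  cell <- droplevels(cell)
  tab <- table(cell)
  if (any(tab == 0)) {
    stop("empty cell(s): ", paste(names(tab)[tab == 0], collapse = ", "),
         call. = FALSE)
  }
  d$cell <- cell
  fit <- stats::lm(response ~ 0 + cell, data = d)
  means <- stats::coef(fit)
  names(means) <- sub("^cell", "", names(means))
  k <- nlevels(cell)
  n <- nrow(d)
  # overall F of the cell factor against the grand-mean model
  rss0 <- sum((d$response - mean(d$response))^2)
  rss1 <- sum(stats::resid(fit)^2)
  df1 <- k - 1L
  df2 <- n - k
  ms_cell <- max(rss0 - rss1, 0) / df1   # clamp rounding noise on flat data
  ms_resid <- rss1 / df2
  f <- if (df1 == 0) NA_real_
       else if (ms_resid == 0) { if (ms_cell == 0) 0 else Inf }
       else ms_cell / ms_resid
  list(model = fit, cell_means = means, f_value = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE), n = n,
       data = d)
}

#' Simultaneous (max-|t|) adjusted contrasts between cells
#'
#' Pairwise differences of cell means from a [fit_cell_means_model()] fit,
#' with family-wise adjusted p-values by the single-step max-|t| method
#' (the simultaneous-inference machinery behind Tukey-HSD-style post hoc
#' comparisons on a linear model), computed via [multcomp::glht()].  The
#' multivariate-t probabilities are quasi-Monte-Carlo; the seed makes them
#' reproducible.
#'
#' @param cell_fit result of [fit_cell_means_model()].
#' @param contrasts list of length-2 character vectors `c(cell_1, cell_2)`,
#'   each testing `mean(cell_1) - mean(cell_2) == 0`.
#' @param seed integer seed for the adjustment's integration.
#' @return data.frame `label`, `mean_1`, `mean_2`, `estimate`, `se`,
#'   `t_value`, `p_adjusted`.
#' @export
adjusted_contrasts <- function(cell_fit, contrasts, seed = 1L) {
  means <- cell_fit$cell_means
  cells <- names(means)
  K <- matrix(0, nrow = length(contrasts), ncol = length(cells),
              dimnames = list(NULL, paste0("cell", cells)))
  labels <- character(length(contrasts))
  for (i in seq_along(contrasts)) {
    pair <- contrasts[[i]]
    stopifnot(length(pair) == 2L)
    miss <- setdiff(pair, cells)
    if (length(miss)) {
      stop("contrast references an unestimated cell: ", miss[1L],
           call. = FALSE)
    }
    K[i, paste0("cell", pair[1L])] <- K[i, paste0("cell", pair[1L])] + 1
    K[i, paste0("cell", pair[2L])] <- K[i, paste0("cell", pair[2L])] - 1
    labels[i] <- paste(pair[1L], "-", pair[2L])
  }
  rownames(K) <- labels
  out <- data.frame(
    label = labels,
    mean_1 = unname(means[vapply(contrasts, `[`, "", 1L)]),
    mean_2 = unname(means[vapply(contrasts, `[`, "", 2L)]),
    estimate = 0, se = 0, t_value = 0, p_adjusted = 1,
    stringsAsFactors = FALSE
  )
  # a cell contrasted with itself is identically zero; it contributes
  # nothing to the max-|t| family and would degenerate the integration
  live <- rowSums(K != 0) > 0
  if (any(live)) {
    glht_fit <- multcomp::glht(cell_fit$model,
                               linfct = K[live, , drop = FALSE])
    set.seed(seed)
    sm <- summary(glht_fit, test = multcomp::adjusted("single-step"))
    out$estimate[live] <- unname(sm$test$coefficients)
    out$se[live] <- unname(sm$test$sigma)
    out$t_value[live] <- unname(sm$test$tstat)
    out$p_adjusted[live] <- unname(sm$test$pvalues)
  }
  out
}

#' The six within-species chromosome-by-temperature contrasts
#'
#' For the 12-cell chromosome × species × temperature model: the
#' temperature difference (second temperature minus first) within each
#' chromosome and species, i.e. six of the 66 possible pairwise
#' comparisons.
#'
#' @param species_levels,temperature_levels condition labels (defaults
#'   match [build_model_frame()]).
#' @return list of length-2 cell-label vectors for [adjusted_contrasts()].
#' @export
within_species_temp_contrasts <- function(species_levels = c("sim", "san"),
                                          temperature_levels = c("18", "24")) {
  out <- list()
  for (sp in species_levels) {
    for (chr in c("X", "2", "3")) {
      out[[length(out) + 1L]] <- c(
        paste(chr, sp, temperature_levels[2L], sep = "."),
        paste(chr, sp, temperature_levels[1L], sep = ".")
      )
    }
  }
  out
}
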
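#' Pool vial-level counts per cross
#'
#' Sums balancer-class and deficiency-class daughter counts over vials for
#' each stock × species × temperature, mirroring a screen in which vials
#' are kept until they stop producing and tallies are pooled per cross.
#'
#' @param counts vial-level data.frame (`stock_id`, `species`,
#'   `temperature`, `n_bal`, `n_df`).
#' @param panel optional `deficiency_panel`; when supplied, stocks of the
#'   panel with no progeny in some condition are listed in the
#'   `"no_progeny"` attribute of the result.
#' @return data.frame `stock_id`, `species`, `temperature`, `n_df`,
#'   `n_bal`, `total`, one row per cross with at least one vial.
#' @export
aggregate_counts <- function(counts, panel = NULL) {
  stopifnot(all(c("stock_id", "species", "temperature", "n_bal", "n_df")
                %in% names(counts)))
  if (!is.null(panel)) {
    unknown <- setdiff(unique(counts$stock_id), panel$deficiencies$stock_id)
    if (length(unknown)) {
      stop("counts refer to stock_id absent from the panel: ",
           unknown[1L], call. = FALSE)
    }
  }
  agg <- stats::aggregate(
    counts[c("n_df", "n_bal")],
    by = counts[c("stock_id", "species", "temperature")],
    FUN = sum
  )
  agg$total <- agg$n_df + agg$n_bal
  agg <- agg[order(agg$stock_id, agg$species, agg$temperature), ]
  rownames(agg) <- NULL
  if (!is.null(panel)) {
    full <- expand.grid(stock_id = panel$deficiencies$stock_id,
                        species = unique(counts$species),
                        temperature = unique(counts$temperature),
                        stringsAsFactors = FALSE)
    key <- function(d) paste(d$stock_id, d$species, d$temperature)
    missing <- full[!key(full) %in% key(agg), , drop = FALSE]
    rownames(missing) <- NULL
    attr(agg, "no_progeny") <- missing
  }
  agg
}

#' Relative viability of deficiency-class daughters
#'
#' `v = n_df / (n_df + n_bal)`: 0.5 when the two classes segregate 1:1,
#' 0 under complete lethality of the deficiency class.
#'
#' @param n_df,n_bal non-negative integer counts (vectorised).
#' @return fractions in `[0, 1]`.
#' @export
relative_viability <- function(n_df, n_bal) {
  if (any(n_df + n_bal == 0)) {
    stop("relative viability undefined for zero total progeny", call. = FALSE)
  }
  n_df / (n_df + n_bal)
}

#' Chi-square test of 1:1 segregation
#'
#' Tests the pooled balancer:deficiency daughter ratio against the 1:1
#' expectation of a balanced cross: statistic
#' \eqn{(n_{df} - n_{bal})^2 / (n_{df} + n_{bal})}, referred to the upper
#' tail of \eqn{\chi^2_1}, without continuity correction.  The statistic is
#' symmetric in its arguments; directionality enters only at the calling
#' stage ([classify_hi()]).
#'
#' @param n_df,n_bal non-negative integer counts (vectorised).
#' @return list with components `statistic` and `p_value`.
#' @export
chi2_ratio_test <- function(n_df, n_bal) {
  total <- n_df + n_bal
  if (any(total == 0)) {
    stop("chi-square ratio test undefined for zero total progeny",
         call. = FALSE)
  }
  stat <- (n_df - n_bal)^2 / total
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Call hybrid inviability per cross
#'
#' A cross is flagged HI when the deficiency class shows a significant
#' *dearth* relative to its balancer-class sisters: `p < alpha`,
#' `n_df < n_bal`, and at least `min_total` pooled daughters.  A
#' significant *excess* of deficiency-class daughters is never called HI.
#' Complete-lethal crosses (`n_df == 0` with `n_bal >= min_total`) are
#' always called HI.  Crosses under `min_total` are marked untestable.
#'
#' @param records aggregated counts from [aggregate_counts()].
#' @param alpha significance level for the per-cross test (default 0.05; no
#'   multiple-testing correction is applied by default).
#' @param min_total minimum pooled daughters for a testable cross.
#' @return the records annotated with `v_hat`, `chi2`, `p_value`,
#'   `testable`, `complete_lethal`, `hi_call`.
#' @export
classify_hi <- function(records, alpha = 0.05, min_total = 20L) {
  stopifnot(alpha > 0, alpha < 1, min_total >= 1)
  out <- records
  out$v_hat <- ifelse(out$total > 0, out$n_df / out$total, NA_real_)
  ok <- out$total > 0
  out$chi2 <- NA_real_
  out$p_value <- NA_real_
  if (any(ok)) {
    t2 <- chi2_ratio_test(out$n_df[ok], out$n_bal[ok])
    out$chi2[ok] <- t2$statistic
    out$p_value[ok] <- t2$p_value
  }
  out$testable <- out$total >= min_total
  out$complete_lethal <- out$n_df == 0 & out$n_bal > 0
  out$hi_call <- (out$testable & !is.na(out$p_value) & out$p_value < alpha &
                    out$n_df < out$n_bal) |
                 (out$n_df == 0 & out$n_bal >= min_total)
  out
}

#' Extract the HI set for one condition
#'
#' @param classified output of [classify_hi()].
#' @param panel the `deficiency_panel` supplying intervals.
#' @param species,temperature condition labels.
#' @return an `hi_set`: condition labels, member stock ids, and their
#'   arm-tagged intervals.
#' @export
hi_set <- function(classified, panel, species, temperature) {
  sel <- classified$species == species &
    classified$temperature == temperature & classified$hi_call
  members <- classified$stock_id[sel]
  ints <- panel$deficiencies[panel$deficiencies$stock_id %in% members,
                             c("arm", "start", "end", "stock_id")]
  rownames(ints) <- NULL
  structure(list(species = species, temperature = temperature,
                 members = members, intervals = ints),
            class = "hi_set")
}

#' @export
print.hi_set <- function(x, ...) {
  cat(sprintf("HI set %s/%s: %d deficiencies\n", x$species, x$temperature,
              length(x$members)))
  invisible(x)
}

#' Write a per-cross viability table
#'
#' @param classified output of [classify_hi()].
#' @param path output TSV path.
#' @export
write_viability <- function(classified, path) {
  cols <- c("stock_id", "species", "temperature", "n_df", "n_bal", "v_hat",
            "chi2", "p_value", "hi_call", "complete_lethal", "testable")
  utils::write.table(classified[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
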
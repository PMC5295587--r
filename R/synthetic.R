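#' Build a synthetic screen scenario
#'
#' A scenario bundles everything needed to simulate a two-species,
#' two-temperature deficiency screen: the panel geometry, the latent
#' incompatibility loci with condition-specific penetrance, and the
#' vial-level count model.  Progeny counts follow two independent Poisson
#' classes per producing vial: balancer-class daughters with mean `lambda`
#' and deficiency-class daughters with mean `lambda * v`, where `v` is the
#' product over uncovered loci of `1 - penetrance(locus, species,
#' temperature)`.
#'
#' @param n_deficiencies number of deficiencies tiled across the arms.
#' @param arms arm table (`arm`, `length`, `chromosome`).
#' @param tiling_overlap fraction in `[0, 1)` of each interval's length
#'   shared with its neighbour; 0 gives pairwise-disjoint tiles.
#' @param loci data.frame of latent loci: `arm`, `position`, and penetrance
#'   columns `pen_san_18`, `pen_san_24`, `pen_sim_18`, `pen_sim_24`
#'   (lethality probabilities in `[0, 1]`).  May have zero rows.
#' @param lambda mean progeny per class per producing vial (> 0).
#' @param vials_per_cross vials set up per cross (>= 1).
#' @param vial_fail_prob probability a vial yields no progeny at all.
#' @param seed integer seed governing all randomness in the scenario.
#' @return A `screen_scenario` list.
#' @export
screen_scenario <- function(n_deficiencies = 223L,
                            arms = default_arms(),
                            tiling_overlap = 0.35,
                            loci = empty_loci(),
                            lambda = 15,
                            vials_per_cross = 20L,
                            vial_fail_prob = 0.5,
                            seed = 1L) {
  stopifnot(lambda > 0, vials_per_cross >= 1,
            vial_fail_prob >= 0, vial_fail_prob < 1,
            tiling_overlap >= 0, tiling_overlap < 1,
            n_deficiencies >= 1)
  pen_cols <- c("pen_san_18", "pen_san_24", "pen_sim_18", "pen_sim_24")
  stopifnot(all(c("arm", "position", pen_cols) %in% names(loci)))
  if (nrow(loci)) {
    stopifnot(all(loci$arm %in% arms$arm))
    len <- arms$length[match(loci$arm, arms$arm)]
    stopifnot(all(loci$position >= 0 & loci$position < len))
    stopifnot(all(as.matrix(loci[pen_cols]) >= 0 & as.matrix(loci[pen_cols]) <= 1))
  }
  structure(
    list(n_deficiencies = as.integer(n_deficiencies), arms = arms,
         tiling_overlap = tiling_overlap, loci = loci, lambda = lambda,
         vials_per_cross = as.integer(vials_per_cross),
         vial_fail_prob = vial_fail_prob, seed = as.integer(seed)),
    class = "screen_scenario"
  )
}

empty_loci <- function() {
  data.frame(arm = character(0), position = numeric(0),
             pen_san_18 = numeric(0), pen_san_24 = numeric(0),
             pen_sim_18 = numeric(0), pen_sim_24 = numeric(0),
             stringsAsFactors = FALSE)
}

# draw loci with a given composition of temperature-shared and
# temperature-restricted penetrance classes, for one focal species
draw_loci <- function(arms, n_shared, n_only18, n_only24, species) {
  n <- n_shared + n_only18 + n_only24
  arm <- sample(arms$arm, n, replace = TRUE, prob = arms$length)
  position <- floor(stats::runif(n) * arms$length[match(arm, arms$arm)])
  p18 <- p24 <- numeric(n)
  cls <- rep(c("shared", "only18", "only24"), c(n_shared, n_only18, n_only24))
  p <- stats::runif(n, 0.55, 0.95)
  hi <- stats::runif(n, 0.8, 1)
  p18[cls == "shared"] <- p[cls == "shared"]
  p24[cls == "shared"] <- p[cls == "shared"]
  p18[cls == "only18"] <- hi[cls == "only18"]
  p24[cls == "only24"] <- hi[cls == "only24"]
  loci <- data.frame(arm = arm, position = position,
                     pen_san_18 = 0, pen_san_24 = 0,
                     pen_sim_18 = 0, pen_sim_24 = 0,
                     stringsAsFactors = FALSE)
  loci[[paste0("pen_", species, "_18")]] <- p18
  loci[[paste0("pen_", species, "_24")]] <- p24
  loci
}

#' Preset screen scenarios
#'
#' Two scenario families mirroring the contrast between the study's hybrid
#' genotypes:
#'
#' * `san_like` — a dense map: 70 latent loci in the paternal genome, most
#'   (60) with penetrance equal at the two temperatures, plus 5 restricted
#'   to each temperature.  Temperature shifts the incompatibility landscape
#'   little, so the temperature-by-species interaction is weak.
#' * `sim_like` — a sparse, temperature-contingent map: 15 loci, 9 lethal
#'   only at 24\eqn{\degree}, 5 only at 18\eqn{\degree}, 1 shared, so
#'   viability depends strongly on rearing temperature.
#'
#' @param name `"san_like"` or `"sim_like"`.
#' @param seed integer seed; loci draws are reproducible given the seed.
#' @param ... further arguments passed to [screen_scenario()] (e.g.
#'   `lambda`, `vials_per_cross`).
#' @return A `screen_scenario`.
#' @export
preset_scenario <- function(name, seed = 1L, ...) {
  presets <- c("san_like", "sim_like")
  if (!is.character(name) || length(name) != 1L || !name %in% presets) {
    stop("unknown preset; available presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  arms <- default_arms()
  set.seed(seed)
  loci <- switch(name,
    san_like = draw_loci(arms, n_shared = 60, n_only18 = 5, n_only24 = 5,
                         species = "san"),
    sim_like = draw_loci(arms, n_shared = 1, n_only18 = 5, n_only24 = 9,
                         species = "sim")
  )
  screen_scenario(loci = loci, seed = seed, ...)
}

#' Generate a tiled deficiency panel
#'
#' Each arm receives a share of the deficiencies proportional to its length
#' (largest-remainder rounding so the total is exact).  Intervals on an arm
#' all have the same length and are spaced so that adjacent intervals share
#' `tiling_overlap` of their length; the tiles span the whole arm.  The
#' construction is deterministic, so the same scenario always yields the
#' same panel.
#'
#' @param scenario a `screen_scenario`.
#' @return A `deficiency_panel`.
#' @export
generate_panel <- function(scenario) {
  arms <- scenario$arms
  n <- scenario$n_deficiencies
  o <- scenario$tiling_overlap
  share <- n * arms$length / sum(arms$length)
  n_arm <- floor(share)
  rem <- n - sum(n_arm)
  if (rem > 0) {
    extra <- order(share - n_arm, decreasing = TRUE)[seq_len(rem)]
    n_arm[extra] <- n_arm[extra] + 1L
  }
  defs <- vector("list", nrow(arms))
  for (i in seq_len(nrow(arms))) {
    k <- n_arm[i]
    L <- arms$length[i]
    if (k == 0L) next
    # interval length so that k tiles with pairwise overlap o*len span [0, L)
    len <- L / (k - (k - 1) * o)
    if (len < 1 || len > L) {
      stop(sprintf("infeasible tiling on arm %s: %d intervals of length %.1f",
                   arms$arm[i], k, len), call. = FALSE)
    }
    step <- len * (1 - o)
    start <- floor((seq_len(k) - 1L) * step)
    end <- pmin(floor(start + len), L)
    defs[[i]] <- data.frame(
      arm = arms$arm[i], start = start, end = end,
      stock_id = sprintf("Df_%s_%03d", arms$arm[i], seq_len(k)),
      stringsAsFactors = FALSE
    )
  }
  panel <- new_deficiency_panel(
    arms, do.call(rbind, defs),
    euchromatin = data.frame(arm = arms$arm, start = 0, end = arms$length,
                             stringsAsFactors = FALSE)
  )
  validate_panel(panel)
}

# survival multiplier v for every deficiency x species x temperature
survival_table <- function(panel, loci) {
  defs <- panel$deficiencies
  conds <- expand.grid(species = c("san", "sim"), temperature = c("18", "24"),
                       stringsAsFactors = FALSE)
  out <- defs[rep(seq_len(nrow(defs)), each = nrow(conds)),
              c("stock_id", "arm", "start", "end")]
  out$species <- rep(conds$species, times = nrow(defs))
  out$temperature <- rep(conds$temperature, times = nrow(defs))
  out$v <- 1
  if (nrow(loci)) {
    for (r in seq_len(nrow(out))) {
      hit <- loci$arm == out$arm[r] &
        loci$position >= out$start[r] & loci$position < out$end[r]
      if (any(hit)) {
        pen <- loci[[paste0("pen_", out$species[r], "_", out$temperature[r])]][hit]
        out$v[r] <- prod(1 - pen)
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate progeny counts for a deficiency screen
#'
#' For every deficiency × species × temperature cross, `vials_per_cross`
#' vials are attempted; each yields progeny with probability
#' `1 - vial_fail_prob`.  A producing vial contributes independent Poisson
#' counts: `n_bal ~ Pois(lambda)` and `n_df ~ Pois(lambda * v)`, with `v`
#' the multiplicative survival of deficiency-class daughters given the loci
#' the deletion uncovers.  Vials that fail produce no row.  All randomness
#' is drawn from one generator seeded with `scenario$seed`, in fixed order
#' (vial fates, then balancer counts, then deficiency counts), so the same
#' scenario always yields an identical table.
#'
#' @param panel a `deficiency_panel` (typically from [generate_panel()]).
#' @param scenario the `screen_scenario` holding loci and count parameters.
#' @return data.frame with columns `stock_id`, `species`, `temperature`,
#'   `vial_id`, `n_bal`, `n_df`.
#' @export
simulate_screen <- function(panel, scenario) {
  surv <- survival_table(panel, scenario$loci)
  set.seed(scenario$seed)
  nv <- scenario$vials_per_cross
  grid <- surv[rep(seq_len(nrow(surv)), each = nv), ]
  grid$vial_id <- rep(seq_len(nv), times = nrow(surv))
  produced <- stats::runif(nrow(grid)) >= scenario$vial_fail_prob
  grid$n_bal <- 0L
  grid$n_df <- 0L
  grid$n_bal[produced] <- stats::rpois(sum(produced), scenario$lambda)
  grid$n_df[produced] <- stats::rpois(sum(produced),
                                      scenario$lambda * grid$v[produced])
  out <- grid[produced, c("stock_id", "species", "temperature", "vial_id",
                          "n_bal", "n_df")]
  rownames(out) <- NULL
  out
}

#' Write simulated counts / truth tables
#'
#' `write_counts` writes the progeny-count TSV consumed by
#' [aggregate_counts()]; `write_truth` writes the planted loci with their
#' four condition penetrances, for parameter-recovery checks.
#'
#' @param counts data.frame from [simulate_screen()].
#' @param scenario a `screen_scenario`.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
write_truth <- function(scenario, path) {
  utils::write.table(scenario$loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a progeny-count TSV
#'
#' Columns `stock_id  species  temperature  vial_id  n_bal  n_df`;
#' `#`-comments and an optional header are ignored.
#'
#' @param path path to the counts TSV.
#' @return data.frame of vial-level counts.
#' @export
read_counts <- function(path) {
  cols <- c("stock_id", "species", "temperature", "vial_id", "n_bal", "n_df")
  raw <- read_screen_tsv(path, cols)
  if (is.null(raw$data)) stop("counts file is empty: ", path, call. = FALSE)
  df <- raw$data
  df$n_bal <- as_coord(df$n_bal, raw$line, path, "n_bal")
  df$n_df <- as_coord(df$n_df, raw$line, path, "n_df")
  if (any(df$n_bal < 0 | df$n_df < 0)) {
    stop("negative counts in ", path, call. = FALSE)
  }
  df
}
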
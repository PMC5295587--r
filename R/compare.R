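members_of <- function(x) {
  if (inherits(x, "hi_set")) x$members else as.character(x)
}

#' Partition two HI sets over a common universe
#'
#' Exact set arithmetic on stock ids, restricted to the universe of stocks
#' testable in both conditions: shared calls, calls specific to each
#' condition, and the marginal set sizes.
#'
#' @param a,b `hi_set` objects or character vectors of stock ids.
#' @param universe character vector of stock ids testable in both
#'   conditions; both sets must lie inside it.
#' @return an `overlap_result` (counts and id lists; randomization fields
#'   unset — see [compare_conditions()]).
#' @export
partition_hi_sets <- function(a, b, universe) {
  a <- unique(members_of(a))
  b <- unique(members_of(b))
  universe <- unique(as.character(universe))
  out_a <- setdiff(a, universe)
  out_b <- setdiff(b, universe)
  if (length(out_a) || length(out_b)) {
    stop("HI set member outside the comparison universe: ",
         c(out_a, out_b)[1L], call. = FALSE)
  }
  both <- intersect(a, b)
  structure(
    list(n_universe = length(universe), n_a = length(a), n_b = length(b),
         n_both = length(both), n_only_a = length(a) - length(both),
         n_only_b = length(b) - length(both),
         shared = both, only_a = setdiff(a, b), only_b = setdiff(b, a),
         p_randomization = NA_real_, permutations = NA_integer_,
         p_hypergeometric = NA_real_),
    class = "overlap_result"
  )
}

check_overlap_counts <- function(n_universe, n_a, n_b, n_both,
                                 strict = TRUE) {
  if (n_a > n_universe || n_b > n_universe) {
    stop("set larger than universe", call. = FALSE)
  }
  if (n_both < 0) stop("negative overlap is infeasible", call. = FALSE)
  lo <- max(0, n_a + n_b - n_universe)
  if (strict && (n_both < lo || n_both > min(n_a, n_b))) {
    stop(sprintf("infeasible overlap %d for sets of %d and %d in universe %d",
                 n_both, n_a, n_b, n_universe), call. = FALSE)
  }
}

#' Randomization test for HI-set overlap
#'
#' Null model: redraw set A as a uniformly random subset of size `n_a` from
#' the universe, holding set B fixed, and recompute the overlap.  The
#' returned p-value is the upper-tail (enrichment) estimate
#' `(1 + #{draws with overlap >= n_both}) / (permutations + 1)`; a
#' depletion tail is available via `alternative = "less"`.  This simple
#' label-shuffling null is exactly the hypergeometric distribution, which
#' [hypergeometric_tail()] computes in closed form as an oracle.
#'
#' @param n_universe number of stocks testable in both conditions.
#' @param n_a,n_b HI-set sizes; `n_both` their observed overlap.
#' @param permutations number of random subsets drawn (default 1e5).
#' @param seed optional integer seed.
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return the Monte-Carlo p-value.
#' @export
overlap_randomization_test <- function(n_universe, n_a, n_b, n_both,
                                       permutations = 100000L, seed = NULL,
                                       alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  check_overlap_counts(n_universe, n_a, n_b, n_both)
  if (permutations < 1) stop("permutations must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # stocks 1..n_b represent set B; overlap of a random subset is the count
  # of drawn ids landing in B
  exceed <- 0L
  for (i in seq_len(permutations)) {
    ov <- sum(sample.int(n_universe, n_a) <= n_b)
    if (alternative == "greater") {
      if (ov >= n_both) exceed <- exceed + 1L
    } else {
      if (ov <= n_both) exceed <- exceed + 1L
    }
  }
  (1 + exceed) / (permutations + 1)
}

#' Hypergeometric upper tail for set overlap
#'
#' Closed-form oracle for [overlap_randomization_test()]:
#' `P(X >= n_both)` where `X` is hypergeometric with population
#' `n_universe`, `n_b` successes, and `n_a` draws.
#'
#' Tail queries beyond the feasible overlap range are legal (an overlap
#' exceeding `min(n_a, n_b)` is simply impossible, so its tail is 0).
#'
#' @inheritParams overlap_randomization_test
#' @return the exact tail probability.
#' @export
hypergeometric_tail <- function(n_universe, n_a, n_b, n_both) {
  check_overlap_counts(n_universe, n_a, n_b, n_both, strict = FALSE)
  stats::phyper(n_both - 1, m = n_b, n = n_universe - n_b, k = n_a,
                lower.tail = FALSE)
}

#' Full between-condition comparison
#'
#' Partitions two HI sets over the universe and attaches the randomization
#' p-value and its hypergeometric oracle.
#'
#' @inheritParams partition_hi_sets
#' @inheritParams overlap_randomization_test
#' @return an `overlap_result` with all fields populated.
#' @export
compare_conditions <- function(a, b, universe, permutations = 100000L,
                               seed = NULL) {
  res <- partition_hi_sets(a, b, universe)
  res$p_randomization <- overlap_randomization_test(
    res$n_universe, res$n_a, res$n_b, res$n_both,
    permutations = permutations, seed = seed
  )
  res$permutations <- as.integer(permutations)
  res$p_hypergeometric <- hypergeometric_tail(
    res$n_universe, res$n_a, res$n_b, res$n_both
  )
  res
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap: %d/%d and %d/%d share %d (only-A %d, only-B %d)\n",
              x$n_a, x$n_universe, x$n_b, x$n_universe, x$n_both,
              x$n_only_a, x$n_only_b))
  if (!is.na(x$p_randomization)) {
    cat(sprintf("  randomization p = %.4g (%d permutations); hypergeometric p = %.4g\n",
                x$p_randomization, x$permutations, x$p_hypergeometric))
  }
  invisible(x)
}
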
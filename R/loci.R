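intervals_of <- function(hi) {
  if (inherits(hi, "hi_set")) hi$intervals else hi
}

#' Merge overlapping HI deficiencies into clusters
#'
#' Connected components of the interval-overlap graph, computed per arm by
#' an end-point sweep: overlapping deficiencies flagged in the same
#' condition are assumed to share a causal locus, so a chain of mutually
#' overlapping deletions collapses into one cluster.  Note that a chain can
#' lack a common intersection, so the component count is a lower bound on
#' the number of causal regions; see [minimal_locus_count()].
#'
#' @param hi an `hi_set` or a data.frame with `arm`, `start`, `end`,
#'   `stock_id`.
#' @return list with `component_count` and `clusters` (data.frame `arm`,
#'   `span_start`, `span_end`, `n_members`, `member_ids`).
#' @export
merge_overlapping_hi <- function(hi) {
  ints <- intervals_of(hi)
  clusters <- list()
  for (arm in unique(ints$arm)) {
    a <- ints[ints$arm == arm, , drop = FALSE]
    a <- a[order(a$start, a$end), , drop = FALSE]
    cur_end <- -Inf
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      data.frame(arm = arm, span_start = min(cur$start),
                 span_end = max(cur$end), n_members = nrow(cur),
                 member_ids = paste(cur$stock_id, collapse = ","),
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(a))) {
      if (a$start[i] >= cur_end) {           # half-open: abutting starts anew
        clusters[[length(clusters) + 1L]] <- flush(cur)
        cur <- a[i, , drop = FALSE]
        cur_end <- a$end[i]
      } else {
        cur <- rbind(cur, a[i, , drop = FALSE])
        cur_end <- max(cur_end, a$end[i])
      }
    }
    clusters[[length(clusters) + 1L]] <- flush(cur)
  }
  clusters <- do.call(rbind, clusters)
  if (is.null(clusters)) {
    clusters <- data.frame(arm = character(0), span_start = numeric(0),
                           span_end = numeric(0), n_members = integer(0),
                           member_ids = character(0), stringsAsFactors = FALSE)
  }
  list(component_count = nrow(clusters), clusters = clusters)
}

greedy_stab_arm <- function(start, end) {
  o <- order(end, start)
  start <- start[o]; end <- end[o]
  points <- numeric(0)
  covered <- rep(FALSE, length(start))
  for (i in seq_along(start)) {
    if (covered[i]) next
    p <- end[i] - 1                          # rightmost point of [start, end)
    points <- c(points, p)
    covered <- covered | (start <= p & p < end)
  }
  points
}

#' Minimal number of causal regions for an HI set
#'
#' The minimum number of point loci such that every HI-flagged deficiency
#' interval contains at least one point (a minimum stabbing set), computed
#' per arm by the classical greedy rule — sort by interval end, place a
#' point at the end of the first uncovered interval, discard all intervals
#' containing it — and summed over arms.  The greedy rule is exact for
#' interval stabbing; [brute_force_min_cover()] provides an exhaustive
#' cross-check for small inputs.  The overlap-cluster count is reported
#' alongside, and always satisfies
#' `component_count <= minimal_count <= n_members`.
#'
#' @param hi an `hi_set` or a data.frame with `arm`, `start`, `end`,
#'   `stock_id`.
#' @return a `locus_estimate`: list with `minimal_count`,
#'   `component_count`, `n_members`, and `points` (data.frame `arm`,
#'   `position` of representative loci).
#' @export
minimal_locus_count <- function(hi) {
  ints <- intervals_of(hi)
  pts <- list()
  for (arm in unique(ints$arm)) {
    a <- ints[ints$arm == arm, , drop = FALSE]
    p <- greedy_stab_arm(a$start, a$end)
    pts[[arm]] <- data.frame(arm = arm, position = p,
                             stringsAsFactors = FALSE)
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(arm = character(0), position = numeric(0))
  rownames(points) <- NULL
  structure(
    list(minimal_count = nrow(points),
         component_count = merge_overlapping_hi(ints)$component_count,
         n_members = nrow(ints),
         points = points),
    class = "locus_estimate"
  )
}

#' @export
print.locus_estimate <- function(x, ...) {
  cat(sprintf("%d HI deficiencies -> %d overlap clusters, minimal causal regions: %d\n",
              x$n_members, x$component_count, x$minimal_count))
  invisible(x)
}

#' Exact minimum stabbing set by exhaustive search
#'
#' Test oracle for [minimal_locus_count()] on one arm: enumerates all
#' subsets of candidate points (the `end - 1` coordinate of each interval)
#' and returns the size of the smallest subset covering every interval.
#' Refuses more than 12 intervals.
#'
#' @param intervals data.frame with `start`, `end` (one arm).
#' @return integer minimum number of stabbing points.
#' @export
brute_force_min_cover <- function(intervals) {
  n <- nrow(intervals)
  if (n == 0L) return(0L)
  if (n > 12L) stop("brute force limited to 12 intervals", call. = FALSE)
  cand <- unique(intervals$end - 1)
  m <- length(cand)
  # coverage bitmask over intervals for each candidate point
  mask <- vapply(cand, function(p) {
    sum(2^(which(intervals$start <= p & p < intervals$end) - 1L))
  }, numeric(1))
  full <- 2^n - 1
  # dynamic programme over all candidate subsets
  cov <- numeric(2^m)
  size <- integer(2^m)
  best <- n
  for (s in seq_len(2^m - 1)) {
    low <- bitwAnd(s, -s)
    j <- as.integer(log2(low)) + 1L
    cov[s + 1] <- bitwOr(cov[s - low + 1], mask[j])
    size[s + 1] <- size[s - low + 1] + 1L
    if (cov[s + 1] == full && size[s + 1] < best) best <- size[s + 1]
  }
  as.integer(best)
}

#' Uniformity test for HI-allele density across arms
#'
#' Pearson goodness-of-fit statistic against equal expected counts per arm,
#' with a simulated (Monte-Carlo) p-value: null replicates are multinomial
#' draws of the total over the arms with uniform probabilities, and
#' `p = (1 + #{replicate >= observed}) / (replicates + 1)`.
#'
#' @param per_arm_counts named integer vector of HI counts per arm (k >= 2).
#' @param replicates number of null replicates (default 2000).
#' @param seed optional integer seed for the null draws.
#' @return a `uniformity_result`: list with `per_arm_counts`, `statistic`,
#'   `p_simulated`, `replicates`, `dof`.
#' @export
arm_density_test <- function(per_arm_counts, replicates = 2000L, seed = NULL) {
  k <- length(per_arm_counts)
  n <- sum(per_arm_counts)
  if (k < 2L) stop("need counts for at least two arms", call. = FALSE)
  if (n < 1) stop("total count must be at least 1", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  expected <- n / k
  stat <- sum((per_arm_counts - expected)^2 / expected)
  if (!is.null(seed)) set.seed(seed)
  null_draws <- stats::rmultinom(replicates, size = n, prob = rep(1 / k, k))
  null_stat <- colSums((null_draws - expected)^2 / expected)
  # tolerance against ties at the observed statistic, as in simulated
  # goodness-of-fit practice
  exceed <- sum(null_stat >= stat * (1 - 64 * .Machine$double.eps))
  structure(
    list(per_arm_counts = per_arm_counts, statistic = stat,
         p_simulated = (1 + exceed) / (replicates + 1),
         replicates = as.integer(replicates), dof = k - 1L),
    class = "uniformity_result"
  )
}

#' @export
print.uniformity_result <- function(x, ...) {
  cat(sprintf("Arm-density uniformity: X-squared = %.4f, simulated p = %.4g (%d replicates)\n",
              x$statistic, x$p_simulated, x$replicates))
  invisible(x)
}
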
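#' Default chromosome-arm table
#'
#' The five major arms of the *D. melanogaster* genome with approximate
#' euchromatic lengths (bp) and the chromosome each arm belongs to.  Arms
#' are configurable throughout the package; this table is the default used
#' by the synthetic simulator and by [parse_panel()] when no arm table is
#' supplied.
#'
#' @return A data.frame with columns `arm`, `length`, `chromosome`.
#' @export
default_arms <- function() {
  data.frame(
    arm        = c("X", "2L", "2R", "3L", "3R"),
    length     = c(23542271, 23513712, 25286936, 28110227, 32079331),
    chromosome = c("X", "2", "2", "3", "3"),
    stringsAsFactors = FALSE
  )
}

#' Map arm labels to chromosome labels
#'
#' `X` maps to `X`; `2L`/`2R` to `2`; `3L`/`3R` to `3`; `4` to `4`.
#'
#' @param arm character vector of arm names.
#' @return character vector of chromosome labels.
#' @export
arm_to_chromosome <- function(arm) {
  sub("[LR]$", "", as.character(arm))
}

# Read a headered-or-headerless TSV, skipping '#' comments; returns the
# data.frame plus the original file line number of each row (for error
# messages that point at the offending line).
read_screen_tsv <- function(path, columns) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(list(data = NULL, line = integer(0)))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  # optional header row
  if (identical(trimws(fields[[1L]]), columns)) {
    keep <- keep[-1L]
    fields <- fields[-1L]
  }
  bad <- which(lengths(fields) != length(columns))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s: expected %d tab-separated fields",
                 keep[bad[1L]], path, length(columns)), call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- columns
  list(data = df, line = keep)
}

# Coerce a character column to integer, erroring with the file line number.
as_coord <- function(x, line, path, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) | out != floor(out))
  if (length(bad)) {
    stop(sprintf("non-integer %s at line %d of %s: '%s'",
                 what, line[bad[1L]], path, x[bad[1L]]), call. = FALSE)
  }
  out
}

new_deficiency_panel <- function(arms, deficiencies, euchromatin = NULL) {
  structure(
    list(arms = arms, deficiencies = deficiencies, euchromatin = euchromatin),
    class = "deficiency_panel"
  )
}

validate_panel <- function(panel, path = "<panel>", line = NULL) {
  arms <- panel$arms
  defs <- panel$deficiencies
  stopifnot(all(c("arm", "length", "chromosome") %in% names(arms)),
            all(c("arm", "start", "end", "stock_id") %in% names(defs)))
  if (any(arms$length <= 0)) stop("arm lengths must be positive", call. = FALSE)
  if (is.null(line)) line <- seq_len(nrow(defs))
  where <- function(i) sprintf("line %d of %s", line[i], path)

  unknown <- which(!defs$arm %in% arms$arm)
  if (length(unknown)) {
    stop(sprintf("unknown arm '%s' at %s", defs$arm[unknown[1L]],
                 where(unknown[1L])), call. = FALSE)
  }
  empty <- which(defs$end <= defs$start)
  if (length(empty)) {
    stop(sprintf("empty or inverted interval [%s, %s) at %s",
                 defs$start[empty[1L]], defs$end[empty[1L]],
                 where(empty[1L])), call. = FALSE)
  }
  len <- arms$length[match(defs$arm, arms$arm)]
  oob <- which(defs$start < 0 | defs$end > len)
  if (length(oob)) {
    stop(sprintf("interval outside arm bounds at %s", where(oob[1L])),
         call. = FALSE)
  }
  dup <- which(duplicated(defs$stock_id))
  if (length(dup)) {
    stop(sprintf("duplicate stock_id '%s' at %s", defs$stock_id[dup[1L]],
                 where(dup[1L])), call. = FALSE)
  }
  if (!is.null(panel$euchromatin)) {
    eu <- panel$euchromatin
    if (any(!eu$arm %in% arms$arm)) {
      stop("euchromatin interval on unknown arm", call. = FALSE)
    }
    elen <- arms$length[match(eu$arm, arms$arm)]
    if (any(eu$start < 0 | eu$end > elen | eu$end <= eu$start)) {
      stop("euchromatin interval outside arm bounds or empty", call. = FALSE)
    }
  }
  panel
}

#' Read and validate a deficiency panel
#'
#' The panel file is a TSV with columns `arm  start  end  stock_id`
#' (BED-compatible column order with the stock identifier in column 4);
#' coordinates are 0-based, half-open integers.  `#`-prefixed lines and an
#' optional header row are ignored.  Overlapping deficiencies on an arm are
#' legal — overlap between adjacent deletions is what makes minimal-region
#' counting informative.
#'
#' @param path path to the panel TSV.
#' @param arm_table path to a TSV `arm  length  chromosome`, or a
#'   data.frame of the same shape; defaults to [default_arms()].
#' @param euchromatin optional path to a TSV `arm  start  end` of
#'   euchromatic intervals, or an equivalent data.frame.
#' @return A `deficiency_panel`: list with components `arms`,
#'   `deficiencies` (row order as in the file) and `euchromatin`.
#' @export
parse_panel <- function(path, arm_table = default_arms(), euchromatin = NULL) {
  if (is.character(arm_table)) {
    raw <- read_screen_tsv(arm_table, c("arm", "length", "chromosome"))
    arm_table <- raw$data
    arm_table$length <- as_coord(arm_table$length, raw$line, "arm table", "length")
  }
  raw <- read_screen_tsv(path, c("arm", "start", "end", "stock_id"))
  if (is.null(raw$data)) {
    defs <- data.frame(arm = character(0), start = numeric(0),
                       end = numeric(0), stock_id = character(0),
                       stringsAsFactors = FALSE)
    return(new_deficiency_panel(arm_table, defs, read_euchromatin(euchromatin)))
  }
  defs <- raw$data
  defs$start <- as_coord(defs$start, raw$line, path, "start")
  defs$end <- as_coord(defs$end, raw$line, path, "end")
  panel <- new_deficiency_panel(arm_table, defs, read_euchromatin(euchromatin))
  validate_panel(panel, path = path, line = raw$line)
}

read_euchromatin <- function(euchromatin) {
  if (is.null(euchromatin) || is.data.frame(euchromatin)) return(euchromatin)
  raw <- read_screen_tsv(euchromatin, c("arm", "start", "end"))
  eu <- raw$data
  eu$start <- as_coord(eu$start, raw$line, euchromatin, "start")
  eu$end <- as_coord(eu$end, raw$line, euchromatin, "end")
  eu
}

#' @export
print.deficiency_panel <- function(x, ...) {
  cat(sprintf("Deficiency panel: %d deficiencies on %d arms (%s)\n",
              nrow(x$deficiencies), nrow(x$arms),
              paste(x$arms$arm, collapse = ", ")))
  if (!is.null(x$euchromatin)) {
    cat(sprintf("  euchromatin table: %d intervals; coverage %.4f\n",
                nrow(x$euchromatin), coverage_fraction(x)))
  }
  invisible(x)
}

#' Do two half-open intervals overlap?
#'
#' Intervals are `[start, end)` on the same arm; abutting intervals
#' (`end == start`) do not overlap.
#'
#' @param a,b numeric length-2 vectors `c(start, end)`.
#' @return `TRUE` iff the intervals share at least one base.
#' @export
intervals_overlap <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L, a[1L] < a[2L], b[1L] < b[2L])
  a[1L] < b[2L] && b[1L] < a[2L]
}

# 0-based half-open -> IRanges (1-based closed)
as_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

#' Fraction of euchromatin covered by the panel
#'
#' The union of (deficiency intersected with euchromatin) widths, divided by
#' total euchromatin width, summed over arms.  Requires the panel to carry a
#' euchromatin table.
#'
#' @param panel a `deficiency_panel`.
#' @return fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(panel) {
  eu <- panel$euchromatin
  if (is.null(eu)) {
    stop("coverage_fraction requires a euchromatin table in the panel",
         call. = FALSE)
  }
  defs <- panel$deficiencies
  total <- 0
  covered <- 0
  for (arm in unique(eu$arm)) {
    e <- eu[eu$arm == arm, , drop = FALSE]
    er <- IRanges::reduce(as_iranges(e$start, e$end))
    total <- total + sum(IRanges::width(er))
    d <- defs[defs$arm == arm, , drop = FALSE]
    if (nrow(d) == 0L) next
    dr <- IRanges::reduce(as_iranges(d$start, d$end))
    covered <- covered + sum(IRanges::width(IRanges::intersect(dr, er)))
  }
  if (total == 0) stop("euchromatin table has zero total width", call. = FALSE)
  covered / total
}

#' Write a panel's deficiency table as TSV
#'
#' @param panel a `deficiency_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel$deficiencies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
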
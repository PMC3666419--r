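#' Resolve fractional filter thresholds to integer carrier counts
#'
#' Converts "at least a fraction `p_affected` of affected individuals are
#' carriers" and "at most a fraction `p_control` of controls are carriers"
#' into integer thresholds: `X = ceiling(p_affected * n_affected)` (the
#' smallest carrier count satisfying the fraction) and `Y = floor(p_control *
#' n_controls)` (the largest count satisfying it). A small numerical guard
#' protects integral products against binary floating-point fuzz (e.g.
#' `0.9 * 50` is not exactly 45 in double precision).
#'
#' @param p_affected Fraction in \[0, 1\]: minimum fraction of affected
#'   carriers.
#' @param p_control Fraction in \[0, 1\]: maximum fraction of control
#'   carriers.
#' @param n_affected Positive integer: number of affected individuals.
#' @param n_controls Nonnegative integer: number of controls.
#'
#' @return Named integer vector `c(min_affected = X, max_controls = Y)`.
#'
#' @examples
#' resolve_thresholds(0.8, 0.2, 10, 10)  # X = 8, Y = 2
#' resolve_thresholds(0.8, 0.2, 5, 5)    # X = 4, Y = 1
#' @export
resolve_thresholds <- function(p_affected, p_control = 0,
                               n_affected, n_controls = 0L) {
  for (p in c(p_affected, p_control)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("threshold fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  check_count_vector(n_affected, "n_affected", minimum = 1L)
  check_count_vector(n_controls, "n_controls")
  eps <- 1e-9
  c(min_affected = as.integer(ceiling(p_affected * n_affected - eps)),
    max_controls = as.integer(floor(p_control * n_controls + eps)))
}

#' Expected candidate SNVs for an arbitrary design (front door)
#'
#' Single entry point dispatching to the unrelated or full-sib filtered
#' expectation according to the cohort design. Thresholds may be given as
#' integer carrier counts or as fractions (resolved with
#' [resolve_thresholds()]).
#'
#' @param mode `"dominant"` or `"recessive"`.
#' @param relatedness `"unrelated"` or `"full_sib"`.
#' @param n_affected Positive integer: affected individuals.
#' @param n_controls Nonnegative integer: control individuals.
#' @param min_affected Integer carrier threshold `X`; alternative to
#'   `min_affected_frac`.
#' @param max_controls Integer carrier threshold `Y`; alternative to
#'   `max_controls_frac`. Default 0 (no control may carry).
#' @param min_affected_frac,max_controls_frac Fractional thresholds in
#'   \[0, 1\]; exactly one of the count/fraction pair may be supplied.
#' @inheritParams expected_sfs_derived
#'
#' @return Expected number of SNVs passing the filter.
#'
#' @examples
#' expected_snvs("dominant", "unrelated", n_affected = 10, n_controls = 10,
#'               min_affected_frac = 0.8, max_controls_frac = 0.2,
#'               theta = 13333)  # 28.51
#' @export
expected_snvs <- function(mode = c("dominant", "recessive"),
                          relatedness = c("unrelated", "full_sib"),
                          n_affected, n_controls = 0L,
                          min_affected = NULL, max_controls = NULL,
                          min_affected_frac = NULL, max_controls_frac = NULL,
                          theta = 13333) {
  mode <- check_mode(mode)
  relatedness <- match.arg(relatedness)
  if (!is.null(min_affected) && !is.null(min_affected_frac)) {
    stop("supply 'min_affected' or 'min_affected_frac', not both",
         call. = FALSE)
  }
  if (!is.null(max_controls) && !is.null(max_controls_frac)) {
    stop("supply 'max_controls' or 'max_controls_frac', not both",
         call. = FALSE)
  }
  if (is.null(min_affected)) {
    if (is.null(min_affected_frac)) {
      stop("an affected-carrier threshold is required", call. = FALSE)
    }
    min_affected <- resolve_thresholds(min_affected_frac, 0, n_affected,
                                       n_controls)[["min_affected"]]
  }
  if (is.null(max_controls)) {
    max_controls <- if (is.null(max_controls_frac)) 0L else
      resolve_thresholds(0, max_controls_frac, n_affected,
                         n_controls)[["max_controls"]]
  }
  if (relatedness == "unrelated") {
    expected_filtered_casecontrol(n_affected, n_controls, mode,
                                  min_affected, max_controls, theta)
  } else {
    expected_sib_filtered_casecontrol(n_affected, n_controls, mode,
                                      min_affected, max_controls, theta)
  }
}

## ---------------------------------------------------------------------------
## Reference grid reproduction
##
## The published reference grids share one layout: 15 sample sizes by 8
## design/filter columns. Columns 1-3 use all N individuals as affected with
## 100% / 90% / 80% carrier thresholds; columns 4-8 split the cohort into
## affected and controls. Cells whose fractional thresholds are not integral
## for the row's design (e.g. 90% of N = 5) are undefined and left NA, as in
## the published grids.

table_rows <- c(1L, 2L, 3L, 4L, 5L, 10L, 11L, 13L, 20L, 21L, 23L, 50L, 51L,
                53L, 100L)

# Per-column design: affected/control sizes as functions of N, threshold
# fractions, and the N values for which the published grids define the cell.
table_columns <- function() {
  list(
    list(label = "Na=N 100%",              n_a = function(n) n,
         n_c = function(n) 0L, p_a = 1.0, p_c = 0,
         defined = table_rows),
    list(label = "Na=N 90%",               n_a = function(n) n,
         n_c = function(n) 0L, p_a = 0.9, p_c = 0,
         defined = c(10L, 20L, 50L, 100L)),
    list(label = "Na=N 80%",               n_a = function(n) n,
         n_c = function(n) 0L, p_a = 0.8, p_c = 0,
         defined = c(5L, 10L, 20L, 50L, 100L)),
    list(label = "Na=N/2 Nc=N/2 100%a 0%c", n_a = function(n) n %/% 2L,
         n_c = function(n) n %/% 2L, p_a = 1.0, p_c = 0,
         defined = c(2L, 4L, 10L, 20L)),
    list(label = "Na=N-1 Nc=1 100%a 0%c",  n_a = function(n) n - 1L,
         n_c = function(n) 1L, p_a = 1.0, p_c = 0,
         defined = c(2L, 3L, 4L, 5L, 10L, 11L, 13L, 20L, 21L, 23L, 50L)),
    list(label = "Na=N-1 Nc=1 >=80%a 0%c", n_a = function(n) n - 1L,
         n_c = function(n) 1L, p_a = 0.8, p_c = 0,
         defined = c(11L, 21L, 51L)),
    list(label = "Na=N-3 Nc=3 >=80%a 0%c", n_a = function(n) n - 3L,
         n_c = function(n) 3L, p_a = 0.8, p_c = 0,
         defined = c(13L, 23L, 53L)),
    list(label = "Na=N/2 Nc=N/2 >=80%a <=20%c", n_a = function(n) n %/% 2L,
         n_c = function(n) n %/% 2L, p_a = 0.8, p_c = 0.2,
         defined = c(10L, 20L, 50L))
  )
}

# table_id -> (relatedness, mode)
table_design <- function(table_id) {
  switch(as.character(table_id),
         "2" = list(relatedness = "unrelated", mode = "dominant"),
         "3" = list(relatedness = "unrelated", mode = "recessive"),
         "4" = list(relatedness = "full_sib", mode = "dominant"),
         "5" = list(relatedness = "full_sib", mode = "recessive"),
         stop("'table_id' must be 2, 3, 4 or 5", call. = FALSE))
}

#' Reproduce a published reference grid of expected SNV counts
#'
#' Recomputes one of the four published grids of expected candidate SNV
#' counts: grid 2 (unrelated, dominant), 3 (unrelated, recessive), 4
#' (full-sibs, dominant), 5 (full-sibs, recessive). Each grid has 15 sample
#' sizes N and 8 design/filter columns (all-affected with 100%/90%/80%
#' thresholds; affected/control splits N/2+N/2, (N-1)+1 and (N-3)+3 with
#' stringent or 80%/20% thresholds). Cells the published grids leave blank
#' are returned as `NA`.
#'
#' @param table_id Integer in `2:5` selecting the grid.
#' @inheritParams expected_sfs_derived
#'
#' @return A data frame of class `"snv_table"` with column `N` and one
#'   numeric column per design; attributes `table_id`, `mode` and
#'   `relatedness`.
#'
#' @examples
#' grid <- reproduce_table(3, theta = 13333)
#' grid[grid$N == 20, 2]  # 333.33
#' @export
reproduce_table <- function(table_id, theta = 13333) {
  theta <- as_theta(theta)
  design <- table_design(table_id)
  cols <- table_columns()
  out <- data.frame(N = table_rows)
  for (j in seq_along(cols)) {
    col <- cols[[j]]
    vals <- rep(NA_real_, length(table_rows))
    for (k in seq_along(table_rows)) {
      n <- table_rows[k]
      if (!(n %in% col$defined)) next
      n_a <- col$n_a(n)
      n_c <- col$n_c(n)
      thr <- resolve_thresholds(col$p_a, col$p_c, n_a, n_c)
      vals[k] <- expected_snvs(design$mode, design$relatedness, n_a, n_c,
                               min_affected = thr[["min_affected"]],
                               max_controls = thr[["max_controls"]],
                               theta = theta)
    }
    out[[col$label]] <- vals
  }
  structure(out, table_id = table_id, mode = design$mode,
            relatedness = design$relatedness,
            class = c("snv_table", "data.frame"))
}

#' Write an expected-SNV grid as TSV or CSV
#'
#' Serialises a [reproduce_table()] grid with two-decimal cells, `"NA"` for
#' undefined cells, a `.` decimal separator and no thousands separators, so
#' the file re-parses to the printed precision regardless of locale.
#'
#' @param x An `"snv_table"` data frame.
#' @param file Connection or path; `""` (default) writes to standard output.
#' @param format `"tsv"` (default) or `"csv"`.
#'
#' @return Invisibly, the character matrix that was written.
#' @export
write_snv_table <- function(x, file = "", format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "snv_table") || is.data.frame(x))
  m <- as.matrix(cbind(
    N = format(x$N, trim = TRUE, scientific = FALSE),
    vapply(x[-1L], function(col) {
      ifelse(is.na(col), "NA", formatC(col, format = "f", digits = 2))
    }, character(nrow(x)))
  ))
  colnames(m) <- names(x)
  utils::write.table(m, file = file, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(m)
}

#' @export
print.snv_table <- function(x, ...) {
  cat(sprintf("Expected SNV grid %s (%s, %s)\n",
              attr(x, "table_id"), attr(x, "mode"), attr(x, "relatedness")))
  print.data.frame(x, digits = 8, row.names = FALSE)
  invisible(x)
}
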
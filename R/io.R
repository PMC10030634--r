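# Canonical visit-table columns.  Units are embedded in the names (_C, _Wm2,
# _mW) because the W/mW boundary is the most dangerous unit mix-up in this
# model.
VISIT_REQUIRED <- c("T_a_C", "T_hd_C", "T_th_C", "T_ab_C", "G_Wm2")
VISIT_OPTIONAL <- c("visit_id", "M_mW", "condition")

#' Validate and normalise a visit table
#'
#' A visit table is a data.frame with one row per stay at a flower and
#' columns `T_a_C`, `T_hd_C`, `T_th_C`, `T_ab_C` (surface and air
#' temperatures, degC), `G_Wm2` (global radiation, W m^-2), and optionally
#' `visit_id`, `M_mW` (measured energy turnover, mW; may contain `NA`) and
#' `condition` (feeding-regime label).  `as_visits()` checks column
#' presence, numeric types, temperatures above absolute zero and
#' non-negative radiation, and (re)derives the logical `is_sun` column from
#' the 100 W m^-2 shade/sunshine threshold.
#'
#' @param x A data.frame.
#' @return The validated data.frame with class `c("bee_visits",
#'   "data.frame")` and a consistent `is_sun` column.
#' @examples
#' as_visits(data.frame(
#'   T_a_C = 20, T_hd_C = 30, T_th_C = 38, T_ab_C = 24, G_Wm2 = 50
#' ))
#' @export
as_visits <- function(x) {
  if (inherits(x, "bee_visits")) {
    return(x)
  }
  if (!is.data.frame(x)) {
    stop("a visit table must be a data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(VISIT_REQUIRED, names(x))
  if (length(missing_cols)) {
    stop("visit table lacks required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in c(VISIT_REQUIRED, intersect("M_mW", names(x)))) {
    if (!is.numeric(x[[col]])) {
      stop("visit column '", col, "' must be numeric", call. = FALSE)
    }
  }
  for (col in c("T_a_C", "T_hd_C", "T_th_C", "T_ab_C")) {
    bad <- which(x[[col]] <= -273.15)
    if (length(bad)) {
      stop(sprintf(
        "row %d, column %s: temperature at or below absolute zero",
        bad[1], col
      ), call. = FALSE)
    }
  }
  bad <- which(x$G_Wm2 < 0)
  if (length(bad)) {
    stop(sprintf("row %d, column G_Wm2: negative global radiation", bad[1]),
      call. = FALSE
    )
  }
  x$is_sun <- is_sunshine(x$G_Wm2)
  class(x) <- c("bee_visits", "data.frame")
  x
}

#' Read / write a visit table
#'
#' Visit tables are plain comma-separated text with a header, decimal
#' points, UTF-8, and the canonical column names (units embedded):
#' `visit_id, T_a_C, T_hd_C, T_th_C, T_ab_C, G_Wm2, M_mW, condition`.
#' Missing measured energy turnover is an empty cell, never a sentinel
#' number.  `read_visits()` validates every row (see [as_visits()]) and
#' derives `is_sun`; errors name the offending row and column.
#' `write_visits()` drops the derived `is_sun` column so that a read/write
#' round trip is value-identical.
#'
#' @param path CSV file path.
#' @return `read_visits()`: a validated visit table.  `write_visits()`: the
#'   path, invisibly.
#' @examples
#' v <- simulate_visits(synthetic_config(n_visits = 3), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_visits(v, f)
#' head(read_visits(f))
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) {
    stop("visit file not found: ", path, call. = FALSE)
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_visits(x)
}

#' @rdname read_visits
#' @param visits A visit table.
#' @export
write_visits <- function(visits, path) {
  visits <- as_visits(visits)
  out <- as.data.frame(visits)
  out$is_sun <- NULL
  keep <- c(
    intersect("visit_id", names(out)),
    VISIT_REQUIRED,
    intersect(c("M_mW", "condition"), names(out)),
    setdiff(names(out), c(VISIT_OPTIONAL, VISIT_REQUIRED))
  )
  utils::write.csv(out[, unique(keep), drop = FALSE], path,
    row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8", na = ""
  )
  invisible(path)
}
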
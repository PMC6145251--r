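#' Extraction kinetics series
#'
#' Container for one experiment's time--concentration observations: time in
#' minutes and solvent-phase concentration of the extracted compound in
#' mg/100 g, plus condition metadata (e.g. the agitation frequency of the
#' medium).
#'
#' @param times Strictly increasing times in minutes, `>= 0`.
#' @param concentrations Nonnegative concentrations (mg/100 g), same length.
#' @param condition_label Free-text condition label, e.g. `"150 rpm"`.
#' @param temperature Extraction temperature in degrees C (metadata only).
#' @param x_eq Optional known equilibrium concentration (mg/100 g).
#' @return A `kinetics_series` object (list with the validated fields).
#' @examples
#' kinetics_series(c(0, 10, 30, 130), c(0, 5.2, 9.8, 13.0), "150 rpm")
#' @export
kinetics_series <- function(times, concentrations, condition_label = "unlabelled",
                            temperature = 35, x_eq = NULL) {
  if (!is.numeric(times) || !is.numeric(concentrations)) {
    stop("`times` and `concentrations` must be numeric", call. = FALSE)
  }
  if (length(times) != length(concentrations)) {
    stop("`times` and `concentrations` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be finite and >= 0 (minutes)", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    stop("`concentrations` must be finite and >= 0 (mg/100 g)", call. = FALSE)
  }
  if (!is.null(x_eq)) {
    stopifnot(is.numeric(x_eq), length(x_eq) == 1L, is.finite(x_eq), x_eq > 0)
  }
  structure(
    list(
      times = as.numeric(times),
      concentrations = as.numeric(concentrations),
      condition_label = as.character(condition_label),
      temperature = as.numeric(temperature),
      x_eq = x_eq
    ),
    class = "kinetics_series"
  )
}

#' @export
print.kinetics_series <- function(x, ...) {
  cat(sprintf(
    "<kinetics_series> %s: %d observations, t = %g..%g min, X = %.3g..%.3g mg/100 g%s\n",
    x$condition_label, length(x$times),
    min(x$times), max(x$times),
    min(x$concentrations), max(x$concentrations),
    if (is.null(x$x_eq)) "" else sprintf(", x_eq = %.4g", x$x_eq)
  ))
  invisible(x)
}

#' @export
as.data.frame.kinetics_series <- function(x, ...) {
  data.frame(
    time_min = x$times,
    concentration = x$concentrations,
    condition = x$condition_label,
    stringsAsFactors = FALSE
  )
}

#' Read kinetics series from CSV
#'
#' Reads delimited text with header columns `time_min` and `concentration`.
#' A long-format file may carry an additional `condition` column, in which
#' case one series per condition is returned.
#'
#' @param path Path to a CSV file.
#' @param condition_label Label for a single-condition file without a
#'   `condition` column; defaults to the file name.
#' @param temperature Temperature metadata attached to each series.
#' @return A single `kinetics_series`, or a named list of them for a
#'   long-format file.
#' @export
read_kinetics_csv <- function(path, condition_label = NULL, temperature = 35) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("malformed CSV '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (nrow(df) == 0L) {
    stop(sprintf("input file '%s' contains no observations", path), call. = FALSE)
  }
  need <- c("time_min", "concentration")
  if (!all(need %in% names(df))) {
    stop(sprintf(
      "input file '%s' must have columns %s (found: %s)",
      path, paste(need, collapse = ", "), paste(names(df), collapse = ", ")
    ), call. = FALSE)
  }
  if ("condition" %in% names(df)) {
    conds <- unique(df$condition)
    out <- lapply(conds, function(cc) {
      sub <- df[df$condition == cc, , drop = FALSE]
      sub <- sub[order(sub$time_min), , drop = FALSE]
      kinetics_series(sub$time_min, sub$concentration,
                      condition_label = cc, temperature = temperature)
    })
    stats::setNames(out, conds)
  } else {
    if (is.null(condition_label)) {
      condition_label <- sub("\\.[^.]*$", "", basename(path))
    }
    df <- df[order(df$time_min), , drop = FALSE]
    kinetics_series(df$time_min, df$concentration,
                    condition_label = condition_label,
                    temperature = temperature)
  }
}

#' Write kinetics series to CSV
#'
#' Writes the same dialect [read_kinetics_csv()] reads: columns `time_min`,
#' `concentration`, `condition`. A list of series is written long-format.
#'
#' @param series A `kinetics_series` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinetics_csv <- function(series, path) {
  if (inherits(series, "kinetics_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
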
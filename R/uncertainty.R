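#' Combine relative standard uncertainties in quadrature
#'
#' Uncorrelated relative standard uncertainties (percent, 1 SD) combine as
#' the square root of the sum of squares. The running cumulative column of
#' a film-dosimetry uncertainty budget is exactly this applied step by
#' step: 1.40% and 0.71% give 1.57%, adding a 1.00% film-measurement step
#' gives 1.86%.
#'
#' @param values numeric vector of components (% at 1 SD, all >= 0).
#' @return combined uncertainty (% at 1 SD), full precision.
#' @export
combine_quadrature <- function(values) {
  if (length(values) == 0) stop_input("no components to combine")
  if (any(values < 0)) stop_input("uncertainty components must be >= 0")
  sqrt(sum(values^2))
}

#' Expand a standard uncertainty by a coverage factor
#'
#' `k = 2` converts a combined standard uncertainty (1 SD) to an expanded
#' uncertainty at roughly 95% coverage.
#'
#' @param u combined standard uncertainty (% at 1 SD, >= 0).
#' @param k coverage factor (> 0).
#' @return expanded uncertainty `k * u`.
#' @export
expand_uncertainty <- function(u, k = 2) {
  if (any(u < 0)) stop_input("uncertainty must be >= 0")
  if (k <= 0) stop_input("coverage factor must be > 0")
  k * u
}

#' Build an uncertainty budget
#'
#' Ordered components with their running quadrature cumulative and the
#' final coverage-factor expansion. Values are stored at full precision;
#' display rounds to two decimals.
#'
#' @param components named numeric vector or data.frame with `label` and
#'   `value` columns (% at 1 SD).
#' @param k coverage factor for the expanded row.
#' @return an object of class `uncertainty_budget`.
#' @export
uncertainty_budget <- function(components, k = 2) {
  if (is.data.frame(components)) {
    labels <- as.character(components$label)
    values <- as.numeric(components$value)
  } else {
    values <- as.numeric(components)
    labels <- names(components) %||% paste("Step", seq_along(values))
  }
  if (length(values) == 0) stop_input("empty budget")
  if (any(values < 0)) stop_input("uncertainty components must be >= 0")
  cumulative <- sqrt(cumsum(values^2))
  structure(list(labels = labels, values = values, cumulative = cumulative,
                 k = k,
                 combined = cumulative[length(cumulative)],
                 expanded = expand_uncertainty(cumulative[length(cumulative)], k)),
            class = "uncertainty_budget")
}

#' Render an uncertainty budget as a table
#'
#' Produces the budget in the conventional layout: one row per component
#' with its per-step and cumulative uncertainty (1 SD, two decimals for
#' display), and a final combined-expanded row at the coverage factor.
#' Optionally writes a CSV that round-trips through
#' [read_budget_csv()].
#'
#' @param budget an [uncertainty_budget()].
#' @param csv_path optional CSV destination.
#' @return list with `text` (character lines) and `table` (data.frame),
#'   invisibly printed.
#' @export
render_budget <- function(budget, csv_path = NULL) {
  if (!inherits(budget, "uncertainty_budget")) stop_input("not a budget")
  tab <- data.frame(source = budget$labels,
                    step_pct_1sd = budget$values,
                    cumulative_pct_1sd = budget$cumulative)
  lines <- c(
    sprintf("%-55s %12s %16s", "Source of uncertainty", "Step (1SD) %",
            "Cumulative (1SD) %"),
    sprintf("%-55s %12.2f %16.2f", tab$source, tab$step_pct_1sd,
            tab$cumulative_pct_1sd),
    sprintf("%-55s %12s %16.2f",
            sprintf("Combined expanded uncertainty (k=%g)", budget$k), "-",
            budget$expanded))
  if (!is.null(csv_path)) {
    out <- rbind(tab, data.frame(
      source = sprintf("Combined expanded (k=%g)", budget$k),
      step_pct_1sd = NA_real_, cumulative_pct_1sd = budget$expanded))
    write.csv(cbind(out, k = budget$k), csv_path, row.names = FALSE)
  }
  list(text = lines, table = tab)
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(render_budget(x)$text, sep = "\n")
  invisible(x)
}

#' Read an uncertainty budget back from CSV
#'
#' Inverse of the CSV written by [render_budget()].
#'
#' @param path CSV path.
#' @return an [uncertainty_budget()].
#' @export
read_budget_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  comp <- df[!is.na(df$step_pct_1sd), ]
  uncertainty_budget(data.frame(label = comp$source,
                                value = comp$step_pct_1sd),
                     k = df$k[1])
}

#' Read budget components from a JSON definition
#'
#' Accepts `{"components": [{"label": ..., "value": ...}, ...], "k": 2}`
#' or a plain label -> value object.
#'
#' @param path JSON path.
#' @param k coverage factor override (default: the file's, else 2).
#' @return an [uncertainty_budget()].
#' @export
read_budget_json <- function(path, k = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$components)) {
    comp <- j$components
    kk <- k %||% j$k %||% 2
    uncertainty_budget(data.frame(label = comp$label, value = comp$value),
                       k = kk)
  } else {
    uncertainty_budget(unlist(j), k = k %||% 2)
  }
}
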
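# bin edges and significance thresholds per observable kind
.deviation_spec <- list(
  noe = list(edges = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30), threshold = 0.1,
             unit = "nm"),
  j   = list(edges = c(1, 2, 3, 4, 5), threshold = 2, unit = "Hz"),
  s2  = list(edges = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5), threshold = 0.2,
             unit = ""))

#' Histogram of deviations over half-open bins
#'
#' Bins are `[e1, e2), [e2, e3), ..., [e_{n-1}, e_n), [e_n, Inf)`; values
#' below the first edge are not counted.
#'
#' @param values non-negative deviations
#' @param edges increasing bin edges
#' @return named integer vector of counts, one per bin
#' @export
deviation_histogram_counts <- function(values, edges) {
  stopifnot(all(diff(edges) > 0))
  k <- length(edges)
  counts <- integer(k)
  for (i in seq_len(k - 1))
    counts[i] <- sum(values >= edges[i] & values < edges[i + 1])
  counts[k] <- sum(values >= edges[k])
  names(counts) <- c(paste0(utils::head(edges, -1), "-", edges[-1]),
                     paste0(">", edges[k]))
  counts
}

#' Deviation report against experimental values
#'
#' Scores calculated against experimental observables: per-record deviation
#' `|calc - exp|`, the standard histogram binning for the observable kind
#' (NOE violations in nm, 3J deviations in Hz, S2 deviations), and the
#' count of significant deviations (at least 0.1 nm, 2 Hz, or 0.2
#' respectively).
#'
#' @param calc calculated values
#' @param exp_vals experimental values (same length); for `kind = "noe"`
#'   pass the violation sizes directly as `calc` and leave `exp_vals` NULL
#' @param kind `"noe"`, `"j"` or `"s2"`
#' @return object of class `"deviation_report"`: `records` (calc, exp,
#'   deviation), `histogram`, `edges`, `threshold`, `n_significant`
#' @export
deviation_report <- function(calc, exp_vals = NULL,
                             kind = c("noe", "j", "s2")) {
  kind <- match.arg(kind)
  spec <- .deviation_spec[[kind]]
  if (is.null(exp_vals)) {
    dev <- calc
    records <- data.frame(deviation = dev)
  } else {
    if (length(calc) != length(exp_vals))
      stop("calculated and experimental value sets differ in length")
    dev <- abs(calc - exp_vals)
    records <- data.frame(calc = calc, exp = exp_vals, deviation = dev)
  }
  structure(list(records = records,
                 histogram = deviation_histogram_counts(dev, spec$edges),
                 edges = spec$edges, threshold = spec$threshold,
                 unit = spec$unit, kind = kind,
                 n_significant = sum(dev >= spec$threshold)),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("deviation report (%s): %d records, %d significant (>= %g %s)\n",
              x$kind, nrow(x$records), x$n_significant, x$threshold, x$unit))
  print(x$histogram)
  invisible(x)
}
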
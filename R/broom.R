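# broom-style accessors for scan results and pipeline runs

#' Tidy and summarize selection-scan results
#'
#' `tidy()` returns the per-site score table as a plain tibble;
#' `glance()` returns a one-row summary (site counts, mean and max
#' absolute z). For a `sweep_run`, `tidy()` returns the called peaks and
#' `glance()` the per-stage record counts.
#'
#' @param x A `sweep_scan`, `sweep_windows` or `sweep_run` object.
#' @param ... Unused; for generic consistency.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.sweep_scan <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidiers
#' @export
glance.sweep_scan <- function(x, ...) {
  z <- if ("z" %in% names(x)) x$z[!is.na(x$z)] else numeric(0)
  tibble::tibble(
    metric = x$metric[1],
    n_sites = nrow(x),
    n_valid = sum(x$valid),
    prop_valid = mean(x$valid),
    mean_abs_z = if (length(z)) mean(abs(z)) else NA_real_,
    max_abs_z = if (length(z)) max(abs(z)) else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.sweep_run <- function(x, ...) tibble::as_tibble(unclass(x$peaks))

#' @rdname tidiers
#' @export
glance.sweep_run <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$scores),
    n_valid = sum(x$scores$valid),
    n_windows = nrow(x$windows),
    n_peaks = nrow(x$peaks),
    n_regions = nrow(x$regions),
    region_bp = if (nrow(x$regions)) {
      sum(x$regions$end - x$regions$start + 1)
    } else 0L)
}
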
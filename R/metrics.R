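#' Relative surface-area error against an expert area
#'
#' `delta_w = 100 * |A - A_Z| / A_Z` percent, where `A_Z` is the pixel
#' count of the expert (gold standard) marking and `A` the algorithm's.
#' Reported to one decimal by convention.
#'
#' @param A algorithm pixel count.
#' @param A_Z expert pixel count, strictly positive.
#' @param digits decimals to round to (default 1); `NULL` for no rounding.
#' @return the error in percent.
#' @export
delta_w <- function(A, A_Z, digits = 1) {
  hs_assert(all(A_Z > 0), "hs_undefined_reference",
            "expert area A_Z must be positive")
  out <- 100 * abs(A - A_Z) / A_Z
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Per-class comparison of algorithm and expert pixel counts
#'
#' Builds the standard accounting table: per-class counts for both
#' sources, the share of the whole image (percentages are taken against
#' the expert total, i.e. the full image area), and the surface-area error
#' [delta_w()].  The unclassified set appears as its own row without an
#' error entry.
#'
#' @param algorithm named numeric vector of algorithm pixel counts;
#'   a name `unclassified` is allowed.
#' @param expert named numeric vector of expert pixel counts over the same
#'   class names.
#' @return data.frame with columns `class`, `algorithm_px`, `expert_px`,
#'   `algorithm_pct`, `expert_pct`, `delta_w_pct`.
#' @export
surface_report <- function(algorithm, expert) {
  cls <- setdiff(names(expert), "unclassified")
  hs_assert(length(cls) > 0 && !is.null(names(algorithm)), "hs_config_error",
            "both count vectors must be named by class")
  missing <- setdiff(cls, names(algorithm))
  hs_assert(length(missing) == 0, "hs_config_error",
            "algorithm counts missing class(es): %s", toString(missing))
  total <- sum(expert)
  rows <- c(cls, "unclassified")
  alg <- vapply(rows, function(cl)
    if (cl %in% names(algorithm)) unname(algorithm[[cl]]) else 0, numeric(1))
  exp_ <- vapply(rows, function(cl)
    if (cl %in% names(expert)) unname(expert[[cl]]) else 0, numeric(1))
  dw <- rep(NA_real_, length(rows))
  has <- rows != "unclassified" & exp_ > 0
  dw[has] <- delta_w(alg[has], exp_[has])
  data.frame(class = rows,
             algorithm_px = alg,
             expert_px = exp_,
             algorithm_pct = round(100 * alg / total, 1),
             expert_pct = round(100 * exp_ / total, 1),
             delta_w_pct = dw,
             row.names = NULL)
}

#' Compare two label maps class by class
#'
#' @param lm algorithm [label_map()].
#' @param expert expert [label_map()] on the same grid with the same class
#'   names.
#' @return the [surface_report()] data.frame.
#' @export
class_report <- function(lm, expert) {
  hs_assert(all(dim(lm$labels) == dim(expert$labels)), "hs_config_error",
            "label maps must be congruent")
  hs_assert(setequal(lm$classes, expert$classes), "hs_config_error",
            "class name mismatch: %s vs %s",
            toString(lm$classes), toString(expert$classes))
  counts <- function(x) {
    cnt <- label_counts(x)
    structure(cnt$pixels, names = cnt$class)
  }
  surface_report(counts(lm), counts(expert))
}

#' Summary of per-acquisition errors over a measurement series
#'
#' @param errors numeric vector of per-acquisition maximal errors, percent.
#' @return a `sequence_error_summary`: list with `mean`, `min`, `max`, `n`.
#' @export
sequence_summary <- function(errors) {
  hs_assert(length(errors) > 0, "hs_parameter_error", "empty error list")
  structure(list(mean = mean(errors), min = min(errors), max = max(errors),
                 n = length(errors)),
            class = "sequence_error_summary")
}

#' @export
print.sequence_error_summary <- function(x, ...) {
  cat(sprintf("%d acquisitions: mean %.1f%%, min %.1f%%, max %.1f%%\n",
              x$n, x$mean, x$min, x$max))
  invisible(x)
}
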
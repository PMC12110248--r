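#' Per-image gland census and atrophy index
#'
#' The traced glands are aggregated into the per-image quantitative outputs:
#' the class counts `N_L`, `N_M`, `N_S` and their total `N_T`, the mean gland
#' width per class (`AveWidth`), and the atrophy index
#' `(N_L - (N_M + N_S)) / N_T`, which spans `[-1, 1]`: 1 for an eyelid whose
#' glands all run the full visible length, -1 when every gland is shortened.
#'
#' @name metrics
NULL

#' Count glands per length class
#'
#' @param glands list of `mg_gland` objects (or anything with a `label`
#'   element).
#' @return named integer vector `c(N_L, N_M, N_S, N_T)`.
#' @export
count_glands <- function(glands) {
  labels <- vapply(glands, `[[`, character(1), "label")
  n_l <- sum(labels == "L"); n_m <- sum(labels == "M"); n_s <- sum(labels == "S")
  c(N_L = n_l, N_M = n_m, N_S = n_s, N_T = n_l + n_m + n_s)
}

#' Mean gland width of one class
#'
#' Each gland carries one width per member peak (one per layer); its summary
#' width is the mean (configurably the median) of those, and `AveWidth` of a
#' class is the mean of the summary widths over the glands of that class. An
#' empty class has no average: `NA` is returned rather than 0 so that cohort
#' summaries are not biased.
#'
#' @param glands list of `mg_gland` objects.
#' @param label `"L"`, `"M"` or `"S"`.
#' @param width_summary `"mean"` or `"median"` per-gland summary.
#' @return mean width in px, or `NA_real_` for an empty class.
#' @export
ave_width <- function(glands, label, width_summary = c("mean", "median")) {
  width_summary <- match.arg(width_summary)
  f <- if (width_summary == "mean") mean else stats::median
  sel <- Filter(function(g) g$label == label, glands)
  if (!length(sel)) return(NA_real_)
  mean(vapply(sel, function(g) f(g$widths), numeric(1)))
}

#' Atrophy index
#'
#' `(N_L - (N_M + N_S)) / N_T` with `N_T = N_L + N_M + N_S`. Equals 1 when
#' every gland is long (healthy, full-length gland field) and -1 when every
#' gland is shortened.
#'
#' @param n_l,n_m,n_s class counts (non-negative integers).
#' @return the index, a real in `[-1, 1]`.
#' @export
atrophy_index <- function(n_l, n_m, n_s) {
  if (any(c(n_l, n_m, n_s) < 0)) stop("counts must be non-negative", call. = FALSE)
  n_t <- n_l + n_m + n_s
  if (n_t == 0) stop("atrophy index undefined for zero glands", call. = FALSE)
  (n_l - (n_m + n_s)) / n_t
}

#' Summarize traced glands into a census
#'
#' @param glands list of `mg_gland` objects.
#' @param width_summary per-gland width summary, see [ave_width()].
#' @return `gland_census` list with `counts` (named vector), `ave_width`
#'   (named list over `L`, `M`, `S`; `NA` for empty classes) and
#'   `atrophy_index` (`NA` when no gland was found).
#' @export
gland_census <- function(glands, width_summary = "mean") {
  counts <- count_glands(glands)
  aw <- lapply(stats::setNames(nm = c("L", "M", "S")), function(lb)
    ave_width(glands, lb, width_summary))
  ai <- if (counts[["N_T"]] > 0)
    atrophy_index(counts[["N_L"]], counts[["N_M"]], counts[["N_S"]])
  else NA_real_
  structure(list(counts = counts, ave_width = aw, atrophy_index = ai),
            class = "gland_census")
}

#' @export
print.gland_census <- function(x, ...) {
  c_ <- x$counts
  cat(sprintf("Gland census: N_L=%d N_M=%d N_S=%d (N_T=%d)\n",
              c_[["N_L"]], c_[["N_M"]], c_[["N_S"]], c_[["N_T"]]))
  aw <- vapply(x$ave_width, function(v) if (is.na(v)) "-" else sprintf("%.1f", v),
               character(1))
  cat(sprintf("AveWidth (px): L=%s M=%s S=%s\n", aw[["L"]], aw[["M"]], aw[["S"]]))
  cat(sprintf("Atrophy index: %s\n",
              if (is.na(x$atrophy_index)) "undefined (no glands)"
              else sprintf("%.3f", x$atrophy_index)))
  invisible(x)
}
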
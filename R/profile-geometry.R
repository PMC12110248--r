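#' Eyelid-following profile lines
#'
#' Four piecewise-linear lines are laid across the everted lid at fixed
#' fractions of its local vertical extent, so that each line stays at a
#' comparable depth into the gland field even when the lid is curved. The
#' mask's bounding columns are split into equal-width vertical zones; in each
#' zone the foreground's top and bottom boundary rows (per-column medians,
#' unbiased at the zone center even for a curved lid) give the local extent,
#' an anchor
#' is placed at `top + depth * extent` at the zone's horizontal center, and
#' consecutive anchors are joined by straight segments, extended flat to the
#' foreground's left and right ends.
#'
#' @name profile-geometry
NULL

#' Build eyelid-following profile lines from a mask
#'
#' @param mask eyelid mask (0/1 matrix, non-empty foreground).
#' @param depths fractions of the per-zone vertical extent, ordered top to
#'   bottom; one line per value.
#' @param n_zones number of equal-width vertical zones over the foreground's
#'   bounding columns.
#' @return list of `profile_line` objects, one per depth, each a list with
#'   `layer` (1-based, 1 = topmost), `depth`, `anchors` (data.frame `x`, `y`),
#'   `xs` (all integer columns spanned, increasing) and `ys` (interpolated row
#'   positions, one per column).
#' @export
build_profile_lines <- function(mask, depths = c(0.10, 0.45, 0.55, 0.75),
                                n_zones = 5) {
  validate_mask(mask)
  fg_cols <- which(colSums(mask) > 0)
  x0 <- min(fg_cols); x1 <- max(fg_cols)
  edges <- seq(x0, x1 + 1, length.out = n_zones + 1)
  zones <- lapply(seq_len(n_zones), function(z) {
    lo <- ceiling(edges[z]); hi <- floor(edges[z + 1] - 1e-9)
    cols <- lo:hi
    sub <- mask[, cols, drop = FALSE]
    occupied <- colSums(sub) > 0
    if (!any(occupied))
      return(list(center = (lo + hi) / 2, top = NA_real_, bottom = NA_real_))
    # per-column extremes summarized by the median: an estimate of the
    # boundary at the zone center that a curved lid does not bias, unlike the
    # zone-wide min/max (which mixes boundary rows from different columns)
    tops <- apply(sub[, occupied, drop = FALSE], 2, function(v) min(which(v > 0)))
    bots <- apply(sub[, occupied, drop = FALSE], 2, function(v) max(which(v > 0)))
    list(center = (lo + hi) / 2,
         top = stats::median(tops), bottom = stats::median(bots))
  })
  if (all(vapply(zones, function(z) is.na(z$top), logical(1))))
    stop("invalid mask: all zones empty", call. = FALSE)
  empty <- vapply(zones, function(z) is.na(z$top), logical(1))
  if (any(empty))
    message("zone(s) with empty foreground skipped: ",
            paste(which(empty), collapse = ", "))
  centers <- vapply(zones, `[[`, numeric(1), "center")[!empty]
  tops    <- vapply(zones, `[[`, numeric(1), "top")[!empty]
  bots    <- vapply(zones, `[[`, numeric(1), "bottom")[!empty]
  xs <- x0:x1
  lapply(seq_along(depths), function(i) {
    d <- depths[i]
    ay <- tops + d * (bots - tops)
    ys <- if (length(centers) == 1) rep(ay, length(xs))
          else stats::approx(centers, ay, xout = xs, rule = 2)$y
    structure(list(layer = i, depth = d,
                   anchors = data.frame(x = centers, y = ay),
                   xs = xs, ys = ys),
              class = "profile_line")
  })
}

#' Sample gray values beneath a profile line
#'
#' For every integer column the line spans, its (interpolated) row position is
#' rounded to the nearest pixel row and the gray value there recorded. Rows
#' falling outside the image are clamped to the border.
#'
#' @param img gray image matrix.
#' @param line a `profile_line` from [build_profile_lines()].
#' @return a `gray_profile`: list with `layer`, `xs`, `ys` (rounded sampled
#'   rows) and `values` (gray values, one per column).
#' @export
extract_profile <- function(img, line) {
  validate_gray_image(img)
  ys <- round(line$ys)
  if (any(ys < 1 | ys > nrow(img)) ||
      any(line$xs < 1 | line$xs > ncol(img))) {
    message("profile line clamped to image bounds")
    ys <- pmin(pmax(ys, 1), nrow(img))
  }
  xs <- pmin(pmax(line$xs, 1), ncol(img))
  structure(list(layer = line$layer, xs = line$xs, ys = ys,
                 values = img[cbind(ys, xs)], normalized = FALSE),
            class = "gray_profile")
}
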
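#' Peak detection on gray-value profiles
#'
#' Each smoothed profile is scanned for local maxima; a maximum qualifies as a
#' gland candidate when its prominence (height above the highest surrounding
#' valley separating it from any higher peak) reaches 0.1 on the
#' `[0, 1]`-normalized scale and its width at half height reaches 2 px.
#' Near-duplicate detections closer than 10 px are fused, and implausibly wide
#' peaks (> 90 px) are discarded.
#'
#' @name signal-peaks
NULL

#' Smooth a gray-value profile
#'
#' Savitzky--Golay smoothing (default: linear fit over an 11-sample window,
#' which for a symmetric window equals a moving average) followed by
#' normalization to `[0, 1]` by division by 255, the scale on which the
#' prominence threshold is defined. A plain moving average with a long window
#' is available as the exploratory alternative.
#'
#' @param profile `gray_profile` from [extract_profile()].
#' @param window filter window length (samples; must not exceed the profile
#'   length).
#' @param order polynomial order of the Savitzky--Golay fit.
#' @param method `"savgol"` or `"moving_average"`.
#' @return the profile with smoothed values on `[0, 1]` and
#'   `normalized = TRUE`.
#' @export
smooth_profile <- function(profile, window = 11, order = 1,
                           method = c("savgol", "moving_average")) {
  method <- match.arg(method)
  v <- profile$values
  if (length(v) < window)
    stop("profile length ", length(v), " is shorter than the smoothing window ",
         window, "; need at least ", window, " samples", call. = FALSE)
  sm <- switch(method,
    savgol = signal::sgolayfilt(v, p = order, n = window),
    moving_average = stats::filter(v, rep(1 / window, window), sides = 2) |>
      (\(f) { f[is.na(f)] <- v[is.na(f)]; as.numeric(f) })()
  )
  profile$values <- pmin(pmax(sm, 0), 255) / 255
  profile$normalized <- TRUE
  profile
}

# Local maxima with plateau handling: a plateau flanked by strictly lower
# samples peaks at its midpoint. Returns indices.
local_maxima <- function(x) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i - 1L] < x[i]) {
      e <- i
      while (e < n && x[e + 1L] == x[i]) e <- e + 1L
      if (e < n && x[e + 1L] < x[i]) {
        peaks <- c(peaks, (i + e) %/% 2L)
        i <- e
      }
    }
    i <- i + 1L
  }
  peaks
}

# Prominence and bases of a peak by definition: extend left/right until a
# strictly higher sample or the signal edge; the minima of those stretches are
# the bases; prominence = height - max(left min, right min).
peak_prominence <- function(x, ip) {
  h <- x[ip]
  i <- ip; lmin <- h; lbase <- ip
  while (i > 1L && x[i - 1L] <= h) {
    i <- i - 1L
    if (x[i] < lmin) { lmin <- x[i]; lbase <- i }
  }
  j <- ip; rmin <- h; rbase <- ip
  while (j < length(x) && x[j + 1L] <= h) {
    j <- j + 1L
    if (x[j] < rmin) { rmin <- x[j]; rbase <- j }
  }
  list(prominence = h - max(lmin, rmin), left_base = lbase, right_base = rbase)
}

# Interpolated width of the peak at evaluation height `h`, confined to
# [left_base, right_base]; crossings between samples found linearly.
peak_width_at <- function(x, ip, lb, rb, h) {
  i <- ip
  while (i > lb && x[i] > h) i <- i - 1L
  left_ip <- if (x[i] > h) as.numeric(i)
             else i + (h - x[i]) / (x[i + 1L] - x[i])
  j <- ip
  while (j < rb && x[j] > h) j <- j + 1L
  right_ip <- if (x[j] > h) as.numeric(j)
              else j - (h - x[j]) / (x[j - 1L] - x[j])
  right_ip - left_ip
}

#' Detect gland-candidate peaks on a smoothed profile
#'
#' Local maxima are gated by prominence on the smoothed, normalized profile.
#' The reported width is the interpolated width of the peak at half its
#' height above its own base (evaluation level apex − prominence/2), which
#' for a Gaussian cross-section recovers the FWHM regardless of the tarsus
#' baseline. When `raw` is supplied (the unsmoothed profile), widths are
#' measured on it at the detected location, so the smoothing window does not
#' inflate narrow glands; detection itself always uses the smoothed values.
#'
#' @param profile smoothed, normalized `gray_profile`.
#' @param prominence minimum prominence on the `[0, 1]` scale.
#' @param min_width minimum width in px (peaks narrower are rejected).
#' @param raw optional unsmoothed `gray_profile` (same columns) for width
#'   measurement.
#' @return data.frame with one row per peak, ordered by `x`: `layer`, `x`
#'   (column), `y` (row from the profile line), `index` (sample index),
#'   `height` and `prominence` (smoothed, normalized), `width` (px).
#' @export
detect_peaks <- function(profile, prominence = 0.1, min_width = 2, raw = NULL) {
  if (!isTRUE(profile$normalized))
    stop("profile must be smoothed/normalized first (see smooth_profile)",
         call. = FALSE)
  x <- profile$values
  w_sig <- if (is.null(raw)) x else {
    rv <- raw$values
    if (max(rv) > 1) rv <- rv / 255
    rv
  }
  rows <- list()
  for (ip in local_maxima(x)) {
    pr <- peak_prominence(x, ip)
    if (pr$prominence < prominence) next
    apex_w <- w_sig[ip]
    lmin <- min(w_sig[pr$left_base:ip])
    rmin <- min(w_sig[ip:pr$right_base])
    prom_w <- apex_w - max(lmin, rmin)
    if (prom_w <= 0) next
    wd <- peak_width_at(w_sig, ip, pr$left_base, pr$right_base,
                        apex_w - 0.5 * prom_w)
    if (wd < min_width) next
    rows[[length(rows) + 1L]] <- data.frame(
      layer = profile$layer, x = profile$xs[ip], y = profile$ys[ip],
      index = ip, height = x[ip], prominence = pr$prominence, width = wd)
  }
  if (!length(rows)) return(empty_peaks())
  out <- do.call(rbind, rows)
  out[order(out$x), , drop = FALSE]
}

empty_peaks <- function() {
  data.frame(layer = integer(0), x = numeric(0), y = numeric(0),
             index = integer(0), height = numeric(0), prominence = numeric(0),
             width = numeric(0))
}

#' Fuse peaks closer than the double-detection distance
#'
#' Two peaks of the same profile closer than `min_separation` px cannot be
#' distinct glands: they are replaced by one peak at their rounded midpoint
#' whose width is the sum of the two widths. Applied left to right and
#' repeated until no pair violates the separation; a chain of mutually close
#' peaks therefore collapses pairwise with accumulating width.
#'
#' @param peaks peak data.frame ordered by `x`.
#' @param min_separation px; pairs with `|dx|` strictly below are fused.
#' @param fused_height `"max"` (default) or `"mean"` summary for the fused
#'   peak's height and prominence.
#' @return fused peak data.frame; never more rows than the input.
#' @export
fuse_close_peaks <- function(peaks, min_separation = 10,
                             fused_height = c("max", "mean")) {
  fused_height <- match.arg(fused_height)
  hf <- if (fused_height == "max") max else mean
  p <- peaks[order(peaks$x), , drop = FALSE]
  repeat {
    n <- nrow(p)
    if (n < 2) break
    gaps <- diff(p$x)
    k <- which(gaps < min_separation)
    if (!length(k)) break
    i <- k[1]
    a <- p[i, ]; b <- p[i + 1, ]
    merged <- data.frame(
      layer = a$layer, x = round((a$x + b$x) / 2),
      y = round((a$y + b$y) / 2), index = round((a$index + b$index) / 2),
      height = hf(c(a$height, b$height)),
      prominence = hf(c(a$prominence, b$prominence)),
      width = a$width + b$width)
    p <- rbind(if (i > 1) p[seq_len(i - 1), ], merged,
               if (i + 1 < n) p[seq(i + 2, n), ])
    p <- p[order(p$x), , drop = FALSE]
  }
  rownames(p) <- NULL
  p
}

#' Discard implausibly wide peaks
#'
#' A peak much wider than any gland body is a background structure (e.g. a
#' bright fold); peaks wider than `max_width` px (strictly) are removed.
#'
#' @param peaks peak data.frame.
#' @param max_width px cutoff.
#' @return filtered peak data.frame, order preserved.
#' @export
drop_wide_peaks <- function(peaks, max_width = 90) {
  out <- peaks[peaks$width <= max_width, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full peak stage for one profile
#'
#' Smooth, detect, fuse and filter in one call, measuring widths on the raw
#' profile.
#'
#' @param profile raw `gray_profile`.
#' @param cfg `peaks` section of [mg_config()].
#' @return peak data.frame.
#' @keywords internal
profile_peaks <- function(profile, cfg) {
  sm <- smooth_profile(profile, cfg$smooth_window, cfg$smooth_order,
                       cfg$smooth_method)
  pk <- detect_peaks(sm, cfg$prominence, cfg$min_width, raw = profile)
  pk <- fuse_close_peaks(pk, cfg$fuse_distance, cfg$fused_height)
  drop_wide_peaks(pk, cfg$max_width)
}
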
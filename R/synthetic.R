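#' Synthetic meibography scenes with known ground truth
#'
#' Generates images that emulate the phenomenology of infrared meibography of
#' the everted eyelid: a curved eyelid band of tarsus gray, bright
#' quasi-vertical gland stripes with Gaussian cross-section, optional
#' saturated specular-reflection discs, an optional lateral illumination
#' gradient, and additive sensor noise. Each gland's intended length class is
#' known from the fraction of the band depth it covers, so every stage of the
#' pipeline - and the whole of it - can be validated without clinical images.
#' All randomness flows from the explicit seed; the same truth renders
#' bit-identically.
#'
#' @name synthetic
NULL

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Draw a random synthetic scene description
#'
#' The defaults describe a clean, well-everted lid at the device's native
#' resolution: 6-12 glands with Gaussian cross-section scale 5-15 px, packed
#' at an anatomical pitch of 50-80 px (roughly 1-1.5 mm at this
#' magnification; never closer than 40 px between center paths), tarsus gray
#' 60, gland amplitude ~90 gray levels, additive noise sd 5, no reflections
#' and flat illumination. The visible everted band hugs the gland field - a
#' lid showing few glands exposes a correspondingly narrow strip, not a
#' gland-free expanse of tarsus - with a small gland-free flank on either
#' side. The band is 140 px deep with a mild parabolic bow.
#'
#' @param seed integer seed; the only source of randomness.
#' @param n_glands number of glands, or `NULL` to draw uniformly from 6-12.
#' @param classes character vector of intended classes (`"L"`, `"M"`, `"S"`),
#'   recycled/overridden per gland, or `NULL` to draw with probabilities
#'   0.6/0.25/0.15 (a moderately affected lid).
#' @param canvas `c(rows, cols)` image size.
#' @param band_top row of the band's top boundary at the lid center.
#' @param band_extent vertical depth of the band, px.
#' @param band_bow parabolic bow of the band boundaries, px (0 = straight).
#' @param base_gray tarsus gray level inside the band.
#' @param bg_gray gray level outside the band (periocular skin and lid
#'   surface, which in the infrared is of moderate brightness - the frame has
#'   no black void around the everted lid).
#' @param amplitude peak gland brightness over the tarsus, gray levels.
#' @param amp_jitter per-gland uniform jitter on `amplitude`.
#' @param sigma_range range of the Gaussian cross-section scale, px.
#' @param pitch_range range of the center-to-center gland spacing, px.
#' @param min_clearance hard floor on the distance between adjacent gland
#'   center paths, px (enforced against pitch and tilt).
#' @param flank gland-free strip between the outermost gland centers and the
#'   mask's horizontal ends, px.
#' @param tilt_max maximum horizontal drift of a gland center from bottom to
#'   top, px.
#' @param noise_sd additive Gaussian noise sd, gray levels.
#' @param reflections list of `list(y =, x =, r =)` saturated discs.
#' @param illumination relative left-right multiplicative gradient (0 = flat;
#'   0.2 means +/-10% across the frame).
#' @return a `synth_truth` list describing the scene.
#' @export
synth_truth <- function(seed = 1, n_glands = NULL, classes = NULL,
                        canvas = c(720, 1280), band_top = 260,
                        band_extent = 140, band_bow = 40,
                        base_gray = 60, bg_gray = 75,
                        amplitude = 90, amp_jitter = 15,
                        sigma_range = c(5, 15), pitch_range = c(50, 80),
                        min_clearance = 40, flank = 30, tilt_max = 5,
                        noise_sd = 5, reflections = list(),
                        illumination = 0) {
  if (pitch_range[1] - 2 * tilt_max < min_clearance)
    stop("pitch_range and tilt_max violate the minimum clearance", call. = FALSE)
  with_seed(seed, {
    if (is.null(n_glands)) n_glands <- sample(6:12, 1)
    if (is.null(classes))
      classes <- sample(c("L", "M", "S"), n_glands, replace = TRUE,
                        prob = c(0.6, 0.25, 0.15))
    classes <- rep_len(classes, n_glands)
    # covered depth fraction f: the gland spans depths [1 - f, 1]; drawn well
    # inside each class's band so rounding never flips the crossing count
    f <- vapply(classes, function(cl) switch(cl,
      L = stats::runif(1, 0.95, 1.00),
      M = stats::runif(1, 0.63, 0.88),
      S = stats::runif(1, 0.48, 0.53)), numeric(1))
    # anatomical layout: glands at a quasi-regular pitch; the visible band
    # spans the gland field plus a small flank on either side
    pitches <- stats::runif(max(n_glands - 1, 0), pitch_range[1], pitch_range[2])
    field <- sum(pitches)
    mask_w <- field + 2 * flank
    if (mask_w > canvas[2] - 80)
      stop("gland field does not fit the canvas", call. = FALSE)
    mask_x0 <- round((canvas[2] - mask_w) / 2)
    mask_x1 <- round(mask_x0 + mask_w)
    centers <- mask_x0 + flank + cumsum(c(0, pitches))
    glands <- lapply(seq_len(n_glands), function(i) list(
      center_x = centers[i],
      sigma = stats::runif(1, sigma_range[1], sigma_range[2]),
      amplitude = amplitude + stats::runif(1, -amp_jitter, amp_jitter),
      top_extent = f[i],
      tilt = stats::runif(1, -tilt_max, tilt_max),
      class = classes[i]))
    structure(list(
      seed = seed, canvas = canvas, band_top = band_top,
      band_extent = band_extent, band_bow = band_bow,
      base_gray = base_gray, bg_gray = bg_gray,
      mask_x0 = mask_x0, mask_x1 = mask_x1,
      glands = glands, noise_sd = noise_sd,
      reflections = reflections, illumination = illumination),
      class = "synth_truth")
  })
}

# band boundaries as functions of column (vectorized); columns beyond the
# mask span continue at the boundary value so off-mask evaluation stays sane
band_top_at <- function(truth, x) {
  cx <- (truth$mask_x0 + truth$mask_x1) / 2
  half <- (truth$mask_x1 - truth$mask_x0) / 2
  xi <- pmin(pmax((x - cx) / half, -1), 1)
  truth$band_top + truth$band_bow * xi^2
}

#' Render a synthetic scene
#'
#' Pure function of the truth: the tarsus band is drawn at its base gray,
#' each gland added as a Gaussian-profile bright stripe along its (possibly
#' tilted) center path, truncated at its top extent; the illumination
#' gradient is applied, saturated reflection discs pasted, and clipped
#' Gaussian noise added from the truth's seed (overridable to study noise
#' stability).
#'
#' @param truth a `synth_truth` from [synth_truth()].
#' @param noise_seed seed for the additive noise only; defaults to the
#'   truth's own seed, so rendering is bit-reproducible.
#' @return list with `image` (gray matrix), `mask` (0/1 matrix) and `truth`.
#' @export
synth_render <- function(truth, noise_seed = NULL) {
  h <- truth$canvas[1]; w <- truth$canvas[2]
  xs <- seq_len(w)
  top <- band_top_at(truth, xs)
  bot <- top + truth$band_extent
  if (any(bot > h - 1) || any(top < 2))
    stop("eyelid band exceeds the canvas", call. = FALSE)
  rows <- seq_len(h)
  inband <- outer(rows, xs, function(y, x) y >= top[x] & y <= bot[x])
  inband[, xs < truth$mask_x0 | xs > truth$mask_x1] <- FALSE
  img <- matrix(truth$bg_gray, h, w)
  img[inband] <- truth$base_gray
  for (g in truth$glands) {
    gx0 <- max(1, floor(g$center_x - 4 * g$sigma - abs(g$tilt)))
    gx1 <- min(w, ceiling(g$center_x + 4 * g$sigma + abs(g$tilt)))
    cols <- gx0:gx1
    y0 <- max(1, floor(min(top[cols]) + (1 - g$top_extent) * truth$band_extent))
    y1 <- min(h, ceiling(max(bot[cols])))
    if (g$top_extent > 1 || y1 <= y0)
      stop("gland outside the eyelid band", call. = FALSE)
    yy <- y0:y1
    Y <- matrix(yy, length(yy), length(cols))
    X <- matrix(cols, length(yy), length(cols), byrow = TRUE)
    topm <- matrix(top[cols], length(yy), length(cols), byrow = TRUE)
    botm <- topm + truth$band_extent
    depth <- (Y - topm) / truth$band_extent
    cg <- g$center_x + g$tilt * (1 - depth)       # drift grows towards the top
    contrib <- g$amplitude * exp(-(X - cg)^2 / (2 * g$sigma^2))
    active <- depth >= (1 - g$top_extent) - 1e-9 & Y <= botm & Y >= topm
    contrib[!active] <- 0
    img[yy, cols] <- img[yy, cols] + contrib * inband[yy, cols]
  }
  if (truth$illumination != 0) {
    grad <- 1 + truth$illumination * ((xs - 1) / (w - 1) - 0.5)
    img <- sweep(img, 2, grad, `*`)
  }
  for (rf in truth$reflections) {
    yy <- pmax(1, rf$y - rf$r):pmin(h, rf$y + rf$r)
    xx <- pmax(1, rf$x - rf$r):pmin(w, rf$x + rf$r)
    disc <- outer(yy, xx, function(a, b) (a - rf$y)^2 + (b - rf$x)^2 <= rf$r^2)
    img[yy, xx][disc] <- 255
  }
  if (truth$noise_sd > 0) {
    if (is.null(noise_seed)) noise_seed <- truth$seed
    img <- img + with_seed(noise_seed,
      matrix(stats::rnorm(h * w, 0, truth$noise_sd), h, w))
  }
  list(image = round(pmin(pmax(img, 0), 255)), mask = inband + 0, truth = truth)
}

#' Ground-truth census of a synthetic scene
#'
#' Each gland's class follows from which profile depths its rendered extent
#' crosses (a gland ending exactly on a line counts as crossing it, matching
#' the renderer's inclusive truncation); glands crossing fewer than two
#' depths are undetectable by construction and excluded. Counts, per-class
#' mean widths (from the closed-form Gaussian FWHM `2.355 * sigma`) and the
#' atrophy index are computed with the census formulas of the metrics module.
#'
#' @param truth a `synth_truth`.
#' @param depths profile depth fractions.
#' @return a `gland_census`.
#' @export
expected_census <- function(truth, depths = c(0.10, 0.45, 0.55, 0.75)) {
  total <- length(depths)
  glands <- list()
  for (g in truth$glands) {
    n_cross <- sum(depths >= (1 - g$top_extent) - 1e-9)
    if (n_cross < 2) next
    fwhm <- 2 * sqrt(2 * log(2)) * g$sigma
    glands[[length(glands) + 1L]] <- structure(
      list(label = classify_gland(n_cross, total),
           widths = rep(fwhm, n_cross), n_layers = n_cross),
      class = "mg_gland")
  }
  gland_census(glands)
}
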
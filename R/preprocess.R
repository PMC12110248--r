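#' Contrast-enhancement chain for meibography images
#'
#' The raw infrared frame is transformed into the high-contrast working image
#' from which gray-value profiles are sampled. Stages, in order:
#' histogram centering of dark frames, specular-reflection detection and
#' inpainting, dark-pixel suppression, contrast-limited adaptive histogram
#' equalization, gray-level morphological closing, and a final global
#' histogram equalization. Every stage preserves the image dimensions and the
#' `[0, 255]` range, and the whole chain is a pure function of
#' (image, mask, config).
#'
#' @name preprocess
NULL

#' Center the gray histogram of a dark frame
#'
#' Shifts every pixel by the same integer offset so that the mean gray value
#' over the mask foreground lands on `target` (clipping at 0/255 can leave the
#' achieved mean slightly off; the shift itself is exact to rounding).
#' Under-illuminated frames are common with hand-held meibography; brighter
#' frames pass through untouched when `darker_only` is set (the default), so
#' centering only ever brightens.
#'
#' @param img gray image matrix.
#' @param mask eyelid mask (foreground must be non-empty).
#' @param target target foreground mean, gray levels.
#' @param darker_only only shift when the foreground mean is below `target`.
#' @return shifted gray image.
#' @export
center_histogram <- function(img, mask, target = 100, darker_only = TRUE) {
  validate_gray_image(img)
  validate_mask(mask, img)
  fg_mean <- mean(img[mask == 1])
  if (darker_only && fg_mean >= target) return(img)
  shift <- round(target - fg_mean)
  pmin(pmax(img + shift, 0), 255)
}

# Sobel-3 gradient + non-maximum suppression edge response, as used to
# localize the specular light reflex. With the lower hysteresis threshold at
# 0 every non-zero gradient is a weak candidate, so the hysteresis step
# reduces to retaining the directional maxima at or above the high threshold.
canny_edges <- function(img, aperture = 3, lo = 0, hi = 255) {
  if (aperture != 3) stop("only the 3x3 Sobel aperture is implemented", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  if (h < 3 || w < 3) return(matrix(FALSE, h, w))
  p <- matrix(0, h + 2, w + 2)              # edge-replicated pad
  p[2:(h + 1), 2:(w + 1)] <- img
  p[1, ] <- p[2, ]; p[h + 2, ] <- p[h + 1, ]
  p[, 1] <- p[, 2]; p[, w + 2] <- p[, w + 1]
  sh <- function(dy, dx) p[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)                      # quantize to 0/45/90/135 degrees
  sector <- (round(ang / (pi / 4)) %% 4L)
  pm <- matrix(0, h + 2, w + 2); pm[2:(h + 1), 2:(w + 1)] <- mag
  shm <- function(dy, dx) pm[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  n1 <- mag; n2 <- mag
  off <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    sel <- sector == s
    d <- off[[as.character(s)]]
    n1[sel] <- shm(d[1], d[2])[sel]
    n2[sel] <- shm(-d[1], -d[2])[sel]
  }
  mag >= hi & mag >= n1 & mag >= n2 & mag > lo
}

# 8-connected labeling: 4-connected EBImage::bwlabel, then union of labels
# touching diagonally.
label8 <- function(bin) {
  if (!any(bin)) return(integer(0))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bin * 1))))
  lab <- t(lab)
  h <- nrow(lab); w <- ncol(lab)
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) apply(unique(pairs), 1, function(p) unite(p[1], p[2]))
  root <- vapply(seq_len(n), find, integer(1))
  out <- lab
  out[lab > 0] <- match(root, sort(unique(root)))[lab[lab > 0]]
  out
}

#' Detect specular reflections
#'
#' Saturated ("burned") pixels at or above `saturation_floor` are grouped into
#' 8-connected components. A Canny-style edge response (3x3 Sobel aperture
#' with hysteresis thresholds at the two extremes of the gray range) is
#' computed to localize the light reflex: a component is reported as a
#' reflection when the edge response fires on or next to it. When the edge
#' response is empty everywhere (a degenerate frame), saturation alone
#' decides.
#'
#' @param img gray image matrix.
#' @param aperture Sobel aperture (3).
#' @param lo,hi hysteresis thresholds (0 and 255, the extremes).
#' @param saturation_floor gray level at or above which a pixel counts as
#'   saturated.
#' @return list of components, each an integer matrix of (row, col) pixel
#'   coordinates; empty list when nothing is saturated. The edge map is
#'   attached as attribute `edges`.
#' @export
detect_reflections <- function(img, aperture = 3, lo = 0, hi = 255,
                               saturation_floor = 250) {
  validate_gray_image(img)
  sat <- img >= saturation_floor
  edges <- canny_edges(img, aperture, lo, hi)
  comps <- list()
  if (any(sat)) {
    lab <- label8(sat)
    for (k in seq_len(max(lab))) {
      px <- which(lab == k, arr.ind = TRUE)
      colnames(px) <- c("row", "col")
      comps[[length(comps) + 1L]] <- px
    }
    if (any(edges)) {
      near <- vapply(comps, function(px) {
        ring <- neighbor_ring(px, nrow(img), ncol(img))
        any(edges[px]) || (nrow(ring) > 0 && any(edges[ring]))
      }, logical(1))
      comps <- comps[near]
    }
  }
  structure(comps, edges = edges)
}

# 8-neighbour ring of a pixel set: all in-bounds neighbours not in the set.
neighbor_ring <- function(px, h, w) {
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
    cbind(px[, 1] + offs$dy[i], px[, 2] + offs$dx[i])))
  nb <- nb[nb[, 1] >= 1 & nb[, 1] <= h & nb[, 2] >= 1 & nb[, 2] <= w, , drop = FALSE]
  nb <- unique(nb)
  inset <- paste(nb[, 1], nb[, 2]) %in% paste(px[, 1], px[, 2])
  ring <- nb[!inset, , drop = FALSE]
  colnames(ring) <- c("row", "col")
  ring
}

#' Inpaint reflection components
#'
#' Each component's pixels are replaced by the rounded mean gray value of its
#' contour - the 8-neighbour ring of non-component pixels immediately around
#' it - reflecting that the reflex sits on a locally more humid but otherwise
#' ordinary patch of eyelid. Pixels outside the components are untouched.
#'
#' @param img gray image matrix.
#' @param components component list from [detect_reflections()].
#' @param mask optional eyelid mask; only used for the fallback fill value of
#'   a component with no contour (one covering the whole frame).
#' @return inpainted gray image.
#' @export
fill_reflections <- function(img, components, mask = NULL) {
  validate_gray_image(img)
  out <- img
  for (px in components) {
    if (any(px[, 1] < 1 | px[, 1] > nrow(img) | px[, 2] < 1 | px[, 2] > ncol(img)))
      stop("reflection component lies outside the image", call. = FALSE)
    ring <- neighbor_ring(px, nrow(img), ncol(img))
    if (nrow(ring) == 0) {
      fill <- if (!is.null(mask) && sum(mask) > 0) round(mean(img[mask == 1]))
              else round(mean(img))
      warning("reflection component has no contour pixels; filled with mean ",
              fill, call. = FALSE)
    } else {
      fill <- round(mean(out[ring]))
    }
    out[px] <- fill
  }
  out
}

#' Suppress dark pixels
#'
#' Pixels strictly below `threshold` become pure black, sharpening the
#' contrast between gland tissue and the dark inter-gland tarsus.
#'
#' @param img gray image matrix.
#' @param threshold gray level; pixels `< threshold` are zeroed.
#' @return gray image.
#' @export
black_out_dark <- function(img, threshold = 50) {
  validate_gray_image(img)
  img[img < threshold] <- 0
  img
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE over a tile grid, removing the slow illumination gradient across the
#' everted lid while limiting noise amplification through the clip limit. The
#' image is padded by edge replication to a multiple of the tile grid and
#' cropped back. An image too small for the requested grid falls back to the
#' minimal 2x2 tile grid.
#'
#' @param img gray image matrix.
#' @param clip_limit contrast clip limit.
#' @param grid `c(nx, ny)` tile grid.
#' @return equalized gray image in `[0, 255]`.
#' @export
enhance_local_contrast <- function(img, clip_limit = 12, grid = c(20, 20)) {
  validate_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  nx <- grid[1]; ny <- grid[2]
  if (w < 2 * nx || h < 2 * ny) {
    message("image smaller than the CLAHE grid; falling back to the minimal ",
            "2x2 tile grid")
    nx <- 2; ny <- 2
  }
  wp <- ceiling(w / nx) * nx
  hp <- ceiling(h / ny) * ny
  pad <- img[c(seq_len(h), rep(h, hp - h)), c(seq_len(w), rep(w, wp - w)), drop = FALSE]
  res <- EBImage::clahe(as_ebimage(pad), nx = nx, ny = ny, bins = 256,
                        limit = clip_limit, keep.range = FALSE)
  out <- from_ebimage(res)[seq_len(h), seq_len(w), drop = FALSE]
  round(out)
}

#' Gray-level morphological closing
#'
#' Closing with a disc structuring element removes small dark holes inside the
#' bright gland bodies without shifting gland boundaries. Output is pointwise
#' greater than or equal to the input.
#'
#' @param img gray image matrix.
#' @param diameter disc diameter in pixels.
#' @return closed gray image.
#' @export
close_gray <- function(img, diameter = 5) {
  validate_gray_image(img)
  kern <- EBImage::makeBrush(diameter, shape = "disc")
  round(from_ebimage(EBImage::closing(as_ebimage(img), kern)))
}

#' Global histogram equalization
#'
#' Stretches the gray values over the full 8-bit range by the cumulative
#' histogram rule (minimum bin anchored at 0, maximum at 255), separating
#' foreground glands from the background. A constant image is returned
#' unchanged.
#'
#' @param img gray image matrix.
#' @return equalized gray image.
#' @export
equalize_global <- function(img) {
  validate_gray_image(img)
  v <- round(img)
  if (min(v) == max(v)) {
    message("constant image: global equalization skipped")
    return(img)
  }
  counts <- tabulate(as.vector(v) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- cdf[which(counts > 0)[1]]
  map <- round((cdf - cdf_min) / (length(v) - cdf_min) * 255)
  out <- matrix(map[v + 1L], nrow(v), ncol(v))
  pmin(pmax(out, 0), 255)
}

#' Run the full contrast-enhancement chain
#'
#' Applies, in order: histogram centering, reflection detection and
#' inpainting, dark-pixel suppression, CLAHE, gray-level closing, and global
#' equalization, with each stage's parameters taken from `config` and each
#' stage toggleable for ablation.
#'
#' @param img gray image matrix.
#' @param mask eyelid mask of the same dimensions.
#' @param config [mg_config()] list.
#' @param verbose log per-stage summary statistics via `message()`.
#' @return the working gray image, with attribute `n_filled` (count of
#'   inpainted reflection pixels).
#' @export
preprocess_pipeline <- function(img, mask, config = mg_config(), verbose = FALSE) {
  validate_gray_image(img)
  validate_mask(mask, img)
  p <- config$preprocess
  say <- function(stage, x) if (verbose)
    message(sprintf("%-12s min %3d mean %6.1f max %3d", stage,
                    min(x), mean(x), max(x)))
  say("input", img)
  out <- img
  n_filled <- 0L
  if (isTRUE(p$do_center)) {
    out <- center_histogram(out, mask, p$center_target, p$center_darker_only)
    say("center", out)
  }
  if (isTRUE(p$do_reflections)) {
    comps <- detect_reflections(out, p$canny_aperture, p$canny_lo, p$canny_hi,
                                p$saturation_floor)
    n_filled <- sum(vapply(comps, nrow, integer(1)))
    out <- fill_reflections(out, comps, mask)
    say(sprintf("inpaint(%d)", n_filled), out)
  }
  if (isTRUE(p$do_dark)) {
    out <- black_out_dark(out, p$dark_threshold)
    say("dark", out)
  }
  if (isTRUE(p$do_clahe)) {
    out <- enhance_local_contrast(out, p$clahe_clip, p$clahe_grid)
    say("clahe", out)
  }
  if (isTRUE(p$do_closing)) {
    out <- close_gray(out, p$closing_diameter)
    say("closing", out)
  }
  if (isTRUE(p$do_equalize)) {
    out <- equalize_global(out)
    say("equalize", out)
  }
  attr(out, "n_filled") <- n_filled
  out
}
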
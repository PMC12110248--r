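#' Gray images and eyelid masks
#'
#' Throughout the package an image is a plain numeric matrix of 8-bit gray
#' values in `[0, 255]`, indexed `img[y, x]` with row 1 at the top (so `y`
#' grows downwards, matching the "depth into the eyelid" direction). An eyelid
#' mask is a matrix of the same dimensions with values in `{0, 1}`, foreground
#' `1` marking the everted tarsal plate.
#'
#' @name gray-image
#' @keywords internal
NULL

#' Validate a gray image
#'
#' @param img numeric matrix, values expected in `[0, 255]`.
#' @return `img`, invisibly, after validation.
#' @keywords internal
validate_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("gray image must be a numeric matrix", call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop("gray image must have at least one row and one column", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("gray values must lie in [0, 255] with no NA", call. = FALSE)
  invisible(img)
}

#' Validate an eyelid mask against its companion image
#'
#' @param mask matrix of 0/1 values.
#' @param img optional gray image whose dimensions the mask must match.
#' @param require_foreground error when the mask has no foreground pixel.
#' @return `mask`, invisibly.
#' @keywords internal
validate_mask <- function(mask, img = NULL, require_foreground = TRUE) {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop("mask must be a numeric matrix", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  if (!is.null(img) && !identical(dim(mask), dim(img)))
    stop("mask dimensions (", paste(dim(mask), collapse = "x"),
         ") do not match image dimensions (",
         paste(dim(img), collapse = "x"), ")", call. = FALSE)
  if (require_foreground && sum(mask) == 0)
    stop("invalid mask: foreground is empty", call. = FALSE)
  invisible(mask)
}

#' Read a grayscale image file
#'
#' Reads PNG, TIFF or JPEG through [EBImage::readImage()]. Color inputs are
#' converted to luminance; values are rescaled to the 8-bit `[0, 255]` range
#' used by the rest of the package.
#'
#' @param path file path.
#' @return numeric matrix `[y, x]` of gray values in `[0, 255]`.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  im <- EBImage::readImage(path)
  if (EBImage::colorMode(im) != EBImage::Grayscale)
    im <- EBImage::channel(im, "luminance")
  d <- dim(im)
  if (length(d) > 2L) im <- im[, , 1L]
  m <- t(EBImage::imageData(im)) # EBImage is [x, y]; we use [y, x]
  m <- pmin(pmax(m, 0), 1) * 255
  round(m)
}

#' Read a binary eyelid mask file
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path file path.
#' @return 0/1 matrix `[y, x]`.
#' @export
read_mask <- function(path) {
  m <- read_gray(path)
  (m >= 128) + 0
}

#' Write a gray image (or mask) to a PNG/TIFF file
#'
#' @param img numeric matrix in `[0, 255]` (a 0/1 mask is scaled up).
#' @param path output path; format follows the file extension.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  m <- img
  if (max(m) <= 1) m <- m * 255
  EBImage::writeImage(EBImage::Image(t(m / 255)), path)
  invisible(path)
}

# EBImage round-trip helpers: EBImage images are [x, y] in [0, 1].
as_ebimage <- function(img) EBImage::Image(t(img / 255))
from_ebimage <- function(im) {
  m <- t(EBImage::imageData(im)) * 255
  pmin(pmax(m, 0), 255)
}
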
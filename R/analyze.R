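#' End-to-end analysis of one meibography image
#'
#' Runs the full pipeline - contrast enhancement, profile-line construction,
#' profile sampling, peak detection/fusion/filtering, layered-graph gland
#' tracing, census - and assembles an analysis report. The report's config
#' snapshot contains every threshold used, so the run is reproducible
#' bit-for-bit from the report alone.
#'
#' @param image gray image matrix or path to a PNG/TIFF/JPEG file.
#' @param mask 0/1 mask matrix (same dimensions) or path to a mask image.
#' @param config [mg_config()] list or path to a JSON config file.
#' @param image_id identifier recorded in the report; defaults to the file
#'   stem or `"image"`.
#' @param verbose log per-stage statistics.
#' @return `mg_report` list: `image_id`, `config`, `peaks` (per-layer table),
#'   `glands`, `census` ([gland_census()]), `warnings` (named list with the
#'   inpainted-pixel count and any skipped zones / boundary clamps).
#' @export
analyze <- function(image, mask, config = mg_config(), image_id = NULL,
                    verbose = FALSE) {
  if (is.character(image)) {
    if (is.null(image_id))
      image_id <- sub("\\.[^.]+$", "", basename(image))
    image <- read_gray(image)
  }
  if (is.character(mask)) mask <- read_mask(mask)
  if (is.character(config)) config <- read_config(config)
  if (is.null(image_id)) image_id <- "image"
  validate_gray_image(image)
  validate_mask(mask, image)

  notes <- character(0)
  work <- withCallingHandlers(
    preprocess_pipeline(image, mask, config, verbose = verbose),
    message = function(m) {
      notes <<- c(notes, conditionMessage(m))
      if (!verbose) invokeRestart("muffleMessage")
    })
  lines <- withCallingHandlers(
    build_profile_lines(mask, config$profiles$depths, config$profiles$n_zones),
    message = function(m) {
      notes <<- c(notes, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  peak_layers <- lapply(lines, function(ln) {
    prof <- extract_profile(work, ln)
    profile_peaks(prof, config$peaks)
  })
  glands <- trace_glands(peak_layers,
                         full_max_len = config$tracing$full_max_len,
                         pair_max_len = config$tracing$pair_max_len,
                         accept_leq = config$tracing$accept_leq)
  census <- gland_census(glands, config$metrics$width_summary)
  peaks <- do.call(rbind, peak_layers)
  structure(list(
    image_id = image_id,
    config = config,
    lines = lines,
    peaks = peaks,
    glands = glands,
    census = census,
    warnings = list(n_filled_reflection_px = attr(work, "n_filled"),
                    notes = notes)),
    class = "mg_report")
}

#' @export
print.mg_report <- function(x, ...) {
  cat("Meibography analysis:", x$image_id, "\n")
  cat(sprintf("  peaks per layer: %s\n",
              paste(tabulate(x$peaks$layer, length(x$lines)), collapse = ", ")))
  print(x$census)
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' Serializes the config snapshot, per-layer peak table, per-gland records
#' and census. Identical runs produce byte-identical files.
#'
#' @param report `mg_report` from [analyze()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  glands <- lapply(report$glands, function(g) list(
    label = g$label, n_layers = g$n_layers,
    path_length = round(g$path_length, 3),
    nodes = g$nodes, widths = round(g$widths, 3)))
  cc <- report$census
  out <- list(
    image_id = report$image_id,
    config = unclass(report$config),
    peaks = report$peaks,
    glands = glands,
    census = list(counts = as.list(cc$counts),
                  ave_width = cc$ave_width,
                  atrophy_index = cc$atrophy_index),
    warnings = report$warnings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 6, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' One census row for cohort tables
#'
#' @param report `mg_report`.
#' @return one-row data.frame: image id, counts, per-class AveWidth, atrophy
#'   index.
#' @export
census_row <- function(report) {
  cc <- report$census
  data.frame(image_id = report$image_id,
             N_L = cc$counts[["N_L"]], N_M = cc$counts[["N_M"]],
             N_S = cc$counts[["N_S"]], N_T = cc$counts[["N_T"]],
             AveWidth_L = cc$ave_width$L, AveWidth_M = cc$ave_width$M,
             AveWidth_S = cc$ave_width$S,
             atrophy_index = cc$atrophy_index)
}

#' Analyze a directory of image/mask pairs
#'
#' Pairs are discovered by shared file stem between the two directories.
#' Unmatched or failing inputs are listed as warnings and skipped.
#'
#' @param images_dir directory of meibography images.
#' @param masks_dir directory of mask images with matching stems.
#' @param config [mg_config()] list or JSON path.
#' @param out optional path for the cohort CSV.
#' @param trim_quantiles optional `c(lo, hi)` percentile bounds (e.g.
#'   `c(0.05, 0.95)`); atrophy indices outside are dropped from the summary
#'   block (off by default - a cohort-statistics concern, not a detector one).
#' @return data.frame of census rows, with attributes `summary` (per-class
#'   mean counts) and `skipped`.
#' @export
batch_analyze <- function(images_dir, masks_dir, config = mg_config(),
                          out = NULL, trim_quantiles = NULL) {
  if (is.character(config)) config <- read_config(config)
  imgs <- list.files(images_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                     ignore.case = TRUE)
  masks <- list.files(masks_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      ignore.case = TRUE)
  stem <- function(f) sub("\\.[^.]+$", "", f)
  common <- intersect(stem(imgs), stem(masks))
  skipped <- setdiff(union(stem(imgs), stem(masks)), common)
  for (s in skipped) warning("unmatched image/mask stem skipped: ", s,
                             call. = FALSE)
  rows <- list()
  for (s in sort(common)) {
    ip <- file.path(images_dir, imgs[match(s, stem(imgs))])
    mp <- file.path(masks_dir, masks[match(s, stem(masks))])
    r <- tryCatch(census_row(analyze(ip, mp, config, image_id = s)),
                  error = function(e) {
                    warning("analysis failed for ", s, ": ",
                            conditionMessage(e), call. = FALSE)
                    skipped <<- c(skipped, s)
                    NULL
                  })
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), N_L = integer(0), N_M = integer(0),
               N_S = integer(0), N_T = integer(0), AveWidth_L = numeric(0),
               AveWidth_M = numeric(0), AveWidth_S = numeric(0),
               atrophy_index = numeric(0))
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  sel <- tab
  if (!is.null(trim_quantiles) && nrow(tab)) {
    qs <- stats::quantile(tab$atrophy_index, trim_quantiles, na.rm = TRUE)
    sel <- tab[!is.na(tab$atrophy_index) & tab$atrophy_index >= qs[1] &
                 tab$atrophy_index <= qs[2], , drop = FALSE]
  }
  attr(tab, "summary") <- if (nrow(sel))
    colMeans(sel[, c("N_L", "N_M", "N_S", "N_T")]) else NULL
  attr(tab, "skipped") <- skipped
  tab
}

#' QC overlay of profile lines, peaks and gland skeletons
#'
#' Draws the four profile lines, the detected peaks (with their widths as
#' horizontal ticks) and each traced gland's node chain onto the input image
#' and writes the result as an RGB image.
#'
#' @param report `mg_report` from [analyze()].
#' @param image the gray image matrix the report was computed from.
#' @param path output image path (PNG recommended).
#' @return `path`, invisibly.
#' @export
write_overlay <- function(report, image, path) {
  h <- nrow(image); w <- ncol(image)
  g <- image / 255
  rgb <- array(rep(g, 3), dim = c(h, w, 3))
  put <- function(y, x, col) {
    ok <- y >= 1 & y <= h & x >= 1 & x <= w
    for (ch in 1:3) rgb[cbind(y[ok], x[ok], ch)] <<- col[ch]
  }
  for (ln in report$lines)
    put(round(ln$ys), ln$xs, c(0.2, 0.5, 1))            # profile lines: blue
  if (!is.null(report$peaks) && nrow(report$peaks)) {
    pk <- report$peaks
    put(pk$y, pk$x, c(1, 1, 0))                          # peaks: yellow
    for (i in seq_len(nrow(pk))) {
      half <- round(pk$width[i] / 2)
      put(rep(pk$y[i], 2 * half + 1), (pk$x[i] - half):(pk$x[i] + half),
          c(1, 0.6, 0))
    }
  }
  cols <- list(L = c(0, 1, 0), M = c(1, 0.5, 0), S = c(1, 0, 0))
  for (gl in report$glands) {
    nd <- gl$nodes
    for (i in seq_len(nrow(nd) - 1)) {
      n <- max(abs(nd$y[i + 1] - nd$y[i]), abs(nd$x[i + 1] - nd$x[i])) + 1
      put(round(seq(nd$y[i], nd$y[i + 1], length.out = n)),
          round(seq(nd$x[i], nd$x[i + 1], length.out = n)),
          cols[[gl$label]])
    }
  }
  eb <- EBImage::Image(aperm(rgb, c(2, 1, 3)), colormode = EBImage::Color)
  EBImage::writeImage(eb, path)
  invisible(path)
}

#' Write a synthetic scene triplet to disk
#'
#' Emits the rendered image, its eyelid mask and the ground-truth description
#' (JSON) for a given scene.
#'
#' @param truth `synth_truth` (e.g. from [synth_truth()]).
#' @param out_dir output directory, created if needed.
#' @param stem file stem for the triplet.
#' @return named character vector of the three paths, invisibly.
#' @export
write_synth_triplet <- function(truth, out_dir, stem = "scene") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- synth_render(truth)
  paths <- c(image = file.path(out_dir, paste0(stem, ".png")),
             mask = file.path(out_dir, paste0(stem, "_mask.png")),
             truth = file.path(out_dir, paste0(stem, "_truth.json")))
  write_gray(sc$image, paths["image"])
  write_gray(sc$mask * 255, paths["mask"])
  jsonlite::write_json(unclass(truth), paths["truth"], auto_unbox = TRUE,
                       digits = 8, pretty = TRUE)
  invisible(paths)
}
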
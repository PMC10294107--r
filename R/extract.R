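#' Compensate a box located on an eroded mask
#'
#' Components relocated after erosion are smaller than the true seed by
#' the kernel radius on every side; this expands the box back by
#' `(kernel - 1) / 2` pixels per side, clamped to the scene bounds.
#'
#' @param box one-row boxes data frame (or a full frame, expanded
#'   row-wise).
#' @param kernel erosion kernel side length used upstream.
#' @param bounds scene size as `c(width, height)` in pixels; `NULL`
#'   skips clamping.
#' @return the expanded box frame.
#' @export
erosion_compensation <- function(box, kernel, bounds = NULL) {
  r <- (kernel - 1L) %/% 2L
  x0 <- box$x - r
  y0 <- box$y - r
  x1 <- box$x + box$w + r
  y1 <- box$y + box$h + r
  if (!is.null(bounds)) {
    x0 <- pmax(x0, 0L); y0 <- pmax(y0, 0L)
    x1 <- pmin(x1, bounds[1]); y1 <- pmin(y1, bounds[2])
  }
  box$x <- as.integer(x0); box$y <- as.integer(y0)
  box$w <- as.integer(x1 - x0); box$h <- as.integer(y1 - y0)
  box
}

#' Crop one seed from a scene and resize to a square
#'
#' Expands the box by `pad` pixels per side (clamped at the borders),
#' embeds the region centered in a square canvas filled with the
#' background color, and resizes to `out_side` (bilinear). A region that
#' is already a square of side `out_side` is returned pixel-identical.
#'
#' @param scene RGB scene array (normally the MSRCR-enhanced scene).
#' @param box one-row boxes data frame.
#' @param pad extra margin per side in pixels.
#' @param out_side output side length (default 227).
#' @param bg background fill color, length-3 RGB in 0..255; `NULL` uses
#'   the per-channel median of the scene (background dominates a seed
#'   scene, so this approximates the background color).
#' @return a `seed_crop`: `out_side x out_side x 3` array (0..255) with
#'   attributes `scene_id`, `box` and `separated_by`.
#' @export
crop_seed <- function(scene, box, pad = 0, out_side = 227, bg = NULL) {
  if (box$w < 1 || box$h < 1)
    stop_parameter("degenerate box: width and height must be >= 1")
  d <- dim(scene)
  x0 <- max(box$x - pad, 0L)
  y0 <- max(box$y - pad, 0L)
  x1 <- min(box$x + box$w + pad, d[2])
  y1 <- min(box$y + box$h + pad, d[1])
  region <- unclass(scene)[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  rh <- dim(region)[1]; rw <- dim(region)[2]
  side <- max(rh, rw)
  if (is.null(bg))
    bg <- apply(unclass(scene), 3, median)
  canvas <- array(rep(bg, each = side * side), c(side, side, 3))
  ro <- (side - rh) %/% 2L
  co <- (side - rw) %/% 2L
  canvas[(ro + 1):(ro + rh), (co + 1):(co + rw), ] <- region
  if (side != out_side) {
    img <- EBImage::Image(aperm(canvas, c(2, 1, 3)) / 255,
                          colormode = "Color")
    img <- EBImage::resize(img, w = out_side, h = out_side,
                           filter = "bilinear")
    canvas <- quantize8(aperm(EBImage::imageData(img), c(2, 1, 3)) * 255)
  }
  structure(canvas, scene_id = scene_id(scene), box = box,
            separated_by = box$separated_by, class = "seed_crop")
}

#' Run the full seed-splitting pipeline on one scene
#'
#' Stages: MSRCR enhancement, Otsu binarization, component localization
#' by tight bounding rectangle, contact judgment from rectangle size;
#' non-touching boxes are cropped directly, touching clusters are masked
#' out, separated by erosion (EOP) or marker-based watershed (WA),
#' relocated, compensated (EOP only) and cropped. All crops come from
#' the enhanced scene unless `crop_raw = TRUE`.
#'
#' @param scene raw RGB scene array.
#' @param retinex [retinex_params()].
#' @param rule [contact_rule()].
#' @param sep [separation_config()].
#' @param min_area minimum component area in pixels squared; `NULL`
#'   means adaptive: components below 0.1 x the median component area
#'   are dropped as debris (an absolute floor of 32 px is always
#'   applied first).
#' @param pad crop margin per side in pixels.
#' @param out_side crop side length.
#' @param crops if `FALSE`, skip crop extraction (boxes only; used by
#'   the sweep harness where only box accuracy is needed).
#' @param crop_raw crop from the raw scene instead of the enhanced one.
#' @param enhanced optionally a precomputed [msrcr()] result for this
#'   scene, to avoid recomputation across configurations.
#' @return a `pipeline_result` list: `crops` (list of `seed_crop`),
#'   `boxes` (final boxes frame), `n_detected`, `scene_id`, `warnings`.
#'   A blank scene (degenerate histogram) yields zero boxes plus a
#'   warning record instead of an error.
#' @export
run_pipeline <- function(scene, retinex = retinex_params(),
                         rule = contact_rule(),
                         sep = separation_config("EOP", kernel = 13),
                         min_area = NULL, pad = 2, out_side = 227,
                         crops = TRUE, crop_raw = FALSE, enhanced = NULL) {
  if (is.null(enhanced)) enhanced <- msrcr(scene, retinex)
  empty <- function(warnings) {
    structure(list(crops = list(), boxes = boxes_frame(), n_detected = 0L,
                   scene_id = scene_id(scene), warnings = warnings),
              class = "pipeline_result")
  }
  mask <- tryCatch(binarize(enhanced), seedseg_degenerate_error = identity)
  if (inherits(mask, "condition"))
    return(empty(paste("blank scene:", conditionMessage(mask))))

  boxes <- locate_seeds(mask, min_area = 32)
  if (nrow(boxes) == 0L) return(empty("no components above minimum area"))
  if (is.null(min_area)) min_area <- 0.1 * median(boxes$area)
  boxes <- boxes[boxes$area >= min_area, , drop = FALSE]
  if (nrow(boxes) == 0L) return(empty("no components above minimum area"))
  boxes <- classify_touching(boxes, rule)

  med_side <- sqrt(median(as.numeric(boxes$w) * as.numeric(boxes$h)))
  sep_run <- sep
  if (sep$method == "WA" && is.null(sep$wa_min_distance))
    sep_run$wa_min_distance <- max(3, round(med_side / 2))

  lab <- label_components8(mask)
  final <- boxes[!boxes$touching, , drop = FALSE]
  for (k in which(boxes$touching)) {
    bx <- boxes[k, ]
    rows <- (bx$y + 1):(bx$y + bx$h)
    cols <- (bx$x + 1):(bx$x + bx$w)
    sub <- lab[rows, cols, drop = FALSE] == bx$component_id
    if (sep$method == "EOP") {
      sb <- separate_eop(sub, sep_run, min_area = 16)
      if (isTRUE(attr(sb, "eroded"))) {
        sb$x <- sb$x + bx$x
        sb$y <- sb$y + bx$y
        sb <- erosion_compensation(sb, sep_run$kernel,
                                   bounds = c(ncol(mask), nrow(mask)))
      } else {
        sb$x <- sb$x + bx$x
        sb$y <- sb$y + bx$y
      }
    } else {
      sb <- separate_wa(sub, sep_run)
      attr(sb, "basins") <- NULL
      sb$x <- sb$x + bx$x
      sb$y <- sb$y + bx$y
    }
    sb$touching <- TRUE
    sb$component_id <- bx$component_id
    final <- rbind(final, sb)
  }
  final <- final[order(final$y, final$x), , drop = FALSE]
  rownames(final) <- NULL

  crop_list <- list()
  if (crops && nrow(final) > 0L) {
    src <- if (crop_raw) scene else enhanced
    bg <- apply(unclass(src), 3, median)
    crop_list <- lapply(seq_len(nrow(final)), function(i)
      crop_seed(src, final[i, ], pad = pad, out_side = out_side, bg = bg))
  }
  structure(list(crops = crop_list, boxes = final,
                 n_detected = nrow(final), scene_id = scene_id(scene),
                 warnings = character(0)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result '%s': %d seed box(es), %d crop(s)\n",
              x$scene_id, nrow(x$boxes), length(x$crops)))
  if (nrow(x$boxes) > 0)
    cat(sprintf("  touching clusters separated: %d box(es) via %s\n",
                sum(x$boxes$separated_by != "none"),
                paste(setdiff(unique(x$boxes$separated_by), "none"),
                      collapse = "/")))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Scan a class-folder image dataset
#'
#' Counts image files (bmp/jpg/jpeg/png, case-insensitive) in each
#' immediate subfolder of `root` — the layout used to publish individual
#' seed images sorted into quality-class folders.
#'
#' @param root dataset root directory.
#' @return a `dataset_layout` list: `root`, `counts` (named integer
#'   vector per class folder), `total`.
#' @export
scan_dataset <- function(root) {
  if (!dir.exists(root)) stop_io(sprintf("no such dataset root: %s", root))
  folders <- list.dirs(root, recursive = FALSE, full.names = TRUE)
  counts <- vapply(folders, function(f)
    length(list.files(f, pattern = "\\.(bmp|jpe?g|png)$",
                      ignore.case = TRUE)), integer(1))
  names(counts) <- basename(folders)
  structure(list(root = root, counts = counts, total = sum(counts)),
            class = "dataset_layout")
}

#' @export
print.dataset_layout <- function(x, ...) {
  cat(sprintf("dataset at %s: %d class folder(s), %d image(s) total\n",
              x$root, length(x$counts), x$total))
  for (nm in names(x$counts)) cat(sprintf("  %-20s %6d\n", nm, x$counts[[nm]]))
  invisible(x)
}
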
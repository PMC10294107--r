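#' Otsu threshold of an intensity histogram
#'
#' Returns the gray level `t` in 0..255 maximizing the between-class
#' variance `w0 * w1 * (mu0 - mu1)^2` of the split into pixels `<= t`
#' (background class) and `> t`. Ties break toward the lowest level.
#'
#' @param histogram integer vector of 256 counts for levels 0..255.
#' @return the threshold level (integer in 0..255).
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256L || any(histogram < 0))
    stop_parameter("histogram must be 256 non-negative counts")
  if (sum(histogram > 0) < 2L)
    stop_degenerate("degenerate histogram: fewer than two occupied levels")
  h <- as.numeric(histogram)
  lev <- 0:255
  n <- sum(h)
  w0 <- cumsum(h)                # pixels at levels <= t
  s0 <- cumsum(h * lev)
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s0 / w0
  mu1 <- (s0[256] - s0) / w1
  score <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  score[!valid] <- -Inf
  lev[which.max(score)]
}

# ITU-R 601 luma of an RGB scene, rounded to integer levels 0..255
scene_luma <- function(scene) {
  quantize8(0.299 * scene[, , 1] + 0.587 * scene[, , 2] + 0.114 * scene[, , 3])
}

#' Binarize a scene with Otsu adaptive thresholding
#'
#' Converts to grayscale with ITU-R 601 luma weights, picks the Otsu
#' threshold of the 256-bin histogram, and marks foreground pixels.
#' Seeds are brighter than the background, so by default foreground is
#' the class above the threshold.
#'
#' @param scene RGB scene array (0..255).
#' @param invert if `TRUE` the foreground is the class at or below the
#'   threshold (dark objects on bright ground).
#' @return logical matrix of the scene's height x width; `TRUE` =
#'   foreground.
#' @export
binarize <- function(scene, invert = FALSE) {
  g <- scene_luma(scene)
  h <- tabulate(as.vector(g) + 1L, nbins = 256L)
  t <- otsu_threshold(h)
  if (invert) g <= t else g > t
}

boxes_frame <- function(x = integer(), y = integer(), w = integer(),
                        h = integer(), component_id = integer(),
                        area = integer()) {
  data.frame(x = as.integer(x), y = as.integer(y),
             w = as.integer(w), h = as.integer(h),
             component_id = as.integer(component_id),
             area = as.integer(area),
             touching = logical(length(x)),
             separated_by = rep("none", length(x)),
             unseparated = logical(length(x)),
             stringsAsFactors = FALSE)
}

#' Locate seeds as tight bounding rectangles
#'
#' Labels 8-connected foreground components and reports each component
#' with pixel area at least `min_area` as its tight axis-aligned bounding
#' box (0-based, half-open). Boxes are ordered by `y` then `x` of the
#' top-left corner.
#'
#' @param mask logical foreground matrix.
#' @param min_area minimum component pixel area to keep.
#' @return data frame with columns `x, y, w, h, component_id, area,
#'   touching, separated_by, unseparated` (the last three initialized to
#'   defaults).
#' @export
locate_seeds <- function(mask, min_area = 0) {
  if (!is.matrix(mask)) stop_parameter("mask must be a matrix")
  lab <- label_components8(mask)
  n <- max(lab)
  if (n == 0L) return(boxes_frame())
  idx <- which(lab > 0L)
  labs <- lab[idx]
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  rmin <- tapply(r, labs, min); rmax <- tapply(r, labs, max)
  cmin <- tapply(c, labs, min); cmax <- tapply(c, labs, max)
  area <- tapply(r, labs, length)
  keep <- area >= min_area
  b <- boxes_frame(x = cmin[keep] - 1L, y = rmin[keep] - 1L,
                   w = cmax[keep] - cmin[keep] + 1L,
                   h = rmax[keep] - rmin[keep] + 1L,
                   component_id = as.integer(names(area))[keep],
                   area = area[keep])
  b <- b[order(b$y, b$x), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Contact-judgment rule
#'
#' A box is judged to contain touching seeds when its rectangle is
#' markedly larger than the single-seed reference: area above
#' `area_ratio` times the reference area, or longest side above
#' `side_ratio` times the reference side (the square root of the
#' reference area). The reference defaults to the median box area of the
#' scene, which is robust because touching clusters are a minority.
#'
#' @param area_ratio area threshold ratio (> 1).
#' @param side_ratio longest-side threshold ratio (> 1).
#' @param reference `"median-of-scene"` or an explicit calibrated
#'   single-seed box area in pixels squared.
#' @return a `contact_rule` list.
#' @export
contact_rule <- function(area_ratio = 1.5, side_ratio = 1.4,
                         reference = "median-of-scene") {
  if (area_ratio <= 1 || side_ratio <= 1)
    stop_parameter("contact ratios must exceed 1")
  if (!identical(reference, "median-of-scene") &&
      !(is.numeric(reference) && length(reference) == 1L && reference > 0))
    stop_parameter("reference must be 'median-of-scene' or a positive area")
  structure(list(area_ratio = area_ratio, side_ratio = side_ratio,
                 reference = reference),
            class = "contact_rule")
}

#' Flag boxes that contain physically touching seeds
#'
#' @param boxes data frame from [locate_seeds()].
#' @param rule a [contact_rule()].
#' @return the boxes with the `touching` column set.
#' @export
classify_touching <- function(boxes, rule = contact_rule()) {
  ref <- rule$reference
  if (identical(ref, "median-of-scene")) {
    if (nrow(boxes) == 0L)
      stop_parameter("median-of-scene reference needs at least one box")
    ref <- median(as.numeric(boxes$w) * as.numeric(boxes$h))
  }
  box_area <- as.numeric(boxes$w) * as.numeric(boxes$h)
  long_side <- pmax(boxes$w, boxes$h)
  boxes$touching <- box_area > rule$area_ratio * ref |
    long_side > rule$side_ratio * sqrt(ref)
  boxes
}

#' Separation configuration
#'
#' @param method `"EOP"` (erosion) or `"WA"` (marker-based watershed).
#' @param kernel odd square erosion kernel side length in pixels.
#' @param wa_min_distance minimum marker separation in pixels for the
#'   watershed; `NULL` means auto (half the scene's median seed side).
#' @return a `separation_config` list.
#' @export
separation_config <- function(method = c("EOP", "WA"), kernel = 13,
                              wa_min_distance = NULL) {
  method <- match.arg(method)
  if (kernel %% 2 != 1 || kernel < 3)
    stop_parameter("kernel must be odd and >= 3")
  structure(list(method = method, kernel = as.integer(kernel),
                 wa_min_distance = wa_min_distance),
            class = "separation_config")
}

#' Morphological erosion with a square kernel
#'
#' A foreground pixel survives iff every pixel of the centered
#' `kernel x kernel` square neighborhood is foreground; pixels outside
#' the image count as background, so objects touching the border erode
#' there too.
#'
#' @param mask logical foreground matrix.
#' @param kernel odd side length (>= 1); 1 is the identity.
#' @return eroded logical matrix of the same shape.
#' @export
erode_mask <- function(mask, kernel) {
  if (length(kernel) != 1L || kernel < 1 || kernel %% 2 != 1)
    stop_parameter("erosion kernel must be a single odd value >= 1")
  if (kernel == 1) return(mask)
  r <- (kernel - 1L) %/% 2L
  # zero-pad so the out-of-image neighborhood counts as background
  padded <- matrix(0, nrow(mask) + 2L * r, ncol(mask) + 2L * r)
  padded[(r + 1L):(r + nrow(mask)), (r + 1L):(r + ncol(mask))] <- mask
  e <- EBImage::erode(EBImage::Image(t(padded)),
                      EBImage::makeBrush(as.integer(kernel), shape = "box"))
  t(EBImage::imageData(e))[(r + 1L):(r + nrow(mask)),
                           (r + 1L):(r + ncol(mask))] > 0.5
}

# tight box of a mask, as a one-row boxes frame; NULL if mask is empty
mask_tight_box <- function(mask, component_id = 1L) {
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  boxes_frame(x = min(c) - 1L, y = min(r) - 1L,
              w = diff(range(c)) + 1L, h = diff(range(r)) + 1L,
              component_id = component_id, area = length(idx))
}

#' Separate a touching cluster by erosion (EOP)
#'
#' Erodes the cluster mask with the configured square kernel and
#' relocates components by tight bounding rectangles. The returned boxes
#' live in the eroded geometry; callers compensate box extents by the
#' kernel radius before cropping (see [erosion_compensation()]).
#'
#' @param cluster_mask logical matrix holding one touching cluster.
#' @param config a [separation_config()] with `method = "EOP"`.
#' @param min_area minimum surviving component area in the eroded mask.
#' @return boxes data frame; `eroded` attribute `TRUE` when boxes need
#'   compensation. If erosion removes the whole cluster, the original
#'   cluster box is returned with `unseparated = TRUE`.
#' @export
separate_eop <- function(cluster_mask, config = separation_config("EOP"),
                         min_area = 16) {
  if (config$method != "EOP")
    stop_parameter("separate_eop needs method = 'EOP'")
  e <- erode_mask(cluster_mask, config$kernel)
  b <- locate_seeds(e, min_area = min_area)
  if (nrow(b) == 0L) {
    b <- mask_tight_box(cluster_mask)
    if (is.null(b)) return(boxes_frame())
    b$unseparated <- TRUE
    b$separated_by <- "EOP"
    attr(b, "eroded") <- FALSE
    return(b)
  }
  b$separated_by <- "EOP"
  attr(b, "eroded") <- TRUE
  b
}

# local maxima of a distance map with minimum mutual separation;
# returns an integer marker matrix (0 = none, 1..m = marker ids)
distance_markers <- function(dist, mask, min_distance) {
  win <- 2L * max(1L, as.integer(round(min_distance / 2))) + 1L
  dil <- t(EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(dist)), EBImage::makeBrush(win, shape = "box"))))
  cand <- mask & dist >= 1 & dist >= dil - 1e-9
  if (!any(cand)) return(matrix(0L, nrow(mask), ncol(mask)))
  plats <- label_components8(cand)
  np <- max(plats)
  peak <- numeric(np); cr <- numeric(np); cc <- numeric(np)
  for (p in seq_len(np)) {
    idx <- which(plats == p)
    nr <- nrow(mask)
    r <- (idx - 1L) %% nr + 1L
    c <- (idx - 1L) %/% nr + 1L
    peak[p] <- max(dist[idx])
    cr[p] <- round(mean(r)); cc[p] <- round(mean(c))
    if (!mask[cr[p], cc[p]]) { cr[p] <- r[1]; cc[p] <- c[1] }
  }
  ord <- order(-peak, cr, cc)
  keep <- integer(0)
  for (p in ord) {
    if (length(keep) == 0L ||
        all(sqrt((cr[keep] - cr[p])^2 + (cc[keep] - cc[p])^2) >=
            min_distance))
      keep <- c(keep, p)
  }
  markers <- matrix(0L, nrow(mask), ncol(mask))
  for (m in seq_along(keep)) markers[cr[keep[m]], cc[keep[m]]] <- m
  markers
}

#' Separate a touching cluster by marker-based watershed (WA)
#'
#' Markers are local maxima of the Euclidean distance transform of the
#' cluster, thinned to a minimum mutual separation; basins are grown
#' from the markers over the cluster foreground (Voronoi-style region
#' growing on the distance map), so the basins partition the cluster
#' exactly. Each basin is reported as its tight bounding rectangle.
#'
#' @param cluster_mask logical matrix holding one touching cluster.
#' @param config a [separation_config()] with `method = "WA"`; its
#'   `wa_min_distance` must be set (the pipeline fills the auto value).
#' @return boxes data frame in the original geometry; attribute
#'   `basins` holds the integer basin label matrix. If no markers are
#'   found the original cluster box is returned with
#'   `unseparated = TRUE`.
#' @export
separate_wa <- function(cluster_mask, config = separation_config("WA")) {
  if (config$method != "WA")
    stop_parameter("separate_wa needs method = 'WA'")
  mind <- config$wa_min_distance
  if (is.null(mind)) mind <- max(3, round(min(dim(cluster_mask)) / 4))
  d <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(cluster_mask)))))
  markers <- distance_markers(d, cluster_mask, mind)
  nm <- max(markers)
  if (nm == 0L) {
    b <- mask_tight_box(cluster_mask)
    if (is.null(b)) return(boxes_frame())
    b$unseparated <- TRUE
    b$separated_by <- "WA"
    return(b)
  }
  if (nm == 1L) {
    b <- mask_tight_box(cluster_mask)
    b$separated_by <- "WA"
    attr(b, "basins") <- ifelse(cluster_mask, 1L, 0L) * 1L
    return(b)
  }
  basins <- EBImage::propagate(EBImage::Image(t(d)),
                               seeds = EBImage::Image(t(markers)),
                               mask = EBImage::Image(t(cluster_mask)))
  basins <- t(EBImage::imageData(basins))
  out <- NULL
  for (m in seq_len(nm)) {
    bm <- mask_tight_box(basins == m, component_id = m)
    if (!is.null(bm)) out <- rbind(out, bm)
  }
  out$separated_by <- "WA"
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "basins") <- basins
  out
}
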
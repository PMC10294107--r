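#' Construct a scene from a numeric array
#'
#' A scene is a `height x width x 3` numeric array with values in 0..255
#' (8-bit RGB) carrying a `scene_id` attribute.
#'
#' @param x numeric array, `height x width x 3`, values in 0..255.
#' @param id character scene identifier.
#' @return the array with class `seed_scene`.
#' @export
as_scene <- function(x, id = "scene") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop_parameter("a scene must be a height x width x 3 array")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop_parameter("scene values must be in 0..255")
  structure(x, scene_id = as.character(id), class = "seed_scene")
}

#' @export
print.seed_scene <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("seed_scene '%s': %d x %d px, 3-channel 8-bit RGB\n",
              scene_id(x), d[2], d[1]))
  invisible(x)
}

scene_id <- function(scene) {
  id <- attr(scene, "scene_id")
  if (is.null(id)) "scene" else id
}

#' Read a scene image file
#'
#' Reads an 8-bit RGB image (PNG, JPG or BMP) into a scene array.
#'
#' @param path image file path.
#' @return a [as_scene()] array, `height x width x 3`, values 0..255.
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such image file: %s", path))
  img <- EBImage::readImage(path)
  d <- dim(img)
  dat <- EBImage::imageData(img)
  if (length(d) == 2L) dat <- array(rep(dat, 3L), c(d[1], d[2], 3L))
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
  # EBImage stores width x height in [0,1]; convert to row-major 0..255
  x <- aperm(dat, c(2L, 1L, 3L)) * 255
  as_scene(round(x), id = sub("\\.[^.]+$", "", basename(path)))
}

#' Write a scene image file
#'
#' @param scene a scene array (0..255).
#' @param path output path; format from the extension (png/jpg/jpeg/bmp
#'   are accepted, bmp is written as png content is not supported by the
#'   underlying writer and raises an error).
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  img <- EBImage::Image(aperm(scene, c(2L, 1L, 3L)) / 255,
                        colormode = "Color")
  ok <- try(EBImage::writeImage(img, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop_io(sprintf("cannot write image: %s", path))
  invisible(path)
}

# clamp and quantize a numeric array to 8-bit levels
quantize8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}
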
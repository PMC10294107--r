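#' Synthetic scene generator configuration
#'
#' Describes a rendered benchmark scene: bright convex, ellipse-like,
#' soybean-hued seed blobs on a dark background, a controllable fraction
#' of seeds joined in pairs by thin "tiny contact" bridges, a horizontal
#' illumination ramp and additive pixel noise. The default scene is
#' 1024 x 683 px, a 3:2 format at desk scale; soybeans are commercially
#' size-graded and near-spherical, so the default size dispersion is
#' small (major semi-axis 20-26 px, aspect ratio 0.75-1).
#'
#' @param width,height scene size in pixels.
#' @param n_seeds number of seeds.
#' @param touching_fraction fraction of seeds placed in tiny-contact
#'   pairs; the number of pairs is `floor(touching_fraction * n_seeds / 2)`.
#' @param bridge_width contact-bridge thickness in pixels.
#' @param seed_axes_range min/max major semi-axis in pixels; the minor
#'   semi-axis is the major times a uniform draw from `aspect_range`.
#' @param aspect_range minor/major axis ratio range.
#' @param base_color mean seed RGB (0..255).
#' @param color_jitter per-seed uniform color deviation (0..255).
#' @param background_color background RGB (0..255).
#' @param noise_sigma additive Gaussian pixel noise standard deviation.
#' @param illum_gradient maximum relative brightness ramp across the
#'   scene width (0 disables).
#' @param rng_seed integer random seed; the scene and its ground truth
#'   are fully determined by it.
#' @return a `gen_config` list.
#' @export
gen_config <- function(width = 1024, height = 683, n_seeds = 40,
                       touching_fraction = 0.2, bridge_width = 3,
                       seed_axes_range = c(20, 26),
                       aspect_range = c(0.75, 1),
                       base_color = c(205, 170, 90), color_jitter = 18,
                       background_color = c(30, 30, 32),
                       noise_sigma = 4, illum_gradient = 0.15,
                       rng_seed = 1L) {
  if (touching_fraction < 0 || touching_fraction > 1)
    stop_parameter("touching_fraction must be in [0, 1]")
  if (bridge_width < 1) stop_parameter("bridge_width must be >= 1")
  if (any(seed_axes_range <= 0) || diff(seed_axes_range) < 0)
    stop_parameter("seed_axes_range must be positive and ordered")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_seeds = as.integer(n_seeds),
                 touching_fraction = touching_fraction,
                 bridge_width = bridge_width,
                 seed_axes_range = seed_axes_range,
                 aspect_range = aspect_range,
                 base_color = base_color, color_jitter = color_jitter,
                 background_color = background_color,
                 noise_sigma = noise_sigma,
                 illum_gradient = illum_gradient,
                 rng_seed = as.integer(rng_seed)),
            class = "gen_config")
}

# radius of a rotated ellipse boundary along direction phi from center
ellipse_support <- function(a, b, rot, phi) {
  psi <- phi - rot
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

# rasterize one ellipse: local logical mask over pixel centers, with
# 0-based bbox origin (x0, y0)
ellipse_local_mask <- function(cx, cy, a, b, rot, width, height) {
  ex <- sqrt((a * cos(rot))^2 + (b * sin(rot))^2)
  ey <- sqrt((a * sin(rot))^2 + (b * cos(rot))^2)
  c0 <- max(floor(cx - ex), 0); c1 <- min(ceiling(cx + ex), width - 1)
  r0 <- max(floor(cy - ey), 0); r1 <- min(ceiling(cy + ey), height - 1)
  xs <- c0:c1; ys <- r0:r1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(rot) + dy * sin(rot)) / a
  v <- (-dx * sin(rot) + dy * cos(rot)) / b
  list(x0 = as.integer(c0), y0 = as.integer(r0), mask = u^2 + v^2 <= 1)
}

# rasterize a thick segment (the contact bridge) as a local mask
segment_local_mask <- function(p1, p2, half_width, width, height) {
  c0 <- max(floor(min(p1[1], p2[1]) - half_width - 1), 0)
  c1 <- min(ceiling(max(p1[1], p2[1]) + half_width + 1), width - 1)
  r0 <- max(floor(min(p1[2], p2[2]) - half_width - 1), 0)
  r1 <- min(ceiling(max(p1[2], p2[2]) + half_width + 1), height - 1)
  xs <- c0:c1; ys <- r0:r1
  px <- outer(rep(1, length(ys)), xs)
  py <- outer(ys, rep(1, length(xs)))
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else
    pmin(pmax(((px - p1[1]) * vx + (py - p1[2]) * vy) / len2, 0), 1)
  d2 <- (px - (p1[1] + t * vx))^2 + (py - (p1[2] + t * vy))^2
  list(x0 = as.integer(c0), y0 = as.integer(r0),
       mask = d2 <= half_width^2)
}

paint_local <- function(canvas, lm, value) {
  rows <- (lm$y0 + 1):(lm$y0 + nrow(lm$mask))
  cols <- (lm$x0 + 1):(lm$x0 + ncol(lm$mask))
  block <- canvas[rows, cols]
  block[lm$mask] <- value
  canvas[rows, cols] <- block
  canvas
}

#' Generate one synthetic seed scene with ground truth
#'
#' Places rotated ellipses by dart throwing with a guaranteed boundary
#' gap of at least 6 px between non-designated seeds. Designated
#' touching pairs are placed with a 2 px boundary gap along the line of
#' centers and joined by an explicitly drawn bridge of the configured
#' width, so the "tiny contact" regime that square-kernel erosion
#' targets is controlled exactly. Rendering adds per-seed color jitter,
#' a multiplicative illumination ramp and Gaussian noise, then
#' quantizes to 8-bit. The output is fully determined by
#' `config$rng_seed`.
#'
#' @param config a [gen_config()].
#' @return list of `scene` (a [as_scene()] array) and `truth`, a
#'   `scene_truth` list: `seeds` (per seed: `center`, `axes`, `rot`,
#'   bbox origin `x0`/`y0` and local `mask`), `touching_pairs` (pair
#'   index matrix), `union_mask`, `boxes` (tight per-seed boxes frame),
#'   `config`.
#' @export
generate_scene <- function(config = gen_config()) {
  W <- config$width; H <- config$height
  n <- config$n_seeds
  amax <- config$seed_axes_range[2]
  if (n * pi * amax^2 > 0.4 * W * H)
    stop_parameter("infeasible packing: total seed area exceeds 40% of scene")

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$rng_seed)

  n_pairs <- floor(config$touching_fraction * n / 2)
  gap_free <- 6; gap_pair <- 2; margin <- 8

  draw_shape <- function() {
    a <- runif(1, config$seed_axes_range[1], config$seed_axes_range[2])
    b <- a * runif(1, config$aspect_range[1], config$aspect_range[2])
    list(a = a, b = b, rot = runif(1, 0, pi))
  }
  fits_free <- function(cx, cy, a, placed, skip = 0L) {
    if (cx < a + margin || cx > W - 1 - a - margin ||
        cy < a + margin || cy > H - 1 - a - margin) return(FALSE)
    for (s in seq_along(placed)) {
      if (s == skip) next
      p <- placed[[s]]
      if (sqrt((p$cx - cx)^2 + (p$cy - cy)^2) < a + p$a + gap_free)
        return(FALSE)
    }
    TRUE
  }

  place_all <- function() {
    placed <- list()
    pairs <- matrix(integer(0), ncol = 2)
    # designated pairs first, then singles
    for (p in seq_len(n_pairs)) {
      sa <- draw_shape(); sb <- draw_shape()
      ok <- FALSE
      for (try in 1:400) {
        cxa <- runif(1, sa$a + margin, W - 1 - sa$a - margin)
        cya <- runif(1, sa$a + margin, H - 1 - sa$a - margin)
        if (!fits_free(cxa, cya, sa$a, placed)) next
        phi <- runif(1, 0, 2 * pi)
        d <- ellipse_support(sa$a, sa$b, sa$rot, phi) +
          ellipse_support(sb$a, sb$b, sb$rot, phi + pi) + gap_pair
        cxb <- cxa + d * cos(phi); cyb <- cya + d * sin(phi)
        if (!fits_free(cxb, cyb, sb$a, placed)) next
        placed[[length(placed) + 1]] <-
          list(cx = cxa, cy = cya, a = sa$a, b = sa$b, rot = sa$rot,
               phi = phi)
        placed[[length(placed) + 1]] <-
          list(cx = cxb, cy = cyb, a = sb$a, b = sb$b, rot = sb$rot,
               phi = NA)
        pairs <- rbind(pairs, c(length(placed) - 1L, length(placed)))
        ok <- TRUE
        break
      }
      if (!ok) return(NULL)
    }
    for (s in seq_len(n - 2 * n_pairs)) {
      sh <- draw_shape()
      ok <- FALSE
      for (try in 1:400) {
        cx <- runif(1, sh$a + margin, W - 1 - sh$a - margin)
        cy <- runif(1, sh$a + margin, H - 1 - sh$a - margin)
        if (fits_free(cx, cy, sh$a, placed)) {
          placed[[length(placed) + 1]] <-
            list(cx = cx, cy = cy, a = sh$a, b = sh$b, rot = sh$rot,
                 phi = NA)
          ok <- TRUE
          break
        }
      }
      if (!ok) return(NULL)
    }
    list(placed = placed, pairs = pairs)
  }

  layout <- NULL
  for (restart in 1:20) {
    layout <- place_all()
    if (!is.null(layout)) break
  }
  if (is.null(layout))
    stop_parameter("packing failed: scene capacity exceeded after retries")
  placed <- layout$placed; pairs <- layout$pairs

  seeds <- vector("list", n)
  union_mask <- matrix(FALSE, H, W)
  for (s in seq_len(n)) {
    p <- placed[[s]]
    lm <- ellipse_local_mask(p$cx, p$cy, p$a, p$b, p$rot, W, H)
    seeds[[s]] <- list(center = c(p$cx, p$cy), axes = c(p$a, p$b),
                       rot = p$rot, x0 = lm$x0, y0 = lm$y0,
                       mask = lm$mask)
    union_mask <- paint_local(union_mask, lm, TRUE)
  }

  bridges <- vector("list", nrow(pairs))
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ia <- pairs[k, 1]; ib <- pairs[k, 2]
      pa <- placed[[ia]]; pb <- placed[[ib]]
      phi <- pa$phi
      u <- c(cos(phi), sin(phi))
      p1 <- c(pa$cx, pa$cy) +
        (ellipse_support(pa$a, pa$b, pa$rot, phi) - 1.5) * u
      p2 <- c(pb$cx, pb$cy) -
        (ellipse_support(pb$a, pb$b, pb$rot, phi + pi) - 1.5) * u
      bridges[[k]] <- segment_local_mask(p1, p2, config$bridge_width / 2,
                                         W, H)
      union_mask <- paint_local(union_mask, bridges[[k]], TRUE)
    }
  }

  # render: background, seeds with per-seed jittered color, bridges in
  # the pair's mean color, illumination ramp, noise, 8-bit quantization
  img <- array(0, c(H, W, 3))
  seed_colors <- matrix(0, n, 3)
  for (s in seq_len(n))
    seed_colors[s, ] <- config$base_color +
      runif(3, -config$color_jitter, config$color_jitter)
  for (ch in 1:3) {
    plane <- matrix(config$background_color[ch], H, W)
    for (s in seq_len(n))
      plane <- paint_local(plane, seeds[[s]][c("x0", "y0", "mask")],
                           seed_colors[s, ch])
    if (nrow(pairs) > 0)
      for (k in seq_len(nrow(pairs)))
        plane <- paint_local(plane, bridges[[k]],
                             mean(seed_colors[pairs[k, ], ch]))
    if (config$illum_gradient > 0) {
      ramp <- 1 + config$illum_gradient * ((0:(W - 1)) / (W - 1) - 0.5)
      plane <- plane * matrix(ramp, H, W, byrow = TRUE)
    }
    img[, , ch] <- plane
  }
  if (config$noise_sigma > 0)
    img <- img + rnorm(length(img), 0, config$noise_sigma)
  scene <- as_scene(quantize8(img),
                    id = sprintf("synth-%d", config$rng_seed))

  boxes <- do.call(rbind, lapply(seq_len(n), function(s) {
    sd <- seeds[[s]]
    idx <- which(sd$mask, arr.ind = TRUE)
    data.frame(x = sd$x0 + min(idx[, 2]) - 1L,
               y = sd$y0 + min(idx[, 1]) - 1L,
               w = diff(range(idx[, 2])) + 1L,
               h = diff(range(idx[, 1])) + 1L,
               seed = s)
  }))
  truth <- structure(list(seeds = seeds, touching_pairs = pairs,
                          union_mask = union_mask, boxes = boxes,
                          config = config),
                     class = "scene_truth")
  list(scene = scene, truth = truth)
}

#' Generate an in-memory benchmark
#'
#' Renders `n_scenes` scenes from one configuration, giving scene `i`
#' the seed `config$rng_seed + i - 1`.
#'
#' @param n_scenes number of scenes.
#' @param config a [gen_config()].
#' @return list of `list(scene = , truth = )` pairs.
#' @export
generate_benchmark <- function(n_scenes, config = gen_config()) {
  lapply(seq_len(n_scenes), function(i) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + i - 1L
    generate_scene(cfg)
  })
}

#' Run-length encode a logical mask
#'
#' @param mask logical matrix.
#' @return list with `nrow`, `ncol`, `first` (value of the first run)
#'   and `runs` (alternating run lengths, column-major order).
#' @export
mask_to_rle <- function(mask) {
  r <- rle(as.vector(mask))
  list(nrow = nrow(mask), ncol = ncol(mask),
       first = r$values[1], runs = r$lengths)
}

#' Decode a run-length encoded mask
#'
#' @param enc a [mask_to_rle()] encoding.
#' @return the logical matrix.
#' @export
rle_to_mask <- function(enc) {
  vals <- rep(c(enc$first, !enc$first), length.out = length(enc$runs))
  matrix(inverse.rle(structure(list(lengths = as.integer(enc$runs),
                                    values = as.logical(vals)),
                               class = "rle")),
         nrow = enc$nrow, ncol = enc$ncol)
}

truth_to_json <- function(truth, path) {
  seeds <- lapply(truth$seeds, function(sd) {
    list(center = sd$center, axes = sd$axes, rot = sd$rot,
         x0 = sd$x0, y0 = sd$y0, mask = mask_to_rle(sd$mask))
  })
  obj <- list(seeds = seeds,
              touching_pairs = truth$touching_pairs,
              union_mask = mask_to_rle(truth$union_mask),
              boxes = truth$boxes,
              config = unclass(truth$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

json_rle <- function(node) {
  list(nrow = as.integer(node$nrow), ncol = as.integer(node$ncol),
       first = isTRUE(node$first),
       runs = as.integer(unlist(node$runs)))
}

json_to_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  seeds <- lapply(obj$seeds, function(sd) {
    list(center = as.numeric(unlist(sd$center)),
         axes = as.numeric(unlist(sd$axes)),
         rot = as.numeric(sd$rot),
         x0 = as.integer(sd$x0), y0 = as.integer(sd$y0),
         mask = rle_to_mask(json_rle(sd$mask)))
  })
  pairs <- if (length(obj$touching_pairs) == 0)
    matrix(integer(0), ncol = 2)
  else do.call(rbind, lapply(obj$touching_pairs,
                             function(p) as.integer(unlist(p))))
  boxes <- do.call(rbind, lapply(obj$boxes, function(b)
    data.frame(x = as.integer(b$x), y = as.integer(b$y),
               w = as.integer(b$w), h = as.integer(b$h),
               seed = as.integer(b$seed))))
  cfg <- do.call(gen_config, lapply(obj$config, unlist))
  structure(list(seeds = seeds, touching_pairs = pairs,
                 union_mask = rle_to_mask(json_rle(obj$union_mask)),
                 boxes = boxes, config = cfg),
            class = "scene_truth")
}

#' Write a benchmark directory
#'
#' Writes `n_scenes` PNG scenes, one ground-truth JSON sidecar per scene
#' (masks as run-length encodings) and a manifest recording the
#' configuration and per-scene seeds, sufficient to regenerate the
#' directory bit-exactly.
#'
#' @param n_scenes number of scenes.
#' @param config a [gen_config()].
#' @param out output directory (created if missing).
#' @return `out`, invisibly.
#' @export
make_benchmark <- function(n_scenes, config = gen_config(), out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) stop_io(sprintf("cannot create directory: %s", out))
  scenes <- character(n_scenes)
  for (i in seq_len(n_scenes)) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + i - 1L
    sc <- generate_scene(cfg)
    scenes[i] <- sprintf("scene_%03d", i)
    write_scene(sc$scene, file.path(out, paste0(scenes[i], ".png")))
    truth_to_json(sc$truth, file.path(out, paste0(scenes[i], ".truth.json")))
  }
  manifest <- list(n_scenes = n_scenes, config = unclass(config),
                   scenes = scenes,
                   scene_seeds = config$rng_seed + seq_len(n_scenes) - 1L)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Regenerate a benchmark from its manifest
#'
#' @param manifest path to a `manifest.json` written by
#'   [make_benchmark()].
#' @param out output directory.
#' @return `out`, invisibly.
#' @export
make_benchmark_from_manifest <- function(manifest, out) {
  if (!file.exists(manifest)) stop_io("manifest not found")
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  make_benchmark(m$n_scenes, do.call(gen_config, as.list(m$config)), out)
}

#' Load a benchmark directory
#'
#' @param dir directory written by [make_benchmark()].
#' @return list of `list(scene = , truth = )` pairs, as
#'   [generate_benchmark()] returns.
#' @export
load_benchmark <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_io(sprintf("no manifest.json in %s", dir))
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  lapply(m$scenes, function(s) {
    list(scene = read_scene(file.path(dir, paste0(s, ".png"))),
         truth = json_to_truth(file.path(dir, paste0(s, ".truth.json"))))
  })
}
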
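# Fixtures are built in code at test time; nothing is stored on disk.

# plain numeric array of an image object, all extra attributes dropped
arr <- function(x) {
  x <- unclass(x)
  array(as.numeric(x), dim(x))
}

# small scene for pipeline-level tests: fast to enhance, same physics
# as the full-size default
small_gen_config <- function(rng_seed = 7, n_seeds = 10,
                             touching_fraction = 0, ...) {
  gen_config(width = 512, height = 342, n_seeds = n_seeds,
             touching_fraction = touching_fraction, rng_seed = rng_seed,
             ...)
}

# flat two-tone scene: dark field with a bright axis-aligned block
two_tone_scene <- function(n = 8, m = 8, lo = 40, hi = 200) {
  x <- array(lo, c(n, m, 3))
  x[3:6, 3:6, ] <- hi
  as_scene(x, id = "two-tone")
}

# bright disk on dark ground, used for contrast-gain checks
disk_scene <- function(n = 120, m = 160, r = 25, lo = 30, hi = 190) {
  x <- array(lo, c(n, m, 3))
  d <- outer((1:n) - n / 2, rep(1, m))^2 + outer(rep(1, n), (1:m) - m / 2)^2
  for (ch in 1:3) { p <- x[, , ch]; p[d <= r^2] <- hi; x[, , ch] <- p }
  as_scene(x, id = "disk")
}

# two filled squares joined by a thin horizontal bridge
bridged_squares_mask <- function(side = 20, bridge_w = 4, bridge_len = 6,
                                 pad = 10) {
  h <- side + 2 * pad
  w <- 2 * side + bridge_len + 2 * pad
  mask <- matrix(FALSE, h, w)
  mask[pad + 1:side, pad + 1:side] <- TRUE
  mask[pad + 1:side, pad + side + bridge_len + 1:side] <- TRUE
  mid <- pad + side %/% 2
  rows <- (mid - bridge_w %/% 2 + 1):(mid - bridge_w %/% 2 + bridge_w)
  mask[rows, (pad + side + 1):(pad + side + bridge_len)] <- TRUE
  mask
}

# deterministic random blob mask (union of random rectangles)
random_blob_mask <- function(n = 120, m = 160, blobs = 20, seed = 1) {
  set.seed(seed)
  mask <- matrix(FALSE, n, m)
  for (b in seq_len(blobs)) {
    r0 <- sample(n - 8, 1); c0 <- sample(m - 8, 1)
    mask[r0 + 1:sample(3:8, 1), c0 + 1:sample(3:8, 1)] <- TRUE
  }
  mask[1:n > n - 2, ] <- FALSE  # keep away from the lower border
  mask
}

one_box <- function(x, y, w, h, ...) {
  b <- data.frame(x = x, y = y, w = w, h = h, component_id = 1L,
                  area = w * h, touching = FALSE, separated_by = "none",
                  unseparated = FALSE, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) b[[nm]] <- extra[[nm]]
  b
}
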
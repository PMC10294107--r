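test_that("otsu threshold separates a two-delta histogram", {
  h <- integer(256)
  h[50 + 1] <- 400; h[200 + 1] <- 600
  t <- otsu_threshold(h)
  expect_true(t >= 50 && t < 200)
})

test_that("otsu threshold equals the exhaustive scan", {
  set.seed(3)
  for (i in 1:25) {
    n1 <- sample(200:2000, 1); n2 <- sample(200:2000, 1)
    g <- c(rnorm(n1, runif(1, 40, 90), runif(1, 5, 25)),
           rnorm(n2, runif(1, 120, 220), runif(1, 5, 25)))
    h <- tabulate(pmax(pmin(round(g), 255), 0) + 1, nbins = 256)
    expect_identical(otsu_threshold(h), oracle_otsu(h))
  }
})

test_that("degenerate histograms are rejected", {
  h <- integer(256); h[128] <- 1000
  expect_error(otsu_threshold(h), class = "seedseg_degenerate_error")
  expect_error(otsu_threshold(rep(1, 100)), class = "seedseg_parameter_error")
  black <- as_scene(array(0, c(8, 8, 3)))
  expect_error(binarize(black), class = "seedseg_degenerate_error")
})

test_that("binarize recovers the generator's union mask", {
  sc <- generate_scene(small_gen_config(rng_seed = 3))
  mask <- binarize(sc$scene)
  sym_diff <- sum(xor(mask, sc$truth$union_mask))
  expect_lt(sym_diff / sum(sc$truth$union_mask), 0.02)
})

test_that("inverting the scene and the polarity flag gives the same mask", {
  sc <- generate_scene(small_gen_config(rng_seed = 5))
  inv <- as_scene(255 - unclass(sc$scene))
  expect_identical(binarize(sc$scene), binarize(inv, invert = TRUE))
})

test_that("locate_seeds reports tight boxes in deterministic order", {
  mask <- matrix(FALSE, 30, 30)
  mask[8:17, 6:15] <- TRUE  # rows y=7..16, cols x=5..14
  b <- locate_seeds(mask)
  expect_equal(nrow(b), 1L)
  expect_equal(unlist(b[1, c("x", "y", "w", "h")], use.names = FALSE),
               c(5, 7, 10, 10))
  mask[22:25, 20:26] <- TRUE
  b2 <- locate_seeds(mask)
  expect_equal(b2$y, c(7, 21))   # ordered by row then column
  expect_equal(b2$x, c(5, 19))
})

test_that("locate_seeds agrees with the exhaustive component-walk oracle", {
  mask <- random_blob_mask(blobs = 50, seed = 14)
  got <- locate_seeds(mask)
  want <- oracle_boxes(mask)
  expect_equal(got[, c("x", "y", "w", "h", "area")], want,
               ignore_attr = TRUE)
})

test_that("boxes are tight: every box edge touches a component pixel", {
  mask <- random_blob_mask(blobs = 30, seed = 8)
  lab <- seedseg:::label_components8(mask)
  b <- locate_seeds(mask)
  for (i in seq_len(nrow(b))) {
    comp <- lab[(b$y[i] + 1):(b$y[i] + b$h[i]),
                (b$x[i] + 1):(b$x[i] + b$w[i]), drop = FALSE] ==
      b$component_id[i]
    expect_true(any(comp[1, ]) && any(comp[nrow(comp), ]) &&
                  any(comp[, 1]) && any(comp[, ncol(comp)]))
  }
})

test_that("contact judgment flags oversized rectangles only", {
  same <- do.call(rbind, lapply(1:10, function(i)
    one_box(10 * i, 0, 10, 10)))
  expect_false(any(classify_touching(same)$touching))
  mixed <- rbind(do.call(rbind, lapply(1:9, function(i)
    one_box(20 * i, 0, 10, 10))), one_box(0, 40, 15, 15))
  flags <- classify_touching(mixed, contact_rule(area_ratio = 1.5))$touching
  expect_identical(flags, c(rep(FALSE, 9), TRUE))
  expect_error(classify_touching(locate_seeds(matrix(FALSE, 5, 5))),
               class = "seedseg_parameter_error")
  expect_error(contact_rule(area_ratio = 0.9),
               class = "seedseg_parameter_error")
})

test_that("erosion follows its definition on analytic fixtures", {
  m <- bridged_squares_mask(side = 20, bridge_w = 4)
  e <- erode_mask(m, 13)
  b <- locate_seeds(e)
  expect_equal(nrow(b), 2L)            # bridge eliminated
  expect_true(all(b$w == 8 & b$h == 8))  # 20 - 2*6 per side
  sq <- matrix(FALSE, 40, 40); sq[10:21, 10:21] <- TRUE  # 12x12
  expect_false(any(erode_mask(sq, 13)))  # thinner than the kernel
  expect_error(erode_mask(sq, 4), class = "seedseg_parameter_error")
  expect_identical(erode_mask(sq, 1), sq)
})

test_that("erosion equals the brute-force neighborhood-AND oracle", {
  set.seed(31)
  for (i in 1:5) {
    mask <- matrix(runif(60 * 70) < 0.6, 60, 70)
    expect_identical(erode_mask(mask, 5), oracle_erode(mask, 5))
  }
})

test_that("erosion is anti-extensive and composable", {
  mask <- random_blob_mask(blobs = 25, seed = 40)
  e3 <- erode_mask(mask, 3)
  expect_true(all(e3 <= mask))
  expect_identical(erode_mask(e3, 5), erode_mask(mask, 7))  # 3 + 5 - 1
})

test_that("EOP separation splits bridged clusters and passes singles through", {
  m <- bridged_squares_mask(side = 20, bridge_w = 3)
  b <- separate_eop(m, separation_config("EOP", 13))
  expect_equal(nrow(b), 2L)
  expect_true(isTRUE(attr(b, "eroded")))
  single <- matrix(FALSE, 40, 40); single[8:32, 8:32] <- TRUE
  b1 <- separate_eop(single, separation_config("EOP", 13))
  expect_equal(nrow(b1), 1L)
  expect_false(b1$unseparated)
  # three chained squares, two thin bridges
  chain <- matrix(FALSE, 40, 90)
  for (k in 0:2) chain[10:29, 10 + k * 26 + 0:19] <- TRUE
  chain[19:21, 30:35] <- TRUE; chain[19:21, 56:61] <- TRUE
  expect_equal(nrow(separate_eop(chain, separation_config("EOP", 13))), 3L)
  # fully eroded cluster falls back to the original box, flagged
  tiny <- matrix(FALSE, 20, 20); tiny[8:12, 8:12] <- TRUE
  bt <- separate_eop(tiny, separation_config("EOP", 13))
  expect_equal(nrow(bt), 1L)
  expect_true(bt$unseparated)
  expect_equal(unlist(bt[1, c("x", "y", "w", "h")], use.names = FALSE),
               c(7, 7, 5, 5))
})

test_that("watershed separation splits touching convex blobs", {
  # two overlapping disks, centers 30 px apart, radii 18
  n <- 60; m <- 90
  d1 <- outer((1:n) - 30, rep(1, m))^2 + outer(rep(1, n), (1:m) - 30)^2
  d2 <- outer((1:n) - 30, rep(1, m))^2 + outer(rep(1, n), (1:m) - 60)^2
  mask <- d1 <= 18^2 | d2 <= 18^2
  b <- separate_wa(mask, separation_config("WA", wa_min_distance = 15))
  expect_equal(nrow(b), 2L)
  basins <- attr(b, "basins")
  # basins partition the cluster: disjoint by construction, union-exact
  expect_identical(basins > 0, mask)
  expect_setequal(unique(as.vector(basins)), c(0L, 1L, 2L))
  # a single disk stays whole
  b1 <- separate_wa(d1 <= 18^2, separation_config("WA", wa_min_distance = 15))
  expect_equal(nrow(b1), 1L)
  expect_false(b1$unseparated)
})

test_that("watershed and erosion agree on a tiny-contact fixture", {
  m <- bridged_squares_mask(side = 20, bridge_w = 3)
  be <- separate_eop(m, separation_config("EOP", 13))
  bw <- separate_wa(m, separation_config("WA", wa_min_distance = 12))
  expect_equal(nrow(be), 2L)
  expect_equal(nrow(bw), 2L)
  expect_identical(attr(bw, "basins") > 0, m)
})
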
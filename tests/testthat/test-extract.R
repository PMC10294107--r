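test_that("erosion compensation expands boxes by the kernel radius", {
  b <- one_box(50, 50, 8, 8)
  cb <- erosion_compensation(b, 13)
  expect_equal(unlist(cb[1, c("x", "y", "w", "h")], use.names = FALSE),
               c(44, 44, 20, 20))
  expect_equal(erosion_compensation(b, 1)[, c("x", "y", "w", "h")],
               b[, c("x", "y", "w", "h")], ignore_attr = TRUE)
  # clamped at scene bounds
  edge <- erosion_compensation(one_box(2, 2, 8, 8), 13, bounds = c(20, 20))
  expect_equal(unlist(edge[1, c("x", "y", "w", "h")], use.names = FALSE),
               c(0, 0, 16, 16))
})

test_that("erosion then compensation recovers a square's extent exactly", {
  mask <- matrix(FALSE, 60, 60)
  mask[21:40, 16:35] <- TRUE   # 20x20 at x=15, y=20
  b <- locate_seeds(erode_mask(mask, 13))
  cb <- erosion_compensation(b, 13, bounds = c(60, 60))
  expect_equal(unlist(cb[1, c("x", "y", "w", "h")], use.names = FALSE),
               c(15, 20, 20, 20))
})

test_that("crop_seed is the identity on an exact-size square region", {
  set.seed(12)
  sc <- as_scene(seedseg:::quantize8(array(runif(300 * 300 * 3, 0, 255),
                                           c(300, 300, 3))))
  crop <- crop_seed(sc, one_box(20, 30, 227, 227), pad = 0)
  expect_identical(arr(crop), unclass(sc)[31:257, 21:247, ])
})

test_that("crop_seed squares, pads with background and resizes to 227", {
  sc <- as_scene(array(10, c(400, 400, 3)))
  sc[101:160, 151:250, ] <- 200   # 100 wide x 60 tall at x=150, y=100
  crop <- crop_seed(sc, one_box(150, 100, 100, 60), pad = 0, bg = c(10, 10, 10))
  expect_identical(dim(unclass(crop)), c(227L, 227L, 3L))
  # bright band occupies the vertical middle ~60/100 of the square
  expect_true(all(crop[114, , 1] == 200))
  expect_true(all(crop[5, , 1] == 10))
  # padded extent crossing the border still yields exactly 227x227
  edge <- crop_seed(sc, one_box(0, 0, 50, 50), pad = 30, bg = c(10, 10, 10))
  expect_identical(dim(unclass(edge)), c(227L, 227L, 3L))
  expect_error(crop_seed(sc, one_box(5, 5, 0, 3)),
               class = "seedseg_parameter_error")
})

test_that("pipeline crops every seed exactly once on a zero-touching scene", {
  sc <- generate_scene(small_gen_config(rng_seed = 19))
  res <- run_pipeline(sc$scene)
  expect_equal(nrow(res$boxes), nrow(sc$truth$boxes))
  expect_equal(length(res$crops), nrow(res$boxes))
  expect_true(all(vapply(res$crops, function(cr)
    identical(dim(unclass(cr)), c(227L, 227L, 3L)), logical(1))))
  m <- match_boxes(res$boxes, sc$truth)
  expect_true(all(m$proper))
  expect_false(anyDuplicated(m$matched_truth) > 0)
  # crop centers sit on the true seed centers within 3 px
  cx <- res$boxes$x + res$boxes$w / 2
  cy <- res$boxes$y + res$boxes$h / 2
  tx <- sc$truth$boxes$x[m$matched_truth] + sc$truth$boxes$w[m$matched_truth] / 2
  ty <- sc$truth$boxes$y[m$matched_truth] + sc$truth$boxes$h[m$matched_truth] / 2
  expect_true(all(abs(cx - tx) <= 3 & abs(cy - ty) <= 3))
})

test_that("pipeline splits a tiny-contact pair and survives blank scenes", {
  sc <- generate_scene(small_gen_config(rng_seed = 23, n_seeds = 10,
                                        touching_fraction = 0.2))
  expect_equal(nrow(sc$truth$touching_pairs), 1L)
  res <- run_pipeline(sc$scene, sep = separation_config("EOP", 13))
  expect_equal(nrow(res$boxes), 10L)
  expect_true(all(match_boxes(res$boxes, sc$truth)$proper))
  blank <- as_scene(array(12, c(60, 80, 3)))
  bres <- run_pipeline(blank, enhanced = blank)
  expect_equal(length(bres$crops), 0L)
  expect_match(bres$warnings, "blank")
})

test_that("repeated pipeline runs are byte-identical", {
  sc <- generate_scene(small_gen_config(rng_seed = 29, n_seeds = 8,
                                        touching_fraction = 0.25))
  r1 <- run_pipeline(sc$scene)
  r2 <- run_pipeline(sc$scene)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("scan_dataset counts images per class folder", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "A")); dir.create(file.path(root, "B"))
  px <- as_scene(array(100, c(4, 4, 3)))
  for (f in c("a1.png", "a2.png", "a3.png"))
    write_scene(px, file.path(root, "A", f))
  write_scene(px, file.path(root, "B", "b1.jpg"))
  write_scene(px, file.path(root, "B", "b2.png"))
  writeLines("not an image", file.path(root, "B", "notes.txt"))
  d <- scan_dataset(root)
  expect_equal(d$counts, c(A = 3L, B = 2L))
  expect_equal(d$total, 5L)
  empty <- withr::local_tempdir()
  e <- scan_dataset(empty)
  expect_equal(e$total, 0L)
  expect_length(e$counts, 0L)
  expect_error(scan_dataset(file.path(root, "missing")),
               class = "seedseg_io_error")
})
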
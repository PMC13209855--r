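test_that("databar crop removes exactly the bottom rows", {
  img <- micrograph(matrix(seq_len(1089 * 32) %% 256, 1089, 32),
                    databar_height = 65)
  out <- crop_databar(img, 65)
  expect_equal(dim(out$data), c(1024, 32))
  expect_identical(out$data, img$data[1:1024, ])
  expect_equal(out$scalebar_px, img$scalebar_px)
  expect_identical(crop_databar(img, 0), img)
  expect_error(crop_databar(img, 1089), "height")
})

test_that("min-max normalization maps the range affinely onto 0-255", {
  img <- micrograph(matrix(c(10, 20, 15, 10), 2, 2))
  out <- normalize_contrast(img)
  expect_equal(sort(unique(as.vector(out$data))), c(0, 128, 255))
  expect_equal(out$data[1, 1], 0)
  expect_equal(out$data[2, 1], 255)
  expect_equal(out$data[1, 2], 128)  # 127.5 rounds half-to-even
  # already full-range image is unchanged
  full <- micrograph(matrix(c(0L, 255L, 100L, 37L), 2, 2))
  expect_identical(normalize_contrast(full)$data, full$data)
  # constant image: declared degenerate rule
  expect_warning(z <- normalize_contrast(micrograph(matrix(7, 3, 3))),
                 "constant")
  expect_true(all(z$data == 0))
})

test_that("segmentation finds disjoint disks exactly and propagates backend errors", {
  ms <- simulate_micrograph(micrograph_sim_params(
    image_width = 1024, image_height = 1024, n_particles = 50,
    allow_border = FALSE, seed = 1))
  img <- normalize_contrast(crop_databar(ms$image, 65))
  mask <- segment_instances(img)
  expect_equal(max(mask), 50)
  # labels are compact 1..K
  expect_setequal(sort(unique(mask[mask > 0])), 1:50)

  blank <- micrograph(matrix(30L, 64, 64))
  expect_equal(max(segment_instances(suppressWarnings(normalize_contrast(blank)))), 0)

  bad <- function(data, config) stop("boom")
  expect_error(segment_instances(img, backend = bad), "custom.*boom")
  expect_error(segment_instances(img, backend = "cellpose"), "unknown")
})

test_that("watershed splits two disks overlapping 10% of the smaller", {
  r1 <- 22; r2 <- 18
  d <- distance_for_overlap(r2, r1, 0.10)
  m <- matrix(30, 160, 160)
  m <- paint_disk(m, 80, 60, r1, 200)
  m <- paint_disk(m, 80, 60 + d, r2, 180)
  img <- micrograph(m)
  mask <- segment_instances(normalize_contrast(img))
  expect_equal(max(mask), 2)
  # the split respects the true centers
  expect_false(mask[80, 60] == mask[80, round(60 + d)])
})

test_that("instances below min_area_px are dropped and labels compacted", {
  m <- matrix(30, 64, 64)
  m <- paint_disk(m, 20, 20, 8, 200)
  m[50, 50] <- 200  # single-pixel speck
  mask <- segment_instances(normalize_contrast(micrograph(m)),
                            imaging_config(min_area_px = 9))
  expect_equal(max(mask), 1)
  expect_equal(mask[50, 50], 0L)
})

test_that("border exclusion flags exactly the boundary-touching instances", {
  mask <- matrix(0L, 10, 10)
  mask[4:6, 4:6] <- 1L   # interior
  mask[2:3, 1] <- 2L     # one pixel run on column 1
  tab <- exclude_border_particles(mask)
  expect_equal(tab$excluded_reason[tab$label == 1], "none")
  expect_equal(tab$excluded_reason[tab$label == 2], "border")

  ms <- simulate_micrograph(micrograph_sim_params(
    image_width = 512, image_height = 512, n_particles = 25,
    allow_border = TRUE, seed = 3))
  res <- size_particles(ms$image)
  expect_equal(res$summary$valid_n, sum(!ms$truth$touches_border))
})

test_that("scale calibration is the stated ratio", {
  sc <- calibrate_scale(229, 20)
  expect_equal(sc$um_per_px, 20 / 229)
  expect_equal(round(sc$um_per_px, 6), 0.087336)
  expect_equal(calibrate_scale(100, 100)$um_per_px, 1)
  expect_equal(round(30 * sc$um_per_px, 3), 2.620)
  expect_error(calibrate_scale(0, 20), "positive")
  expect_error(calibrate_scale(229, -1), "positive")
})

test_that("measured diameter of a rendered disk matches its true size", {
  m <- matrix(30, 100, 100)
  m <- paint_disk(m, 50, 50, 23, 200)  # 46 px diameter
  sc <- calibrate_scale(229, 20)
  mask <- segment_instances(normalize_contrast(micrograph(m)))
  tab <- measure_particles(mask, sc)
  expect_equal(nrow(tab), 1)
  expect_lt(abs(tab$diameter_um - 4.017), sc$um_per_px)  # within 1 px
  # empty mask gives an empty table
  empty <- measure_particles(matrix(0L, 10, 10), sc)
  expect_equal(nrow(empty), 0)
})

test_that("enclosing circle recovers a partially occluded disk", {
  # disk A 30% hidden behind disk B, both segmented: the visible arc of A
  # still pins down its full diameter
  rA <- 20; rB <- 25
  d <- distance_for_overlap(rA, rB, 0.30)
  m <- matrix(0L, 140, 140)
  m <- paint_disk(m, 70, 50, rA, 1L)
  m <- paint_disk(m, 70, 50 + d, rB, 2L)  # B painted over A's hidden lens
  sc <- calibrate_scale(100, 100)  # 1 um per px
  tab <- measure_particles(m, sc)
  dA <- tab$diameter_um[tab$label == 1]
  expect_lt(abs(dA - 2 * rA) / (2 * rA), 0.03)
})

test_that("size summary reproduces hand-computed descriptors", {
  tab <- data.frame(diameter_um = c(2, 4, 6), excluded_reason = "none")
  s <- summarize_sizes(tab)
  expect_equal(s$mean_um, 4)
  expect_equal(s$d50_um, 4)
  expect_equal(s$valid_n, 3)

  tab9 <- data.frame(diameter_um = 1:9, excluded_reason = "none")
  s9 <- summarize_sizes(tab9)
  expect_equal(s9$d10_um, 1.8)
  expect_equal(s9$d90_um, 8.2)
  expect_true(s9$d10_um <= s9$d50_um && s9$d50_um <= s9$d90_um)
  expect_equal(sum(s9$histogram$count), s9$valid_n)
  expect_equal(s9$histogram$bin_lo_um[1], 0)
  expect_equal(diff(s9$histogram$bin_lo_um[1:2]), 0.5)

  set.seed(21)
  big <- data.frame(diameter_um = rlnorm(1000, log(3.7), 0.45),
                    excluded_reason = "none")
  expect_lt(abs(summarize_sizes(big)$d50_um / 3.7 - 1), 0.05)

  expect_error(summarize_sizes(
    data.frame(diameter_um = NA_real_, excluded_reason = "border")),
    "no retained")
})

test_that("doubling the scale doubles every physical diameter", {
  m <- matrix(0L, 80, 80)
  m <- paint_disk(m, 30, 30, 10, 1L)
  m <- paint_disk(m, 60, 60, 7, 2L)
  t1 <- measure_particles(m, calibrate_scale(229, 20))
  t2 <- measure_particles(m, calibrate_scale(229, 40))
  expect_equal(t2$diameter_um, 2 * t1$diameter_um)
})

test_that("overlay tints exactly the instance pixels, deterministically", {
  m <- matrix(30L, 20, 20)
  img <- micrograph(m)
  empty <- render_overlay(img, matrix(0L, 20, 20))
  expect_equal(empty[, , 1], m / 255)
  expect_equal(empty[, , 1], empty[, , 2])

  mask <- matrix(0L, 20, 20); mask[5:8, 5:8] <- 1L
  ov <- render_overlay(img, mask)
  changed <- which(ov[, , 1] != m / 255 | ov[, , 2] != m / 255 |
                     ov[, , 3] != m / 255)
  expect_setequal(changed, which(mask == 1L))
  expect_identical(ov, render_overlay(img, mask))
  expect_error(render_overlay(img, matrix(0L, 5, 5)), "dimensions")
})

test_that("the sizing pipeline is deterministic end to end", {
  ms <- simulate_micrograph(micrograph_sim_params(
    image_width = 256, image_height = 256, n_particles = 6, seed = 2))
  a <- size_particles(ms$image)
  b <- size_particles(ms$image)
  expect_identical(a$table, b$table)
  expect_identical(a$mask, b$mask)
})
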
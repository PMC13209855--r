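test_that("zero-particle simulation gives a blank content region with databar", {
  ms <- simulate_micrograph(micrograph_sim_params(
    image_width = 128, image_height = 96, n_particles = 0, noise_sd = 0,
    scalebar_px = 50))
  expect_equal(nrow(ms$truth), 0)
  expect_equal(dim(ms$image$data), c(96 + 65, 128))
  content <- ms$image$data[1:96, ]
  expect_true(all(content == 30))
  bar <- ms$image$data[97:161, ]
  expect_setequal(unique(as.vector(bar)), c(70, 255))
  # scale bar is exactly scalebar_px long in every row it occupies
  sb_rows <- which(apply(bar == 255, 1, any))
  for (r in sb_rows) expect_equal(sum(bar[r, ] == 255), 50)
})

test_that("simulation is a pure function of parameters and seed", {
  p <- micrograph_sim_params(image_width = 256, image_height = 256,
                             n_particles = 10, seed = 42)
  a <- simulate_micrograph(p)
  b <- simulate_micrograph(p)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth, b$truth)
  # and it does not disturb the caller's RNG stream
  set.seed(99); x1 <- rnorm(3)
  set.seed(99); invisible(simulate_micrograph(p)); x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("rendered disk extents match truth diameters within one pixel", {
  ms <- simulate_micrograph(micrograph_sim_params(
    image_width = 1024, image_height = 1024, n_particles = 50,
    allow_border = FALSE, noise_sd = 0, seed = 1))
  expect_equal(nrow(ms$truth), 50)
  expect_true(all(!ms$truth$touches_border))
  img <- ms$image$data[1:1024, ]
  comp <- EBImage::imageData(EBImage::bwlabel(img > 30))
  for (i in seq_len(50)) {
    lab <- comp[round(ms$truth$row[i]), round(ms$truth$col[i])]
    px <- which(comp == lab, arr.ind = TRUE)
    ext <- max(diff(range(px[, 1])), diff(range(px[, 2]))) + 1
    expect_lt(abs(ext - ms$truth$diameter_px[i]), 1 + 1e-9)
  }
})

test_that("truth count equals rendered-particle count and diameters are positive", {
  ms <- simulate_micrograph(micrograph_sim_params(
    image_width = 512, image_height = 512, n_particles = 20,
    allow_border = TRUE, seed = 8))
  expect_equal(nrow(ms$truth), 20)
  expect_true(all(ms$truth$diameter_um > 0))
})

test_that("simulated diameters follow the specified log-normal", {
  # coarse scale so 1000 disjoint disks fit in one frame
  ms <- simulate_micrograph(micrograph_sim_params(
    image_width = 2048, image_height = 2048, scalebar_px = 57,
    n_particles = 1000, median_um = 3.7, sigma_log = 0.45,
    noise_sd = 0, seed = 7))
  d <- ms$truth$diameter_um
  expect_equal(length(d), 1000)
  expect_lt(abs(stats::median(d) / 3.7 - 1), 0.05)
  ks <- suppressWarnings(stats::ks.test(d, stats::plnorm,
                                        meanlog = log(3.7), sdlog = 0.45))
  expect_gt(ks$p.value, 0.01)
})

test_that("infeasible placement fails with a count of placed particles", {
  expect_error(
    simulate_micrograph(micrograph_sim_params(
      image_width = 64, image_height = 64, n_particles = 50, seed = 1)),
    "placed")
})

test_that("overlap constraint bounds the pairwise hidden fraction", {
  ms <- simulate_micrograph(micrograph_sim_params(
    image_width = 700, image_height = 700, n_particles = 40,
    max_overlap_fraction = 0.2, allow_border = FALSE, noise_sd = 0,
    seed = 3))
  tr <- ms$truth
  for (i in 1:(nrow(tr) - 1)) {
    for (j in (i + 1):nrow(tr)) {
      d <- sqrt((tr$row[i] - tr$row[j])^2 + (tr$col[i] - tr$col[j])^2)
      ov <- lens_area(tr$diameter_px[i] / 2, tr$diameter_px[j] / 2, d)
      amin <- pi * min(tr$diameter_px[i], tr$diameter_px[j])^2 / 4
      expect_lte(ov, 0.2 * amin + 1e-6)
    }
  }
})

test_that("assay replicate simulation honors mean, noise and seed", {
  p0 <- data.frame(formulation = c("A", "B"), true_mean = c(3.43, 1.96),
                   replicate_sd = 0)
  r0 <- simulate_assay_replicates(p0, seed = 5)
  expect_equal(r0$value, c(3.43, 3.43, 3.43, 1.96, 1.96, 1.96))

  p1 <- data.frame(formulation = "CON", true_mean = 3.43,
                   replicate_sd = 0.06, n_replicates = 3)
  r1 <- simulate_assay_replicates(p1, seed = 11)
  se <- 0.06 / sqrt(3)
  expect_lt(abs(mean(r1$value) - 3.43), 3 * se)
  expect_identical(r1, simulate_assay_replicates(p1, seed = 11))

  expect_error(simulate_assay_replicates(p1[0, ]), "at least one")
  expect_error(simulate_assay_replicates(
    data.frame(formulation = "A", true_mean = 1, replicate_sd = -1)), "sd")
})

test_that("peak-area simulation evaluates the response line exactly at zero noise", {
  curve <- calibration_curve(6379.25, 2232.78)
  pk <- simulate_peak_areas(c(0, 10), curve, noise_sd = 0, seed = 1)
  expect_equal(pk$area, c(2232.78, 66025.28))
  # round trip through quantification recovers amounts exactly
  amounts <- c(2.45, 5, 12.25, 61.25, 122.5)
  pk2 <- simulate_peak_areas(amounts, curve, noise_sd = 0, seed = 1)
  q <- quantify_injection(pk2$area, curve)
  expect_equal(q$amount, amounts, tolerance = 1e-12)
  expect_error(simulate_peak_areas(-1, curve), ">= 0")
})
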
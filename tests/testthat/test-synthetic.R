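test_that("curve generation is deterministic and respects the border margin", {
  cfg <- generator_config(seed = 9)
  c1 <- generate_curve(cfg)
  c2 <- generate_curve(cfg)
  expect_identical(c1, c2)
  px <- which(c1 == 1L, arr.ind = TRUE)
  expect_true(all(px[, 1] >= 3 & px[, 1] <= cfg$height - 2))
  expect_true(all(px[, 2] >= 3 & px[, 2] <= cfg$width - 2))
  expect_error(generator_config(height = 8, width = 8), "too small")
})

test_that("open splines have two endpoints, ellipses are thin loops", {
  for (seed in c(1, 5, 23, 77)) {
    sp <- generate_curve(generator_config(seed = seed, kind = "open-spline"))
    nb <- fg_neighbor_count(sp)
    expect_equal(sum(sp == 1L & nb == 1L), 2)
    expect_equal(oracle_components(sp), 1L)

    el <- generate_curve(generator_config(seed = seed, kind = "closed-ellipse"))
    nbe <- fg_neighbor_count(el)
    expect_true(all(nbe[el == 1L] == 2L))
    expect_equal(oracle_components(el), 1L)
  }
})

test_that("rendering follows the Gaussian cross-profile formula", {
  gt <- matrix(0L, 17, 17)
  gt[9, 9] <- 1L
  cfg <- generator_config(height = 17, width = 17, sigma = 1, peak = 200,
                          noise_sd = 0, jitter = 0, seed = 1)
  img <- render_boundary(gt, cfg)
  expect_equal(img[9, 9], 200L)                        # d = 0
  expect_equal(img[9, 11], as.integer(round(200 * exp(-2))))  # d = 2 -> 27
  expect_equal(img[9, 11], 27L)
  expect_equal(img[9, 10], as.integer(round(200 * exp(-0.5))))
  # intensity is non-increasing in the distance to the curve
  expect_true(all(diff(img[9, 9:17]) <= 0))
  # sub-1 responses are zeroed
  expect_equal(img[9, 17], 0L)
  expect_equal(img[1, 1], 0L)
})

test_that("the noiseless ridge coincides with the ground truth", {
  for (seed in c(2, 13)) {
    cfg <- generator_config(seed = seed, noise_sd = 0)
    s <- generate_sample(cfg)
    # the intensity argmax per column lies within 1 pixel of the curve
    gt_rows <- apply(s$gt_edge, 2, function(col) which(col == 1L)[1])
    for (j in which(!is.na(gt_rows))) {
      peak_row <- which.max(s$boundary[, j])
      expect_lte(abs(peak_row - gt_rows[j]), 1)
    }
  }
})

test_that("gaps split an open boundary into several blobs", {
  cfg <- generator_config(seed = 4, noise_sd = 0, gap_prob = 1)
  s <- generate_sample(cfg)
  expect_gte(oracle_components(binarize(s$boundary)), 2L)
  # without gaps the same configuration renders one blob
  cfg0 <- generator_config(seed = 4, noise_sd = 0, gap_prob = 0)
  s0 <- generate_sample(cfg0)
  expect_equal(oracle_components(binarize(s0$boundary)), 1L)
  expect_identical(s0$gt_edge, s$gt_edge)  # gaps affect the rendering only
})

test_that("datasets use derived per-sample seeds and can be written to disk", {
  cfg <- generator_config(seed = 50)
  ds <- generate_dataset(3, cfg)
  expect_length(ds, 3)
  expect_false(identical(ds[[1]]$boundary, ds[[2]]$boundary))
  # sample k reproduces from seed + k - 1
  again <- generate_sample(generator_config(seed = 52))
  expect_identical(ds[[3]]$boundary, again$boundary)

  dir <- withr::local_tempdir()
  generate_dataset(2, cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "boundaries", "002.png")))
  expect_true(file.exists(file.path(dir, "gt", "001.png")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 50)
  expect_identical(read_gray(file.path(dir, "boundaries", "001.png")),
                   ds[[1]]$boundary)
})

test_that("noise is additive, clipped and reproducible", {
  cfg_n <- generator_config(seed = 31, noise_sd = 10)
  cfg_0 <- generator_config(seed = 31, noise_sd = 0)
  sn <- generate_sample(cfg_n)
  s0 <- generate_sample(cfg_0)
  expect_identical(sn$gt_edge, s0$gt_edge)
  expect_false(identical(sn$boundary, s0$boundary))
  expect_true(all(sn$boundary >= 0L & sn$boundary <= 255L))
  expect_identical(generate_sample(cfg_n)$boundary, sn$boundary)
})
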
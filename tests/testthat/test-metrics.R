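test_that("ensure_nonempty adds a centre pixel only to empty maps and is idempotent", {
  b <- matrix(0L, 4, 4)
  b[2, 2] <- 1L
  expect_identical(ensure_nonempty(b), b)
  e11 <- ensure_nonempty(matrix(0L, 11, 11))
  expect_equal(which(e11 == 1L, arr.ind = TRUE)[1, ], c(row = 6, col = 6))
  expect_equal(sum(e11), 1)
  e1 <- ensure_nonempty(matrix(0L, 1, 1))
  expect_equal(e1[1, 1], 1L)
  e46 <- ensure_nonempty(matrix(0L, 4, 6))
  expect_equal(which(e46 == 1L, arr.ind = TRUE)[1, ], c(row = 3, col = 4))
  expect_identical(ensure_nonempty(e46), e46)
})

test_that("sde matches hand values and the empty-map correction", {
  p <- matrix(0L, 1, 4); p[1, 1] <- 1L
  g <- matrix(0L, 1, 4); g[1, 4] <- 1L
  expect_equal(sde(p, g), 3)
  expect_equal(sde(p, p), 0)
  # empty prediction against a centre-pixel-only ground truth scores 0
  gt <- matrix(0L, 11, 11); gt[6, 6] <- 1L
  expect_equal(sde(matrix(0L, 11, 11), gt), 0)
  expect_error(sde(matrix(0L, 2, 2), matrix(0L, 3, 3)), "dimensions")
})

test_that("sde is symmetric, agrees with a brute-force oracle, and penalises displacement", {
  withr::with_seed(111, {
    for (rep in 1:10) {
      a <- matrix(as.integer(runif(15 * 15) < 0.1), 15, 15)
      b <- matrix(as.integer(runif(15 * 15) < 0.1), 15, 15)
      expect_equal(sde(a, b), oracle_sde(a, b), tolerance = 1e-12)
      expect_equal(sde(a, b), sde(b, a), tolerance = 1e-12)
    }
  })
  # moving the only predicted pixel farther from gt never decreases the score
  gt <- matrix(0L, 1, 9); gt[1, 1] <- 1L
  scores <- sapply(2:9, function(c) {
    p <- matrix(0L, 1, 9); p[1, c] <- 1L
    sde(p, gt)
  })
  expect_true(all(diff(scores) >= 0))
})

test_that("iou_box scores matched component boxes", {
  gt <- matrix(0L, 8, 8); gt[1:4, 1:4] <- 1L
  pr <- matrix(0L, 8, 8); pr[1:2, 1:4] <- 1L
  expect_equal(iou_box(pr, gt), 8 / 16)
  expect_equal(iou_box(gt, gt), 1)
  # disjoint boxes
  a <- matrix(0L, 8, 8); a[1, 1] <- 1L
  b <- matrix(0L, 8, 8); b[8, 8] <- 1L
  expect_equal(iou_box(a, b), 0)
  # one-to-one matching: a single sprawling prediction cannot serve two
  # ground-truth components
  gt2 <- matrix(0L, 9, 9); gt2[2, 2:3] <- 1L; gt2[8, 7:8] <- 1L
  pr2 <- matrix(0L, 9, 9); pr2[2, 2:8] <- 1L; pr2[3:8, 8] <- 1L
  expect_lt(iou_box(pr2, gt2), 0.5)
  expect_error(iou_box(matrix(0L, 2, 2), matrix(0L, 3, 3)), "dimensions")
})

test_that("evaluate_pairs aggregates with mean, median and population sd", {
  # pair 1: identical maps (sde 0); pair 2: single pixels 6 apart (sde 6)
  m <- matrix(0L, 1, 7); m[1, 1] <- 1L
  g2 <- matrix(0L, 1, 7); g2[1, 7] <- 1L
  rep_ <- evaluate_pairs(list(m, m), list(m, g2))
  agg <- rep_$aggregates
  expect_equal(agg$mean[agg$metric == "sde"], 3)
  expect_equal(agg$median[agg$metric == "sde"], 3)
  expect_equal(agg$sd[agg$metric == "sde"], 3)      # population sd of {0, 6}
  expect_equal(rep_$per_image$sde, c(0, 6))
  expect_equal(rep_$per_image$iou_box[1], 1)
  expect_error(evaluate_pairs(list(), list()), "non-empty")
  expect_error(evaluate_pairs(list(m), list(m, m)), "equal length")
})

test_that("evaluate_pairs writes CSV and JSON reports", {
  m <- matrix(0L, 5, 5); m[3, 2:4] <- 1L
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  evaluate_pairs(list(m), list(m), names = "img1", csv = csv, json = js)
  tab <- read.csv(csv)
  expect_equal(tab$sde[tab$image == "img1"], 0)
  expect_equal(tab$iou_box[tab$image == "<mean>"], 1)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$aggregates$mean, c(0, 1))
})
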
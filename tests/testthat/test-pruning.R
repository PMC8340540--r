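test_that("spur_length_limit follows the diagonal formula", {
  expect_equal(spur_length_limit(100, 3, 4), 5)
  expect_equal(spur_length_limit(0, 17, 29), 0)
  expect_equal(spur_length_limit(2, 481, 321), 0.02 * sqrt(481^2 + 321^2),
               tolerance = 1e-12)
  expect_equal(spur_length_limit(2, 481, 321), 11.565, tolerance = 1e-4)
  expect_error(spur_length_limit(101, 10, 10), "\\[0, 100\\]")
  expect_error(spur_length_limit(-1, 10, 10), "\\[0, 100\\]")
})

test_that("a two-pixel spur on a line is removed at l = 2 and kept at l = 1", {
  e <- matrix(0L, 7, 9)
  e[4, 2:8] <- 1L          # 7-pixel horizontal line
  e[2:3, 5] <- 1L          # 2-pixel vertical spur at its centre
  line_only <- matrix(0L, 7, 9)
  line_only[4, 2:8] <- 1L
  expect_identical(prune_spurs(e, 2), line_only)
  expect_identical(prune_spurs(e, 1), e)
  expect_identical(prune_spurs(e, 0), e)  # l = 0 is the identity
})

test_that("whole open curves and closed loops are never pruned", {
  open_curve <- random_thin_map(5, "open-spline")
  attr(open_curve, "curve_path") <- NULL
  expect_identical(prune_spurs(open_curve, 1000), open_curve)
  loop <- random_thin_map(6, "closed-ellipse")
  attr(loop, "curve_path") <- NULL
  expect_identical(prune_spurs(loop, 1000), loop)
})

test_that("pruning removes exactly the implanted spurs within the limit", {
  withr::with_seed(51, {
    for (rep in 1:20) {
      sk <- make_spur_skeleton(sample(1e6, 1))
      l <- sample(0:7, 1)
      pruned <- prune_spurs(sk$edge, l)
      # each implanted spur is removed iff its length is within the limit
      for (k in seq_along(sk$cols)) {
        spur_px <- cbind(sk$row + sk$dirs[k] * seq_len(sk$lens[k]), sk$cols[k])
        if (sk$lens[k] <= l) {
          expect_true(all(pruned[spur_px] == 0L))
        } else {
          expect_true(all(pruned[spur_px] == 1L))
        }
      }
      # the main line always survives (its end segments exceed every limit)
      expect_true(all(pruned[sk$row, 5:56] == 1L))
      # never grows, components preserved
      expect_true(all(pruned <= sk$edge))
      expect_identical(oracle_components(pruned), oracle_components(sk$edge))
      # postcondition: no remaining endpoint-to-junction branch of length <= l
      if (l >= 1) expect_true(all(oracle_branch_lengths(pruned) > l))
    }
  })
})

test_that("pruning shrinks monotonically in the length limit", {
  withr::with_seed(61, {
    for (rep in 1:5) {
      sk <- make_spur_skeleton(sample(1e6, 1))
      prev <- prune_spurs(sk$edge, 0)
      for (l in c(1, 2, 4, 8)) {
        cur <- prune_spurs(sk$edge, l)
        expect_true(all(cur <= prev))
        prev <- cur
      }
    }
  })
})

test_that("cascaded spurs are pruned to a fixed point", {
  # a forked spur: a 3-pixel stem off the line whose tip carries two 1-pixel
  # twigs; the stem only becomes removable after the twigs are gone
  e <- matrix(0L, 11, 13)
  e[6, 2:12] <- 1L         # 11-pixel horizontal line
  e[3:5, 6] <- 1L          # 3-pixel stem
  e[2, 5] <- 1L            # twig 1
  e[2, 7] <- 1L            # twig 2
  line_only <- matrix(0L, 11, 13)
  line_only[6, 2:12] <- 1L
  # l = 4: twig 1 goes first, then the twig-2 + stem chain (length 4)
  expect_identical(prune_spurs(e, 4), line_only)
  # l = 1: twig 1 goes; with the fork dissolved, twig 2 now heads a branch of
  # length 4 that exceeds the limit, so it stays along with the stem
  stem <- line_only
  stem[3:5, 6] <- 1L
  stem[2, 7] <- 1L
  expect_identical(prune_spurs(e, 1), stem)
})
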
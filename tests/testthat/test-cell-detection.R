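test_that("Otsu threshold maximizes between-class variance (brute-force oracle)", {
  set.seed(8)
  img <- matrix(sample(c(rnorm(200, 30, 5), rnorm(200, 180, 10))), 20, 20)
  mask <- threshold_channel(img, "otsu")
  thr <- attr(mask, "threshold")
  # oracle: scan 256 candidate thresholds for max between-class variance
  rng <- range(img)
  cand <- seq(rng[1], rng[2], length.out = 256)
  bcv <- vapply(cand, function(t) {
    w1 <- mean(img <= t)
    if (w1 == 0 || w1 == 1) return(0)
    (w1 * (1 - w1)) * (mean(img[img <= t]) - mean(img[img > t]))^2
  }, numeric(1))
  best <- cand[which.max(bcv)]
  # same class split as the oracle's optimum
  expect_equal(as.vector(mask), as.vector(img > best))
})

test_that("thresholding handles bimodal and degenerate inputs", {
  img <- matrix(c(rep(0, 50), rep(200, 50)), 10, 10)
  mask <- threshold_channel(img, "otsu")
  expect_true(all(mask[img == 200]))
  expect_false(any(mask[img == 0]))
  expect_error(threshold_channel(matrix(5, 4, 4), "otsu"), "degenerate")
  expect_false(any(threshold_channel(matrix(0, 4, 4), "fixed", t = 0.5)))
})

test_that("clean_mask removes small components, keeps large ones", {
  m <- matrix(FALSE, 30, 30)
  expect_equal(sum(clean_mask(m, 5)), 0)
  m[5, 5] <- TRUE                      # 1-px component
  m[15:19, 10:19] <- TRUE              # 50-px component
  m[25, 25:28] <- TRUE                 # 4-px component
  out <- clean_mask(m, min_area = 10)
  expect_equal(sum(out), 50)
  expect_true(all(out[15:19, 10:19]))
})

test_that("positive-cell selection respects the overlap-fraction rule", {
  # 10 square nuclei, 6 overlapping the immuno mask by >= 50%
  nuc <- matrix(FALSE, 40, 110)
  imm <- matrix(FALSE, 40, 110)
  for (k in 1:10) {
    cols <- (k - 1) * 11 + (1:4)
    nuc[10:13, cols] <- TRUE
    covered <- if (k <= 6) 1:4 else 1 # 100% vs 25% of columns
    imm[10:13, cols[covered]] <- TRUE
  }
  p <- detect_positive_cells(nuc, imm, min_overlap_fraction = 0.5)
  expect_equal(p$n, 6)
  # centroid of the first nucleus: cols 1:4, rows 10:13, pixel-center coords
  expect_equal(sort(p$y)[1], mean((10:13) - 0.5))
  expect_equal(sort(p$x)[1], mean((1:4) - 0.5))
  # disjoint masks give an empty pattern; mismatched shapes error
  expect_equal(detect_positive_cells(nuc, matrix(FALSE, 40, 110))$n, 0)
  expect_error(detect_positive_cells(nuc, matrix(FALSE, 5, 5)), "shape")
  # emitted count never exceeds the component count
  expect_lte(detect_positive_cells(nuc, imm, 0)$n, 10)
})

test_that("area percent is the true-pixel fraction and is monotone under union", {
  expect_equal(area_percent(matrix(TRUE, 5, 5)), 100)
  m <- matrix(FALSE, 10, 10); m[1:5, 1:5] <- TRUE
  expect_equal(area_percent(m), 25)
  m2 <- m; m2[6, 6] <- TRUE
  expect_gt(area_percent(m2), area_percent(m))
  expect_gte(area_percent(m), 0)
  expect_lte(area_percent(m2), 100)
})

test_that("full round trip on a zero-noise field recovers the positive set", {
  fx <- render_fixture(n_pos = 50, n_neg = 50)
  f <- render_field(fx$pos, fx$neg, render_spec())
  un <- unmix(to_optical_density(f$image))
  immuno <- threshold_channel(un$D, "otsu")
  nuclei <- threshold_channel(un$H, "otsu")
  jac <- sum(immuno & f$dab_mask) / sum(immuno | f$dab_mask)
  expect_gt(jac, 0.9)
  expect_lt(abs(area_percent(immuno) - 100 * mean(f$dab_mask)), 1)
  det <- detect_positive_cells(nuclei, immuno)
  expect_equal(det$n, 50) # recall and precision both 1
  derr <- sqrt(outer(det$x, fx$pos$x, "-")^2 + outer(det$y, fx$pos$y, "-")^2)
  expect_lte(max(apply(derr, 2, min)), 2) # centroids within 2 px of truth
  expect_true(all(det$x >= 0 & det$x <= fx$window$width))
})

test_that("watershed splitting separates touching nuclei", {
  m <- matrix(FALSE, 40, 60)
  for (ctr in list(c(20, 20), c(20, 33))) { # two discs fused at the waist
    for (r in 1:40) for (c in 1:60)
      if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 8^2) m[r, c] <- TRUE
  }
  lab <- split_nuclei(m)
  expect_gte(max(lab), 2)
})
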
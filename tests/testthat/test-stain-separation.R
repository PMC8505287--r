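test_that("optical density follows the Beer-Lambert log rule with clamping", {
  expect_equal(to_optical_density(c(255, 255, 255)), c(0, 0, 0))
  expect_equal(to_optical_density(25.5), 1.0)
  # zero intensity is clamped at eps = 1
  expect_equal(to_optical_density(0), log10(255))
})

test_that("stain system rows are unit norm and invertible", {
  st <- stain_system()
  expect_equal(unname(rowSums(st$M^2)), c(1, 1, 1))
  expect_equal(unname(st$M %*% st$M_inv), diag(3), tolerance = 1e-12)
  # residual is orthogonal to both stains
  expect_equal(sum(st$S_R * st$S_H), 0, tolerance = 1e-12)
  expect_equal(sum(st$S_R * st$S_D), 0, tolerance = 1e-12)
  expect_error(stain_system(c(1, 0, 0), c(2, 0, 0)), "singular|collinear")
})

test_that("unmixing recovers known stain mixtures", {
  st <- stain_system()
  # pure DAB pixel
  un <- unmix(matrix(st$S_D, 1, 3), st)
  expect_equal(un$H[1], 0, tolerance = 1e-12)
  expect_equal(un$D[1], 1, tolerance = 1e-12)
  # known mixture, checked against an independent 3x3 solve
  od <- 0.3 * st$S_H + 0.7 * st$S_D
  un <- unmix(matrix(od, 1, 3), st)
  oracle <- solve(t(st$M), od)
  expect_equal(unname(un$raw[1, ]), unname(oracle), tolerance = 1e-9)
  expect_equal(un$H[1], 0.3, tolerance = 1e-6)
  expect_equal(un$D[1], 0.7, tolerance = 1e-6)
})

test_that("unmixing is linear and composes back to the input OD", {
  st <- stain_system()
  set.seed(5)
  od1 <- matrix(runif(30, 0, 2), 10, 3)
  od2 <- matrix(runif(30, 0, 2), 10, 3)
  u1 <- unmix(od1, st, clip = FALSE)$raw
  u2 <- unmix(od2, st, clip = FALSE)$raw
  u12 <- unmix(2 * od1 + 3 * od2, st, clip = FALSE)$raw
  expect_equal(u12, 2 * u1 + 3 * u2, tolerance = 1e-10)
  expect_equal(od_compose(u1, st), od1, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("zero-noise renders are exactly recovered by unmixing", {
  fx <- render_fixture(n_pos = 20, n_neg = 20)
  f <- render_field(fx$pos, fx$neg, render_spec())
  un <- unmix(to_optical_density(f$image))
  amp <- max(f$conc_D)
  expect_lt(max(abs(un$H - f$conc_H)) / max(f$conc_H), 0.01)
  expect_lt(max(abs(un$D - f$conc_D)) / amp, 0.01)
})

test_that("renders satisfy their degenerate contracts", {
  w <- ihc_window(32, 32)
  none <- point_pattern(numeric(0), numeric(0), w)
  f <- render_field(none, none, render_spec(32, 32))
  expect_true(all(f$image == 255))
  # one DAB+H nucleus: OD at its center is in span(S_H, S_D); a DAB-only
  # render (h_amplitude = 0) gives OD parallel to S_D
  one <- point_pattern(16, 16, w)
  f1 <- render_field(one, NULL, render_spec(32, 32, h_amplitude = 0))
  od <- to_optical_density(f1$image[16, 16, ])
  st <- stain_system()
  cosang <- sum(od * st$S_D) / sqrt(sum(od^2))
  expect_equal(cosang, 1, tolerance = 1e-9)
})

test_that("white balance rescales a shaded background to I0", {
  img <- array(200, c(8, 8, 3))
  wb <- white_balance(img)
  expect_equal(max(wb), 255)
})
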
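test_that("generators return exactly n points inside the window, reproducibly", {
  w <- field_window()
  for (spec in list(csr_spec(37), thomas_spec(37), lattice_spec(37),
                    pattern_spec("coincident", 37))) {
    p1 <- generate_pattern(spec, w, seed = 11)
    p2 <- generate_pattern(spec, w, seed = 11)
    expect_equal(p1$n, 37)
    expect_true(all(p1$x >= 0 & p1$x <= w$width))
    expect_true(all(p1$y >= 0 & p1$y <= w$height))
    expect_identical(p1$x, p2$x) # bitwise reproducibility
    expect_identical(p1$y, p2$y)
  }
})

test_that("degenerate regimes behave by definition", {
  w <- field_window()
  p <- generate_pattern(pattern_spec("coincident", 100), w, seed = 3)
  expect_equal(length(unique(p$x)), 1)
  expect_equal(length(unique(p$y)), 1)
  expect_equal(p$n, 100)
  empty <- generate_pattern(csr_spec(0), w, seed = 3)
  expect_equal(empty$n, 0)
  expect_error(pattern_spec("csr", -1), "non-negative")
})

test_that("CSR coordinates have uniform-distribution moments", {
  p <- generate_pattern(csr_spec(1e4), unit_window(), seed = 21)
  tol <- 3 * (1 / sqrt(12)) / 100 # 3 SE of the mean of U(0,1) at n = 1e4
  expect_lt(abs(mean(p$x) - 0.5), tol)
  expect_lt(abs(mean(p$y) - 0.5), tol)
})

test_that("CSR patterns pass a chi-square quadrat uniformity test at the expected rate", {
  # 5x5 quadrats, n = 250: expected 10 per cell; alpha = 0.05
  rejections <- vapply(1:60, function(s) {
    p <- generate_pattern(csr_spec(250), field_window(), seed = 400 + s)
    qx <- cut(p$x, seq(0, 1000, length.out = 6), include.lowest = TRUE)
    qy <- cut(p$y, seq(0, 1000, length.out = 6), include.lowest = TRUE)
    counts <- as.vector(table(qx, qy))
    suppressWarnings(stats::chisq.test(counts)$p.value) < 0.05
  }, logical(1))
  # binomial 99.9% bound around 0.05 with 60 draws
  expect_lt(mean(rejections), 0.05 + 3.29 * sqrt(0.05 * 0.95 / 60))
})

test_that("Clark-Evans ratio separates clustered and regular regimes", {
  w <- field_window()
  for (s in 1:20) {
    r_thomas <- uniformity_index(
      generate_pattern(thomas_spec(150), w, seed = s))$clark_evans
    r_latt <- uniformity_index(
      generate_pattern(lattice_spec(150, j = 0.1), w, seed = s))$clark_evans
    expect_lt(r_thomas, 1)
    expect_gt(r_latt, 1)
  }
})

test_that("cohort generation is deterministic and has the designed shape", {
  co <- generate_cohort(csr_spec(0), csr_spec(0), n_samples = 15,
                        n_fields = 10, n_range = c(50, 200), seed = 2)
  expect_equal(nrow(co$fields), 300)
  expect_equal(unname(table(co$fields$group)), c(150L, 150L),
               ignore_attr = TRUE)
  expect_true(all(co$fields$n >= 50 & co$fields$n <= 200))
  co2 <- generate_cohort(csr_spec(0), csr_spec(0), n_samples = 15,
                         n_fields = 10, n_range = c(50, 200), seed = 2)
  expect_identical(lapply(co$patterns, `[[`, "x"),
                   lapply(co2$patterns, `[[`, "x"))
  # partial-rerun stability: field stream depends only on its own indices
  expect_identical(field_seed(2, 1, 3, 7), field_seed(2, 1, 3, 7))
  expect_false(field_seed(2, 1, 3, 7) == field_seed(2, 2, 3, 7))
})

test_that("cohort CSV/manifest round-trips through disk", {
  co <- generate_cohort(csr_spec(0), csr_spec(0), n_samples = 2,
                        n_fields = 3, n_range = c(10, 20), seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- read_patterns_csv(paths[["points"]], co$window)
  expect_equal(nrow(back$fields), 12)
  expect_equal(sum(back$fields$n), sum(co$fields$n))
})
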
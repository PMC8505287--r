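test_that("K estimator matches hand-evaluated cases", {
  w <- ihc_window(100, 100)
  p <- point_pattern(c(10, 10), c(10, 15), w) # two points at distance 5
  dg <- c(1, 4.9, 5, 20)
  K <- ripley_k(p, dg)
  expect_equal(K, c(0, 0, 10000, 10000)) # |W| * 2 / (2 * 1) once d >= 5
  # coincident points: all pairwise distances zero
  pc <- point_pattern(rep(3, 5), rep(3, 5), w)
  expect_equal(ripley_k(pc, c(0.1, 50)), c(10000, 10000))
  expect_error(ripley_k(point_pattern(1, 1, w)), "fewer than 2")
})

test_that("K estimator equals the brute-force pair-count oracle", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:60, 1)
    p <- generate_pattern(csr_spec(n), field_window(), seed = s)
    dg <- k_distance_grid(p$window, 25)
    expect_equal(ripley_k(p, dg), k_oracle(p, dg))
  }
})

test_that("K is invariant under translation and 90-degree rotation", {
  w <- ihc_window(300, 300)
  inner <- generate_pattern(csr_spec(80), ihc_window(250, 250), seed = 6)
  p <- point_pattern(inner$x, inner$y, w)
  dg <- k_distance_grid(w)
  base <- ripley_k(p, dg)
  shifted <- point_pattern(p$x + 40, p$y + 50, w)
  expect_equal(ripley_k(shifted, dg), base)
  rot <- point_pattern(p$y, w$width - p$x, w) # 90-degree rotation
  expect_equal(ripley_k(rot, dg), base)
})

test_that("K is non-decreasing and the envelope orders correctly", {
  p <- generate_pattern(csr_spec(120), field_window(), seed = 14)
  K <- ripley_k(p)
  expect_true(all(diff(K) >= 0))
  env <- csr_envelope(120, field_window(), n_sim = 50, seed = 31)
  expect_true(all(env$env_lo <= env$K0_mean + 1e-12))
  expect_true(all(env$K0_mean <= env$env_hi + 1e-12))
  env2 <- csr_envelope(120, field_window(), n_sim = 50, seed = 31)
  expect_identical(env$env_hi, env2$env_hi) # deterministic under seed
  expect_error(csr_envelope(1, field_window()), "n >= 2")
})

test_that("envelope width shrinks with the point count", {
  w <- field_window()
  width_at <- function(n) {
    mean(vapply(1:15, function(s) {
      env <- csr_envelope(n, w, n_sim = 50, seed = 700 + s)
      mean((env$env_hi - env$env_lo) / (pi * env$d_grid^2))
    }, numeric(1)))
  }
  expect_lt(width_at(500), width_at(50))
})

test_that("classification separates cluster, CSR and lattice regimes", {
  w <- field_window()
  verdicts <- function(spec, seeds) vapply(seeds, function(s) {
    p <- generate_pattern(spec, w, seed = s)
    k <- k_analysis(p, n_sim = 100, seed = 5000 + s)
    classify_pattern(k)$verdict
  }, character(1))
  expect_true(all(verdicts(thomas_spec(150), 1:5) == "clustered"))
  expect_true(all(verdicts(lattice_spec(150, j = 0.1), 1:5) == "avoidance"))
  # K identical to the null mean is called random
  k0 <- list(d_grid = 1:10, K_obs = (1:10)^2, K0_mean = (1:10)^2,
             env_lo = (1:10)^2 - 1, env_hi = (1:10)^2 + 1)
  expect_equal(classify_pattern(k0)$verdict, "random")
  # run rule: isolated single-point excursions are not enough
  k1 <- k0; k1$K_obs[4] <- k0$env_hi[4] + 5
  expect_equal(classify_pattern(k1, min_run_fraction = 0.2)$verdict, "random")
})

test_that("uniformity index hits its definitional endpoints", {
  co <- generate_pattern(pattern_spec("coincident", 100), field_window(),
                         seed = 2)
  expect_equal(uniformity_index(co)$index, 0)
  hex <- generate_pattern(lattice_spec(400, j = 0), hex_window(), seed = 2)
  expect_equal(uniformity_index(hex)$index, 1, tolerance = 0.03)
  flagged <- uniformity_index(point_pattern(1, 1, field_window()))
  expect_false(flagged$defined)
  expect_true(is.na(flagged$index))
})

test_that("uniformity index is ~1/2.1491 under CSR and ordered across regimes", {
  w <- field_window()
  ui <- function(spec, seeds) vapply(seeds, function(s)
    uniformity_index(generate_pattern(spec, w, seed = s))$index, numeric(1))
  csr_mean <- mean(ui(csr_spec(1000), 1:20))
  expect_equal(csr_mean, 1 / 2.1491, tolerance = 0.05)
  for (s in 1:20) {
    vals <- c(uniformity_index(generate_pattern(pattern_spec("coincident", 150),
                                                w, seed = s))$index,
              ui(thomas_spec(150), s), ui(csr_spec(150), s),
              ui(lattice_spec(150, j = 0.1), s))
    expect_true(all(diff(vals) > 0)) # coincident < thomas < csr < lattice
  }
})

test_that("Donnelly edge correction lowers the index on CSR patterns", {
  p <- generate_pattern(csr_spec(500), field_window(), seed = 77)
  plain <- uniformity_index(p)$index
  corr <- uniformity_index(p, edge_correction = "donnelly")$index
  expect_lt(corr, plain)
})
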
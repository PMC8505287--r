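# shared fixtures for the suite; everything is generated in code

unit_window <- function() ihc_window(1, 1)
field_window <- function() ihc_window(1000, 1000)

# window whose aspect ratio lets a ~400-point hexagonal lattice tile it
# exactly (20 x 20 with dy/dx = sqrt(3)/2)
hex_window <- function() ihc_window(1000, 866)

csr_spec <- function(n) pattern_spec("csr", n)
thomas_spec <- function(n, sigma = 30)
  pattern_spec("thomas_cluster", n, parent_intensity = 1e-5,
               offspring_spread = sigma)
lattice_spec <- function(n, j = 0.1) pattern_spec("jittered_lattice", n,
                                                  jitter = j)

# brute-force O(n^2) pair-count K oracle, independent of ripley_k()
k_oracle <- function(p, d_grid) {
  n <- p$n
  A <- p$window$width * p$window$height
  cnt <- numeric(length(d_grid))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dij <- sqrt((p$x[i] - p$x[j])^2 + (p$y[i] - p$y[j])^2)
    cnt <- cnt + (dij <= d_grid)
  }
  cnt * A / (n * (n - 1))
}

# non-overlapping positive/negative nucleus layout for render tests
render_fixture <- function(n_pos = 50, n_neg = 50, seed = 9, side = 512,
                           min_sep = 14) {
  w <- ihc_window(side, side)
  all <- generate_pattern(pattern_spec("csr", n_pos + n_neg,
                                       min_sep = min_sep), w, seed = seed)
  list(pos = point_pattern(all$x[seq_len(n_pos)], all$y[seq_len(n_pos)], w),
       neg = point_pattern(all$x[n_pos + seq_len(n_neg)],
                           all$y[n_pos + seq_len(n_neg)], w),
       window = w)
}
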
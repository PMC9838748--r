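# Independent oracles kept deliberately naive: explicit double loops over
# pixel pairs, no shared code with the package's vectorized paths.

# enumerate all horizontal right-neighbor pairs of a gray matrix
enumerate_pairs <- function(g) {
  is <- c(); js <- c()
  for (r in seq_len(nrow(g))) {
    for (cc in seq_len(ncol(g) - 1L)) {
      a <- g[r, cc]; b <- g[r, cc + 1L]
      if (is.na(a) || is.na(b)) next
      is <- c(is, a); js <- c(js, b)
    }
  }
  list(i = is, j = js)
}

oracle_contrast <- function(g) {
  p <- enumerate_pairs(g)
  mean((p$i - p$j)^2)
}

oracle_homogeneity <- function(g) {
  p <- enumerate_pairs(g)
  mean(1 / (1 + abs(p$i - p$j)))
}

oracle_diff_counts <- function(g) {
  p <- enumerate_pairs(g)
  tab <- tabulate(abs(p$i - p$j) + 1L, nbins = 256L)
  names(tab) <- 0:255
  tab
}

# small layout/grid for fast simulation-heavy tests
small_grid <- function(n = 16) wavelength_grid(seq(400, 1000, length.out = n))
small_layout <- function() scene_layout(rows = 12, cols = 20,
                                        dye_rows = c(3, 10), dye_cols = c(2, 9),
                                        panel_rows = c(3, 10), panel_cols = c(12, 19))
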
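test_that("gray conversion is the truncating channel mean", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(rgb_to_gray(px(255, 255, 255))[1, 1], 255L)
  expect_equal(rgb_to_gray(px(1, 1, 2))[1, 1], 1L)   # floor(4/3)
  expect_equal(rgb_to_gray(px(0, 0, 0))[1, 1], 0L)
  expect_equal(rgb_to_gray(px(10, 20, 31))[1, 1], 20L)
  expect_error(rgb_to_gray(array(0, c(2, 2, 4))), "3-channel")
  expect_error(rgb_to_gray(px(0, 0, 300)), "8-bit")
})

test_that("min-max normalization stretches to 0-255 and rejects flat images", {
  g <- matrix(c(10L, 15L, 20L), 1, 3)
  out <- normalize_minmax(g)
  expect_identical(out, matrix(c(0L, 128L, 255L), 1, 3))  # round(5*25.5)=128
  expect_equal(min(out), 0); expect_equal(max(out), 255)

  full <- matrix(c(0L, 77L, 255L), 1, 3)
  expect_identical(normalize_minmax(full), full)  # identity when extremes attained
  expect_error(normalize_minmax(matrix(5L, 2, 2)), "constant")
})

test_that("the horizontal GLCM counts ordered right-neighbor pairs", {
  P <- glcm_horizontal(matrix(c(5L, 7L), 1, 2))
  expect_equal(P$p[6, 8], 1)
  expect_equal(sum(P$p), 1)

  const <- glcm_horizontal(matrix(3L, 1, 10))
  expect_equal(const$p[4, 4], 1)

  toy <- rbind(c(0L, 1L, 1L), c(0L, 0L, 1L))
  P <- glcm_horizontal(toy)
  expect_equal(P$total_pairs, 4)
  expect_equal(P$p[1, 1], 0.25)  # (0,0)
  expect_equal(P$p[1, 2], 0.50)  # (0,1) twice
  expect_equal(P$p[2, 2], 0.25)  # (1,1)
  expect_equal(glcm_contrast(P), 0.5)
  expect_equal(glcm_homogeneity(P), 0.75)
  expect_error(glcm_horizontal(matrix(1L, 3, 1)), "2 columns")
})

test_that("diagonal-only matrices give contrast 0 and homogeneity 1", {
  P <- glcm_horizontal(matrix(rep(c(9L, 9L, 200L, 200L), each = 4), 4, 4,
                              byrow = TRUE))
  expect_true(all(P$counts[row(P$counts) != col(P$counts)] == 0))
  expect_equal(glcm_contrast(P), 0)
  expect_equal(glcm_homogeneity(P), 1)
})

test_that("metrics agree with the brute-force pair enumerator (property)", {
  set.seed(99)
  for (rep in 1:100) {
    nr <- sample(2:16, 1); nc <- sample(2:16, 1)
    g <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
    P <- glcm_horizontal(g)
    expect_equal(glcm_contrast(P), oracle_contrast(g), tolerance = 1e-12)
    expect_equal(glcm_homogeneity(P), oracle_homogeneity(g), tolerance = 1e-12)
    expect_equal(P$total_pairs, nr * (nc - 1))
    expect_true(glcm_homogeneity(P) > 0 && glcm_homogeneity(P) <= 1)
    expect_true(glcm_contrast(P) >= 0 && glcm_contrast(P) <= 255^2)
    expect_equal(glcm_contrast(P) == 0, glcm_homogeneity(P) == 1)
  }
})

test_that("growing jitter degrades homogeneity and raises contrast", {
  set.seed(5)
  mags <- c(1, 4, 12)
  stats <- sapply(mags, function(m) {
    hs <- numeric(200); cs <- numeric(200)
    for (s in 1:200) {
      g <- matrix(128L + sample(seq(-m, m), 24 * 24, replace = TRUE), 24, 24)
      P <- glcm_horizontal(g)
      hs[s] <- glcm_homogeneity(P); cs[s] <- glcm_contrast(P)
    }
    c(h = mean(hs), ct = mean(cs))
  })
  expect_true(all(diff(stats["h", ]) < 0))
  expect_true(all(diff(stats["ct", ]) > 0))
})

test_that("pearson matches direct covariance arithmetic and checks inputs", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  hand <- sum((x - 2) * (y - 7 / 3)) /
    sqrt(sum((x - 2)^2) * sum((y - 7 / 3)^2))
  expect_equal(pearson(x, y), hand)
  expect_equal(round(pearson(x, y), 3), 0.982)
  expect_equal(pearson(x, -2 * x + 5), -1)
  expect_equal(pearson(x, x), 1)
  expect_error(pearson(x, c(2, 2, 2)), "constant")
  expect_error(pearson(1:2, 1:2), "3 observations")
  expect_error(pearson(1:4, 1:3), "equal length")
})

test_that("photo analysis skips pairs spanning masked-out pixels", {
  g <- rbind(c(0L, 255L, 10L, 12L),
             c(90L, 91L, 92L, 93L))
  roi <- matrix(TRUE, 2, 4)
  roi[1, 2] <- FALSE  # removes the (0,255) and (255,10) pairs
  ts <- analyze_dye_photo(g, roi, normalize = FALSE)
  pairs <- list(c(10, 12), c(90, 91), c(91, 92), c(92, 93))
  expect_equal(ts$total_pairs, 4)
  expect_equal(ts$contrast, mean(sapply(pairs, function(p) diff(p)^2)))

  # a constant ROI cannot be normalized
  expect_error(analyze_dye_photo(matrix(7L, 3, 5), matrix(TRUE, 3, 5)),
               "constant")
})

test_that("contrast and homogeneity anticorrelate across the packaged suite", {
  suite <- builtin_texture_suite()
  res <- t(sapply(suite, function(sp) {
    img <- generate_texture_image(sp$hist, sp$rows, sp$cols)
    ts <- analyze_dye_photo(img)
    c(ts$contrast, ts$homogeneity)
  }))
  expect_lt(pearson(res[, 1], res[, 2]), 0)
})
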
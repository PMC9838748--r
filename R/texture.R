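#' Convert an 8-bit RGB image to gray by integer-mean
#'
#' Per pixel the three channel brightnesses are summed and the sum divided
#' by 3 discarding the remainder: `floor((R + G + B) / 3)`. This is the
#' truncating integer mean (not the luminance-weighted conversion), kept
#' deliberately simple so every gray level is exactly reproducible.
#'
#' @param rgb 3-D array `[row, col, 3]`, either integers 0-255 or the
#'   `[0, 1]` doubles returned by [png::readPNG()] (converted exactly via
#'   `round(v * 255)`).
#' @return Integer gray matrix (class `gray_image` values 0-255).
#' @export
rgb_to_gray <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("expected a 3-channel image array [row, col, 3]")
  }
  if (max(rgb) <= 1 && is.double(rgb)) rgb <- round(rgb * 255)
  if (any(rgb != floor(rgb)) || min(rgb) < 0 || max(rgb) > 255) {
    stop("channels must be 8-bit integers in [0, 255]")
  }
  s <- rgb[, , 1, drop = FALSE] + rgb[, , 2, drop = FALSE] + rgb[, , 3, drop = FALSE]
  g <- matrix(as.integer(s %/% 3), dim(rgb)[1], dim(rgb)[2])
  g
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Min-max normalization to the full 0-255 gray range
#'
#' `v' = round((v - min) * 255 / (max - min))`, rounding half away from
#' zero; the output attains both 0 and 255. A constant image has no
#' defined stretch and is an error (callers analysing flat fields should
#' bypass normalization explicitly).
#'
#' @param g Integer gray matrix; `NA` pixels (outside a region of
#'   interest) are ignored for the min/max and propagated.
#' @return Integer gray matrix spanning 0-255.
#' @export
normalize_minmax <- function(g) {
  lo <- min(g, na.rm = TRUE)
  hi <- max(g, na.rm = TRUE)
  if (hi == lo) stop("constant image: min-max normalization is undefined")
  out <- round_half_away((g - lo) * 255 / (hi - lo))
  storage.mode(out) <- "integer"
  out
}

#' Horizontal gray-level co-occurrence matrix
#'
#' Counts ordered pairs `(g[r, c], g[r, c + 1])` — each pixel with its
#' right-hand neighbour within the same row — and normalizes by the pair
#' count. The matrix is deliberately not symmetrized: the metrics below
#' depend only on `|i - j|`, so symmetrization would not change them, and
#' the ordered counts preserve the raw neighbourhood statistics. Pairs in
#' which either pixel is `NA` (outside the region of interest) are
#' skipped, so pairs never span a masked-out pixel.
#'
#' @param g Integer gray matrix with at least 2 columns.
#' @param levels Number of gray levels (default 256, indices 0-255).
#' @return An object of class `cooc_matrix`: `p` (`levels x levels`
#'   probabilities), `counts`, and `total_pairs`.
#' @export
glcm_horizontal <- function(g, levels = 256L) {
  nc <- ncol(g)
  if (is.null(nc) || nc < 2) stop("GLCM needs an image with at least 2 columns")
  i <- as.vector(g[, -nc, drop = FALSE])
  j <- as.vector(g[, -1, drop = FALSE])
  keep <- !is.na(i) & !is.na(j)
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) stop("no valid horizontal pairs in the region")
  if (min(c(i, j)) < 0 || max(c(i, j)) >= levels) {
    stop(sprintf("gray levels outside [0, %d]", levels - 1L))
  }
  counts <- tabulate(i * levels + j + 1L, nbins = levels * levels)
  counts <- matrix(counts, levels, levels, byrow = TRUE)  # row = i, col = j
  structure(list(p = counts / sum(counts), counts = counts,
                 total_pairs = sum(counts), levels = levels),
            class = "cooc_matrix")
}

#' Co-occurrence contrast
#'
#' `sum_{i,j} p(i,j) * (i - j)^2` — the standard GLCM contrast, zero iff
#' all mass sits on the diagonal and large when neighbouring pixels differ
#' strongly. Bounded by `(levels - 1)^2`.
#'
#' @param P A [glcm_horizontal()] result.
#' @return Non-negative scalar.
#' @export
glcm_contrast <- function(P) {
  idx <- seq_len(P$levels) - 1L
  D <- outer(idx, idx, `-`)
  sum(P$p * D * D)
}

#' Co-occurrence homogeneity
#'
#' `sum_{i,j} p(i,j) / (1 + |i - j|)`, where `i` is the gray level of a
#' pixel and `j` that of its right-hand neighbour. Equals 1 exactly when
#' every pixel matches its neighbour (all mass on the diagonal) and decays
#' toward 0 as neighbour differences grow.
#'
#' @param P A [glcm_horizontal()] result.
#' @return Scalar in `(0, 1]`.
#' @export
glcm_homogeneity <- function(P) {
  idx <- seq_len(P$levels) - 1L
  D <- abs(outer(idx, idx, `-`))
  sum(P$p / (1 + D))
}

#' Pearson correlation with defined-input checks
#'
#' Sample Pearson correlation of two equal-length vectors (n >= 3); a
#' constant vector has no defined correlation and is an error rather than
#' an `NA`.
#'
#' @param x,y Numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: input is constant")
  }
  stats::cor(x, y)
}

#' Per-image texture summary
#'
#' @param contrast,homogeneity Scalars from the GLCM metrics.
#' @param total_pairs Pair count entering the co-occurrence matrix.
#' @return An object of class `texture_summary`.
#' @export
texture_summary <- function(contrast, homogeneity, total_pairs = NA_real_) {
  structure(list(contrast = contrast, homogeneity = homogeneity,
                 total_pairs = total_pairs),
            class = "texture_summary")
}

#' @export
print.texture_summary <- function(x, ...) {
  cat(sprintf("<texture_summary> contrast %.3f, homogeneity %.4f (%s pairs)\n",
              x$contrast, x$homogeneity, format(x$total_pairs, big.mark = ",")))
  invisible(x)
}

#' Visible-light texture analysis of a dye photograph
#'
#' Pipeline for one dried-dye photo: crop to the ROI bounding rectangle,
#' convert to gray by the truncating channel mean, min-max normalize over
#' the ROI pixels, then compute the horizontal co-occurrence contrast and
#' homogeneity. Pixels outside the ROI are excluded and no pixel pair
#' spans a masked-out pixel.
#'
#' @param rgb 3-channel 8-bit image array, or an already-gray integer
#'   matrix (then the gray-conversion step is skipped).
#' @param roi Optional logical ROI mask matching the image's spatial
#'   shape; default analyses the full frame.
#' @param normalize Apply min-max normalization (default `TRUE`; the
#'   constant-image error propagates to the caller).
#' @return A [texture_summary()].
#' @export
analyze_dye_photo <- function(rgb, roi = NULL, normalize = TRUE) {
  g <- if (length(dim(rgb)) == 3L) rgb_to_gray(rgb) else {
    if (any(rgb != floor(rgb), na.rm = TRUE)) stop("gray image must be integer-valued")
    g2 <- rgb; storage.mode(g2) <- "integer"; g2
  }
  if (!is.null(roi)) {
    check_mask(roi, dim(g), "ROI mask")
    rr <- range(which(rowSums(roi) > 0))
    cc <- range(which(colSums(roi) > 0))
    gbox <- g[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    mbox <- roi[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    gbox[!mbox] <- NA_integer_
    g <- gbox
  }
  if (normalize) g <- normalize_minmax(g)
  P <- glcm_horizontal(g)
  texture_summary(glcm_contrast(P), glcm_homogeneity(P), P$total_pairs)
}

#' Built-in texture fixture suite for the seven dyes
#'
#' One prescribed neighbor-difference histogram per dye, consumed by
#' [generate_texture_image()]. The dark-pink and white entries encode the
#' study's printed worked examples exactly: dark pink
#' `{d=0: 45192, d=2: 38275, d=3: 16533}` over 100,000 pairs (100 x 1001,
#' contrast 3.019, homogeneity 0.6208) and white
#' `{d=0: 1990175, d=1: 9300, d=2: 525}` over 2,000,000 pairs
#' (2000 x 1001, contrast 0.0057, homogeneity 0.9975). The other five
#' histograms are documented synthetic stand-ins (the underlying imagery
#' is not deposited) whose difference mass increases with visual
#' heterogeneity, which makes contrast rise as homogeneity falls across
#' the suite.
#'
#' @return Named list per dye: `hist` ([diff_histogram()]), `rows`, `cols`.
#' @export
builtin_texture_suite <- function() {
  list(
    red        = list(hist = diff_histogram(c(`0` = 70000, `1` = 20000, `2` = 10000)),
                      rows = 100L, cols = 1001L),
    yellow     = list(hist = diff_histogram(c(`0` = 40000, `2` = 30000, `4` = 30000)),
                      rows = 100L, cols = 1001L),
    dark_pink  = list(hist = diff_histogram(c(`0` = 45192, `2` = 38275, `3` = 16533)),
                      rows = 100L, cols = 1001L),
    black      = list(hist = diff_histogram(c(`0` = 55000, `1` = 30000, `2` = 15000)),
                      rows = 100L, cols = 1001L),
    light_pink = list(hist = diff_histogram(c(`0` = 80000, `1` = 15000, `2` = 5000)),
                      rows = 100L, cols = 1001L),
    brown      = list(hist = diff_histogram(c(`0` = 50000, `1` = 25000, `3` = 25000)),
                      rows = 100L, cols = 1001L),
    white      = list(hist = diff_histogram(c(`0` = 1990175, `1` = 9300, `2` = 525)),
                      rows = 2000L, cols = 1001L)
  )
}
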
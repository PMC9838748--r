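#' Horizontal neighbor-difference histogram
#'
#' The distribution of absolute gray-level differences `d = |left - right|`
#' over all horizontal right-neighbor pixel pairs of an image. Used as the
#' exact specification consumed by [generate_texture_image()]: co-occurrence
#' contrast and homogeneity depend on the pair distribution only through
#' `d`, so prescribing this histogram prescribes both metrics exactly.
#'
#' @param counts Named integer vector: names are differences `0..255`,
#'   values are ordered-pair counts (>= 0).
#' @return An object of class `diff_histogram` with a full length-256
#'   `counts` vector (index `d + 1`) and `total_pairs`.
#' @export
#' @examples
#' h <- diff_histogram(c(`0` = 45192, `2` = 38275, `3` = 16533))
#' h$total_pairs  # 100000
diff_histogram <- function(counts) {
  d <- as.integer(names(counts))
  if (length(d) == 0 || anyNA(d) || any(d < 0) || any(d > 255)) {
    stop("counts must be named by integer differences in [0, 255]")
  }
  if (anyDuplicated(d)) stop("duplicate difference levels in counts")
  cnt <- as.numeric(counts)
  if (any(cnt < 0) || any(cnt != floor(cnt))) stop("counts must be non-negative integers")
  full <- numeric(256)
  full[d + 1L] <- cnt
  structure(list(counts = full, total_pairs = sum(full)),
            class = "diff_histogram")
}

#' @export
print.diff_histogram <- function(x, ...) {
  nz <- which(x$counts > 0) - 1L
  cat(sprintf("<diff_histogram> %d pairs over %d difference levels: %s\n",
              x$total_pairs, length(nz),
              paste(sprintf("d=%d:%d", nz, x$counts[nz + 1L]), collapse = " ")))
  invisible(x)
}

#' Difference histogram of an existing gray image
#'
#' @param g Integer gray matrix (0-255).
#' @return A [diff_histogram()].
#' @export
diff_histogram_of <- function(g) {
  nc <- ncol(g)
  if (nc < 2) stop("image must have at least 2 columns")
  d <- abs(g[, -nc, drop = FALSE] - g[, -1, drop = FALSE])
  tab <- tabulate(as.vector(d) + 1L, nbins = 256L)
  names(tab) <- 0:255
  diff_histogram(tab[tab > 0])
}

#' Synthesize a gray image with an exactly prescribed difference histogram
#'
#' Constructs a `rows x cols` image (integers 0-255) whose multiset of
#' absolute horizontal right-neighbor differences equals `hist` exactly,
#' and which contains at least one 0 and one 255 pixel so that min-max
#' normalization is the identity on it.
#'
#' Construction: the first row is a constant 255 row (pinning 255 and
#' consuming `cols - 1` zero-difference pairs). Each remaining row takes
#' `cols - 1` differences from the pool, sorts them in descending order
#' and realizes them as a zigzag walk from 0 (alternately adding and
#' subtracting); with non-increasing step magnitudes the walk provably
#' stays within `[0, d_max]`, so any difference multiset is realizable and
#' every such row pins a 0 pixel. Row boundaries contribute no pairs, so
#' the histogram is reproduced with zero discrepancy.
#'
#' @param hist A [diff_histogram()] with
#'   `total_pairs == rows * (cols - 1)`, at least `cols - 1` pairs at
#'   `d = 0`, and `rows >= 2`.
#' @param rows,cols Image dimensions (`cols >= 2`).
#' @return Integer matrix `rows x cols` with values in 0-255.
#' @export
generate_texture_image <- function(hist, rows, cols) {
  if (!inherits(hist, "diff_histogram")) stop("hist must be a diff_histogram")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2 || cols < 2) stop("image must be at least 2 x 2")
  need <- as.double(rows) * (cols - 1L)
  if (hist$total_pairs != need) {
    stop(sprintf(
      "pair budget mismatch: histogram holds %.0f pairs but a %d x %d image has %.0f",
      hist$total_pairs, rows, cols, need))
  }
  if (hist$counts[1] < cols - 1L) {
    stop(sprintf(
      "insufficient d=0 budget: pinning the constant 255 row needs %d zero-difference pairs, histogram has %.0f",
      cols - 1L, hist$counts[1]))
  }

  counts <- hist$counts
  counts[1] <- counts[1] - (cols - 1L)           # spent on the pin row
  pool <- rep.int(0:255, counts)
  pool <- sort(pool, decreasing = TRUE)          # deterministic assignment

  img <- matrix(0L, rows, cols)
  img[1, ] <- 255L
  per_row <- cols - 1L
  for (r in 2:rows) {
    d <- pool[((r - 2L) * per_row + 1L):((r - 1L) * per_row)]
    # descending-magnitude zigzag: stays in [0, max(d)] for any multiset
    signs <- rep_len(c(1L, -1L), per_row)
    img[r, ] <- c(0L, cumsum(as.integer(signs * d)))
  }
  storage.mode(img) <- "integer"
  img
}
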
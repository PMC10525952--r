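#' Box counting over a ladder of box sizes
#'
#' For each box edge length `s` the image is partitioned into an
#' axis-aligned grid of `s x s` boxes anchored at the top-left corner
#' (partial boxes at the right/bottom edges are included), and the number
#' of boxes containing at least one foreground pixel is counted.
#'
#' @param binary 0/1 matrix with at least one foreground pixel.
#' @param sizes positive integer box edge lengths, each `<= min(W, H)`.
#' @return object of class `box_count_curve`: list with `sizes`
#'   (increasing) and `counts`.
#' @examples
#' m <- matrix(1L, 64, 64)
#' box_count(m, c(2, 4, 8, 16, 32))$counts
#' @export
box_count <- function(binary, sizes) {
  assert_binary(binary)
  fg <- which(binary == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    stop(errorCondition("box_count: image has no foreground (dimension undefined)",
                        class = c("perioFD_empty_object", "error")))
  }
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) stop_invalid("box sizes must be positive integers")
  if (any(sizes > min(dim(binary)))) {
    stop_invalid("box size exceeds image extent min(W, H) = ", min(dim(binary)))
  }
  sizes <- sort(unique(sizes))
  counts <- vapply(sizes, function(s) {
    by <- (fg[, 1] - 1L) %/% s
    bx <- (fg[, 2] - 1L) %/% s
    length(unique(by * (((ncol(binary) - 1L) %/% s) + 1L) + bx))
  }, integer(1))
  structure(list(sizes = sizes, counts = counts), class = "box_count_curve")
}

#' Fractal dimension from a box-count curve
#'
#' Ordinary least squares of `log N(s)` on `log(1/s)`; the slope is the
#' box-counting dimension. Sizes with zero counts are excluded and their
#' number recorded. A curve with constant counts (e.g. a single pixel)
#' has slope 0 and undefined fit quality.
#'
#' @param curve a `box_count_curve`.
#' @return object of class `fd_estimate`: list with `fd`, `r_squared`,
#'   `curve`, `n_points_used`, `n_zero_dropped`.
#' @export
fd_from_curve <- function(curve) {
  keep <- curve$counts > 0
  s <- curve$sizes[keep]
  n <- curve$counts[keep]
  if (length(s) < 2) {
    stop(errorCondition("fd_from_curve: fewer than 2 sizes with nonzero counts",
                        class = c("perioFD_insufficient_data", "error")))
  }
  x <- log(1 / s)
  y <- log(n)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    slope <- 0
    NA_real_  # flat curve: slope 0 exact, fit quality undefined
  } else {
    1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  structure(list(fd = slope, r_squared = r2, curve = curve,
                 n_points_used = length(s),
                 n_zero_dropped = sum(!keep)),
            class = "fd_estimate")
}

#' Default box-size ladder
#'
#' The ladder used by the common box-counting implementation in image
#' analysis software: `{2, 3, 4, 6, 8, 12, 16, 32, 64}`, filtered to the
#' image extent at estimation time.
#' @return integer vector.
#' @export
default_box_sizes <- function() c(2L, 3L, 4L, 6L, 8L, 12L, 16L, 32L, 64L)

#' Estimate the fractal dimension of a binary image
#'
#' [box_count()] on a configured size ladder, then [fd_from_curve()].
#'
#' @param binary 0/1 matrix (typically a trabecular skeleton).
#' @param sizes box-size ladder; defaults to [default_box_sizes()]
#'   filtered to `<= min(W, H)`.
#' @return an `fd_estimate`.
#' @examples
#' fx <- make_fractal_fixture("filled_square", size = 64)
#' estimate_fd(fx$pixels)$fd
#' @export
estimate_fd <- function(binary, sizes = NULL) {
  if (inherits(binary, "skeleton_map")) binary <- binary$pixels
  if (inherits(binary, "fixture_image")) binary <- binary$pixels
  if (is.null(sizes)) {
    sizes <- default_box_sizes()
    sizes <- sizes[sizes <= min(dim(binary))]
  }
  fd_from_curve(box_count(binary, sizes))
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("<fd_estimate: D = %.4f, r^2 = %s, %d sizes used%s>\n",
              x$fd,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              x$n_points_used,
              if (x$n_zero_dropped > 0) sprintf(", %d zero-count sizes dropped", x$n_zero_dropped) else ""))
  invisible(x)
}
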
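#' Analytic fractal test fixtures
#'
#' Deterministic binary images whose box-counting dimension is known in
#' closed form. These serve as ground truth for the fractal-dimension
#' estimator: a space-filling square has dimension 2, a straight line 1,
#' an isolated point 0, and the Sierpinski carpet log(8)/log(3).
#'
#' @param kind one of `"sierpinski_carpet"`, `"filled_square"`,
#'   `"horizontal_line"`, `"single_point"`.
#' @param depth recursion depth; required for `"sierpinski_carpet"`
#'   (image side is then `3^depth`), ignored otherwise.
#' @param size image side length in pixels. For the carpet it must equal
#'   `3^depth`.
#' @return An object of class `fixture_image`: a list with `pixels`
#'   (0/1 integer matrix), `truth_dim` (known dimension), and `kind`.
#' @examples
#' fx <- make_fractal_fixture("sierpinski_carpet", depth = 3)
#' sum(fx$pixels) # 8^3
#' @export
make_fractal_fixture <- function(kind = c("sierpinski_carpet", "filled_square",
                                          "horizontal_line", "single_point"),
                                 depth = NULL, size = NULL) {
  kind <- match.arg(kind)
  if (kind == "sierpinski_carpet") {
    if (is.null(depth) || depth < 1 || depth != round(depth)) {
      stop_invalid("sierpinski_carpet requires a positive integer depth")
    }
    side <- 3L^as.integer(depth)
    if (!is.null(size) && size != side) {
      stop_invalid("for sierpinski_carpet size must equal 3^depth = ", side)
    }
    px <- sierpinski_carpet(as.integer(depth))
    truth <- log(8) / log(3)
  } else {
    if (is.null(size) || size < 1 || size != round(size)) {
      stop_invalid("size must be a positive integer")
    }
    size <- as.integer(size)
    px <- matrix(0L, size, size)
    truth <- switch(kind,
      filled_square = { px[, ] <- 1L; 2 },
      horizontal_line = { px[ceiling(size / 2), ] <- 1L; 1 },
      single_point = { px[ceiling(size / 2), ceiling(size / 2)] <- 1L; 0 }
    )
  }
  structure(list(pixels = px, truth_dim = truth, kind = kind,
                 depth = if (kind == "sierpinski_carpet") as.integer(depth) else NA_integer_),
            class = "fixture_image")
}

# Pixel (i, j) (0-based) belongs to the carpet iff no base-3 digit pair of
# (i, j) is (1, 1). Vectorized digit test, no recursion.
sierpinski_carpet <- function(depth) {
  side <- 3L^depth
  idx <- 0:(side - 1L)
  keep <- matrix(TRUE, side, side)
  for (k in seq_len(depth)) {
    d <- (idx %/% 3L^(k - 1L)) %% 3L
    keep <- keep & !outer(d == 1L, d == 1L, "&")
  }
  matrix(as.integer(keep), side, side)
}

#' @export
print.fixture_image <- function(x, ...) {
  cat(sprintf("<fixture_image: %s, %dx%d, %d foreground px, truth_dim = %.4f>\n",
              x$kind, nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$truth_dim))
  invisible(x)
}
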
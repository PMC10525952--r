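#' Radiograph container
#'
#' A thin S3 wrapper around an integer matrix of 8-bit gray levels
#' (row = y, column = x, origin at the top-left corner), with optional
#' physical pixel spacing.
#'
#' @param pixels numeric/integer matrix; values are clamped-checked to
#'   \[0, 255\] and stored as integer.
#' @param spacing_mm optional pixel spacing in mm/px.
#' @param source optional source path.
#' @return object of class `radiograph`.
#' @export
radiograph <- function(pixels, spacing_mm = NULL, source = NULL) {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1) {
    stop_invalid("pixels must be a non-empty matrix")
  }
  if (any(pixels < 0) || any(pixels > 255)) {
    stop_invalid("pixel intensities must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, spacing_mm = spacing_mm, source = source),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph %dx%d px, range [%d, %d]%s>\n",
              ncol(x$pixels), nrow(x$pixels), min(x$pixels), max(x$pixels),
              if (is.null(x$spacing_mm)) "" else sprintf(", %.3f mm/px", x$spacing_mm)))
  invisible(x)
}

#' Read a grayscale radiograph image
#'
#' Reads PGM (plain `P2` or binary `P5`, 8- or 16-bit) natively, and PNG
#' when the `png` package is available. 16-bit input is linearly rescaled
#' to \[0, 255\]; RGB PNG is converted to luminance (Rec. 601 weights).
#'
#' @param path image file path (`.pgm` or `.png`).
#' @param spacing_mm optional pixel spacing in mm/px, attached to the result.
#' @return a [radiograph()].
#' @export
read_radiograph <- function(path, spacing_mm = NULL) {
  if (!file.exists(path)) stop_io("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    pgm = read_pgm(path),
    png = read_png_gray(path),
    stop_io("unsupported image format '", ext, "' for ", path,
            " (supported: pgm, png)")
  )
  radiograph(px, spacing_mm = spacing_mm, source = path)
}

read_png_gray <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_io("reading PNG requires the 'png' package; convert ", path, " to PGM")
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    # drop alpha if present, then luminance
    if (dim(a)[3] >= 3) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

# Minimal PGM reader: plain P2 and binary P5, maxval up to 65535.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  token <- function() {
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || !nzchar(ch)) stop_io("truncated PGM header: ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) {
        tok <- ch
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (!length(ch) || grepl("[ \t\r\n]", ch)) break
          tok <- paste0(tok, ch)
        }
        return(tok)
      }
    }
  }
  magic <- token()
  if (!magic %in% c("P2", "P5")) stop_io("not a PGM (P2/P5) file: ", path)
  w <- as.integer(token()); h <- as.integer(token()); maxval <- as.integer(token())
  if (anyNA(c(w, h, maxval)) || w < 1 || h < 1 || maxval < 1) {
    stop_io("malformed PGM header in ", path)
  }
  n <- w * h
  vals <- if (magic == "P2") {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
    if (length(v) < n) stop_io("truncated PGM pixel data: ", path)
    v
  } else {
    bytes_per <- if (maxval > 255) 2L else 1L
    raw <- readBin(con, "raw", n * bytes_per)
    if (length(raw) < n * bytes_per) stop_io("truncated PGM pixel data: ", path)
    if (bytes_per == 2L) {
      hi <- as.integer(raw[seq(1, 2 * n, 2)]); lo <- as.integer(raw[seq(2, 2 * n, 2)])
      hi * 256L + lo
    } else {
      as.integer(raw)
    }
  }
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (maxval != 255) m <- round(m * (255 / maxval))
  matrix(as.integer(m), h, w)
}

#' Write a radiograph (or matrix) as PGM
#'
#' @param image a [radiograph()] or a 0-255 matrix.
#' @param path output path.
#' @param ascii write plain-text `P2` (default) rather than binary `P5`.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(image, path, ascii = TRUE) {
  px <- if (inherits(image, "radiograph")) image$pixels else image
  if (any(px < 0) || any(px > 255)) stop_invalid("pixel values must lie in [0, 255]")
  px <- matrix(as.integer(round(px)), nrow(px), ncol(px))
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(c("P2", paste(ncol(px), nrow(px)), "255"), con)
    writeLines(apply(px, 1, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(c("P5", paste(ncol(px), nrow(px)), "255"), con)
    writeBin(as.raw(as.vector(t(px))), con)
  }
  invisible(path)
}

#' Region-of-interest specification with anatomical landmarks
#'
#' Pixel coordinates are 0-based with origin at the top-left; the
#' rectangle is half-open: it covers columns `[x, x + w)` and rows
#' `[y, y + h)`. Landmarks are `c(x, y)` points: `cej` (cemento-enamel
#' junction), `defect` (most apical point of the bone defect), `apex`
#' (root apex).
#'
#' @param rect numeric `c(x, y, w, h)`.
#' @param cej,defect,apex numeric `c(x, y)` landmark points.
#' @param spacing_mm optional pixel spacing.
#' @param min_size minimum ROI side length (default 32 px).
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(rect, cej, defect, apex, spacing_mm = NULL, min_size = 32L) {
  rect <- as.numeric(rect)
  if (length(rect) != 4 || rect[3] < min_size || rect[4] < min_size) {
    stop_invalid("rect must be c(x, y, w, h) with w, h >= ", min_size)
  }
  for (nm in c("cej", "defect", "apex")) {
    p <- get(nm)
    if (length(p) != 2 || anyNA(p)) stop_invalid(nm, " must be a finite c(x, y) point")
  }
  structure(list(rect = rect,
                 landmarks = list(cej = as.numeric(cej),
                                  defect = as.numeric(defect),
                                  apex = as.numeric(apex)),
                 spacing_mm = spacing_mm),
            class = "roi_spec")
}

check_roi_in_image <- function(image, roi) {
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  r <- roi$rect
  if (r[1] < 0 || r[2] < 0 || r[1] + r[3] > w || r[2] + r[4] > h) {
    stop_invalid(sprintf("ROI rectangle [%g, %g) x [%g, %g) exceeds image %dx%d",
                         r[1], r[1] + r[3], r[2], r[2] + r[4], w, h))
  }
  for (nm in names(roi$landmarks)) {
    p <- roi$landmarks[[nm]]
    if (p[1] < 0 || p[1] >= w || p[2] < 0 || p[2] >= h) {
      stop_invalid("landmark '", nm, "' lies outside image bounds")
    }
  }
  invisible(TRUE)
}

#' Crop the ROI rectangle out of a radiograph
#'
#' @param image a [radiograph()].
#' @param roi an [roi_spec()] (or a plain `c(x, y, w, h)` rectangle).
#' @return a [radiograph()] of exactly `w x h` pixels.
#' @export
crop_roi <- function(image, roi) {
  if (!inherits(image, "radiograph")) image <- radiograph(image)
  r <- if (inherits(roi, "roi_spec")) roi$rect else as.numeric(roi)
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  if (r[1] < 0 || r[2] < 0 || r[3] < 1 || r[4] < 1 ||
      r[1] + r[3] > w || r[2] + r[4] > h) {
    stop_invalid("crop rectangle out of image bounds")
  }
  # 0-based half-open [x, x+w) x [y, y+h) -> 1-based row/col ranges
  sub <- image$pixels[(r[2] + 1):(r[2] + r[4]), (r[1] + 1):(r[1] + r[3]), drop = FALSE]
  radiograph(sub, spacing_mm = image$spacing_mm, source = image$source)
}

#' Percent radiographic bone loss from anatomical landmarks
#'
#' The defect extent is expressed as a fraction of root length:
#' `100 * d(CEJ, defect) / d(CEJ, apex)` with straight-line Euclidean
#' distances. Pixel spacing cancels in the ratio, so the percentage is
#' identical with or without physical calibration.
#'
#' @param landmarks an [roi_spec()] or a list with `cej`, `defect`,
#'   `apex` points.
#' @param spacing_mm optional mm/px; only affects the reported distances,
#'   never the percentage.
#' @return list with `cej_to_defect`, `cej_to_apex` (px, or mm if spacing
#'   given), `unit`, and `percent`.
#' @examples
#' percent_bone_loss(list(cej = c(0, 0), defect = c(0, 5), apex = c(0, 20)))$percent
#' @export
percent_bone_loss <- function(landmarks, spacing_mm = NULL) {
  lm <- if (inherits(landmarks, "roi_spec")) landmarks$landmarks else landmarks
  if (is.null(spacing_mm) && inherits(landmarks, "roi_spec")) {
    spacing_mm <- landmarks$spacing_mm
  }
  cej <- as.numeric(lm$cej); defect <- as.numeric(lm$defect); apex <- as.numeric(lm$apex)
  d_da <- sqrt(sum((apex - cej)^2))
  if (d_da == 0) {
    stop_invalid("degenerate geometry: CEJ and apex coincide (root length zero)")
  }
  d_dd <- sqrt(sum((defect - cej)^2))
  scale <- if (is.null(spacing_mm)) 1 else spacing_mm
  list(cej_to_defect = d_dd * scale,
       cej_to_apex = d_da * scale,
       unit = if (is.null(spacing_mm)) "px" else "mm",
       percent = 100 * d_dd / d_da)
}

#' Read / write the ROI + landmark sidecar JSON
#'
#' Schema: `{"rect":[x,y,w,h],
#' "landmarks":{"cej":[x,y],"defect":[x,y],"apex":[x,y]},
#' "spacing_mm": optional}`, all coordinates 0-based, rectangle half-open.
#'
#' @param roi an [roi_spec()].
#' @param path JSON file path.
#' @return `read_roi_json` returns an [roi_spec()].
#' @export
write_roi_json <- function(roi, path) {
  obj <- list(rect = roi$rect, landmarks = roi$landmarks)
  if (!is.null(roi$spacing_mm)) obj$spacing_mm <- roi$spacing_mm
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stop_io("ROI sidecar not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_spec(rect = obj$rect,
           cej = obj$landmarks$cej,
           defect = obj$landmarks$defect,
           apex = obj$landmarks$apex,
           spacing_mm = obj$spacing_mm)
}
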
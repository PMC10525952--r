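#' Trabecular segmentation configuration
#'
#' Parameters of the radiographic preprocessing sequence that isolates
#' the trabecular pattern: Gaussian blur of the ROI, subtraction of the
#' blurred image from the original with a gray offset added back,
#' binarization, optional morphological opening, and skeletonization.
#' The blur/subtract step removes large-scale brightness variation
#' (soft-tissue and exposure gradients) so the threshold acts on local
#' texture only.
#'
#' @param blur_kernel_px odd Gaussian kernel width in px (default 35; the
#'   kernel sets sigma = `blur_kernel_px / 6`).
#' @param gray_offset value added after subtraction so background sits
#'   mid-gray (default 128).
#' @param binarize_threshold strict threshold: foreground iff intensity
#'   `> threshold` (default 128, i.e. brighter than the restored
#'   background).
#' @param apply_morph_cleanup apply one opening (erosion then dilation)
#'   before skeletonization (default TRUE).
#' @param morph_radius_px square structuring-element radius (default 1,
#'   i.e. 3x3).
#' @param invert treat trabeculae as dark rather than bright (default
#'   FALSE: radiopaque trabeculae are bright).
#' @param min_roi_px minimum ROI side accepted by [extract_skeleton()].
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(blur_kernel_px = 35L, gray_offset = 128,
                                binarize_threshold = 128,
                                apply_morph_cleanup = TRUE,
                                morph_radius_px = 1L,
                                invert = FALSE,
                                min_roi_px = 32L) {
  if (blur_kernel_px < 3 || blur_kernel_px %% 2 == 0) {
    stop_invalid("blur_kernel_px must be an odd integer >= 3")
  }
  if (binarize_threshold < 0 || binarize_threshold > 255) {
    stop_invalid("binarize_threshold must lie in [0, 255]")
  }
  structure(list(blur_kernel_px = as.integer(blur_kernel_px),
                 gray_offset = gray_offset,
                 binarize_threshold = binarize_threshold,
                 apply_morph_cleanup = isTRUE(apply_morph_cleanup),
                 morph_radius_px = as.integer(morph_radius_px),
                 invert = isTRUE(invert),
                 min_roi_px = as.integer(min_roi_px)),
            class = "segmentation_config")
}

# Replicate-pad 1-D convolution along rows then columns (separable kernel).
convolve_sep <- function(m, k) {
  h <- length(k) %/% 2
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2 * h) - h, 1), n)
  conv1 <- function(mat) {
    # convolve along columns of mat (i.e. down each column)
    n <- nrow(mat)
    pm <- mat[pad_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k)) {
      out <- out + k[j] * pm[j:(j + n - 1), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

#' Gaussian blur with edge replication
#'
#' Separable Gaussian smoothing with `sigma = kernel_px / 6`; borders are
#' handled by edge replication so constant images map to themselves.
#'
#' @param image matrix or [radiograph()].
#' @param kernel_px odd kernel width >= 3.
#' @return numeric matrix (not rounded; the caller decides quantization).
#' @export
gaussian_blur <- function(image, kernel_px = 35L) {
  px <- if (inherits(image, "radiograph")) image$pixels else image
  if (kernel_px < 3 || kernel_px %% 2 == 0) stop_invalid("kernel_px must be odd >= 3")
  sigma <- kernel_px / 6
  h <- kernel_px %/% 2
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k <- k / sum(k)
  convolve_sep(px * 1.0, k)
}

#' Background subtraction with gray offset
#'
#' `clip(original - blurred + offset, 0, 255)`: removes large-scale
#' brightness variation and recenters the background at `offset`.
#'
#' @param original,blurred same-shape matrices.
#' @param offset gray level added back (default 128).
#' @return numeric matrix in \[0, 255\].
#' @export
subtract_with_offset <- function(original, blurred, offset = 128) {
  o <- if (inherits(original, "radiograph")) original$pixels else original
  b <- if (inherits(blurred, "radiograph")) blurred$pixels else blurred
  if (!all(dim(o) == dim(b))) stop_invalid("original and blurred must have the same shape")
  pmin(pmax(o - b + offset, 0), 255)
}

#' Binarize by strict thresholding
#'
#' Foreground (candidate trabeculae) are pixels strictly brighter than
#' the threshold.
#'
#' @param image matrix.
#' @param threshold gray level in \[0, 255\].
#' @return 0/1 integer matrix.
#' @export
binarize <- function(image, threshold = 128) {
  px <- if (inherits(image, "radiograph")) image$pixels else image
  if (threshold < 0 || threshold > 255) stop_invalid("threshold must lie in [0, 255]")
  matrix(as.integer(px > threshold), nrow(px), ncol(px))
}

# Flat erosion/dilation with a (2r+1)x(2r+1) square element, via shifted
# minimum/maximum with edge padding chosen so the border behaves as if
# the pattern were surrounded by background.
shift_pad <- function(m, dy, dx, fill) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  ys <- max(1, 1 - dy):min(n, n - dy)
  xs <- max(1, 1 - dx):min(p, p - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

erode_sq <- function(b, r) {
  out <- b
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    out <- pmin(out, shift_pad(b, dy, dx, 0L))
  }
  matrix(as.integer(out), nrow(b), ncol(b))
}

dilate_sq <- function(b, r) {
  out <- b
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    out <- pmax(out, shift_pad(b, dy, dx, 0L))
  }
  matrix(as.integer(out), nrow(b), ncol(b))
}

#' Morphological opening (noise cleanup)
#'
#' One erosion followed by one dilation with a square structuring
#' element; removes foreground specks smaller than the element.
#'
#' @param binary 0/1 matrix.
#' @param radius structuring element radius (element side `2*radius+1`).
#' @return 0/1 integer matrix.
#' @export
morphological_cleanup <- function(binary, radius = 1L) {
  assert_binary(binary)
  dilate_sq(erode_sq(binary, radius), radius)
}

# --- Zhang-Suen thinning -------------------------------------------------
# Neighbor layout (p = center):  p9 p2 p3
#                                p8 p  p4
#                                p7 p6 p5
neighbors8 <- function(b) {
  list(p2 = shift_pad(b, -1L,  0L, 0L), p3 = shift_pad(b, -1L,  1L, 0L),
       p4 = shift_pad(b,  0L,  1L, 0L), p5 = shift_pad(b,  1L,  1L, 0L),
       p6 = shift_pad(b,  1L,  0L, 0L), p7 = shift_pad(b,  1L, -1L, 0L),
       p8 = shift_pad(b,  0L, -1L, 0L), p9 = shift_pad(b, -1L, -1L, 0L))
}

zhang_suen_pass <- function(b, first) {
  nb <- neighbors8(b)
  B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
  ring <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
  A <- matrix(0L, nrow(b), ncol(b))
  for (i in 1:8) A <- A + as.integer(ring[[i]] == 0L & ring[[i + 1]] == 1L)
  cond <- b == 1L & B >= 2 & B <= 6 & A == 1
  if (first) {
    cond <- cond & (nb$p2 * nb$p4 * nb$p6 == 0L) & (nb$p4 * nb$p6 * nb$p8 == 0L)
  } else {
    cond <- cond & (nb$p2 * nb$p4 * nb$p8 == 0L) & (nb$p2 * nb$p6 * nb$p8 == 0L)
  }
  b[cond] <- 0L
  list(b = b, changed = any(cond))
}

# Count 8-connected components among the 8 neighbors of each pixel of
# interest (used for the simple-point test in the 2x2 cleanup pass).
count_nb_components <- function(ring) {
  # ring: logical vector p2..p9 in circular order around the center
  on <- which(ring)
  if (!length(on)) return(0L)
  # adjacency in the 3x3 ring: consecutive ring positions are adjacent,
  # except that two diagonal positions are adjacent only through the
  # edge pixel between them. Positions p2,p4,p6,p8 are edges (odd index
  # here: 1,3,5,7), p3,p5,p7,p9 are corners.
  # Build adjacency among 'on' positions and count components.
  # ring index: 1=p2(edge),2=p3(corner),3=p4(edge),...,8=p9(corner);
  # consecutive positions touch; two edge positions two apart (e.g. p2,p4)
  # touch diagonally as well.
  adj <- function(i, j) {
    d <- min((i - j) %% 8, (j - i) %% 8)
    d == 1 || (d == 2 && i %% 2 == 1 && j %% 2 == 1)
  }
  comp <- integer(8); comp[] <- 0L
  cur <- 0L
  for (s in on) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (u in on) {
          if (comp[u] == 0L && adj(u, v)) {
            comp[u] <- cur
            queue <- c(queue, u)
          }
        }
      }
    }
  }
  cur
}

# Remove pixels that complete a 2x2 all-foreground block, preferring
# simple points (deletion preserves local connectivity). Zhang-Suen can
# leave such staircase blocks; box counting over-counts them.
remove_2x2_blocks <- function(b) {
  repeat {
    n <- nrow(b); p <- ncol(b)
    blk <- b[-n, -p, drop = FALSE] & b[-1, -p, drop = FALSE] &
           b[-n, -1, drop = FALSE] & b[-1, -1, drop = FALSE]
    idx <- which(blk, arr.ind = TRUE)
    if (!nrow(idx)) break
    removed_any <- FALSE
    for (k in seq_len(nrow(idx))) {
      y <- idx[k, 1]; x <- idx[k, 2]
      cand <- rbind(c(y, x), c(y, x + 1), c(y + 1, x), c(y + 1, x + 1))
      # re-check the block still exists (earlier deletions may have broken it)
      if (!all(b[cand] == 1L)) next
      for (c_i in seq_len(4)) {
        cy <- cand[c_i, 1]; cx <- cand[c_i, 2]
        ring <- c(
          if (cy > 1) b[cy - 1, cx] else 0L,                         # p2
          if (cy > 1 && cx < p) b[cy - 1, cx + 1] else 0L,           # p3
          if (cx < p) b[cy, cx + 1] else 0L,                         # p4
          if (cy < n && cx < p) b[cy + 1, cx + 1] else 0L,           # p5
          if (cy < n) b[cy + 1, cx] else 0L,                         # p6
          if (cy < n && cx > 1) b[cy + 1, cx - 1] else 0L,           # p7
          if (cx > 1) b[cy, cx - 1] else 0L,                         # p8
          if (cy > 1 && cx > 1) b[cy - 1, cx - 1] else 0L            # p9
        ) == 1L
        if (count_nb_components(ring) == 1L) {
          b[cy, cx] <- 0L
          removed_any <- TRUE
          break
        }
      }
    }
    if (!removed_any) break  # pathological ring of 2x2 blocks: leave as is
  }
  b
}

#' Skeletonize a binary image
#'
#' Topology-preserving thinning (Zhang-Suen) to one-pixel-wide curves,
#' followed by a staircase cleanup that removes redundant pixels so no
#' 2x2 all-foreground block survives. Trabeculae are dendritic;
#' skeletonization reduces each strut to its medial curve and erases
#' everything that is not curve-like.
#'
#' @param binary 0/1 matrix.
#' @return 0/1 integer matrix, subset of the input foreground.
#' @export
skeletonize <- function(binary) {
  assert_binary(binary)
  b <- binary
  storage.mode(b) <- "integer"
  repeat {
    r1 <- zhang_suen_pass(b, first = TRUE)
    r2 <- zhang_suen_pass(r1$b, first = FALSE)
    b <- r2$b
    if (!r1$changed && !r2$changed) break
  }
  remove_2x2_blocks(b)
}

#' Extract the trabecular skeleton from an ROI patch
#'
#' Runs the full preprocessing sequence: Gaussian blur, subtraction with
#' gray offset, strict binarization, optional morphological opening,
#' skeletonization. All intermediate stages are retained for inspection.
#'
#' @param roi_image [radiograph()] or matrix (the cropped ROI).
#' @param config a [segmentation_config()].
#' @return object of class `skeleton_map`: list with `pixels` (0/1
#'   skeleton) and `stages` (named list `blurred`, `subtracted`,
#'   `binarized`, `cleaned`, `skeleton`).
#' @export
extract_skeleton <- function(roi_image, config = segmentation_config()) {
  px <- if (inherits(roi_image, "radiograph")) roi_image$pixels else roi_image
  if (min(dim(px)) < config$min_roi_px) {
    stop_invalid("ROI smaller than configured minimum of ", config$min_roi_px, " px")
  }
  if (config$invert) px <- 255 - px
  blurred <- gaussian_blur(px, config$blur_kernel_px)
  subtracted <- subtract_with_offset(px, blurred, config$gray_offset)
  binarized <- binarize(subtracted, config$binarize_threshold)
  cleaned <- if (config$apply_morph_cleanup) {
    morphological_cleanup(binarized, config$morph_radius_px)
  } else {
    binarized
  }
  skel <- skeletonize(cleaned)
  structure(list(pixels = skel,
                 stages = list(blurred = blurred, subtracted = subtracted,
                               binarized = binarized, cleaned = cleaned,
                               skeleton = skel),
                 config = config),
            class = "skeleton_map")
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("<skeleton_map %dx%d, %d skeleton px (%.2f%% of ROI)>\n",
              ncol(x$pixels), nrow(x$pixels), sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

#' Write the intermediate stages of a skeleton extraction as PGM series
#'
#' @param skeleton a `skeleton_map` from [extract_skeleton()].
#' @param dir output directory; files are numbered `01_blurred.pgm` ...
#'   `05_skeleton.pgm`.
#' @return the written paths, invisibly.
#' @export
write_stage_snapshots <- function(skeleton, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- names(skeleton$stages)
  paths <- character(0)
  for (i in seq_along(nm)) {
    img <- skeleton$stages[[i]]
    if (all(img %in% c(0, 1))) img <- img * 255L
    p <- file.path(dir, sprintf("%02d_%s.pgm", i, nm[i]))
    write_radiograph(round(img), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
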
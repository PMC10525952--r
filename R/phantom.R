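#' Texture parameters for radiograph phantoms
#'
#' Spectral-synthesis texture: Gaussian white noise filtered in the
#' frequency domain by a power-law `|f|^(-beta/2)` amplitude envelope,
#' renormalized to unit variance. `amplitude` is the texture standard
#' deviation in gray levels.
#'
#' `beta` controls spatial coherence. Near 0 the texture is uncorrelated
#' speckle: after the blur/subtract/threshold protocol only isolated
#' specks survive, the morphological opening removes most of them, and
#' the skeleton is sparse (low fractal dimension) - the phantom analogue
#' of demineralized bone with disrupted trabeculae. Larger `beta` yields
#' spatially coherent, connected structure whose skeleton is a dense
#' dendritic network (high fractal dimension) - the analogue of healthy
#' trabecular bone. Over the calibrated operating range (roughly
#' `beta` in \[0.5, 3\] at 256 px) the measured skeleton FD increases
#' monotonically with `beta`.
#'
#' @param beta spectral exponent (>= 0; 0 is white noise).
#' @param amplitude texture SD in gray levels (0 gives a uniform ROI).
#' @return list with class `texture_params`.
#' @export
texture_params <- function(beta = 2.0, amplitude = 30) {
  if (beta < 0) stop_invalid("beta must be >= 0")
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  structure(list(beta = beta, amplitude = amplitude), class = "texture_params")
}

# Power-law filtered Gaussian noise field, unit variance (unless amplitude 0).
power_law_field <- function(h, w, beta) {
  noise <- matrix(stats::rnorm(h * w), h, w)
  if (beta == 0) return(noise)
  fy <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1) / h
  fx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1) / w
  f <- sqrt(outer(fy^2, fx^2, "+"))
  filt <- ifelse(f == 0, 0, f^(-beta / 2))
  field <- Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE)) / (h * w)
  field / stats::sd(field)
}

#' Synthesize a trabecular radiograph phantom
#'
#' An 8-bit grayscale phantom standing in for an intraoral periapical
#' radiograph: a smooth vertical illumination gradient over the full
#' frame, a band-limited power-law texture inside the ROI rectangle
#' (emulating the trabecular pattern), and consistent CEJ/defect/apex
#' landmarks along the ROI midline. Identical `(params, seed)` give a
#' bit-identical image.
#'
#' @param params a [texture_params()].
#' @param width,height image size in px (>= 64).
#' @param bone_loss_frac fraction of root length at which the defect
#'   base sits below the CEJ (sets the defect landmark).
#' @param roi optional `c(x, y, w, h)` rectangle (0-based, half-open);
#'   default is a centered rectangle spanning ~80% of the frame height.
#' @param seed integer seed.
#' @return list with `image` (a [radiograph()]) and `roi` (an
#'   [roi_spec()]).
#' @export
synth_radiograph <- function(params = texture_params(), width = 256, height = 256,
                             bone_loss_frac = 0.25, roi = NULL, seed = NULL) {
  if (width < 64 || height < 64) stop_invalid("image must be at least 64x64")
  if (is.null(roi)) {
    rw <- round(width * 0.5); rh <- round(height * 0.8)
    roi <- c(round((width - rw) / 2), round((height - rh) / 2), rw, rh)
  }
  rx <- roi[1]; ry <- roi[2]; rw <- roi[3]; rh <- roi[4]
  if (rx < 0 || ry < 0 || rx + rw > width || ry + rh > height) {
    stop_invalid("ROI rectangle exceeds image bounds")
  }
  # landmarks on the ROI vertical midline: CEJ at the top edge, apex at
  # the bottom edge, defect a fixed fraction of root length below CEJ
  mid_x <- rx + rw / 2
  cej <- c(mid_x, ry)
  apex <- c(mid_x, ry + rh - 1)
  defect <- c(mid_x, ry + bone_loss_frac * (rh - 1))
  if (any(c(cej, apex, defect) < 0) || apex[2] >= height || defect[2] >= height) {
    stop_invalid("landmarks fall outside image bounds")
  }
  img <- with_seed(seed, {
    base <- matrix(rep(seq(110, 150, length.out = height), width), height, width)
    if (params$amplitude > 0) {
      tex <- params$amplitude * power_law_field(rh, rw, params$beta)
    } else {
      tex <- matrix(0, rh, rw)
    }
    base[(ry + 1):(ry + rh), (rx + 1):(rx + rw)] <-
      base[(ry + 1):(ry + rh), (rx + 1):(rx + rw)] + tex
    matrix(as.integer(pmin(pmax(round(base), 0), 255)), height, width)
  })
  list(image = radiograph(img),
       roi = roi_spec(rect = roi, cej = cej, defect = defect, apex = apex))
}

#' Default phantom texture parameters per periodontitis stage
#'
#' A fixed mapping from stage label to phantom texture coherence,
#' calibrated once (at 256 px, default segmentation) so that the full
#' pipeline (crop, preprocess, skeletonize, box-count) reproduces the
#' per-stage mean fractal dimensions reported for real cohorts: about
#' 1.21 (Control and stage I) falling to about 1.02 (stage IV). Lower
#' `beta` at higher stage emulates the loss of coherent trabecular
#' structure with advancing demineralization.
#'
#' @return named list of [texture_params()] keyed by stage label.
#' @export
phantom_stage_params <- function() {
  list(
    Control = texture_params(beta = 1.85, amplitude = 30),
    I       = texture_params(beta = 1.84, amplitude = 30),
    II      = texture_params(beta = 1.78, amplitude = 30),
    III     = texture_params(beta = 1.53, amplitude = 30),
    IV      = texture_params(beta = 1.30, amplitude = 30)
  )
}

#' Default bone-loss fraction per stage used by the phantom simulator
#' @return named numeric vector of root-length fractions.
#' @export
phantom_stage_bone_loss <- function() {
  c(Control = 0.05, I = 0.121, II = 0.254, III = 0.579, IV = 0.770)
}
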
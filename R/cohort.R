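#' Published per-stage cohort distribution parameters
#'
#' Per-stage means and standard deviations of percent radiographic bone
#' loss and fractal dimension, and the within-stage Pearson correlation
#' between the two, as reported for a 75-subject cross-sectional cohort
#' (15 subjects per group: healthy controls and periodontitis stages
#' I-IV). Controls have no bone-loss entry: percent bone loss is
#' undefined for healthy periodontium.
#'
#' @return An object of class `cohort_params`: a named list of per-stage
#'   parameter lists with fields `n`, `fd_mean`, `fd_sd`, and (for staged
#'   groups) `bl_mean`, `bl_sd`, `within_r`.
#' @seealso [simulate_cohort()]
#' @export
default_cohort_params <- function() {
  p <- list(
    Control = list(n = 15L, fd_mean = 1.21, fd_sd = 0.07),
    I   = list(n = 15L, fd_mean = 1.21, fd_sd = 0.06, bl_mean = 12.1, bl_sd = 2.6,  within_r = -0.639),
    II  = list(n = 15L, fd_mean = 1.19, fd_sd = 0.05, bl_mean = 25.4, bl_sd = 4.7,  within_r = -0.561),
    III = list(n = 15L, fd_mean = 1.11, fd_sd = 0.05, bl_mean = 57.9, bl_sd = 6.1,  within_r = 0.226),
    IV  = list(n = 15L, fd_mean = 1.02, fd_sd = 0.11, bl_mean = 77.0, bl_sd = 10.3, within_r = -0.353)
  )
  structure(p, class = "cohort_params")
}

#' Stage labels in severity order
#' @return character vector `c("Control", "I", "II", "III", "IV")`
#' @export
stage_levels <- function() c("Control", "I", "II", "III", "IV")

validate_cohort_params <- function(params) {
  if (!inherits(params, "cohort_params") && !is.list(params)) {
    stop_invalid("params must be a cohort_params list")
  }
  for (st in names(params)) {
    p <- params[[st]]
    if (is.null(p$n) || p$n < 2) stop_invalid("stage ", st, ": n must be >= 2")
    if (p$fd_sd < 0) stop_invalid("stage ", st, ": fd_sd must be >= 0")
    if (!is.null(p$bl_sd) && p$bl_sd < 0) stop_invalid("stage ", st, ": bl_sd must be >= 0")
    if (!is.null(p$within_r) && abs(p$within_r) > 1) {
      stop_invalid("stage ", st, ": within_r must lie in [-1, 1]",
                   " (implied covariance not positive semi-definite otherwise)")
    }
  }
  invisible(params)
}

# Default age-band sampling probabilities per stage. The study reports the
# modal band per stage (Control: 66.7% aged <= 30; I: 66.7% aged 31-40;
# II: 53.3% aged 41-50; IV: 73.3% over 50); remaining mass is spread over
# the other bands. Stage III is not singled out; older-skewed by
# interpolation. These are free configuration, not asserted facts.
default_age_probs <- function() {
  bands <- c("25-30", "31-40", "41-50", "51-60")
  m <- rbind(
    Control = c(0.667, 0.20, 0.10, 0.033),
    I       = c(0.167, 0.667, 0.133, 0.033),
    II      = c(0.05, 0.25, 0.533, 0.167),
    III     = c(0.033, 0.133, 0.40, 0.434),
    IV      = c(0.0, 0.10, 0.167, 0.733)
  )
  colnames(m) <- bands
  m
}

#' Simulate a periodontitis cohort from per-stage distribution parameters
#'
#' Draws, for each periodontitis stage, `n` subjects from a bivariate
#' normal distribution over (percent bone loss, fractal dimension) with
#' the stage's means, SDs and within-stage correlation; controls draw
#' fractal dimension only. Bone loss is clipped to the physical range
#' \[0, 100\] (clipping events are counted in the `clipped` attribute).
#' Ages are drawn from per-stage age-band categorical distributions and
#' genders from a Bernoulli with `p_male`.
#'
#' @param params a `cohort_params` object, e.g. [default_cohort_params()].
#' @param seed integer seed; identical `(params, seed)` give identical
#'   output.
#' @param age_probs stage-by-band probability matrix (rows must cover the
#'   stages in `params`); default [default_age_probs()] restricted to them.
#' @param p_male probability a subject is male (cohort-wide default
#'   44/75, the published sex split).
#' @return A `data.frame` with columns `subject_id`, `stage` (factor in
#'   severity order), `age`, `gender`, `fd`, `bone_loss_pct` (`NA` for
#'   controls), and attribute `clipped` (number of bone-loss values
#'   clipped to \[0, 100\]).
#' @examples
#' coh <- simulate_cohort(default_cohort_params(), seed = 1)
#' table(coh$stage)
#' @export
simulate_cohort <- function(params = default_cohort_params(), seed = NULL,
                            age_probs = NULL, p_male = 44 / 75) {
  validate_cohort_params(params)
  if (is.null(age_probs)) {
    ap <- default_age_probs()
    missing_rows <- setdiff(names(params), rownames(ap))
    if (length(missing_rows)) {
      extra <- matrix(rep(1 / ncol(ap), ncol(ap) * length(missing_rows)),
                      nrow = length(missing_rows),
                      dimnames = list(missing_rows, colnames(ap)))
      ap <- rbind(ap, extra)
    }
    age_probs <- ap
  }
  with_seed(seed, {
    rows <- list()
    clipped <- 0L
    sid <- 0L
    for (st in names(params)) {
      p <- params[[st]]
      n <- as.integer(p$n)
      z1 <- stats::rnorm(n)
      if (!is.null(p$bl_mean)) {
        # 2x2 Cholesky by hand: bl drives z1, fd gets the correlated part
        z2 <- stats::rnorm(n)
        r <- p$within_r
        bl <- p$bl_mean + p$bl_sd * z1
        fd <- p$fd_mean + p$fd_sd * (r * z1 + sqrt(1 - r^2) * z2)
        clipped <- clipped + sum(bl < 0 | bl > 100)
        bl <- pmin(pmax(bl, 0), 100)
      } else {
        fd <- p$fd_mean + p$fd_sd * z1
        bl <- rep(NA_real_, n)
      }
      bands <- colnames(age_probs)
      band <- sample(bands, n, replace = TRUE, prob = age_probs[st, ])
      lims <- do.call(rbind, lapply(strsplit(band, "-"), as.numeric))
      age <- floor(stats::runif(n, lims[, 1], lims[, 2] + 1))
      gender <- ifelse(stats::runif(n) < p_male, "M", "F")
      rows[[st]] <- data.frame(
        subject_id = sprintf("S%03d", sid + seq_len(n)),
        stage = st, age = age, gender = gender,
        fd = fd, bone_loss_pct = bl,
        stringsAsFactors = FALSE
      )
      sid <- sid + n
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$stage <- factor(out$stage, levels = intersect(stage_levels(), names(params)))
    attr(out, "clipped") <- clipped
    out
  })
}

#' Write / read a cohort table as CSV
#'
#' Plain CSV with header `subject_id,stage,age,gender,fd,bone_loss_pct`.
#' @param cohort data.frame as returned by [simulate_cohort()].
#' @param path file path.
#' @return `read_cohort_csv` returns the cohort data.frame with `stage`
#'   as an ordered factor; unknown stage labels are an error naming the
#'   offending rows.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_io("cohort CSV not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "stage", "fd")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_io("cohort CSV ", path, " lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!x$stage %in% stage_levels())
  if (length(bad)) {
    stop_invalid("unknown stage label in rows ", paste(utils::head(bad, 5), collapse = ", "),
                 ": ", paste(unique(x$stage[bad]), collapse = ", "))
  }
  x$stage <- factor(x$stage, levels = stage_levels())
  if (!"bone_loss_pct" %in% names(x)) x$bone_loss_pct <- NA_real_
  x
}
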
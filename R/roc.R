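#' Empirical ROC curve for a "low score marks disease" marker
#'
#' The decision rule is `positive iff score <= t` (a low fractal
#' dimension marks periodontitis). The curve is computed at every
#' distinct score value plus the two degenerate endpoints; tied scores
#' move together.
#'
#' @param scores numeric marker values.
#' @param labels 0/1 (or logical) class labels; both classes must be
#'   present.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`,
#'   `sensitivity`, `specificity` (percent), ordered so the curve runs
#'   from (0, 0) to (1, 1).
#' @export
empirical_roc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop_invalid("scores and labels must match")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0 || nn == 0) stop_invalid("both classes must be present")
  th <- sort(unique(scores))
  tpr <- vapply(th, function(t) mean(scores[labels == 1L] <= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0L] <= t), numeric(1))
  out <- data.frame(threshold = c(-Inf, th),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  out$sensitivity <- 100 * out$tpr
  out$specificity <- 100 * (1 - out$fpr)
  out
}

#' AUC with confidence interval and test against 0.5
#'
#' AUC via the rank-sum (Mann-Whitney) identity, ties counted one half.
#' The standard error follows Hanley and McNeil; the confidence interval
#' is formed on the logit scale and back-transformed (clipped to \[0, 1\]
#' at degenerate AUC values), and the test against the chance line uses
#' `z = (AUC - 0.5) / SE`.
#'
#' @param scores,labels as in [empirical_roc()].
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `se`, `ci` (lo, hi), `p_vs_half`,
#'   `n_positive`, `n_negative`.
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0 || nn == 0) stop_invalid("both classes must be present")
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  # P(pos < neg) + 0.5 P(pos == neg): low scores indicate disease
  cmp <- outer(pos, neg, function(p, n) (p < n) + 0.5 * (p == n))
  A <- mean(cmp)
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (np - 1) * (Q1 - A^2) + (nn - 1) * (Q2 - A^2)) / (np * nn))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (A <= 0 || A >= 1 || se == 0) {
    ci <- c(max(0, A - z * se), min(1, A + z * se))
  } else {
    lg <- log(A / (1 - A))
    se_lg <- se / (A * (1 - A))
    ci <- 1 / (1 + exp(-(lg + c(-1, 1) * z * se_lg)))
  }
  p <- if (se == 0) {
    if (A == 0.5) 1 else 0
  } else {
    2 * stats::pnorm(abs(A - 0.5) / se, lower.tail = FALSE)
  }
  list(auc = A, se = se, ci = ci, p_vs_half = p,
       n_positive = np, n_negative = nn)
}

#' Youden-optimal criterion on an ROC curve
#'
#' The threshold maximizing `J = sensitivity + specificity - 1`, ties
#' broken toward higher sensitivity. The reported criterion is the
#' decision rule `positive iff score <= criterion`.
#'
#' @param curve data.frame from [empirical_roc()].
#' @return list with `criterion`, `sensitivity`, `specificity` (percent),
#'   `J`.
#' @export
youden_criterion <- function(curve) {
  usable <- is.finite(curve$threshold)
  cv <- curve[usable, , drop = FALSE]
  if (!nrow(cv)) stop_invalid("degenerate ROC curve")
  J <- cv$tpr - cv$fpr
  best <- which(J == max(J))
  if (length(best) > 1) best <- best[which.max(cv$tpr[best])]
  list(criterion = cv$threshold[best],
       sensitivity = cv$sensitivity[best],
       specificity = cv$specificity[best],
       J = max(J))
}

#' Exact (Clopper-Pearson) binomial confidence interval, in percent
#'
#' Beta-quantile two-sided interval; the lower bound is 0 when there are
#' no successes and the upper bound 100 when all trials succeed.
#'
#' @param successes,n counts, `0 <= successes <= n`, `n >= 1`.
#' @param conf confidence level.
#' @return numeric `c(lo, hi)` in percent.
#' @examples
#' clopper_pearson(15, 15) # c(78.19..., 100)
#' @export
clopper_pearson <- function(successes, n, conf = 0.95) {
  if (n < 1 || successes < 0 || successes > n) stop_invalid("require 0 <= successes <= n, n >= 1")
  a <- (1 - conf) / 2
  lo <- if (successes == 0) 0 else stats::qbeta(a, successes, n - successes + 1)
  hi <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1, n - successes)
  100 * c(lo, hi)
}

#' ROC classification "situations"
#'
#' A situation names which stages count as positive (diseased) and which
#' as negative for one ROC analysis. The five standard situations are:
#' \describe{
#'   \item{#1}{stages I-IV vs Control (n = 75)}
#'   \item{#2}{stages III-IV vs Control + I + II (n = 75)}
#'   \item{#3}{stages III-IV vs I + II (n = 60)}
#'   \item{#4}{stage IV vs I + II + III (n = 60)}
#'   \item{#5}{stages I-II vs Control (n = 45)}
#' }
#'
#' @param name label, e.g. `"#1"`.
#' @param positive,negative disjoint, non-empty sets of stage labels.
#' @return object of class `situation_spec`.
#' @export
situation_spec <- function(name, positive, negative) {
  if (!length(positive) || !length(negative) || length(intersect(positive, negative))) {
    stop_invalid("positive and negative stage sets must be disjoint and non-empty")
  }
  structure(list(name = name, positive = positive, negative = negative),
            class = "situation_spec")
}

#' @rdname situation_spec
#' @export
default_situations <- function() {
  list(
    situation_spec("#1", c("I", "II", "III", "IV"), "Control"),
    situation_spec("#2", c("III", "IV"), c("Control", "I", "II")),
    situation_spec("#3", c("III", "IV"), c("I", "II")),
    situation_spec("#4", "IV", c("I", "II", "III")),
    situation_spec("#5", c("I", "II"), "Control")
  )
}

#' Run one ROC situation on a cohort
#'
#' Assembles fractal-dimension scores and binary labels per the
#' situation, computes AUC with CI and test against 0.5, the
#' Youden-optimal criterion, and exact binomial CIs for sensitivity and
#' specificity at that criterion.
#'
#' @param cohort data.frame with `stage` and `fd` columns.
#' @param situation a [situation_spec()].
#' @param conf confidence level.
#' @return object of class `roc_result`: list with `situation`, `n`,
#'   `auc`, `auc_ci`, `p_vs_half`, `criterion`, `sensitivity`,
#'   `sensitivity_ci`, `specificity`, `specificity_ci`, `n_positive`,
#'   `n_negative`, `curve`.
#' @export
run_situation <- function(cohort, situation, conf = 0.95) {
  stages <- as.character(cohort$stage)
  missing_stages <- setdiff(c(situation$positive, situation$negative), unique(stages))
  if (length(missing_stages)) {
    stop_invalid("cohort lacks stages required by situation ", situation$name,
                 ": ", paste(missing_stages, collapse = ", "))
  }
  keep <- stages %in% c(situation$positive, situation$negative)
  fd <- cohort$fd[keep]
  lab <- as.integer(stages[keep] %in% situation$positive)
  curve <- empirical_roc(fd, lab)
  a <- roc_auc(fd, lab, conf = conf)
  yc <- youden_criterion(curve)
  np <- a$n_positive; nn <- a$n_negative
  tp <- round(yc$sensitivity / 100 * np)
  tn <- round(yc$specificity / 100 * nn)
  structure(list(situation = situation$name,
                 n = sum(keep),
                 auc = a$auc, auc_ci = a$ci, p_vs_half = a$p_vs_half,
                 criterion = yc$criterion,
                 sensitivity = yc$sensitivity,
                 sensitivity_ci = clopper_pearson(tp, np, conf),
                 specificity = yc$specificity,
                 specificity_ci = clopper_pearson(tn, nn, conf),
                 n_positive = np, n_negative = nn,
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result %s: n = %d, AUC = %.3f (%.3f-%.3f), criterion <= %.3f, sens %.1f%%, spec %.1f%%>\n",
              x$situation, x$n, x$auc, x$auc_ci[1], x$auc_ci[2],
              x$criterion, x$sensitivity, x$specificity))
  invisible(x)
}

#' Published fractal-dimension staging thresholds
#'
#' The three cutoffs that partition the fractal-dimension axis into
#' severity bands: healthy above 1.188; stage III at or below 1.158;
#' stage IV at or below 1.102. All boundaries are closed on the disease
#' side.
#'
#' @param healthy_above,stage3_at_or_below,stage4_at_or_below cutoffs;
#'   must satisfy `stage4 < stage3 < healthy`.
#' @return object of class `staging_rule`.
#' @export
staging_rule <- function(healthy_above = 1.188,
                         stage3_at_or_below = 1.158,
                         stage4_at_or_below = 1.102) {
  if (!(stage4_at_or_below < stage3_at_or_below &&
        stage3_at_or_below < healthy_above)) {
    stop_invalid("cutoffs must satisfy stage4 < stage3 < healthy")
  }
  structure(list(healthy_above = healthy_above,
                 stage3_at_or_below = stage3_at_or_below,
                 stage4_at_or_below = stage4_at_or_below),
            class = "staging_rule")
}

#' Classify periodontal severity from a fractal-dimension value
#'
#' A monotone step function of FD: `fd > 1.188` is healthy;
#' `1.158 < fd <= 1.188` the stage I/II band; `1.102 < fd <= 1.158` the
#' stage III band; `fd <= 1.102` the stage IV band (defaults; boundaries
#' are inclusive on the disease side).
#'
#' @param fd positive fractal-dimension value(s); vectorized.
#' @param rule a [staging_rule()].
#' @return character vector with levels `"Healthy"`, `"Stage I/II"`,
#'   `"Stage III"`, `"Stage IV"`.
#' @examples
#' classify_stage(c(1.20, 1.17, 1.12, 1.05))
#' @export
classify_stage <- function(fd, rule = staging_rule()) {
  if (any(fd <= 0)) stop_invalid("fd must be positive")
  ifelse(fd > rule$healthy_above, "Healthy",
         ifelse(fd > rule$stage3_at_or_below, "Stage I/II",
                ifelse(fd > rule$stage4_at_or_below, "Stage III", "Stage IV")))
}
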
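# Independent brute-force oracles. These deliberately share no code with
# the implementation paths they check.

# Box counting by explicit double loop over grid cells.
oracle_box_count <- function(binary, s) {
  h <- nrow(binary); w <- ncol(binary)
  count <- 0L
  for (by in seq_len(ceiling(h / s))) {
    for (bx in seq_len(ceiling(w / s))) {
      ys <- ((by - 1) * s + 1):min(by * s, h)
      xs <- ((bx - 1) * s + 1):min(bx * s, w)
      if (any(binary[ys, xs] == 1L)) count <- count + 1L
    }
  }
  count
}

# AUC as the mean over all positive-negative pairs of
# [score_p < score_n] + 0.5 [score_p == score_n] (low score = disease).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p < n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Best Youden J by exhaustive sweep over every candidate threshold.
oracle_youden_J <- function(scores, labels) {
  best <- -Inf
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] <= t)
    spec <- mean(scores[labels == 0] > t)
    best <- max(best, sens + spec - 1)
  }
  best
}

random_binary_image <- function(h, w, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.05, 0.6)
  matrix(rbinom(h * w, 1L, p), h, w)
}

# Full phantom -> skeleton -> FD measurement used in several tests.
phantom_fd <- function(beta, seed, size = 192, amplitude = 30) {
  ph <- synth_radiograph(texture_params(beta = beta, amplitude = amplitude),
                         width = size, height = size, seed = seed)
  sk <- extract_skeleton(crop_roi(ph$image, ph$roi))
  estimate_fd(sk$pixels)$fd
}
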
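# synthetic_data module: fixtures, phantoms, cohort simulator

test_that("fractal fixtures have the advertised geometry and truth dimensions", {
  sq <- make_fractal_fixture("filled_square", size = 64)
  expect_equal(dim(sq$pixels), c(64, 64))
  expect_true(all(sq$pixels == 1L))
  expect_equal(sq$truth_dim, 2.0)

  ln <- make_fractal_fixture("horizontal_line", size = 64)
  expect_equal(sum(ln$pixels), 64)
  expect_equal(sum(rowSums(ln$pixels) > 0), 1)
  expect_equal(ln$truth_dim, 1.0)

  pt <- make_fractal_fixture("single_point", size = 32)
  expect_equal(sum(pt$pixels), 1)
  expect_equal(pt$truth_dim, 0.0)
})

test_that("Sierpinski carpet at depth d has exactly 8^d foreground pixels", {
  for (d in 1:4) {
    fx <- make_fractal_fixture("sierpinski_carpet", depth = d)
    expect_equal(dim(fx$pixels), c(3^d, 3^d))
    expect_equal(sum(fx$pixels), 8^d)
    expect_true(all(fx$pixels %in% c(0L, 1L)))
  }
  # brute-force recursive construction must agree at depth 3
  recurse <- function(d) {
    if (d == 0) return(matrix(1L, 1, 1))
    sub <- recurse(d - 1)
    z <- matrix(0L, nrow(sub), ncol(sub))
    rbind(cbind(sub, sub, sub), cbind(sub, z, sub), cbind(sub, sub, sub))
  }
  expect_identical(make_fractal_fixture("sierpinski_carpet", depth = 3)$pixels,
                   recurse(3))
  expect_error(make_fractal_fixture("sierpinski_carpet", depth = 3, size = 64),
               class = "perioFD_invalid_argument")
})

test_that("phantom generation is seed-deterministic and respects bounds", {
  a <- synth_radiograph(texture_params(beta = 1.5), 128, 128, seed = 7)
  b <- synth_radiograph(texture_params(beta = 1.5), 128, 128, seed = 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$roi$rect, b$roi$rect)
  c <- synth_radiograph(texture_params(beta = 1.5), 128, 128, seed = 8)
  expect_false(identical(a$image$pixels, c$image$pixels))

  expect_error(synth_radiograph(width = 32, height = 32),
               class = "perioFD_invalid_argument")
  expect_error(synth_radiograph(roi = c(100, 100, 64, 64), width = 128, height = 128),
               class = "perioFD_invalid_argument")
})

test_that("zero-amplitude phantom has a uniform ROI row-wise (gradient only)", {
  ph <- synth_radiograph(texture_params(beta = 2, amplitude = 0), 128, 128, seed = 1)
  patch <- crop_roi(ph$image, ph$roi)$pixels
  # no texture: every row of the ROI is constant (vertical gradient only)
  expect_true(all(apply(patch, 1, function(r) length(unique(r)) == 1)))
})

test_that("default cohort params carry the published table values", {
  p <- default_cohort_params()
  expect_equal(names(p), c("Control", "I", "II", "III", "IV"))
  expect_equal(p$I$fd_mean, 1.21)
  expect_equal(p$I$fd_sd, 0.06)
  expect_equal(p$Control$fd_mean, 1.21)
  expect_equal(p$Control$fd_sd, 0.07)
  expect_equal(p$IV$fd_mean, 1.02)
  expect_equal(p$IV$fd_sd, 0.11)
  expect_equal(p$I$bl_mean, 12.1)
  expect_equal(p$IV$bl_mean, 77.0)
  expect_equal(p$III$within_r, 0.226)
  expect_equal(p$I$within_r, -0.639)
  expect_null(p$Control$bl_mean)
  expect_null(p$Control$within_r)
  expect_true(all(vapply(p, function(q) q$n == 15L, logical(1))))
})

test_that("cohort simulation is deterministic and validates parameters", {
  a <- simulate_cohort(seed = 42)
  b <- simulate_cohort(seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 75)
  expect_equal(as.vector(table(a$stage)), rep(15L, 5))
  expect_true(all(is.na(a$bone_loss_pct[a$stage == "Control"])))
  staged <- a[a$stage != "Control", ]
  expect_true(all(staged$bone_loss_pct >= 0 & staged$bone_loss_pct <= 100))
  expect_true(all(a$fd > 0))

  bad <- default_cohort_params()
  bad$II$within_r <- -1.4
  expect_error(simulate_cohort(bad, seed = 1), class = "perioFD_invalid_argument")
  bad2 <- default_cohort_params()
  bad2$I$n <- 1L
  expect_error(simulate_cohort(bad2, seed = 1), class = "perioFD_invalid_argument")
})

test_that("zero-SD cohort collapses onto the stage means", {
  p <- default_cohort_params()
  for (st in names(p)) {
    p[[st]]$fd_sd <- 0
    if (!is.null(p[[st]]$bl_sd)) p[[st]]$bl_sd <- 0
  }
  coh <- simulate_cohort(p, seed = 3)
  for (st in c("I", "IV")) {
    sub <- coh[coh$stage == st, ]
    expect_equal(sub$fd, rep(p[[st]]$fd_mean, 15))
    expect_equal(sub$bone_loss_pct, rep(p[[st]]$bl_mean, 15))
  }
})

test_that("simulated moments recover the stage parameters at large n", {
  p <- default_cohort_params()
  n_big <- 10000L
  for (st in names(p)) p[[st]]$n <- n_big
  coh <- simulate_cohort(p, seed = 11)
  for (st in c("Control", "I", "IV")) {
    sub <- coh[coh$stage == st, ]
    se_mean <- p[[st]]$fd_sd / sqrt(n_big)
    expect_lt(abs(mean(sub$fd) - p[[st]]$fd_mean), 3 * se_mean)
    expect_lt(abs(sd(sub$fd) - p[[st]]$fd_sd), 3 * p[[st]]$fd_sd / sqrt(2 * n_big))
  }
  sub <- coh[coh$stage == "II", ]
  r_hat <- cor(sub$bone_loss_pct, sub$fd)
  se_r <- (1 - p$II$within_r^2) / sqrt(n_big)
  expect_lt(abs(r_hat - p$II$within_r), 3 * se_r)
})

test_that("cohort CSV round-trips and rejects unknown stage labels", {
  coh <- simulate_cohort(seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  back <- read_cohort_csv(f)
  expect_equal(nrow(back), 75)
  expect_equal(back$fd, coh$fd, tolerance = 1e-12)
  expect_equal(as.character(back$stage), as.character(coh$stage))

  txt <- readLines(f)
  txt[2] <- sub("Control", "StageX", txt[2])
  writeLines(txt, f)
  expect_error(read_cohort_csv(f), class = "perioFD_invalid_argument")
})
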
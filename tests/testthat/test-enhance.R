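test_that("homomorphic transfer function matches its closed form", {
  p <- hf_params()
  expect_identical(homomorphic_gain(0, p), 0.5)
  expect_equal(homomorphic_gain(40, p), 0.5 + (1 - exp(-1)), tolerance = 1e-12)
  expect_lt(abs(homomorphic_gain(1e6, p) - 1.5), 1e-12)
})

test_that("transfer function is increasing and bounded for random valid params", {
  set.seed(11)
  for (i in 1:20) {
    gl <- runif(1, 0.1, 1)
    p <- hf_params(gamma_high = gl + runif(1, 0.1, 2), gamma_low = gl,
                   c = runif(1, 0.2, 3), d0 = runif(1, 5, 100))
    d <- seq(0, 2 * p$d0, length.out = 200)
    g <- homomorphic_gain(d, p)
    expect_true(all(diff(g) > 0))
    expect_true(all(g >= p$gamma_low & g < p$gamma_high))
  }
  expect_error(hf_params(gamma_high = 0.4, gamma_low = 0.5), "gamma_high")
  expect_error(hf_params(d0 = 0), "d0")
  expect_error(homomorphic_gain(-1), ">= 0")
})

test_that("homomorphic filter preserves constants, shape and range", {
  flat <- matrix(120, 32, 32)
  out <- homomorphic_filter(flat)
  expect_equal(dim(out), c(32L, 32L))
  expect_lt(diff(range(out)), 1e-9)

  zero <- matrix(0, 16, 16)
  expect_silent(homomorphic_filter(zero))

  set.seed(2)
  img <- matrix(runif(64 * 48, 0, 255), 64, 48)
  out <- homomorphic_filter(img)
  expect_equal(dim(out), c(64L, 48L))
  expect_true(all(out >= 0 & out <= 255))
  expect_error(homomorphic_filter(array(0, c(4, 4, 2))), "matrix")
})

test_that("filtering shifts spectral energy from the low to the high band", {
  n <- 64
  x <- matrix(seq_len(n), n, n)
  y <- t(x)
  low <- 60 + 40 * sin(2 * pi * x / n)                  # smooth gradient
  high <- 20 * ((x %/% 2 + y %/% 2) %% 2)               # fine checker
  img <- pmin(pmax(low + high, 0), 255)

  band_energy <- function(m) {
    # independent oracle: raw 2-D transform + centered distance threshold
    sp <- Mod(stats::fft(log(m + 1e-3)))^2
    d1 <- pmin(0:(n - 1), n - 0:(n - 1))
    dist <- sqrt(outer(d1^2, d1^2, `+`))
    sp[1, 1] <- 0  # drop DC
    c(low = sum(sp[dist <= 8 & dist > 0]), high = sum(sp[dist > 8]))
  }
  before <- band_energy(img)
  after <- band_energy(homomorphic_filter(img, rescale = FALSE) |>
                         (\(m) matrix(m, n, n))())
  expect_gt(after[["high"]] / after[["low"]], before[["high"]] / before[["low"]])
})

test_that("a log-domain grating at the cutoff distance is scaled by the gain there", {
  n <- 128
  f <- 40                                               # frequency index = distance 40
  x <- matrix(0:(n - 1), n, n)
  amp <- 0.2
  img <- exp(3 + amp * cos(2 * pi * f * x / n)) - 1e-3
  raw <- homomorphic_filter(img, rescale = FALSE)
  coef_in <- Mod(stats::fft(log(img + 1e-3))[f + 1, 1])
  coef_out <- Mod(stats::fft(log(raw))[f + 1, 1])
  expect_equal(coef_out / coef_in, 0.5 + (1 - exp(-1)), tolerance = 1e-6)
})

test_that("histogram clipping redistributes iteratively and conserves counts", {
  expect_equal(clip_and_redistribute(c(4, 4, 4, 4), 4), c(4, 4, 4, 4))
  out <- clip_and_redistribute(c(8, 0, 0, 0), 2, tol = 1e-9)
  expect_equal(out, c(2, 2, 2, 2), tolerance = 1e-6)

  set.seed(3)
  for (i in 1:25) {
    h <- rpois(64, lambda = runif(1, 1, 30))
    cl <- max(h) * runif(1, 0.3, 1.2)
    if (cl * 64 < sum(h)) next
    out <- clip_and_redistribute(h, cl, tol = 0.25)
    expect_lt(abs(sum(out) - sum(h)), 1e-9)
    expect_true(all(out <= cl + 0.25 + 1e-12))
  }
  expect_error(clip_and_redistribute(c(100, 100), 10), "cannot fit")
  expect_error(clip_and_redistribute(c(-1, 5), 10), ">= 0")
})

test_that("CLAHE lifts contrast on a low-contrast image and stays in range", {
  # smooth texture strictly confined to [100, 140]
  set.seed(5)
  x <- matrix(seq_len(128), 128, 128)
  ph <- 120 + 18 * sin(2 * pi * x / 48) * cos(2 * pi * t(x) / 36) +
    matrix(rnorm(128 * 128), 128, 128)
  ph <- pmin(pmax(ph, 100), 140)
  out <- clahe(ph)
  expect_equal(dim(out), dim(ph))
  expect_true(all(out >= 0 & out <= 255))
  expect_gt(stats::sd(out), stats::sd(ph))

  flat <- matrix(90, 32, 32)
  outf <- clahe(flat)
  expect_lt(diff(range(outf)), 1e-9)
})

test_that("single-tile CLAHE is a monotone mapping of gray level", {
  set.seed(6)
  img <- matrix(runif(32 * 32, 40, 200), 32, 32)
  out <- clahe(img, clahe_params(tile_rows = 1, tile_cols = 1, clip_factor = 4))
  expect_true(all(diff(out[order(img)]) >= -1e-9))
})

test_that("CLAHE rejects a tile grid larger than the image", {
  expect_error(clahe(matrix(1, 8, 8), clahe_params(tile_rows = 16, tile_cols = 16)),
               "larger than image")
})

test_that("unsharp masking sharpens edges and respects its identity cases", {
  set.seed(7)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_identical(unsharp_mask(img, unsharp_params(amount = 0)), img)

  flat <- matrix(77, 32, 32)
  expect_equal(unsharp_mask(flat), flat, tolerance = 1e-9)

  step <- cbind(matrix(80, 32, 16), matrix(160, 32, 16))
  out <- unsharp_mask(step, unsharp_params(blur_sigma = 1, amount = 1))
  grad <- function(m) max(abs(m[, -1] - m[, -ncol(m)]))
  expect_gt(grad(out), grad(step))
})

test_that("combined enhancement preserves constants and the output range", {
  flat <- matrix(50, 32, 32)
  outf <- combined_enhance(flat)
  expect_lt(diff(range(outf)), 1e-9)

  ph <- generate_phantom(phantom_spec(seed = 9))
  out <- combined_enhance(ph)
  expect_equal(dim(out), dim(ph))
  expect_true(all(out >= 0 & out <= 255))
})

test_that("information entropy hits its closed-form anchor cases", {
  expect_identical(information_entropy(matrix(13, 16, 16)), 0)
  uni <- matrix(rep(0:255, length.out = 256 * 4), 32, 32)
  expect_equal(information_entropy(uni), 8, tolerance = 1e-12)
  two <- matrix(rep(c(10, 200), each = 128), 16, 16)
  expect_equal(information_entropy(two), 1, tolerance = 1e-12)
})

test_that("entropy is bounded by [0, log2(n_bins)] on random images", {
  set.seed(10)
  for (i in 1:20) {
    img <- matrix(runif(256, 0, 255), 16, 16)
    e <- information_entropy(img)
    expect_gte(e, 0)
    expect_lte(e, 8)
  }
})

test_that("entropy report tabulates before/after per image", {
  dir <- withr::local_tempdir()
  paths <- vapply(1:3, function(i) {
    p <- file.path(dir, sprintf("im%d.png", i))
    write_gray(generate_phantom(phantom_spec(seed = i)), p)
    p
  }, character(1))
  rep <- entropy_report(paths)
  expect_s3_class(rep, "tbl_df")
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$entropy_gain, rep$entropy_after - rep$entropy_before)
})
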
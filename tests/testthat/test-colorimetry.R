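test_that("lightness decolorization matches reference colorimetry", {
  white <- array(1, c(1, 1, 3))
  expect_equal(to_grayscale_lightness(white)[1, 1, ], rep(255L, 3))
  black <- array(0, c(1, 1, 3))
  expect_equal(to_grayscale_lightness(black)[1, 1, ], rep(0L, 3))
  red <- array(0, c(1, 1, 3))
  red[1, 1, 1] <- 1
  lab <- srgb_to_lab(red)
  expect_equal(lab$L[1, 1], 53.2408, tolerance = 1e-4)
  expect_equal(to_grayscale_lightness(red)[1, 1, 1], 136L)
  # cross-check the Lab pipeline against grDevices::convertColor (which
  # uses slightly different constants, hence the loose tolerance)
  oracle <- grDevices::convertColor(matrix(c(1, 0, 0), 1), "sRGB", "Lab")
  expect_equal(lab$L[1, 1], oracle[1], tolerance = 0.5)
  expect_equal(lab$a[1, 1], oracle[2], tolerance = 0.5)
  expect_equal(lab$b[1, 1], oracle[3], tolerance = 0.5)
  # achromatic input: equal channels, monotone in input value
  ramp <- array(rep(seq(0, 1, length.out = 16), 3), c(16, 1, 3))
  g <- to_grayscale_lightness(ramp)
  expect_equal(g[, , 1], g[, , 2])
  expect_equal(g[, , 1], g[, , 3])
  expect_true(all(diff(g[, 1, 1]) >= 0))
  expect_error(to_grayscale_lightness(matrix(0, 2, 2)), "RGB")
})

test_that("LCh extraction isolates lightness and chroma", {
  red <- array(0, c(1, 2, 3))
  red[1, 1, 1] <- 1
  red[1, 2, 1] <- 1
  lch <- extract_lch(red)
  expect_equal(lch$chroma_raw[1, 1], 104.5518, tolerance = 1e-3)
  expect_equal(lch$chroma[1, 1], 255L) # image max maps to 255
  gray <- array(rep(seq(0.1, 0.9, length.out = 4), 3), c(4, 1, 3))
  lch2 <- extract_lch(gray)
  expect_true(all(lch2$chroma_raw < 1e-10))
  expect_true(all(lch2$chroma == 0L))
  # equal L* and C* but different hue give identical channel outputs
  lab_pair <- rbind(c(60, 30, 0), c(60, 0, 30))
  rgb_pair <- grDevices::convertColor(lab_pair, "Lab", "sRGB")
  img <- array(0, c(2, 1, 3))
  img[1, 1, ] <- rgb_pair[1, ]
  img[2, 1, ] <- rgb_pair[2, ]
  # loose tolerances: convertColor's Lab constants differ slightly from the
  # IEC sRGB pipeline used here
  lch3 <- extract_lch(img)
  expect_lt(abs(lch3$lightness[1, 1] - lch3$lightness[2, 1]), 4)
  expect_lt(abs(lch3$chroma_raw[1, 1] - lch3$chroma_raw[2, 1]), 2)
})

test_that("saturation-luminance statistics behave at the extremes", {
  # white patch: saturation identically 0, r undefined
  white <- array(1, c(4, 4, 3))
  sl <- saturation_luminance(white)
  expect_true(all(sl$s < 1e-6))
  expect_true(sl$degenerate)
  expect_true(is.na(sl$r))
  # an exactly linear decreasing s(Y) relation gives r = -1
  n <- 16
  img <- array(0, c(n, 1, 3))
  for (i in seq_len(n)) {
    # reds of increasing lightness and decreasing chroma
    img[i, 1, ] <- grDevices::convertColor(
      matrix(c(30 + 3 * i, 50 - 3 * i, 0), 1), "Lab", "sRGB")
  }
  sl2 <- saturation_luminance(img)
  expect_lt(sl2$r, -0.9)
  expect_error(saturation_luminance(white,
                                    matrix(c(TRUE, rep(FALSE, 15)), 4, 4)),
               "at least 2")
})

test_that("the synthetic cube has the backlit-translucency signature", {
  cube <- generate_cube_image()
  sl <- saturation_luminance(cube$image, cube$mask)
  expect_lt(sl$r, -0.5)
  # doubling the extinction widens the saturation range over the mask
  cube2 <- generate_cube_image(sigma_e = 4)
  sl2 <- saturation_luminance(cube2$image, cube2$mask)
  range_of <- function(s, m) max(s$s[m]) - min(s$s[m])
  expect_gt(range_of(sl2, cube2$mask), range_of(sl, cube$mask))
  # vanishing extinction: almost uniform image, saturation variance -> 0
  cube0 <- generate_cube_image(sigma_e = 1e-6)
  sl0 <- saturation_luminance(cube0$image, cube0$mask)
  expect_lt(var(sl0$s[cube0$mask]), 1e-6)
  expect_error(generate_cube_image(sigma_e = 0), "positive")
  expect_warning(generate_cube_image(thickness = matrix(1, 8, 8)), "flat")
})

test_that("saturation blending preserves moments and reaches both poles", {
  cube <- generate_cube_image()
  sl <- saturation_luminance(cube$image, cube$mask)
  # w = 0: identity on saturation and on the image
  b0 <- blend_saturation(cube$image, 0, cube$mask)
  expect_equal(b0$s_target, sl$s[cube$mask], tolerance = 1e-9)
  sl_b0 <- saturation_luminance(b0$image, cube$mask)
  expect_equal(sl_b0$r, sl$r, tolerance = 1e-3)
  # w = 1: blended saturation is an affine function of luminance
  b1 <- blend_saturation(cube$image, 1, cube$mask)
  expect_equal(cor(b1$s_blend, sl$Y[cube$mask]), 1, tolerance = 1e-9)
  # mean and SD of the pre-clip blend match the original to 1e-6
  for (w in c(0.25, 0.5, 0.75, 1)) {
    b <- blend_saturation(cube$image, w, cube$mask)
    expect_equal(mean(b$s_blend), sl$mean_s, tolerance = 1e-6)
    expect_equal(sd(b$s_blend), sl$sd_s, tolerance = 1e-6)
  }
  # rendered r is monotonically non-decreasing in w for this negative-r cube
  rs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(w) {
    saturation_luminance(blend_saturation(cube$image, w, cube$mask)$image,
                         cube$mask)$r
  }, numeric(1))
  expect_true(all(diff(rs) >= -1e-6))
  expect_error(blend_saturation(cube$image, 1.5, cube$mask), "\\[0, 1\\]")
  expect_error(blend_saturation(array(1, c(4, 4, 3)), 0.5), "zero variance")
})

test_that("PNG round-trip preserves 8-bit rasters", {
  f <- withr::local_tempfile(fileext = ".png")
  img <- random_image(6, 5, seed = 2)
  write_srgb(img, f)
  back <- read_srgb(f)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
})
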
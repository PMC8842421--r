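# sRGB (IEC 61966-2-1) to CIE XYZ under D65, and the D65 white point used
# throughout. L* uses the CIE [0, 100] scale, never the 8-bit-rescaled
# dialect of some image libraries.
SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
# white point as the exact matrix row sums, so achromatic pixels map to
# a* = b* = 0 without float residue
D65_WHITE <- setNames(as.vector(SRGB_TO_XYZ %*% c(1, 1, 1)),
                      c("X", "Y", "Z"))
D65_UV <- local({
  d <- D65_WHITE[1] + 15 * D65_WHITE[2] + 3 * D65_WHITE[3]
  c(u = unname(4 * D65_WHITE[1] / d), v = unname(9 * D65_WHITE[2] / d))
})

# Accepts h x w x 3 arrays in [0,1] (as png::readPNG) or integer 0..255;
# returns double array in [0,1].
as_srgb01 <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3 && dim(img)[3] >= 3)) {
    stop("expected an RGB raster: h x w x 3 array")
  }
  img <- img[, , 1:3, drop = FALSE]
  if (max(img) > 1 + 1e-9) img <- img / 255
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9) {
    stop("sRGB values must lie in [0, 1] or 0..255")
  }
  pmin(pmax(img, 0), 1)
}

srgb_decode <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

srgb_encode <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

# n x 3 linearized RGB -> n x 3 XYZ
rgb_lin_to_xyz <- function(rgb) rgb %*% t(SRGB_TO_XYZ)

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

# n x 3 XYZ -> n x 3 Lab (D65)
xyz_to_lab <- function(xyz) {
  fx <- lab_f(xyz[, 1] / D65_WHITE[1])
  fy <- lab_f(xyz[, 2] / D65_WHITE[2])
  fz <- lab_f(xyz[, 3] / D65_WHITE[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# n x 3 XYZ -> u'v' chromaticity; the white point maps to D65_UV
xyz_to_upvp <- function(xyz) {
  d <- xyz[, 1] + 15 * xyz[, 2] + 3 * xyz[, 3]
  d[d <= 0] <- NA_real_
  up <- 4 * xyz[, 1] / d
  vp <- 9 * xyz[, 2] / d
  up[is.na(up)] <- D65_UV["u"]   # black pixels: chromaticity undefined,
  vp[is.na(vp)] <- D65_UV["v"]   # treated as neutral (saturation 0)
  cbind(u = up, v = vp)
}

#' Per-pixel CIELab representation of an sRGB image
#'
#' Converts an 8-bit sRGB raster (h x w x 3, values in \[0,1\] or 0..255) to
#' per-pixel L*, a*, b* under the D65 reference white.
#'
#' @param img sRGB raster array.
#' @return list of class `lab_image` with matrices `L` (in \[0,100\]), `a`,
#'   `b`, and the image dimensions.
#' @export
srgb_to_lab <- function(img) {
  s <- as_srgb01(img)
  dm <- dim(s)[1:2]
  flat <- matrix(srgb_decode(as.vector(s)), ncol = 3)
  lab <- xyz_to_lab(rgb_lin_to_xyz(flat))
  structure(list(L = matrix(lab[, 1], dm[1], dm[2]),
                 a = matrix(lab[, 2], dm[1], dm[2]),
                 b = matrix(lab[, 3], dm[1], dm[2]),
                 width = dm[2], height = dm[1],
                 white_point = "D65"),
            class = "lab_image")
}

round_half_up <- function(x) floor(x + 0.5)

#' CIELab-lightness decolorization
#'
#' Grayscale conversion through the lightness dimension of CIELab under D65:
#' per-pixel L* is computed, mapped to 8 bits as `round(L*/100 * 255)` (half
#' up), and replicated across the three channels.
#'
#' @param img sRGB raster array (h x w x 3, \[0,1\] or 0..255).
#' @return integer array h x w x 3 with equal channels, values 0..255.
#' @export
to_grayscale_lightness <- function(img) {
  lab <- srgb_to_lab(img)
  g <- round_half_up(lab$L / 100 * 255)
  g <- pmin(pmax(g, 0), 255)
  out <- array(as.integer(g), dim = c(lab$height, lab$width, 3))
  out
}

#' Lightness and Chroma channel extraction (CIELCh)
#'
#' Converts an sRGB raster to CIELCh and extracts the Lightness channel
#' (L*, mapped as in [to_grayscale_lightness()]) and the Chroma channel
#' (`C* = sqrt(a*^2 + b*^2)`, linearly rescaled to 8 bits over the image
#' maximum; the scale is recorded so C* can be recovered).
#'
#' @param img sRGB raster array.
#' @return list with `lightness` (integer matrix 0..255), `chroma` (integer
#'   matrix 0..255), `chroma_raw` (C* values), `chroma_scale` (the image
#'   maximum C* that maps to 255).
#' @export
extract_lch <- function(img) {
  lab <- srgb_to_lab(img)
  cstar <- sqrt(lab$a^2 + lab$b^2)
  cmax <- max(cstar)
  chroma8 <- if (cmax > 0) round_half_up(cstar / cmax * 255) else
    matrix(0L, nrow(cstar), ncol(cstar))
  list(lightness = matrix(as.integer(
         pmin(pmax(round_half_up(lab$L / 100 * 255), 0), 255)),
         nrow(lab$L), ncol(lab$L)),
       chroma = matrix(as.integer(chroma8), nrow(cstar), ncol(cstar)),
       chroma_raw = cstar,
       chroma_scale = cmax)
}

# Per-pixel u'v' saturation and relative luminance for a flattened image.
satlum_values <- function(img) {
  s <- as_srgb01(img)
  flat <- matrix(srgb_decode(as.vector(s)), ncol = 3)
  xyz <- rgb_lin_to_xyz(flat)
  uv <- xyz_to_upvp(xyz)
  sat <- 13 * sqrt((uv[, 1] - D65_UV["u"])^2 + (uv[, 2] - D65_UV["v"])^2)
  list(s = sat, Y = xyz[, 2], uv = uv, xyz = xyz,
       dim = dim(s)[1:2])
}

#' CIE u'v' saturation versus luminance
#'
#' Computes per-pixel saturation `s = 13 sqrt((u'-u'_n)^2 + (v'-v'_n)^2)`
#' (chromaticity distance from the D65 white point) and relative luminance
#' `Y` in \[0,1\], and their Pearson correlation over the masked pixels. In
#' backlit translucent media, thick regions transmit less light but more
#' saturated color, so `r` is typically negative.
#'
#' @param img sRGB raster array.
#' @param mask logical matrix selecting object pixels (default: all).
#' @return list of class `saturation_map` with matrices `s` and `Y`, the
#'   `mask`, Pearson `r` over masked pixels (`NA` with `degenerate = TRUE`
#'   when either channel is constant), `mean_s`, `sd_s`.
#' @export
saturation_luminance <- function(img, mask = NULL) {
  v <- satlum_values(img)
  smat <- matrix(v$s, v$dim[1], v$dim[2])
  ymat <- matrix(v$Y, v$dim[1], v$dim[2])
  if (is.null(mask)) mask <- matrix(TRUE, v$dim[1], v$dim[2])
  stopifnot(identical(dim(mask), dim(smat)))
  if (sum(mask) < 2) stop("mask must select at least 2 pixels")
  ss <- smat[mask]
  yy <- ymat[mask]
  # tolerance absorbs float residue at the white point (s ~ 1e-7, not 0)
  degenerate <- sd(ss) < 1e-6 || sd(yy) < 1e-9
  r <- if (degenerate) NA_real_ else cor(ss, yy)
  structure(list(s = smat, Y = ymat, mask = mask, r = r,
                 degenerate = degenerate,
                 mean_s = mean(ss), sd_s = sd(ss)),
            class = "saturation_map")
}

#' Saturation-luminance correlation blending
#'
#' Modulates the saturation distribution of the masked region toward the
#' luminance distribution while keeping luminance, hue angle, and the mean
#' and standard deviation of the original saturation unchanged. Within the
#' mask, `z(s)` and `z(Y)` are blended as
#' `z_out = (1 - w) z(s) + w z(Y)`, re-standardized to unit variance, and
#' mapped back to `s_out = mu_s + sigma_s z_out` (clipped at 0). `w = 0`
#' reproduces the input; `w = 1` makes saturation a positive affine function
#' of luminance (`r = +1` before clipping). Chromaticity is moved radially in
#' the u'v' plane toward or away from the D65 white point; pixels that leave
#' the sRGB gamut are pulled back along the same ray and flagged.
#'
#' @param img sRGB raster array.
#' @param w blend weight in \[0,1\].
#' @param mask logical matrix selecting object pixels (default: all).
#' @return list with `image` (sRGB array in \[0,1\]), `s_blend` (blended
#'   masked saturation before the clip at zero, whose mean/SD exactly match
#'   the input saturation), `s_target` (after the zero clip; what is
#'   rendered), `gamut_clipped` (logical matrix), `clip_fraction`, `w`.
#' @export
blend_saturation <- function(img, w, mask = NULL) {
  if (length(w) != 1 || is.na(w) || w < 0 || w > 1) {
    stop("blend weight w must lie in [0, 1]")
  }
  v <- satlum_values(img)
  npx <- length(v$s)
  if (is.null(mask)) mask <- matrix(TRUE, v$dim[1], v$dim[2])
  stopifnot(identical(dim(mask), v$dim))
  sel <- as.vector(mask)
  s <- v$s[sel]
  Y <- v$Y[sel]
  if (sd(s) < 1e-6) stop("masked saturation has (near) zero variance")
  if (sd(Y) < 1e-9) stop("masked luminance has (near) zero variance")
  zs <- (s - mean(s)) / sd(s)
  zy <- (Y - mean(Y)) / sd(Y)
  zb <- (1 - w) * zs + w * zy
  if (sd(zb) == 0) stop("degenerate blend: z-mixture has zero variance")
  zb <- (zb - mean(zb)) / sd(zb)
  s_blend <- mean(s) + sd(s) * zb # exact mean/SD preservation, pre-clip
  s_out <- pmax(s_blend, 0)

  # rescale chromaticity radially about the white point to hit s_out
  scale <- ifelse(s > 0, s_out / s, 0)
  up <- D65_UV["u"] + (v$uv[sel, 1] - D65_UV["u"]) * scale
  vp <- D65_UV["v"] + (v$uv[sel, 2] - D65_UV["v"]) * scale

  to_rgb <- function(up, vp, Y) {
    # u'v'Y -> XYZ -> linear RGB
    X <- Y * 9 * up / (4 * vp)
    Z <- Y * (12 - 3 * up - 20 * vp) / (4 * vp)
    cbind(X, Y, Z) %*% t(solve(SRGB_TO_XYZ))
  }
  rgb <- to_rgb(up, vp, Y)
  out_of_gamut <- apply(rgb < -1e-9 | rgb > 1 + 1e-9, 1, any) & Y > 0
  if (any(out_of_gamut)) {
    # bisection on the chroma factor along the same ray until inside gamut
    lo <- rep(0, sum(out_of_gamut))
    hi <- rep(1, sum(out_of_gamut))
    du <- (up - D65_UV["u"])[out_of_gamut]
    dv <- (vp - D65_UV["v"])[out_of_gamut]
    Yo <- Y[out_of_gamut]
    for (it in 1:30) {
      mid <- (lo + hi) / 2
      rgbm <- to_rgb(D65_UV["u"] + du * mid, D65_UV["v"] + dv * mid, Yo)
      ok <- !apply(rgbm < -1e-9 | rgbm > 1 + 1e-9, 1, any)
      lo[ok] <- mid[ok]
      hi[!ok] <- mid[!ok]
    }
    rgb[out_of_gamut, ] <- to_rgb(D65_UV["u"] + du * lo,
                                  D65_UV["v"] + dv * lo, Yo)
  }
  rgb <- pmin(pmax(rgb, 0), 1)
  flat <- matrix(srgb_decode(as.vector(as_srgb01(img))), ncol = 3)
  flat[sel, ] <- rgb
  out <- array(srgb_encode(as.vector(flat)), dim = c(v$dim, 3))
  clipped <- matrix(FALSE, v$dim[1], v$dim[2])
  clipped[sel] <- out_of_gamut
  list(image = out,
       s_blend = s_blend,   # blended saturation before the clip at zero
       s_target = s_out,    # after the clip at zero (what is rendered)
       gamut_clipped = clipped,
       clip_fraction = mean(out_of_gamut),
       w = w)
}

#' Read and write PNG rasters
#'
#' Thin wrappers over the png package returning/accepting the h x w x 3
#' arrays used throughout the colorimetry module.
#'
#' @param path file path.
#' @param img array in \[0,1\] or integer 0..255.
#' @return [read_srgb()] returns an h x w x 3 array in \[0,1\].
#' @export
read_srgb <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) stop("grayscale PNG: expected an RGB image")
  as_srgb01(img)
}

#' @rdname read_srgb
#' @export
write_srgb <- function(img, path) {
  if (max(img) > 1 + 1e-9) img <- img / 255
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
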
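# Deterministic preprocessing and real-time (on-draw) affine augmentation.
#
# Augmentation happens when an image is drawn into a batch, not offline, so
# two draws of the same image in different epochs see different rasters. All
# four transforms (rotation, shift, shear, zoom) compose into a single
# affine matrix applied in one bilinear resampling pass; out-of-bounds
# samples are filled with the nearest edge pixel ("nearest" fill).

#' Augmentation configuration
#'
#' Ranges follow common augmentation-API conventions: rotation in degrees,
#' shift and zoom as fractions of the image size, shear as a dimensionless
#' intensity. Each draw samples every parameter uniformly from its
#' `[-max, +max]` range (zoom from `[1 - max, 1 + max]`).
#'
#' @param rotation_max_deg Maximum absolute rotation, degrees. Default 5.
#' @param shift_max_frac Maximum absolute horizontal/vertical shift as a
#'   fraction of width/height. Default 0.05.
#' @param shear_max Maximum absolute shear intensity. Default 0.05.
#' @param zoom_max_frac Maximum absolute zoom deviation from 1. Default 0.05.
#' @param fill_mode Out-of-bounds fill rule; only `"nearest"` (edge
#'   replication) is supported.
#' @param seed Optional integer seed used when [augment_image()] is called
#'   without one.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation_max_deg = 5, shift_max_frac = 0.05,
                           shear_max = 0.05, zoom_max_frac = 0.05,
                           fill_mode = "nearest", seed = NULL) {
  check_scalar(rotation_max_deg, "rotation_max_deg", min = 0)
  check_scalar(shift_max_frac, "shift_max_frac", min = 0)
  check_scalar(shear_max, "shear_max", min = 0)
  check_scalar(zoom_max_frac, "zoom_max_frac", min = 0, max = 0.99)
  fill_mode <- match.arg(fill_mode, "nearest")
  structure(list(rotation_max_deg = rotation_max_deg,
                 shift_max_frac = shift_max_frac,
                 shear_max = shear_max, zoom_max_frac = zoom_max_frac,
                 fill_mode = fill_mode, seed = seed),
            class = "augment_config")
}

check_image <- function(img, call = rlang::caller_env()) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      any(dim(img)[1:2] < 1L)) {
    abort("Image must be a non-empty height x width x 3 RGB array.",
          class = "melbalance_invalid_input", call = call)
  }
  invisible(TRUE)
}

# bilinear sampling of img at (possibly fractional) source coords; coords
# are clamped to the image, which implements nearest-edge fill
bilinear_sample <- function(img, sx, sy) {
  h <- dim(img)[1]; w <- dim(img)[2]
  sx <- pmin(pmax(sx, 1), w)
  sy <- pmin(pmax(sy, 1), h)
  x0 <- pmin(floor(sx), w - 1); x1 <- x0 + 1
  y0 <- pmin(floor(sy), h - 1); y1 <- y0 + 1
  if (w == 1) { x0 <- x1 <- rep(1, length(sx)) }
  if (h == 1) { y0 <- y1 <- rep(1, length(sy)) }
  fx <- sx - x0; fy <- sy - y0
  out <- array(0, dim = dim(img))
  for (ch in seq_len(dim(img)[3])) {
    m <- img[, , ch]
    v00 <- m[cbind(y0, x0)]; v01 <- m[cbind(y0, x1)]
    v10 <- m[cbind(y1, x0)]; v11 <- m[cbind(y1, x1)]
    out[, , ch] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
      fy * ((1 - fx) * v10 + fx * v11)
  }
  out
}

# warp with the inverse affine map q_src = A %*% (p_out - C) + t_src + C
affine_warp <- function(img, A, t_src) {
  h <- dim(img)[1]; w <- dim(img)[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  gx <- rep(seq_len(w), each = h) - cx
  gy <- rep(seq_len(h), times = w) - cy
  sx <- A[1, 1] * gx + A[1, 2] * gy + t_src[1] + cx
  sy <- A[2, 1] * gx + A[2, 2] * gy + t_src[2] + cy
  bilinear_sample(img, sx, sy)
}

#' Randomly augment a preprocessed image
#'
#' Draws a rotation, horizontal/vertical shift, shear and zoom from the
#' configured ranges, composes them into one affine transform (applied in
#' that order) and resamples the image once with bilinear interpolation and
#' nearest-edge fill. Output shape equals input shape and pixel values stay
#' in `[0, 1]`.
#'
#' @param img Numeric `height x width x 3` array in `[0, 1]` (see
#'   [preprocess_image()]).
#' @param config An [augment_config()].
#' @param seed Integer seed for this draw; `NULL` uses `config$seed`, and if
#'   that is `NULL` the current RNG stream (the training loop's case, which
#'   is what makes the augmentation "real-time": each draw differs).
#' @return Augmented array of the same shape.
#' @export
augment_image <- function(img, config = augment_config(), seed = NULL) {
  check_image(img)
  stopifnot(inherits(config, "augment_config"))
  seed <- seed %||% config$seed
  with_seed_maybe(seed, {
    h <- dim(img)[1]; w <- dim(img)[2]
    theta <- runif(1, -config$rotation_max_deg, config$rotation_max_deg) * pi / 180
    tx <- runif(1, -config$shift_max_frac, config$shift_max_frac) * w
    ty <- runif(1, -config$shift_max_frac, config$shift_max_frac) * h
    sh <- runif(1, -config$shear_max, config$shear_max)
    zm <- runif(1, 1 - config$zoom_max_frac, 1 + config$zoom_max_frac)
    # forward: p_out = Z %*% Sh %*% (R %*% q + t); invert for sampling
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    Sh <- matrix(c(1, 0, sh, 1), 2, 2)
    Z <- diag(c(zm, zm))
    Ainv <- solve(Z %*% Sh %*% R)
    # p_src = R^-1 (Sh^-1 Z^-1 p_out - t) = Ainv p_out - R^-1 t
    t_src <- -solve(R) %*% c(tx, ty)
    affine_warp(img, Ainv, as.vector(t_src))
  })
}

#' Deterministic preprocessing: crop, resize, normalize
#'
#' Center-crops the image to the target aspect ratio (4:3 by default),
#' resizes it with bilinear interpolation to `width x height`, and scales
#' intensities into `[0, 1]` (inputs with values above 1 are assumed to be
#' 8-bit and divided by 255).
#'
#' @param img Numeric `height x width x 3` RGB array, values in `[0, 1]` or
#'   `[0, 255]`.
#' @param width,height Target size in pixels. Defaults 256 x 192.
#' @return Numeric `height x width x 3` array in `[0, 1]`.
#' @export
preprocess_image <- function(img, width = 256, height = 192) {
  check_image(img)
  check_count(width, "width", min = 1L); check_count(height, "height", min = 1L)
  if (max(img) > 1) img <- img / 255
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(dim(img)[1], dim(img)[2], 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  aspect <- width / height
  if (w / h > aspect) {            # too wide: crop columns
    cw <- round(h * aspect)
    x0 <- floor((w - cw) / 2)
    img <- img[, (x0 + 1):(x0 + cw), , drop = FALSE]
  } else if (w / h < aspect) {     # too tall: crop rows
    ch <- round(w / aspect)
    y0 <- floor((h - ch) / 2)
    img <- img[(y0 + 1):(y0 + ch), , , drop = FALSE]
  }
  resize_bilinear(img, height, width)
}

# resize with pixel-center alignment; exact identity when sizes match
resize_bilinear <- function(img, height, width) {
  h <- dim(img)[1]; w <- dim(img)[2]
  sx <- pmin(pmax((seq_len(width) - 0.5) * (w / width) + 0.5, 1), w)
  sy <- pmin(pmax((seq_len(height) - 0.5) * (h / height) + 0.5, 1), h)
  gx <- rep(sx, each = height)
  gy <- rep(sy, times = width)
  x0 <- pmin(floor(gx), max(w - 1, 1)); x1 <- pmin(x0 + 1, w)
  y0 <- pmin(floor(gy), max(h - 1, 1)); y1 <- pmin(y0 + 1, h)
  fx <- gx - x0; fy <- gy - y0
  out <- array(0, dim = c(height, width, 3L))
  for (chn in 1:3) {
    m <- img[, , chn]
    v <- (1 - fy) * ((1 - fx) * m[cbind(y0, x0)] + fx * m[cbind(y0, x1)]) +
      fy * ((1 - fx) * m[cbind(y1, x0)] + fx * m[cbind(y1, x1)])
    out[, , chn] <- matrix(v, height, width)
  }
  out
}
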
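# Seeded generator of imbalanced two-class lesion-like image datasets.
#
# Each image is a skin-tone textured background with one elliptical lesion.
# Three lesion properties carry the class signal, in the directions a
# dermatologist would recognise: melanoma-like lesions are darker, have a
# more irregular (wavy) border, and are more asymmetric. `separability`
# scales the distance between the class-conditional parameter
# distributions: 0 makes the classes identically distributed, 1 makes a
# single handcrafted border-roughness feature nearly perfectly separating.
# The goal is controllable statistical structure, not photorealism.

#' Synthetic dataset configuration
#'
#' @param n_pos,n_neg Number of positive (melanoma-like) and negative
#'   (nevus-like) images.
#' @param image_height,image_width Raster size in pixels. Defaults 192 x 256.
#' @param separability In `[0, 1]`: distance between the class-conditional
#'   lesion-parameter distributions. Default 0.7 (learnable but imperfect).
#' @param noise_level Non-negative pixel-noise scale (Gaussian speckle with
#'   standard deviation `0.1 * noise_level`). Default 0.1.
#' @param seed Integer seed; the dataset is fully deterministic given it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_pos, n_neg, image_height = 192, image_width = 256,
                         separability = 0.7, noise_level = 0.1, seed = 1) {
  check_count(n_pos, "n_pos", min = 1L)
  check_count(n_neg, "n_neg", min = 1L)
  check_count(image_height, "image_height", min = 16L)
  check_count(image_width, "image_width", min = 16L)
  check_scalar(separability, "separability", min = 0, max = 1)
  check_scalar(noise_level, "noise_level", min = 0)
  check_count(seed, "seed")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 separability = separability, noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# class-conditional lesion parameters; the positive class mean is shifted by
# `separability` along darkness, border irregularity, and asymmetry
draw_lesion_params <- function(label, separability) {
  shift <- separability * label
  list(
    darkness = max(0.05, rnorm(1, 0.35 + 0.25 * shift, 0.05)),
    irregularity = max(0, rnorm(1, 0.08 + 0.15 * shift, 0.03)),
    asymmetry = max(0, rnorm(1, 0.10 + 0.25 * shift, 0.05)),
    radius_frac = runif(1, 0.18, 0.28),
    elongation = runif(1, 0.6, 1),
    angle = runif(1, 0, pi),
    cx_frac = runif(1, 0.4, 0.6), cy_frac = runif(1, 0.4, 0.6),
    phases = runif(4, 0, 2 * pi))
}

render_lesion_image <- function(p, height, width, noise_level) {
  x <- matrix(rep(seq_len(width), each = height), height, width)
  y <- matrix(rep(seq_len(height), times = width), height, width)
  cx <- p$cx_frac * width; cy <- p$cy_frac * height
  # lesion-frame coordinates (rotated, elongated)
  dx <- x - cx; dy <- y - cy
  u <- cos(p$angle) * dx + sin(p$angle) * dy
  v <- (-sin(p$angle) * dx + cos(p$angle) * dy) / p$elongation
  r <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  r0 <- p$radius_frac * min(height, width)
  wave <- 0.6 * sin(3 * theta + p$phases[1]) +
    0.4 * sin(5 * theta + p$phases[2]) +
    0.3 * sin(7 * theta + p$phases[3])
  border <- r0 * (1 + p$irregularity * wave) *
    (1 + p$asymmetry * 0.5 * cos(theta - p$phases[4]))
  edge <- pmax(r0 * 0.08, 1)
  inside <- pmin(pmax((border - r) / edge, 0), 1)   # soft lesion membership
  # pigment is deeper towards an off-centre focus (asymmetric darkening)
  focus <- 1 + p$asymmetry * (u / (r0 + 1)) * inside
  depth <- p$darkness * inside * pmin(pmax(focus, 0.3), 1.7)

  base <- c(0.86, 0.64, 0.54)                       # skin tone RGB
  gx <- (x / width - 0.5); gy <- (y / height - 0.5)
  illum <- 1 - 0.12 * (gx^2 + gy^2)                 # gentle vignette
  img <- array(0, dim = c(height, width, 3))
  tint <- c(0.95, 1.1, 1.25)   # melanin absorbs blue/green hardest
  for (ch in 1:3) {
    plane <- base[ch] * illum * (1 - pmin(depth * tint[ch], 0.95))
    plane <- plane + rnorm(length(plane), sd = 0.1 * noise_level)
    img[, , ch] <- matrix(pmin(pmax(plane, 0), 1), height, width)
  }
  img
}

stratified_split <- function(n, props, seed_offset_rng = TRUE) {
  # deterministic sizes: largest-remainder apportionment, then shuffle
  sizes <- floor(n * props)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(n * props - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  sample(rep(names(props), sizes))
}

#' Generate a synthetic imbalanced lesion image dataset
#'
#' Renders `n_pos + n_neg` images, writes them as binary PPM files under
#' `out_dir/images/`, and writes `manifest.csv` (columns `path`, `label`,
#' `split`) with stratified splits, `params.csv` with each image's drawn
#' lesion parameters (ground truth for validation), and `config.json`
#' echoing all parameters. Fully deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @param splits Named numeric vector of split proportions summing to 1.
#'   Default `c(train = 0.8, val = 0.1, test = 0.1)`, stratified by class.
#'   Use a single named proportion of 1 (e.g. `c(benchmark = 1)`) for a
#'   held-out benchmark set.
#' @return The manifest tibble, invisibly carrying the config as attribute.
#' @export
generate_dataset <- function(config, out_dir,
                             splits = c(train = 0.8, val = 0.1, test = 0.1)) {
  stopifnot(inherits(config, "synth_config"))
  if (abs(sum(splits) - 1) > 1e-9 || is.null(names(splits))) {
    abort("`splits` must be a named vector of proportions summing to 1.",
          class = "melbalance_invalid_input")
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(file.path(out_dir, "images"))) {
    abort(sprintf("Cannot create output directory %s.", out_dir),
          class = "melbalance_invalid_input")
  }
  withr::with_seed(config$seed, {
    labels <- rep(c(1L, 0L), c(config$n_pos, config$n_neg))
    split <- character(length(labels))
    split[labels == 1] <- stratified_split(config$n_pos, splits)
    split[labels == 0] <- stratified_split(config$n_neg, splits)
    rows <- vector("list", length(labels))
    pars <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      p <- draw_lesion_params(labels[i], config$separability)
      img <- render_lesion_image(p, config$image_height, config$image_width,
                                 config$noise_level)
      rel <- file.path("images", sprintf("img_%05d_%d.ppm", i, labels[i]))
      write_ppm(img, file.path(out_dir, rel))
      rows[[i]] <- tibble(path = rel, label = labels[i], split = split[i])
      pars[[i]] <- tibble(path = rel, darkness = p$darkness,
                          irregularity = p$irregularity,
                          asymmetry = p$asymmetry)
    }
    manifest <- dplyr::bind_rows(rows)
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    # ground-truth lesion parameters, for validation against the rendering
    readr::write_csv(dplyr::bind_rows(pars), file.path(out_dir, "params.csv"))
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(structure(manifest, config = config))
  })
}

#' Generate a benchmark-shaped held-out set
#'
#' A synthetic stand-in for a 100-image dermoscopic benchmark: exactly 20
#' positives and 80 negatives by default, all assigned to split
#' `"benchmark"`, generated with its own independent seed.
#'
#' @param out_dir Output directory.
#' @param n_pos,n_neg Class sizes. Defaults 20 / 80.
#' @param seed Independent seed. Default 999.
#' @param ... Further arguments to [synth_config()].
#' @return The manifest tibble (invisibly).
#' @export
generate_benchmark <- function(out_dir, n_pos = 20, n_neg = 80, seed = 999,
                               ...) {
  cfg <- synth_config(n_pos = n_pos, n_neg = n_neg, seed = seed, ...)
  generate_dataset(cfg, out_dir, splits = c(benchmark = 1))
}

#' Load a manifest and its images
#'
#' @param dir Dataset directory containing `manifest.csv` and the images.
#' @param split Optional character vector of splits to keep.
#' @return Tibble with columns `path`, `label`, `split`.
#' @export
load_manifest <- function(dir, split = NULL) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) {
    abort(sprintf("No manifest.csv in %s.", dir),
          class = "melbalance_invalid_input")
  }
  m <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(split)) m <- m[m$split %in% split, ]
  as_tibble(m)
}

#' @rdname load_manifest
#' @param manifest A manifest tibble from [load_manifest()].
#' @return `load_images()`: list of `height x width x 3` arrays in `[0, 1]`.
#' @export
load_images <- function(manifest, dir) {
  lapply(manifest$path, function(p) read_ppm(file.path(dir, p)))
}

#' Binormal score generator with a target AUC
#'
#' Draws negative raw scores from N(0, 1) and positive raw scores from
#' N(mu, 1) with `mu = sqrt(2) * qnorm(auc_target)` — the binormal identity
#' under which the expected AUC equals `auc_target` — then maps both
#' through the logistic function into `[0, 1]` (a strictly increasing map,
#' so the AUC is unchanged).
#'
#' @param n_pos,n_neg Class sizes.
#' @param auc_target Target AUC in `[0.5, 1]`.
#' @param seed Optional integer seed.
#' @return Tibble with columns `label` (0/1) and `score` in `[0, 1]`.
#' @export
generate_scores <- function(n_pos, n_neg, auc_target, seed = NULL) {
  check_count(n_pos, "n_pos", min = 1L)
  check_count(n_neg, "n_neg", min = 1L)
  check_scalar(auc_target, "auc_target", min = 0.5, max = 1)
  mu <- sqrt(2) * qnorm(auc_target)
  with_seed_maybe(seed, {
    raw <- c(rnorm(n_pos, mean = mu), rnorm(n_neg))
    tibble(label = rep(c(1L, 0L), c(n_pos, n_neg)), score = plogis(raw))
  })
}

#' Handcrafted lesion feature: border roughness
#'
#' Mean absolute radial deviation of the lesion border from its best-fit
#' ellipse, estimated from the rendered image by thresholding the red
#' channel. Used as an independent, non-learned reference feature.
#'
#' @param img A rendered lesion image array.
#' @return A single non-negative number (0 when no lesion is found).
#' @export
lesion_border_roughness <- function(img) {
  check_image(img)
  red <- img[, , 1]
  mask <- red < (min(red) + 0.55 * (stats::median(red) - min(red)))
  if (sum(mask) < 20) return(0)
  ys <- row(mask)[mask]; xs <- col(mask)[mask]
  cy <- mean(ys); cx <- mean(xs)
  r <- sqrt((ys - cy)^2 + (xs - cx)^2)
  th <- atan2(ys - cy, xs - cx)
  # border radius per angular bin, roughness = relative spread of the
  # high-order variation around a smooth (low-order) fit
  bins <- cut(th, breaks = seq(-pi, pi, length.out = 65), include.lowest = TRUE)
  rb <- tapply(r, bins, max)
  rb <- rb[is.finite(rb)]
  if (length(rb) < 16) return(0)
  x <- seq_along(rb)
  fit <- stats::lm(rb ~ sin(2 * pi * x / length(rb)) +
                     cos(2 * pi * x / length(rb)))
  sd(stats::residuals(fit)) / mean(rb)
}
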
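# Desk-scale convolutional backbone.
#
# A frozen, seeded random convolutional feature extractor standing in for a
# large ImageNet-pretrained network: two 3x3 convolution stages over an
# aggressively average-pooled image, summarised by global pooling statistics
# into a fixed-length feature vector. Random convolutional features followed
# by a trainable head are a standard cheap baseline; freezing the backbone
# mirrors frozen-backbone transfer learning and keeps training CPU-cheap.
# Any object with `feature_dim` and a `backbone_features()` method satisfies
# the backbone contract, so a real pretrained network can be plugged in.

#' Build the tiny frozen convolutional backbone
#'
#' @param seed Integer seed for the (deterministic) filter initialization.
#' @param channels Integer vector of length 2: channels of the two
#'   convolution stages. The defaults give a 64-dimensional feature vector
#'   and about 2.5k parameters.
#' @param pool Integer vector of length 2: average-pooling factors applied
#'   before each convolution stage.
#' @return An object of class `tiny_backbone` with elements `W1`, `b1`,
#'   `W2`, `b2`, `pool`, `feature_dim`, `n_params`, `seed`.
#' @export
build_tiny_backbone <- function(seed = 1, channels = c(12, 20), pool = c(8, 2)) {
  check_count(seed, "seed")
  stopifnot(length(channels) == 2, all(channels >= 1),
            length(pool) == 2, all(pool >= 1))
  withr::with_seed(seed, {
    c1 <- channels[1]; c2 <- channels[2]
    W1 <- array(rnorm(3 * 3 * 3 * c1, sd = sqrt(2 / (9 * 3))), c(3, 3, 3, c1))
    b1 <- rnorm(c1, sd = 0.01)
    W2 <- array(rnorm(3 * 3 * c1 * c2, sd = sqrt(2 / (9 * c1))), c(3, 3, c1, c2))
    b2 <- rnorm(c2, sd = 0.01)
    structure(
      list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, pool = as.integer(pool),
           feature_dim = 3L * c2 + 4L,
           n_params = length(W1) + length(b1) + length(W2) + length(b2),
           seed = as.integer(seed)),
      class = "tiny_backbone")
  })
}

#' @export
print.tiny_backbone <- function(x, ...) {
  cat(sprintf("<tiny_backbone> seed=%d, %d params, feature_dim=%d\n",
              x$seed, x$n_params, x$feature_dim))
  invisible(x)
}

# average pooling by integer factor (bottom/right remainder cropped)
avg_pool <- function(img, f) {
  if (f == 1) return(img)
  h <- (dim(img)[1] %/% f) * f
  w <- (dim(img)[2] %/% f) * f
  nc <- dim(img)[3]
  x <- img[seq_len(h), seq_len(w), , drop = FALSE]
  out <- array(0, dim = c(h %/% f, w %/% f, nc))
  for (ch in seq_len(nc)) {
    m <- x[, , ch]
    dim(m) <- c(f, h %/% f, w)
    m <- colMeans(m)                      # (h/f) x w
    m <- t(m); dim(m) <- c(f, w %/% f, h %/% f)
    out[, , ch] <- t(colMeans(m))
  }
  out
}

# 3x3 "same" convolution (zero padding) via im2col + one matrix product
conv3x3_same <- function(x, W, b) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]; cout <- dim(W)[4]
  pad <- array(0, dim = c(h + 2, w + 2, cin))
  pad[2:(h + 1), 2:(w + 1), ] <- x
  cols <- matrix(0, h * w, 9 * cin)
  k <- 0L
  for (ch in seq_len(cin)) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        k <- k + 1L
        cols[, k] <- as.vector(pad[dy + seq_len(h), dx + seq_len(w), ch])
      }
    }
  }
  # kernel laid out to match the (dy within dx within channel) column order
  Wm <- matrix(0, 9 * cin, cout)
  k <- 0L
  for (ch in seq_len(cin)) for (dx in 1:3) for (dy in 1:3) {
    k <- k + 1L
    Wm[k, ] <- W[dy, dx, ch, ]
  }
  z <- cols %*% Wm
  z <- sweep(z, 2, b, "+")
  array(z, dim = c(h, w, cout))
}

backbone_forward_one <- function(backbone, img) {
  check_image(img)
  x <- avg_pool(img, backbone$pool[1])
  a1 <- pmax(conv3x3_same(x, backbone$W1, backbone$b1), 0)
  a1 <- avg_pool(a1, backbone$pool[2])
  a2 <- pmax(conv3x3_same(a1, backbone$W2, backbone$b2), 0)
  c2 <- dim(a2)[3]
  flat <- matrix(a2, ncol = c2)
  col_sd <- function(m) {
    if (nrow(m) < 2L) return(numeric(ncol(m)))
    sqrt(pmax(colMeans(m^2) - colMeans(m)^2, 0))
  }
  c(colMeans(flat),
    col_sd(flat),
    apply(flat, 2, max),
    colMeans(matrix(x, ncol = 3)),
    sd(x))
}

#' Extract backbone features from images
#'
#' @param backbone A backbone object, e.g. from [build_tiny_backbone()].
#' @param images A single `height x width x 3` array or a list of them.
#' @return Numeric matrix `n_images x feature_dim`.
#' @export
backbone_features <- function(backbone, images) {
  UseMethod("backbone_features")
}

#' @export
backbone_features.tiny_backbone <- function(backbone, images) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  feats <- vapply(images, function(img) backbone_forward_one(backbone, img),
                  numeric(backbone$feature_dim))
  t(feats)
}
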
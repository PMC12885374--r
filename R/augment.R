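#' Draw a random augmentation parameter set
#'
#' Rotation ~ U(-5, 5) degrees, independent horizontal/vertical reflection
#' each with probability 0.5, shear angle ~ U(-0.05, 0.05) degrees on each
#' axis, output size 224 x 224.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A named list of augmentation parameters.
#' @export
draw_augmentation_params <- function(seed = NULL) {
  draw <- function() {
    list(rotation = runif(1, -5, 5),
         flip_h = runif(1) < 0.5,
         flip_v = runif(1) < 0.5,
         shear_x = runif(1, -0.05, 0.05),
         shear_y = runif(1, -0.05, 0.05),
         out_size = c(224L, 224L))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Inverse-mapped affine warp with bilinear interpolation; coordinates are
# measured from the image center and off-canvas samples are zero-filled.
# `A` maps output coordinates (x, y) to input coordinates.
affine_warp <- function(img, A, out_h, out_w) {
  h <- dim(img)[1]; w <- dim(img)[2]; ch <- dim(img)[3]
  cx_in <- (w + 1) / 2; cy_in <- (h + 1) / 2
  cx_out <- (out_w + 1) / 2; cy_out <- (out_h + 1) / 2
  xo <- rep(seq_len(out_w), each = out_h) - cx_out
  yo <- rep(seq_len(out_h), times = out_w) - cy_out
  xi <- A[1, 1] * xo + A[1, 2] * yo + cx_in
  yi <- A[2, 1] * xo + A[2, 2] * yo + cy_in
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  out <- array(0, c(out_h, out_w, ch))
  # gather the 4 neighbours, treating anything off-canvas as 0
  px <- function(xx, yy, band) {
    ok <- xx >= 1 & xx <= w & yy >= 1 & yy <= h
    v <- numeric(length(xx))
    idx <- which(ok)
    v[idx] <- band[cbind(yy[idx], xx[idx])]
    v
  }
  for (c in seq_len(ch)) {
    band <- img[, , c]
    v <- (1 - fx) * (1 - fy) * px(x0,     y0,     band) +
         fx       * (1 - fy) * px(x0 + 1, y0,     band) +
         (1 - fx) * fy       * px(x0,     y0 + 1, band) +
         fx       * fy       * px(x0 + 1, y0 + 1, band)
    out[, , c] <- matrix(v, out_h, out_w)
  }
  out
}

as_image_array <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (!is.array(img) || length(dim(img)) != 3L)
    stop_config("image must be a matrix or h x w x c array")
  if (any(dim(img)[1:2] < 2L)) stop_config("image spatial dimensions must be >= 2x2")
  img
}

#' Augment an image
#'
#' Applies, in order: rotation by a random angle in \[-5, 5\] degrees,
#' independent horizontal and vertical reflection each with probability 0.5,
#' a random shear of \[-0.05, 0.05\] degrees on each axis, and a resize to
#' 224 x 224. Grayscale inputs are replicated to 3 channels, so the output
#' is always 224 x 224 x 3. Values outside the original canvas are filled
#' with zeros; interpolation is bilinear.
#'
#' @param img numeric matrix (grayscale) or h x w x c array with values in
#'   any range (passed through linearly).
#' @param seed integer seed making the augmentation reproducible; ignored
#'   when `params` is supplied.
#' @param params optional parameter list from [draw_augmentation_params()],
#'   e.g. with rotation/shear forced to 0 for an identity transform.
#' @return A 224 x 224 x 3 numeric array (or `params$out_size` if overridden).
#' @export
augment_image <- function(img, seed = NULL, params = NULL) {
  img <- as_image_array(img)
  if (is.null(params)) params <- draw_augmentation_params(seed)
  th <- params$rotation * pi / 180
  sx <- tan(params$shear_x * pi / 180)
  sy <- tan(params$shear_y * pi / 180)
  h <- dim(img)[1]; w <- dim(img)[2]
  out_h <- params$out_size[1]; out_w <- params$out_size[2]
  # forward chain: rotate -> reflect -> shear -> resize; the warp uses the
  # inverse map from output pixels back to input pixels.
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Fl <- diag(c(if (params$flip_h) -1 else 1, if (params$flip_v) -1 else 1))
  Sh <- matrix(c(1, sy, sx, 1), 2, 2)
  Sc <- diag(c(out_w / w, out_h / h))
  fwd <- Sc %*% Sh %*% Fl %*% R
  out <- affine_warp(img, solve(fwd), out_h, out_w)
  if (dim(out)[3] == 1L) out <- array(rep(out, 3L), c(out_h, out_w, 3L))
  out
}

#' Read / write PNG images
#'
#' Thin wrappers over the `png` package returning/accepting h x w x c arrays
#' with values in \[0, 1\].
#' @param path file path.
#' @return `read_image`: an image array.
#' @export
read_image <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_config("the 'png' package is required for image file IO")
  as_image_array(png::readPNG(path))
}

#' @rdname read_image
#' @param img image array with values in \[0, 1\].
#' @export
write_image <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_config("the 'png' package is required for image file IO")
  png::writePNG(pmin(pmax(as_image_array(img), 0), 1), path)
  invisible(path)
}
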
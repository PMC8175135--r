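# Raster I/O and geometric preprocessing. Images are plain numeric matrices
# (rows = image rows) with intensities in [0, 1]; masks are integer matrices
# restricted to {0, 1, 2}: 0 background, 1 benign nodule, 2 malignant nodule.

#' Read a grayscale image as a [0, 1] numeric matrix
#'
#' 8-bit PNG files are read with the png package; other formats (e.g. JPEG)
#' go through EBImage. Multi-channel images are averaged to one channel.
#'
#' @param path image file path.
#' @return Numeric matrix with values in \code{[0, 1]}.
#' @export
load_gray <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
  } else {
    x <- t(EBImage::imageData(EBImage::readImage(path)))
  }
  if (length(dim(x)) == 3) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE],
                                      c(1, 2), mean)
  x
}

#' @rdname load_gray
#' @param image numeric matrix in \code{[0, 1]}.
#' @export
write_gray <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read or write a label mask PNG (literal byte values 0/1/2)
#'
#' @param path PNG file path.
#' @return \code{read_mask}: integer matrix with values in \{0, 1, 2\}.
#' @export
read_mask <- function(path) {
  m <- round(png::readPNG(path) * 255)
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "integer"
  check_mask(m)
  m
}

#' @rdname read_mask
#' @param mask integer matrix with values in \{0, 1, 2\}.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

check_mask <- function(mask) {
  bad <- setdiff(unique(as.integer(mask)), c(0L, 1L, 2L))
  if (length(bad))
    stop("mask convention violated: values outside {0,1,2} found (",
         paste(bad, collapse = ", "), ")")
  invisible(mask)
}

#' Center-crop an image or mask
#'
#' Returns the centered \code{target} x \code{target} window. When the
#' margin is odd, the extra pixel is dropped from the top/left (i.e. it
#' stays on the bottom/right side of the retained window).
#'
#' @param image matrix (image or mask).
#' @param target side length of the cropped window, in pixels.
#' @return Matrix of dimension \code{target} x \code{target}.
#' @export
center_crop <- function(image, target) {
  d <- dim(image)
  if (target > min(d))
    stop("crop target (", target, ") exceeds image side (", min(d), ")")
  r0 <- (d[1] - target) %/% 2
  c0 <- (d[2] - target) %/% 2
  image[r0 + seq_len(target), c0 + seq_len(target), drop = FALSE]
}

#' Collapse a three-valued mask to binary for segmentation training
#'
#' The segmentation network only separates nodule from background, so
#' malignant pixels (value 2) are folded into the nodule class: the result
#' is \code{min(mask, 1)} pixelwise. Idempotent; the input is not modified.
#'
#' @param mask integer matrix with values in \{0, 1, 2\}.
#' @return Integer matrix with values in \{0, 1\}.
#' @export
binarize_mask_for_segmentation <- function(mask) {
  check_mask(mask)
  out <- pmin(mask, 1L)
  storage.mode(out) <- "integer"
  out
}

#' Geometric augmentation configuration
#'
#' @param rotation_limit maximum absolute rotation, degrees, in
#'   \code{[0, 45]}.
#' @param shift_limit maximum absolute shift as a fraction of the image
#'   side, in \code{[0, 0.25]}.
#' @param horizontal_flip whether a random horizontal flip may be applied.
#' @param seed optional integer seed for the draw.
#' @return An object of class \code{augment_config}.
#' @export
augment_config <- function(rotation_limit = 15, shift_limit = 0.1,
                           horizontal_flip = TRUE, seed = NULL) {
  if (rotation_limit < 0 || rotation_limit > 45)
    stop("rotation_limit must lie in [0, 45] degrees")
  if (shift_limit < 0 || shift_limit > 0.25)
    stop("shift_limit must lie in [0, 0.25]")
  structure(list(rotation_limit = rotation_limit, shift_limit = shift_limit,
                 horizontal_flip = isTRUE(horizontal_flip), seed = seed),
            class = "augment_config")
}

#' Apply one random geometric augmentation to an image/mask pair
#'
#' Draws a rotation angle, a 2-D shift and (optionally) a horizontal flip,
#' and applies the identical transform to image and mask. The image is
#' resampled bilinearly; the mask with nearest-neighbor so label values stay
#' in \{0, 1, 2\}. Regions shifted or rotated in from outside are filled
#' with 0 for both rasters. Deterministic for a fixed \code{cfg$seed}.
#'
#' @param image numeric matrix.
#' @param mask integer matrix in \{0, 1, 2\}, same shape as \code{image}.
#' @param cfg an [augment_config()].
#' @return List with transformed \code{image} and \code{mask}.
#' @export
augment_pair <- function(image, mask, cfg) {
  stopifnot(inherits(cfg, "augment_config"))
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  angle <- stats::runif(1, -cfg$rotation_limit, cfg$rotation_limit)
  shift <- stats::runif(2, -cfg$shift_limit, cfg$shift_limit) * dim(image)
  flip <- cfg$horizontal_flip && stats::runif(1) < 0.5

  if (flip) {
    image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (abs(angle) > 1e-12 || any(abs(shift) > 1e-12)) {
    m <- affine_about_center(dim(image), angle * pi / 180, shift)
    image <- as.matrix(EBImage::affine(image, m, filter = "bilinear",
                                       output.dim = dim(image), bg.col = 0))
    mask <- as.matrix(EBImage::affine(mask, m, filter = "none",
                                      output.dim = dim(mask), bg.col = 0))
    storage.mode(mask) <- "integer"
  }
  check_mask(mask)
  list(image = image, mask = mask)
}

# 3x2 affine matrix: rotation about the image center composed with a shift.
affine_about_center <- function(d, angle, shift) {
  ctr <- (d + 1) / 2
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2,
              byrow = TRUE)
  off <- ctr - as.numeric(R %*% ctr) + shift
  rbind(t(R), off)
}
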
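#' Specification for a synthetic CT phantom
#'
#' Describes one synthetic CT-like slice: a low-contrast soft-tissue
#' background carrying a configurable number of non-overlapping nodules.
#' Benign nodules are smooth, near-convex ellipses; malignant nodules have
#' spiculated (radially perturbed) margins. Morphology is the class signal:
#' the two classes differ in boundary shape, not gray level, mirroring how
#' benign and malignant nodules present in enhanced CT.
#'
#' @param image_size pixels per side of the square image (>= 64).
#' @param n_nodules number of nodules per image; either a single integer
#'   >= 0 or a length-2 range \code{c(lo, hi)} from which the count is drawn
#'   uniformly per image.
#' @param benign_fraction probability in \code{[0, 1]} that a nodule is
#'   benign.
#' @param nodule_radius_range length-2 vector, minimum and maximum base
#'   radius in pixels; the minimum must be >= 3 and the maximum <=
#'   \code{image_size / 4}.
#' @param spiculation_amplitude boundary modulation amplitude for malignant
#'   nodules, as a fraction of the local radius, in \code{[0, 1]}. Benign
#'   boundaries use a fixed small amplitude (0.03).
#' @param background_noise_sigma standard deviation of the per-pixel
#'   background noise, in intensity units on the \code{[0, 1]} scale.
#' @param nodule_contrast mean intensity offset of nodule interiors above
#'   the local background, on the \code{[0, 1]} scale.
#' @param seed integer seed making generation fully deterministic; NULL
#'   leaves the RNG state alone.
#' @return An object of class \code{phantom_spec}.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(image_size = 256L, n_nodules = 2L,
                         benign_fraction = 0.5,
                         nodule_radius_range = c(8, 24),
                         spiculation_amplitude = 0.4,
                         background_noise_sigma = 0.02,
                         nodule_contrast = 0.35, seed = NULL) {
  image_size <- as.integer(image_size)
  if (image_size < 64L) stop("image_size must be >= 64")
  if (!length(n_nodules) %in% 1:2 || any(n_nodules < 0))
    stop("n_nodules must be a count >= 0 or a range c(lo, hi)")
  if (benign_fraction < 0 || benign_fraction > 1)
    stop("benign_fraction must lie in [0, 1]")
  if (length(nodule_radius_range) != 2 ||
      nodule_radius_range[1] < 3 ||
      nodule_radius_range[2] > image_size / 4 ||
      nodule_radius_range[1] > nodule_radius_range[2])
    stop("nodule_radius_range must satisfy 3 <= min <= max <= image_size/4")
  if (spiculation_amplitude < 0 || spiculation_amplitude > 1)
    stop("spiculation_amplitude must lie in [0, 1]")
  structure(list(image_size = image_size, n_nodules = n_nodules,
                 benign_fraction = benign_fraction,
                 nodule_radius_range = nodule_radius_range,
                 spiculation_amplitude = spiculation_amplitude,
                 background_noise_sigma = background_noise_sigma,
                 nodule_contrast = nodule_contrast, seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("CT phantom spec:", x$image_size, "x", x$image_size, "px,",
      paste(x$n_nodules, collapse = "-"), "nodule(s), benign fraction",
      x$benign_fraction, "\n")
  cat("  radius", x$nodule_radius_range[1], "-", x$nodule_radius_range[2],
      "px, spiculation", x$spiculation_amplitude, ", contrast",
      x$nodule_contrast, "\n")
  invisible(x)
}

# Radial boundary-modulation profile: a random harmonic series whose lobe
# orders are drawn from 5..12, rescaled so max |f| = 1. Star-convex by
# construction, so the rasterized region is always one connected component.
radial_profile <- function() {
  orders <- sample(5:12, 2L)
  w <- stats::runif(2, 0.3, 1)
  phases <- stats::runif(2, 0, 2 * pi)
  theta <- seq(0, 2 * pi, length.out = 721L)
  f <- w[1] * cos(orders[1] * theta + phases[1]) +
    w[2] * cos(orders[2] * theta + phases[2])
  list(orders = orders, w = w / max(abs(f)), phases = phases)
}

eval_profile <- function(prof, theta) {
  prof$w[1] * cos(prof$orders[1] * theta + prof$phases[1]) +
    prof$w[2] * cos(prof$orders[2] * theta + prof$phases[2])
}

#' Generate one synthetic CT phantom image/mask pair
#'
#' Produces a grayscale image with intensities in \code{[0, 1]} and a label
#' mask in the 0/1/2 convention (0 background, 1 benign nodule, 2 malignant
#' nodule). Nodule centers are rejection-sampled until all nodules are
#' pairwise disjoint; if that fails within the retry budget an error is
#' raised. Fully deterministic for a fixed \code{spec$seed}.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements \code{image} (numeric matrix), \code{mask}
#'   (integer matrix in \{0,1,2\}) and \code{nodules} (per-nodule metadata:
#'   label, center, base radius, bounding box, area).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  s <- spec$image_size
  n <- if (length(spec$n_nodules) == 2)
    sample(spec$n_nodules[1]:spec$n_nodules[2], 1L) else spec$n_nodules

  # soft-tissue background: base level + low-frequency gradient + smoothed
  # structural noise + fine per-pixel noise
  gx <- matrix(rep(seq(-1, 1, length.out = s), each = s), s, s)
  grad <- stats::runif(1, -0.06, 0.06) * gx +
    stats::runif(1, -0.06, 0.06) * t(gx)
  coarse <- matrix(stats::rnorm(s * s), s, s)
  coarse <- EBImage::gblur(coarse, sigma = max(4, s / 16))
  coarse <- coarse / max(stats::sd(coarse), 1e-8) * 0.03
  image <- 0.32 + grad + coarse +
    matrix(stats::rnorm(s * s, sd = spec$background_noise_sigma), s, s)
  mask <- matrix(0L, s, s)

  nodules <- list()
  placed <- list()  # center + effective radius for overlap rejection
  for (i in seq_len(n)) {
    benign <- stats::runif(1) < spec$benign_fraction
    amp <- if (benign) 0.03 else spec$spiculation_amplitude
    ok <- FALSE
    # radius and center are rejection-sampled together: crowded layouts
    # resolve by drawing a smaller nodule instead of failing outright
    for (try in seq_len(200L)) {
      r <- stats::runif(1, spec$nodule_radius_range[1],
                        spec$nodule_radius_range[2])
      reff <- r * (1 + amp) + 2
      cy <- stats::runif(1, reff + 2, s - reff - 1)
      cx <- stats::runif(1, reff + 2, s - reff - 1)
      sep <- vapply(placed, function(p)
        sqrt((p$cy - cy)^2 + (p$cx - cx)^2) > p$reff + reff + 2, TRUE)
      if (all(sep)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("phantom placement: could not place ", n, " disjoint nodules ",
           "of radius <= ", spec$nodule_radius_range[2], " in a ", s, "x",
           s, " image within the retry budget")
    placed[[i]] <- list(cy = cy, cx = cx, reff = reff)

    q <- stats::runif(1, 0.65, 0.95)          # ellipse axis ratio
    phi <- stats::runif(1, 0, 2 * pi)         # orientation
    prof <- radial_profile()

    R <- ceiling(reff)
    rows <- max(1, floor(cy) - R):min(s, ceiling(cy) + R)
    cols <- max(1, floor(cx) - R):min(s, ceiling(cx) + R)
    dy <- outer(rows - cy, rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - cx)
    theta <- atan2(dy, dx)
    psi <- theta - phi
    a <- r; b <- r * q
    ell <- a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
    rad <- ell * (1 + amp * eval_profile(prof, theta))
    inside <- sqrt(dy^2 + dx^2) <= rad

    sub <- mask[rows, cols]
    sub[inside] <- if (benign) 1L else 2L
    mask[rows, cols] <- sub
    isub <- image[rows, cols]
    isub[inside] <- isub[inside] + spec$nodule_contrast +
      stats::rnorm(sum(inside), sd = 0.02)
    image[rows, cols] <- isub

    idx <- which(inside, arr.ind = TRUE)
    rr <- range(rows[idx[, 1]]); cc <- range(cols[idx[, 2]])
    nodules[[i]] <- list(
      label = if (benign) "benign" else "malignant",
      center = c(row = cy, col = cx), radius = r, area = sum(inside),
      bbox = c(row_min = rr[1] - 1L, col_min = cc[1] - 1L,
               row_max = rr[2], col_max = cc[2]))  # 0-based, half-open
  }
  image <- pmin(pmax(image, 0), 1)
  list(image = image, mask = mask, nodules = nodules)
}

#' Generate a phantom dataset on disk
#'
#' Writes \code{n_images} image/mask PNG pairs under \code{out_dir}
#' (\code{images/NNNN.png}, \code{masks/NNNN.png}) plus a
#' \code{manifest.json} describing every image (per-image seed, nodule
#' count, per-nodule labels and geometry). Per-image seeds are derived
#' deterministically from \code{spec$seed}, so two runs with the same spec
#' produce identical files and manifests.
#'
#' @param n_images number of image/mask pairs to generate (>= 1).
#' @param spec a [phantom_spec()]; its \code{seed} (default 1 when NULL)
#'   seeds the whole dataset.
#' @param out_dir output directory, created if missing.
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
generate_dataset <- function(n_images, spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"), n_images >= 1)
  base_seed <- if (is.null(spec$seed)) 1L else as.integer(spec$seed)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  entries <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- spec
    sp$seed <- (base_seed + 104729L * i) %% 2147483647L
    ph <- generate_phantom(sp)
    img_rel <- sprintf("images/%04d.png", i)
    msk_rel <- sprintf("masks/%04d.png", i)
    write_gray(ph$image, file.path(out_dir, img_rel))
    write_mask(ph$mask, file.path(out_dir, msk_rel))
    entries[[i]] <- list(id = i, image = img_rel, mask = msk_rel,
                         seed = sp$seed, n_nodules = length(ph$nodules),
                         nodules = ph$nodules)
  }
  manifest <- list(n_images = n_images,
                   image_size = spec$image_size,
                   benign_fraction = spec$benign_fraction,
                   spiculation_amplitude = spec$spiculation_amplitude,
                   base_seed = base_seed,
                   images = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a phantom dataset written by [generate_dataset()]
#'
#' @param dir dataset directory containing \code{manifest.json}.
#' @return A list of records, each with \code{image}, \code{mask} and the
#'   manifest entry (\code{meta}).
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  lapply(manifest$images, function(e)
    list(image = load_gray(file.path(dir, e$image)),
         mask = read_mask(file.path(dir, e$mask)),
         meta = e))
}
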
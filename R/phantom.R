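# Seeded synthetic phantoms: K-class images made of star-convex blobs whose
# radius varies smoothly with angle (truncated Fourier perturbation of an
# ellipse), one mean intensity per class plus Gaussian noise. Star-convexity
# guarantees every blob has a closed boundary, so the Hausdorff distance is
# well defined for every class in every image.

#' Phantom dataset specification
#'
#' @param n_images number of images.
#' @param image_size square image edge in pixels.
#' @param n_classes number of classes K including background; each image
#'   contains K-1 non-overlapping blobs.
#' @param radius_range interval (pixels) the blob semi-axes are drawn from.
#' @param boundary_roughness amplitude of the angular Fourier perturbation of
#'   the blob radius (0 gives exact ellipses).
#' @param class_means per-class mean intensities in `[0, 1]`, background
#'   first; must be pairwise distinct.
#' @param noise_sigma standard deviation of the additive Gaussian pixel
#'   noise (intensity units).
#' @param seed integer seed; per-image substreams are derived by counter so
#'   image i does not depend on `n_images`.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(n_images = 8L, image_size = 64L, n_classes = 4L,
                         radius_range = c(0.10, 0.20) * image_size,
                         boundary_roughness = 0.08,
                         class_means = seq(0.1, 0.9,
                                           length.out = n_classes),
                         noise_sigma = 0.04, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2 (background + 1)")
  if (length(class_means) != n_classes) {
    stop("class_means must have one entry per class")
  }
  if (anyDuplicated(class_means)) stop("class_means must be pairwise distinct")
  if (any(class_means < 0 | class_means > 1)) {
    stop("class_means must lie in [0, 1]")
  }
  if (boundary_roughness < 0) stop("boundary_roughness must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (max(radius_range) * 2.6 > image_size) {
    stop("radii too large for the image; blobs must fit inside")
  }
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 n_classes = n_classes,
                 radius_range = as.numeric(radius_range),
                 boundary_roughness = boundary_roughness,
                 class_means = as.numeric(class_means),
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

image_substream_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 7919) %% 2147483647
}

# rasterise one star-convex blob; returns a logical mask
blob_mask <- function(size, cx, cy, a, b, phi, four_a, four_b) {
  xs <- matrix(rep(seq_len(size), each = size), size)   # col index
  ys <- matrix(rep(seq_len(size), times = size), size)  # row index
  dx <- xs - cx; dy <- ys - cy
  xr <- cos(phi) * dx + sin(phi) * dy
  yr <- -sin(phi) * dx + cos(phi) * dy
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  theta <- atan2(yr, xr)
  pert <- rep(0, length(theta))
  for (m in seq_along(four_a)) {
    pert <- pert + four_a[m] * cos((m + 1L) * theta) +
      four_b[m] * sin((m + 1L) * theta)
  }
  rshape <- pmax(1 + pert, 0.25)
  matrix(rho <= rshape, size, size)
}

#' Generate a phantom dataset
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_dataset`: list of `n_images` elements, each a list with
#'   `image` (numeric matrix in `[0, 1]`, quantised to the 16-bit grid) and
#'   `mask` (integer matrix of class labels, 0 = background); the spec is
#'   attached as attribute `spec`.
#' @export
generate_phantoms <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  size <- spec$image_size
  K <- spec$n_classes
  out <- vector("list", spec$n_images)
  for (i in seq_len(spec$n_images)) {
    out[[i]] <- with_seed(image_substream_seed(spec$seed, i), function() {
      mask <- matrix(0L, size, size)
      margin_scale <- 1 + 3 * spec$boundary_roughness
      for (k in seq_len(K - 1L)) {
        placed <- FALSE
        max_tries <- 100L
        for (try in seq_len(max_tries)) {
          # progressively shrink the sampled radii so crowded images still
          # admit a non-overlapping placement
          shrink <- 0.985^(try - 1L)
          a <- max(3, shrink * stats::runif(1, spec$radius_range[1],
                                            spec$radius_range[2]))
          b <- max(3, shrink * stats::runif(1, spec$radius_range[1],
                                            spec$radius_range[2]))
          margin <- max(a, b) * margin_scale + 1
          if (2 * margin >= size) next
          cx <- stats::runif(1, margin, size - margin)
          cy <- stats::runif(1, margin, size - margin)
          phi <- stats::runif(1, 0, pi)
          nf <- 4L
          four_a <- stats::rnorm(nf) * spec$boundary_roughness / (1 + seq_len(nf) / 2)
          four_b <- stats::rnorm(nf) * spec$boundary_roughness / (1 + seq_len(nf) / 2)
          bm <- blob_mask(size, cx, cy, a, b, phi, four_a, four_b)
          if (!any(bm & mask > 0L)) {
            mask[bm] <- k
            placed <- TRUE
            break
          }
          if (try == max_tries) {
            # z-order fallback: keep only pixels not already claimed
            free <- bm & mask == 0L
            if (sum(free) > 0.3 * sum(bm)) {
              mask[free] <- k
              placed <- TRUE
            }
          }
        }
        if (!placed) {
          stop("could not place blob for class ", k,
               " after bounded retries; use smaller radii")
        }
      }
      img <- matrix(spec$class_means[mask + 1L], size, size)
      if (spec$noise_sigma > 0) {
        img <- img + stats::rnorm(size * size, sd = spec$noise_sigma)
      }
      img <- pmin(pmax(img, 0), 1)
      img <- round(img * 65535) / 65535   # 16-bit grid, exact file round-trip
      list(image = img, mask = mask)
    })
  }
  attr(out, "spec") <- spec
  class(out) <- "phantom_dataset"
  out
}

#' Write a phantom dataset to disk
#'
#' Images are stored as 16-bit grayscale TIFF, masks as 8-bit grayscale PNG
#' whose pixel value is the class label, plus a JSON manifest carrying the
#' generating specification. The round trip [read_dataset()] is pixel-exact.
#'
#' @param dataset a `phantom_dataset`.
#' @param dir target directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- attr(dataset, "spec")
  files <- lapply(seq_along(dataset), function(i) {
    img_f <- sprintf("img_%03d.tif", i)
    msk_f <- sprintf("msk_%03d.png", i)
    tiff::writeTIFF(dataset[[i]]$image, file.path(dir, img_f),
                    bits.per.sample = 16L, compression = "none")
    png::writePNG(dataset[[i]]$mask / 255, file.path(dir, msk_f))
    list(image = img_f, mask = msk_f)
  })
  manifest <- list(format = "mipcnet-phantoms-v1",
                   spec = unclass(spec), files = files)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a phantom dataset from disk
#'
#' @param dir directory written by [write_dataset()].
#' @return a `phantom_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("missing manifest.json in ", dir)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(manifest$format, "mipcnet-phantoms-v1")) {
    stop("unrecognised or corrupt manifest in ", dir)
  }
  sp <- manifest$spec
  spec <- phantom_spec(n_images = sp$n_images, image_size = sp$image_size,
                       n_classes = sp$n_classes,
                       radius_range = sp$radius_range,
                       boundary_roughness = sp$boundary_roughness,
                       class_means = sp$class_means,
                       noise_sigma = sp$noise_sigma, seed = sp$seed)
  files <- manifest$files
  out <- lapply(seq_len(nrow(files)), function(i) {
    img <- tiff::readTIFF(file.path(dir, files$image[i]))
    msk <- png::readPNG(file.path(dir, files$mask[i]))
    list(image = img, mask = matrix(as.integer(round(msk * 255)),
                                    nrow(msk), ncol(msk)))
  })
  attr(out, "spec") <- spec
  class(out) <- "phantom_dataset"
  out
}

#' Stack a phantom dataset into model input arrays
#'
#' @param dataset a `phantom_dataset` (or any list of `image`/`mask` pairs).
#' @param indices which images to stack (default all).
#' @return list with `images` `(n, 1, size, size)` and `labels`
#'   `(n, size, size)` arrays.
#' @export
dataset_tensors <- function(dataset, indices = seq_along(dataset)) {
  size <- dim(dataset[[indices[1]]]$image)
  n <- length(indices)
  images <- array(0, c(n, 1L, size[1], size[2]))
  labels <- array(0L, c(n, size[1], size[2]))
  for (j in seq_along(indices)) {
    images[j, 1L, , ] <- dataset[[indices[j]]]$image
    labels[j, , ] <- dataset[[indices[j]]]$mask
  }
  list(images = images, labels = labels)
}
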
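# Stain handling: Reinhard mean/std color transfer in the l-alpha-beta opponent
# space, principal-component stain augmentation, and PCA-based two-stain
# decomposition of CD45 immunohistochemistry.

# RGB <-> l-alpha-beta. The forward chain is RGB -> LMS cone response (linear),
# log10, then the opponent rotation with the 1/sqrt(3,6,2) scaling.
.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)   # exact inverse so the round trip is lossless
.lab_rot <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.lab_rot_inv <- t(matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)) %*%
  diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2)))

#' Convert between RGB and the perceptual opponent color space
#'
#' The working space of the Reinhard color-transfer method: a log-LMS opponent
#' space with decorrelated lightness and two chromatic axes. Inputs are n x 3
#' matrices of RGB values in \[0,1\]; LMS responses are clamped away from zero
#' before the log.
#'
#' @param rgb,lab n x 3 numeric matrices.
#' @return n x 3 matrix in the other space.
#' @export
rgb_to_lab <- function(rgb) {
  lms <- pmax(rgb %*% t(.rgb2lms), 1e-6)
  log10(lms) %*% t(.lab_rot)
}

#' @rdname rgb_to_lab
#' @export
lab_to_rgb <- function(lab) {
  lms <- 10^(lab %*% t(.lab_rot_inv))
  rgb <- lms %*% t(.lms2rgb)
  pmin(pmax(rgb, 0), 1)
}

flatten_rgb <- function(image) {
  d <- dim(image)
  matrix(image, d[1] * d[2], 3)
}

#' Per-channel color statistics in the Reinhard working space
#'
#' @param image H x W x 3 RGB array in \[0,1\].
#' @param mask Optional logical H x W matrix restricting the statistics to
#'   selected (e.g. foreground) pixels.
#' @return Object of class `stain_stats`: list with `mean` and `sd`, each a
#'   3-vector over the working-space channels. `sd` uses the n-1 denominator
#'   and is 0 for a single-pixel selection.
#' @export
color_stats <- function(image, mask = NULL) {
  px <- flatten_rgb(image)
  if (!is.null(mask)) {
    if (!any(mask)) stop("mask selects no pixels")
    px <- px[as.vector(mask), , drop = FALSE]
  }
  lab <- rgb_to_lab(px)
  s <- if (nrow(lab) > 1L) apply(lab, 2, sd) else c(0, 0, 0)
  structure(list(mean = colMeans(lab), sd = s), class = "stain_stats")
}

#' Reinhard stain normalization
#'
#' Shifts and scales each working-space channel so that the image's color
#' statistics match a target: `lab' = (lab - mean_src) * sd_tgt / sd_src +
#' mean_tgt`. Channels whose source standard deviation is below `1e-6` are
#' shifted only (scale factor 1), which keeps near-constant tiles stable.
#' Output is converted back to RGB and clipped to \[0,1\].
#'
#' @param image H x W x 3 RGB array.
#' @param source Statistics of the image (or its slide), from [color_stats()].
#' @param target Statistics to normalize to.
#' @return Normalized H x W x 3 RGB array.
#' @export
reinhard_normalize <- function(image, source, target) {
  d <- dim(image)
  lab <- rgb_to_lab(flatten_rgb(image))
  scale <- ifelse(source$sd < 1e-6, 1, target$sd / pmax(source$sd, 1e-12))
  lab <- sweep(lab, 2, source$mean)
  lab <- sweep(lab, 2, scale, `*`)
  lab <- sweep(lab, 2, target$mean, `+`)
  array(lab_to_rgb(lab), d)
}

#' Principal color components of an RGB pixel population
#'
#' Fits the principal axes of the RGB scatter, used both for stain
#' augmentation (shifting images along the dominant color-variation
#' directions) and as a diagnostic of staining variability. Degenerate inputs
#' (fewer than 3 distinct directions of variance) are completed to a full
#' orthonormal basis with zero explained variance on the padded axes.
#'
#' @param pixels n x 3 matrix of RGB values (or an H x W x 3 array).
#' @return Object of class `stain_basis`: `components` (orthonormal 3 x 3,
#'   columns = axes, descending variance), `origin` (mean RGB) and
#'   `explained_variance` (3-vector, descending).
#' @export
stain_basis <- function(pixels) {
  if (length(dim(pixels)) == 3L) pixels <- flatten_rgb(pixels)
  stopifnot(ncol(pixels) == 3L, nrow(pixels) >= 1L)
  origin <- colMeans(pixels)
  ctr <- sweep(pixels, 2, origin)
  cv <- crossprod(ctr) / max(1L, nrow(pixels) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  comps <- eg$vectors
  ev <- pmax(eg$values, 0)
  structure(list(components = comps, origin = origin, explained_variance = ev),
            class = "stain_basis")
}

#' Apply a random stain shift along the principal color components
#'
#' Draws one shift `u_k ~ Uniform(-m_k, m_k)` per component, expressed in
#' standard deviations of the fitted basis, and adds
#' `sum_k u_k * sd_k * component_k` to every pixel. With all magnitudes zero
#' the image is returned unchanged; the same seed always reproduces the same
#' shift.
#'
#' @param image H x W x 3 RGB array.
#' @param basis A [stain_basis()].
#' @param magnitudes Non-negative 3-vector of augmentation magnitudes (in
#'   basis standard deviations).
#' @param seed Integer seed.
#' @return Augmented H x W x 3 RGB array, clipped to \[0,1\].
#' @export
augment_stain <- function(image, basis, magnitudes, seed) {
  stopifnot(all(magnitudes >= 0), length(magnitudes) == 3L)
  set.seed(seed)
  u <- runif(3, -magnitudes, magnitudes)
  delta <- as.vector(basis$components %*% (u * sqrt(basis$explained_variance)))
  out <- image
  for (ch in 1:3) out[, , ch] <- out[, , ch] + delta[ch]
  pmin(pmax(out, 0), 1)
}

# Optical density of RGB intensities in [0,1]; the +1/256 guard mirrors the
# common 8-bit convention and keeps OD finite at zero intensity.
optical_density <- function(px) -log((px * 255 + 1) / 256)

#' Decompose a CD45 immunostain into counterstain and positive channels
#'
#' Works in optical density (OD), where stain contributions add
#' (Beer–Lambert). The two leading principal components of the uncentered OD
#' scatter span the stain plane: the first axis carries the dominant stain
#' density, the second the contrast between the two stains. Each pixel's OD
#' is projected onto both axes and rectified at zero, giving two
#' non-negative stain-density maps. Channel assignment is by blue
#' transmission: hematoxylin looks blue, i.e. its OD vector has a *small*
#' blue share (it absorbs red/green), so the axis whose unit OD vector has a
#' blue share below 1/3 is reported as the counterstain and the other
#' (diaminobenzidine brown, which absorbs blue) as the positive channel.
#' Axis signs are fixed so that the first axis has a non-negative mean
#' projection and the second points towards the stain it represents, making
#' the decomposition deterministic.
#'
#' @param image H x W x 3 RGB array.
#' @return List with `counterstain` and `positive` (H x W matrices, >= 0) and
#'   `stain_vectors` (3 x 2 unit OD axis vectors, columns counterstain,
#'   positive).
#' @export
destain_cd45 <- function(image) {
  d <- dim(image)
  od <- optical_density(flatten_rgb(image))
  eg <- eigen(crossprod(od) / nrow(od), symmetric = TRUE)
  v1 <- eg$vectors[, 1]; v2 <- eg$vectors[, 2]
  if (mean(od %*% v1) < 0) v1 <- -v1
  blue_share <- function(v) v[3] / sum(abs(v))
  h <- d[1]; w <- d[2]
  rect <- function(v) matrix(pmax(od %*% v, 0), h, w)
  if (blue_share(v1) < 1 / 3) {
    # first axis transmits blue: hematoxylin counterstain; orient the second
    # axis towards the blue-absorbing (DAB) direction
    if (v2[3] < v2[1]) v2 <- -v2
    list(counterstain = rect(v1), positive = rect(v2),
         stain_vectors = cbind(v1, v2))
  } else {
    if (v2[1] < v2[3]) v2 <- -v2
    list(counterstain = rect(v2), positive = rect(v1),
         stain_vectors = cbind(v2, v1))
  }
}
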
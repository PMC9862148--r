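#' Slice a mask along an anatomical axis
#'
#' Exports the mask as an ordered stack of 2D binary slices along the
#' requested axis (sagittal, coronal or axial), keeping only slices with at
#' least one nonzero pixel, in anatomical order.
#'
#' @param volume A [mask_volume()].
#' @param axis `"sagittal"`, `"coronal"` or `"axial"`.
#' @return List of 2D 0/1 matrices with attribute `n_slices`.
#' @export
slice_mask <- function(volume, axis) {
  stopifnot(inherits(volume, "mask_volume"))
  axis <- match.arg(axis, c("sagittal", "coronal", "axial"))
  d <- volume$axes[[axis]]
  vox <- volume$voxels
  if (sum(vox) == 0) ts_abort("mask has no nonzero voxel", "empty_mask")
  idx <- seq_len(dim(vox)[d])
  slices <- lapply(idx, function(i) {
    switch(d,
           vox[i, , , drop = TRUE],
           vox[, i, , drop = TRUE],
           vox[, , i, drop = TRUE])
  })
  keep <- vapply(slices, function(s) any(s != 0), logical(1))
  out <- slices[keep]
  attr(out, "n_slices") <- sum(keep)
  attr(out, "axis") <- axis
  out
}

#' Build an alpha-standardized luminosity composite
#'
#' Layers a stack of binary slices into one grayscale image: each pixel's
#' luminosity is `min(255, round(255 * c / alpha_ref))`, where `c` is the
#' number of slices in which the pixel is foreground and `alpha_ref` is the
#' reference slice count shared across subjects for one (ROI, axis) — so
#' brighter pixels were present in more slices and luminosities are
#' comparable between subjects. `alpha_ref` must be at least the stack size,
#' otherwise the scaling would saturate asymmetrically.
#'
#' @param stack List of 2D 0/1 matrices (from [slice_mask()]).
#' @param alpha_ref Reference slice count (>= `length(stack)`).
#' @return A `composite_image`: list with `pixels` (2D integer matrix in
#'   `[0, 255]`), `n_slices_used`, `alpha_ref`, `axis`.
#' @export
build_composite <- function(stack, alpha_ref) {
  if (length(stack) == 0L) ts_abort("empty slice stack", "empty_mask")
  alpha_ref <- assert_count(alpha_ref, "alpha_ref", min = 1L)
  if (alpha_ref < length(stack)) {
    ts_abort(sprintf(
      "alpha_ref (%d) below stack size (%d): standardization would saturate",
      alpha_ref, length(stack)), "standardization_error")
  }
  counts <- Reduce(`+`, stack)
  pixels <- pmin(255L, as.integer(round(255 * counts / alpha_ref)))
  pixels <- matrix(pixels, nrow(counts), ncol(counts))
  structure(list(pixels = pixels, n_slices_used = length(stack),
                 alpha_ref = alpha_ref,
                 axis = attr(stack, "axis") %||% NA_character_),
            class = "composite_image")
}

#' Shared alpha reference for one (ROI, axis)
#'
#' The maximum nonzero slice count over all subjects' masks for a given ROI
#' and axis — the standardization constant that makes composite luminosities
#' comparable between subjects.
#'
#' @param masks List of [mask_volume()]s (one per subject, same ROI).
#' @param axis Anatomical axis.
#' @return Integer.
#' @export
alpha_reference <- function(masks, axis) {
  max(vapply(masks, function(m) attr(slice_mask(m, axis), "n_slices"),
             integer(1)))
}

#' Extract the luminosity distribution of a composite
#'
#' Returns the multiset of pixel luminosities passing the background rule.
#' The default `exclude_zero` drops zero-luminosity pixels (background —
#' pixels absent from every slice); `include_zero` keeps the full image.
#'
#' @param image A `composite_image`.
#' @param background_rule `"exclude_zero"` (default) or `"include_zero"`.
#' @return A `luminosity_distribution`: list with `values`,
#'   `background_rule`, `axis`.
#' @export
extract_distribution <- function(image, background_rule = "exclude_zero") {
  stopifnot(inherits(image, "composite_image"))
  background_rule <- match.arg(background_rule,
                               c("exclude_zero", "include_zero"))
  v <- as.vector(image$pixels)
  if (background_rule == "exclude_zero") v <- v[v > 0]
  if (length(v) == 0L) {
    ts_abort("no foreground pixels in composite", "empty_distribution")
  }
  structure(list(values = v, background_rule = background_rule,
                 axis = image$axis),
            class = "luminosity_distribution")
}

#' Quantile-quantile comparison of two luminosity distributions
#'
#' Matches quantiles of the two distributions at levels `k / (n + 1)`,
#' `k = 1..n`, using linear interpolation between order statistics
#' (`stats::quantile` type 7). The divergence score is the mean absolute
#' quantile difference normalized by the 255 luminosity range — 0 exactly
#' when the matched quantiles coincide everywhere; it is a scalar summary of
#' the visual Q-Q readout, symmetric in its arguments.
#'
#' @param dA,dB `luminosity_distribution`s (x and y of the plot).
#' @param n_quantiles Number of quantile levels (default 99).
#' @param labels Length-2 character labels for the two distributions.
#' @return A `qq_curve`: list with `probs`, `qx`, `qy`, `labels`,
#'   `divergence`.
#' @export
qq_compare <- function(dA, dB, n_quantiles = 99L,
                       labels = c("x", "y")) {
  stopifnot(inherits(dA, "luminosity_distribution"),
            inherits(dB, "luminosity_distribution"))
  n_quantiles <- assert_count(n_quantiles, "n_quantiles", min = 1L)
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  qx <- stats::quantile(dA$values, probs, type = 7, names = FALSE)
  qy <- stats::quantile(dB$values, probs, type = 7, names = FALSE)
  structure(list(probs = probs, qx = qx, qy = qy, labels = labels,
                 divergence = mean(abs(qx - qy)) / 255),
            class = "qq_curve")
}

#' @export
print.qq_curve <- function(x, ...) {
  cat(sprintf("<qq_curve> %s vs %s: divergence %.4f (%d levels)\n",
              x$labels[1], x$labels[2], x$divergence, length(x$probs)))
  invisible(x)
}

#' Most similar sibling pair from three labeled Q-Q curves
#'
#' Picks the pair with minimal divergence among the three inter-subject
#' curves of one ROI. Ties are broken toward the `twin-twin` pair (the
#' declared within-family baseline) and flagged; the margin to the runner-up
#' is reported.
#'
#' @param curves Named list of three `qq_curve`s, names = pair labels.
#' @return List with `label`, `divergence`, `margin`, `tie`.
#' @export
most_similar_pair <- function(curves) {
  if (length(curves) != 3L || is.null(names(curves)) ||
      anyDuplicated(names(curves))) {
    ts_abort("need exactly 3 curves with distinct labels", "argument_error")
  }
  div <- vapply(curves, function(cv) cv$divergence, numeric(1))
  m <- min(div)
  winners <- names(div)[div == m]
  tie <- length(winners) > 1L
  label <- if (tie && "twin-twin" %in% winners) "twin-twin" else winners[1]
  margin <- if (length(div) > 1L) unname(sort(div)[2] - m) else NA_real_
  list(label = label, divergence = m, margin = margin, tie = tie)
}

#' Write a composite as an 8-bit grayscale PNG
#'
#' Deterministic: identical composites produce byte-identical files.
#'
#' @param image A `composite_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composite_png <- function(image, path) {
  stopifnot(inherits(image, "composite_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' @rdname write_composite_png
#' @param alpha_ref,axis Metadata to attach on read.
#' @export
read_composite_png <- function(path, alpha_ref = NA_integer_,
                               axis = NA_character_) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  structure(list(pixels = matrix(as.integer(round(m * 255)),
                                 nrow(m), ncol(m)),
                 n_slices_used = NA_integer_, alpha_ref = alpha_ref,
                 axis = axis),
            class = "composite_image")
}
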
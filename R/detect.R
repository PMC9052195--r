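# Probe detection: grayscale conversion, Gaussian/boxcar band-pass, and
# thresholded 3x3 local-maximum selection.

#' Detection parameters
#'
#' @param s_noise characteristic scale of the image noise, pixels
#'   (Gaussian kernel scale).
#' @param s_object characteristic scale of the probes, pixels (boxcar
#'   half-width).  Must exceed `s_noise`.
#' @param threshold_lambda relative threshold in (0, 1) applied to the
#'   global maximum of the band-passed image.
#' @return an object of class `detect_params`.
#' @export
detect_params <- function(s_noise = 1, s_object = 12, threshold_lambda = 0.3) {
  if (!(s_noise > 0 && s_object > s_noise)) {
    stop("need 0 < s_noise < s_object")
  }
  if (!(threshold_lambda > 0 && threshold_lambda < 1)) {
    stop("threshold_lambda must lie in (0, 1)")
  }
  structure(list(s_noise = s_noise, s_object = as.integer(round(s_object)),
                 threshold_lambda = threshold_lambda),
            class = "detect_params")
}

# reflect-pad a matrix by `k` pixels on every side
pad_reflect <- function(img, k) {
  if (k == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  if (k >= nr || k >= nc) stop("kernel too large for image")
  ridx <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  cidx <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  img[ridx, cidx, drop = FALSE]
}

# separable convolution with a symmetric 1-D kernel, reflect boundary
conv_separable <- function(img, kernel) {
  k <- (length(kernel) - 1L) / 2L
  p <- pad_reflect(img, k)
  nr <- nrow(img); nc <- ncol(img)
  tmp <- matrix(0, nr, nc + 2L * k)
  for (i in seq_along(kernel)) {
    tmp <- tmp + kernel[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_along(kernel)) {
    out <- out + kernel[i] * tmp[, (i - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

# unit-sum Gaussian kernel truncated at 3 standard deviations
gaussian_kernel <- function(s) {
  r <- max(1L, ceiling(3 * s))
  w <- dnorm(seq(-r, r), sd = s)
  w / sum(w)
}

#' Gaussian blur with unit-sum separable kernel (reflect boundary)
#' @param img numeric matrix.
#' @param s kernel scale in pixels.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(img, s) {
  conv_separable(img, gaussian_kernel(s))
}

#' Collapse a multi-channel frame to grayscale
#'
#' Sums the channel intensities pixelwise.
#' @param frame a list of numeric matrices (channels), e.g. one frame of
#'   an `image_stack`.
#' @return numeric matrix.
#' @export
to_grayscale <- function(frame) {
  stopifnot(is.list(frame), length(frame) >= 1)
  dims <- lapply(frame, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all channels must share the same shape")
  }
  Reduce(`+`, frame)
}

#' Band-pass filter a grayscale image
#'
#' Subtracts a boxcar smoothing at the object scale from a Gaussian
#' smoothing at the noise scale: `F = G(s_noise) - B(s_object)`.  Both
#' kernels are normalized to unit sum, so constant images map to zero and
#' flat background cancels exactly.
#'
#' @param gray numeric matrix.
#' @param params a [detect_params()].
#' @return filtered matrix of the same shape.
#' @export
bandpass <- function(gray, params = detect_params()) {
  stopifnot(is.matrix(gray), all(is.finite(gray)))
  side <- 2L * params$s_object + 1L
  if (side > min(dim(gray))) stop("s_object too large for this image")
  g <- conv_separable(gray, gaussian_kernel(params$s_noise))
  b <- conv_separable(gray, rep(1 / side, side))
  g - b
}

#' Locate particles as thresholded local maxima
#'
#' A pixel is a detection when it equals the 3x3 local-maximum filter of
#' the band-passed image and exceeds `threshold_lambda` times the global
#' maximum.  Equal-valued plateaus keep only their first pixel in
#' row-major order; detections within `s_object` of the border are flagged
#' in the `edge` column.
#'
#' @param filtered band-passed image from [bandpass()].
#' @param params a [detect_params()].
#' @return data frame with columns `row`, `col`, `value`, `edge`
#'   (1-based pixel coordinates, row-major order).
#' @export
find_particles <- function(filtered, params = detect_params()) {
  stopifnot(is.matrix(filtered), all(is.finite(filtered)))
  empty <- data.frame(row = integer(0), col = integer(0),
                      value = numeric(0), edge = logical(0))
  gmax <- max(filtered)
  # constant inputs band-pass to zero up to float epsilon; treat any
  # residual at that scale as featureless
  if (gmax <= 1e-8 * max(1, max(abs(filtered)))) return(empty)

  nr <- nrow(filtered); nc <- ncol(filtered)
  p <- pad_reflect(filtered, 1L)
  m <- filtered
  for (dr in 0:2) for (dc in 0:2) {
    m <- pmax(m, p[dr + seq_len(nr), dc + seq_len(nc)])
  }
  keep <- filtered == m & m > params$threshold_lambda * gmax
  idx <- which(t(keep))             # row-major order
  if (!length(idx)) return(empty)
  cols <- (idx - 1L) %% nc + 1L
  rows <- (idx - 1L) %/% nc + 1L

  # collapse plateaus: drop a candidate adjacent (8-neighbourhood) to an
  # already kept candidate with the same filter value
  sel <- logical(length(rows))
  for (i in seq_along(rows)) {
    dup <- FALSE
    if (any(sel)) {
      prev <- which(sel)
      dup <- any(abs(rows[prev] - rows[i]) <= 1 &
                 abs(cols[prev] - cols[i]) <= 1 &
                 filtered[cbind(rows[prev], cols[prev])] ==
                   filtered[rows[i], cols[i]])
    }
    sel[i] <- !dup
  }
  rows <- rows[sel]; cols <- cols[sel]
  edge <- rows <= params$s_object | rows > nr - params$s_object |
          cols <= params$s_object | cols > nc - params$s_object
  data.frame(row = rows, col = cols,
             value = filtered[cbind(rows, cols)], edge = edge)
}

#' Detect particles in every frame of an image stack
#'
#' @param stack an `image_stack` (list of frames, each a list of channel
#'   matrices).
#' @param params a [detect_params()].
#' @return data frame with columns `frame`, `row`, `col`, `value`, `edge`.
#' @export
detect_stack <- function(stack, params = detect_params()) {
  out <- lapply(seq_along(stack), function(t) {
    det <- find_particles(bandpass(to_grayscale(stack[[t]]), params), params)
    if (nrow(det)) cbind(frame = t, det) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), row = integer(0), col = integer(0),
                      value = numeric(0), edge = logical(0))
  }
  out
}
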
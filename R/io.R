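# Image-stack I/O: multi-page TIFF, channel-interleaved (green page then
# red page per frame), with a JSON sidecar carrying ground truth when the
# stack is synthetic.

#' Write an image stack as multi-page TIFF
#'
#' Pages are channel-interleaved (green, red, green, red, ...).
#' Intensities are stored as 16-bit samples scaled by `2^bit_depth - 1`;
#' a JSON sidecar (`<path>.json`) records the scaling and, for synthetic
#' stacks, the ground-truth positions and ratios.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @param bit_depth intensity scale used for quantization.
#' @return the path, invisibly.
#' @export
write_image_stack <- function(stack, path, bit_depth = 16) {
  cap <- 2^bit_depth - 1
  pages <- list()
  for (fr in stack) {
    pages[[length(pages) + 1L]] <- pmin(pmax(fr$green / cap, 0), 1)
    pages[[length(pages) + 1L]] <- pmin(pmax(fr$red / cap, 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  truth <- attr(stack, "truth")
  sidecar <- list(n_frames = length(stack), bit_depth = bit_depth,
                  channels = c("green", "red"))
  if (!is.null(truth)) {
    sidecar$truth <- list(positions = truth$positions,
                          ratios = truth$ratios)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path (the `<path>.json` sidecar is read when present).
#' @return an `image_stack`.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar_path <- paste0(path, ".json")
  bit_depth <- 16
  truth <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    bit_depth <- sc$bit_depth %||% 16
    if (!is.null(sc$truth)) {
      truth <- list(positions = as.data.frame(sc$truth$positions),
                    ratios = as.data.frame(sc$truth$ratios))
    }
  }
  cap <- 2^bit_depth - 1
  stopifnot(length(pages) %% 2 == 0)
  stack <- lapply(seq_len(length(pages) / 2), function(t) {
    list(green = pages[[2 * t - 1]] * cap, red = pages[[2 * t]] * cap)
  })
  structure(stack, class = "image_stack", truth = truth)
}
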
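# Stage 1: extract the implant cross-section from the micrograph background.
#
# Composition: grayscale -> global mean threshold (removes most background)
# -> Sobel edges of the thresholded grayscale -> sliding-window foreground
# classification (removes residual background) -> combination of the two
# masks -> morphological closing (fills pores and smooths the outline)
# -> largest connected component.

#' Default stage-1 parameters
#'
#' @param window,stride,edge_frac,min_edge_frac Sliding-window settings:
#'   window and stride in pixels; a pixel is a hard edge above
#'   `edge_frac * max(magnitude)`; a window is foreground with at least
#'   `min_edge_frac * window^2` hard-edge pixels.
#' @param close_radius,close_shape Structuring element of the final closing.
#'   The default radius (35 px) is about 0.6x the 600 um design pore at the
#'   default 10 um/px scale, large enough to fill empty pores into the
#'   implant footprint.
#' @param combine How the mean-threshold and sliding-window masks merge:
#'   `"intersect"` (default) or `"union"`.
#' @param sobel_on Whether Sobel runs on the mean-thresholded grayscale
#'   (`"thresholded"`, default) or the raw grayscale (`"grayscale"`).
#' @param local_mean Use local (adaptive) instead of global mean thresholding.
#' @param min_area_frac,max_area_frac Implant-area sanity band as fractions of
#'   the frame; outside it segmentation is declared failed.
#' @return Named list of stage-1 parameters.
#' @export
stage1_config <- function(window = 32L, stride = 16L, edge_frac = 0.25,
                          min_edge_frac = 0.02, close_radius = 35L,
                          close_shape = "disc",
                          combine = c("intersect", "union"),
                          sobel_on = c("thresholded", "grayscale"),
                          local_mean = FALSE,
                          min_area_frac = 0.01, max_area_frac = 0.99) {
  list(window = as.integer(window), stride = as.integer(stride),
       edge_frac = edge_frac, min_edge_frac = min_edge_frac,
       close_radius = as.integer(close_radius),
       close_shape = match.arg(close_shape, c("disc", "square")),
       combine = match.arg(combine), sobel_on = match.arg(sobel_on),
       local_mean = isTRUE(local_mean),
       min_area_frac = min_area_frac, max_area_frac = max_area_frac)
}

#' Segment the implant region from the background
#'
#' Runs the stage-1 operator chain and returns the implant mask together with
#' the parameters actually used. Fails loudly (naming the collapsed stage)
#' when any intermediate or the final mask is degenerate, i.e. covers less
#' than `min_area_frac` or more than `max_area_frac` of the frame.
#'
#' @param image Color or grayscale micrograph (matrix or 3-channel array,
#'   intensities in `[0, 1]`).
#' @param config Parameter list from [stage1_config()].
#' @return An object of class `implant_region`: list with logical `mask`,
#'   `area_px`, and `params`.
#' @export
segment_implant <- function(image, config = stage1_config()) {
  gray <- to_grayscale(image)
  check_grayscale01(gray)
  npx <- length(gray)
  fail <- function(stage, mask) {
    a <- sum(mask)
    if (a < config$min_area_frac * npx || a > config$max_area_frac * npx) {
      stop("segmentation failed: ", stage, " stage collapsed (mask area ",
           a, " of ", npx, " px)")
    }
  }

  mmask <- mean_threshold(gray, local = config$local_mean)
  fail("mean-threshold", mmask)

  edge_input <- if (config$sobel_on == "thresholded") gray * mmask else gray
  edges <- sobel_edges(edge_input)
  wmask <- sliding_window_classify(
    edges,
    window = config$window, stride = config$stride,
    edge_threshold = config$edge_frac * max(edges),
    min_edge_count = ceiling(config$min_edge_frac * config$window^2)
  )
  fail("sliding-window", wmask)

  comb <- if (config$combine == "intersect") mmask & wmask else mmask | wmask
  fail("mask-combination", comb)

  closed <- morphological_close(comb, config$close_radius, config$close_shape)
  mask <- largest_component(closed)
  fail("closing/largest-component", mask)

  structure(
    list(mask = mask, area_px = sum(mask), params = config),
    class = "implant_region"
  )
}

#' @export
print.implant_region <- function(x, ...) {
  cat(sprintf("implant region: %d px (%.1f%% of frame)\n",
              x$area_px, 100 * x$area_px / length(x$mask)))
  invisible(x)
}
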